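#' Write a volume as NIfTI with an explicit affine
#'
#' @param vol 3D or 4D numeric/integer array.
#' @param affine 4x4 voxel-to-world affine (1-based voxel indexing).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param pixdim4 Optional repetition time (s) for 4D volumes.
#' @return Invisibly, `path`.
#' @export
write_nifti_vol <- function(vol, affine, path, pixdim4 = NULL) {
  ## RNifti xforms map 0-based voxel indices; shift the translation.
  A0 <- affine
  A0[1:3, 4] <- affine[1:3, 4] + affine[1:3, 1:3] %*% rep(1, 3)
  img <- RNifti::asNifti(vol)
  img <- RNifti::`sform<-`(img, structure(A0, code = 2L))
  if (!is.null(pixdim4) && length(dim(vol)) == 4L)
    RNifti::pixdim(img)[4] <- pixdim4
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume and its affine
#'
#' @param path NIfTI file path.
#' @return List with `data` (array) and `affine` (4x4, 1-based voxel
#'   indexing convention used throughout the package).
#' @export
read_nifti_vol <- function(path) {
  img <- RNifti::readNifti(path)
  A0 <- RNifti::xform(img)
  A <- unclass(A0)
  attributes(A) <- list(dim = dim(A))
  A[1:3, 4] <- A[1:3, 4] - A[1:3, 1:3] %*% rep(1, 3)
  list(data = as.array(img), affine = A)
}

#' Write a table with provenance header
#'
#' Tab-separated table preceded by `#`-prefixed key-value metadata lines.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param meta Named character vector/list of metadata.
#' @return Invisibly, `path`.
#' @export
write_table_with_meta <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta))
    writeLines(paste0("# ", names(meta), ": ", unlist(meta)), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

## FNV-1a hash (64-bit arithmetic folded to 32) over a string; used to stamp
## outputs with a config fingerprint without external dependencies.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
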