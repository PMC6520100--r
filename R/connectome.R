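#' Extract mean parcel time series
#'
#' Averages the BOLD series over the member voxels of every kept parcel at
#' each timepoint. Parcels without voxels in the image grid yield a row of
#' NA, flagged in `empty`.
#'
#' @param image 4D numeric BOLD array.
#' @param parc A `parcellation` on the same grid.
#' @param tr_s Repetition time in seconds carried as metadata.
#' @return An object of class `parcel_timeseries`: `ts` (kept parcels x
#'   timepoints matrix), `ids`, `empty` (logical), `tr_s`.
#' @export
extract_timeseries <- function(image, parc, tr_s = NA_real_) {
  stopifnot(length(dim(image)) == 4L, inherits(parc, "parcellation"))
  if (!identical(dim(image)[1:3], dim(parc$labels)))
    stop("image grid does not match parcellation grid")
  kept <- parc$parcels$id[parc$parcels$kept]
  lab <- as.integer(parc$labels)
  N <- dim(image)[4]
  tsmat <- matrix(image, ncol = N)
  sel <- lab %in% kept
  sums <- rowsum(tsmat[sel, , drop = FALSE], lab[sel])
  cnt <- as.vector(rowsum(rep(1, sum(sel)), lab[sel]))
  got <- as.integer(rownames(sums))
  ts <- matrix(NA_real_, length(kept), N)
  m <- match(got, kept)
  ts[m, ] <- sums / cnt
  empty <- !(kept %in% got)
  if (any(empty))
    warning(sum(empty), " parcel(s) have no voxels in the image; rows ",
            "flagged as empty")
  structure(list(ts = ts, ids = kept, empty = empty, tr_s = tr_s),
            class = "parcel_timeseries")
}

## Ledoit-Wolf-style shrinkage of the sample covariance toward a scaled
## identity target; returns the shrunk covariance. X is T x p (observations
## in rows, centred internally).
shrink_covariance <- function(X) {
  T_ <- nrow(X); p <- ncol(X)
  X <- scale(X, center = TRUE, scale = FALSE)
  S <- crossprod(X) / T_
  mu <- mean(diag(S))
  d2 <- sum((S - mu * diag(p))^2)
  if (d2 <= 0) return(S)
  xs2 <- rowSums(X^2)
  xSx <- rowSums((X %*% S) * X)
  b2 <- sum(xs2^2 - 2 * xSx + sum(S^2)) / T_^2
  lambda <- min(1, max(0, b2 / d2))
  (1 - lambda) * S + lambda * mu * diag(p)
}

#' Build a weighted functional connectome
#'
#' Computes statistical dependencies between parcel time series as a
#' symmetric non-negative weighted adjacency matrix. Methods:
#' \describe{
#'   \item{pearson}{Product-moment correlation.}
#'   \item{partial}{Pairwise correlation conditioned on all other parcels,
#'     from the inverse of a shrinkage-regularised covariance (identity
#'     target), which keeps the estimate well-conditioned when the number
#'     of parcels approaches the number of timepoints.}
#'   \item{wavelet}{Pearson correlation of MODWT detail coefficients at the
#'     requested scale (default scale 2).}
#' }
#' Negative correlations are set to 0 (edge absent); no further
#' thresholding is applied, so matrices remain fully connected in the
#' sense of retaining every non-negative edge. Constant rows produce
#' undefined correlations, set to 0 with a warning.
#'
#' @param ts A [extract_timeseries()] result (at least 3 parcels and 8
#'   timepoints).
#' @param method One of `"pearson"`, `"partial"`, `"wavelet"`.
#' @param scale Wavelet scale (required for `method = "wavelet"`).
#' @param wavelet Wavelet family for the wavelet method.
#' @return An object of class `connectome`: `weights` (symmetric matrix in
#'   `[0, 1]`, zero diagonal), `method`, `scale`, `ids`.
#' @export
connectivity <- function(ts, method = c("pearson", "partial", "wavelet"),
                         scale = NULL, wavelet = "db8") {
  stopifnot(inherits(ts, "parcel_timeseries"))
  method <- match.arg(method)
  X <- ts$ts[!ts$empty, , drop = FALSE]
  ids <- ts$ids[!ts$empty]
  if (nrow(X) < 3L) stop("need at least 3 non-empty parcels")
  if (ncol(X) < 8L) stop("need at least 8 timepoints")
  if (method == "wavelet") {
    if (is.null(scale)) scale <- 2L
    n_levels <- max(2L, as.integer(scale))
    if (ncol(X) < 2^n_levels)
      stop("series too short for wavelet scale ", scale)
    pyr <- modwt_pyramid(t(X), wavelet, n_levels)
    X <- t(pyr$W[[as.integer(scale)]])
  } else if (method == "pearson") {
    scale <- NA_integer_
  }
  if (method == "partial") {
    scale <- NA_integer_
    sds <- apply(X, 1, stats::sd)
    const <- sds == 0
    C <- matrix(0, nrow(X), nrow(X))
    use <- which(!const)
    if (length(use) >= 2L) {
      S <- shrink_covariance(t(X[use, , drop = FALSE]))
      P <- solve(S)
      D <- sqrt(diag(P))
      pc <- -P / outer(D, D)
      diag(pc) <- 0
      C[use, use] <- pc
    }
    if (any(const))
      warning(sum(const), " constant parcel series; their partial ",
              "correlations set to 0")
  } else {
    sds <- apply(X, 1, stats::sd)
    const <- sds == 0
    C <- suppressWarnings(stats::cor(t(X)))
    if (any(const)) {
      warning(sum(const), " constant parcel series; their correlations ",
              "set to 0")
      C[const, ] <- 0
      C[, const] <- 0
    }
    C[is.na(C)] <- 0
    diag(C) <- 0
  }
  W <- pmax(C, 0)
  W <- (W + t(W)) / 2
  W <- pmin(W, 1)
  diag(W) <- 0
  dimnames(W) <- list(ids, ids)
  structure(list(weights = W, method = method,
                 scale = if (method == "wavelet") as.integer(scale)
                         else NA_integer_,
                 ids = ids),
            class = "connectome")
}

#' Write / read a connectome matrix
#'
#' Delimited square table with a `#`-prefixed metadata header; the
#' round-trip preserves weights to full double precision.
#'
#' @param conn A `connectome`.
#' @param path Output path.
#' @return `write_connectome` invisibly returns `path`;
#'   `read_connectome` returns the `connectome`.
#' @export
write_connectome <- function(conn, path) {
  stopifnot(inherits(conn, "connectome"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# method: ", conn$method),
               paste0("# scale: ", conn$scale),
               paste0("# ids: ", paste(conn$ids, collapse = ","))), con)
  utils::write.table(format(conn$weights, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(paste0("^# ", key, ": "), "",
                           grep(paste0("^# ", key, ":"), hdr, value = TRUE))
  W <- unname(as.matrix(utils::read.table(text = lines[!grepl("^#", lines)],
                                          sep = "\t")))
  ids <- as.integer(strsplit(get("ids"), ",")[[1]])
  dimnames(W) <- list(ids, ids)
  structure(list(weights = W, method = get("method"),
                 scale = suppressWarnings(as.integer(get("scale"))),
                 ids = ids),
            class = "connectome")
}
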