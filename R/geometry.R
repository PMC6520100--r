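## World-coordinate helpers. Volumes are plain 3D/4D arrays accompanied by a
## 4x4 voxel-to-world affine (1-based voxel index -> mm). The phantom affine
## centres the grid so the mid-sagittal plane is world x = 0.

#' Build a centred scaling affine
#'
#' Voxel-to-world affine mapping 1-based index `(i, j, k)` to mm with the
#' grid centred on the world origin, so the mid-sagittal plane (world
#' `x = 0`) lies midway along the first axis.
#'
#' @param grid_shape Integer vector of 3 grid dimensions.
#' @param voxel_size_mm Voxel edge length(s) in mm (scalar or length 3).
#' @return 4x4 affine matrix.
#' @export
centered_affine <- function(grid_shape, voxel_size_mm) {
  vs <- rep_len(voxel_size_mm, 3L)
  A <- diag(4)
  A[cbind(1:3, 1:3)] <- vs
  A[1:3, 4] <- -vs * (grid_shape + 1) / 2
  A
}

voxel_spacing <- function(affine) sqrt(colSums(affine[1:3, 1:3]^2))

## World coordinates (n x 3) of 1-based voxel linear indices.
voxel_world <- function(idx, dim3, affine) {
  ijk <- arrayInd(idx, dim3)
  t(affine[1:3, 1:3] %*% t(ijk) + affine[1:3, 4])
}

world_to_index <- function(xyz, dim3, affine) {
  ijk <- t(solve(affine[1:3, 1:3]) %*% (t(xyz) - affine[1:3, 4]))
  ijk <- round(ijk)
  bad <- ijk[, 1] < 1 | ijk[, 1] > dim3[1] |
         ijk[, 2] < 1 | ijk[, 2] > dim3[2] |
         ijk[, 3] < 1 | ijk[, 3] > dim3[3]
  lin <- rep(NA_integer_, nrow(ijk))
  if (any(!bad))
    lin[!bad] <- as.integer((ijk[!bad, 3] - 1) * dim3[1] * dim3[2] +
                            (ijk[!bad, 2] - 1) * dim3[1] + ijk[!bad, 1])
  lin
}

## --- Exact Euclidean distance transform (squared), separable lower-envelope
## --- algorithm, with per-axis sample spacing so distances are metric (mm).

edt_1d <- function(f, s) {
  n <- length(f)
  BIG <- 1e300
  if (!any(f < BIG)) return(f)
  d <- numeric(n)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -BIG; z[2L] <- BIG
  s2 <- s * s
  for (q in 2:n) {
    fq <- f[q]
    repeat {
      p <- v[k]
      inter <- ((fq + s2 * q * q) - (f[p] + s2 * p * p)) / (2 * s2 * (q - p))
      if (inter <= z[k]) { k <- k - 1L; if (k == 0L) break } else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- inter
    z[k + 1L] <- BIG
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    p <- v[k]
    d[q] <- s2 * (q - p)^2 + f[p]
  }
  d
}

edt_pass <- function(D2, axis, s) {
  dims <- dim(D2)
  perm <- c(axis, setdiff(1:3, axis))
  M <- aperm(D2, perm)
  dm <- dim(M)
  M <- matrix(M, nrow = dm[1])
  for (col in seq_len(ncol(M))) M[, col] <- edt_1d(M[, col], s)
  M <- array(M, dm)
  aperm(M, order(perm))
}

#' Euclidean distance transform in millimetres
#'
#' Exact distance from every voxel centre to the nearest `TRUE` voxel centre
#' of `mask`, computed with the separable squared-distance lower-envelope
#' algorithm; anisotropic voxels are handled through the affine's column
#' norms so distances are metric.
#'
#' @param mask 3D logical array (non-empty).
#' @param affine 4x4 voxel-to-world affine.
#' @return 3D numeric array of distances in mm (0 inside the mask).
#' @export
distance_transform_mm <- function(mask, affine) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (!any(mask)) stop("mask is empty")
  vs <- voxel_spacing(affine)
  D2 <- array(ifelse(mask, 0, 1e300), dim(mask))
  for (axis in 1:3) D2 <- edt_pass(D2, axis, vs[axis])
  sqrt(D2)
}

#' Mirror a mask across the mid-sagittal plane
#'
#' Reflects a binary mask across world `x = 0` (the interhemispheric
#' fissure of a bilaterally symmetric reference space) by nearest-voxel
#' lookup: each `TRUE` voxel maps to the voxel whose centre is nearest
#' world `(-x, y, z)`. On a grid symmetric about `x = 0` the operation is an
#' exact involution. Voxels whose reflection falls outside the grid are
#' dropped.
#'
#' @param mask 3D logical array.
#' @param affine 4x4 voxel-to-world affine (required).
#' @return 3D logical array of the same shape.
#' @export
mirror_mask <- function(mask, affine) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (missing(affine) || is.null(affine)) stop("'affine' is required")
  out <- array(FALSE, dim(mask))
  idx <- which(mask)
  if (!length(idx)) return(out)
  xyz <- voxel_world(idx, dim(mask), affine)
  xyz[, 1] <- -xyz[, 1]
  tgt <- world_to_index(xyz, dim(mask), affine)
  out[tgt[!is.na(tgt)]] <- TRUE
  out
}

## Voxel-averaged world centroid of a mask (mm).
mask_centroid <- function(mask, affine) {
  idx <- which(mask)
  if (!length(idx)) stop("mask is empty")
  colMeans(voxel_world(idx, dim(mask), affine))
}
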