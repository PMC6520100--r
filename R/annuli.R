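#' Peritumoral 2-mm annuli
#'
#' Dilates a binary tumor mask outward in fixed metric increments and
#' subtracts successive dilations, producing a series of disjoint annuli
#' ("tumor rims") expanding from the tumor margin. Annulus `k` contains
#' exactly the voxels whose Euclidean distance (mm, voxel-centre to nearest
#' tumor voxel centre, anisotropy-aware) lies in `((k-1)*step, k*step]`.
#'
#' @param tumor 3D logical tumor mask (non-empty).
#' @param affine 4x4 voxel-to-world affine.
#' @param step_mm Annulus thickness in mm (default 2).
#' @param max_mm Outer extent of the dilation band in mm (default 30).
#' @return An object of class `annulus_series`: list of logical masks
#'   (`annuli`), `inner_edges_mm`, `step_mm`, `max_mm`.
#' @export
dilate_annuli <- function(tumor, affine, step_mm = 2, max_mm = 30) {
  stopifnot(is.logical(tumor), length(dim(tumor)) == 3L)
  if (!any(tumor)) stop("tumor mask is empty")
  if (step_mm <= 0 || max_mm < step_mm)
    stop("'step_mm' must be positive and 'max_mm' >= 'step_mm'")
  d <- distance_transform_mm(tumor, affine)
  inner <- seq(0, max_mm - step_mm, by = step_mm)
  annuli <- lapply(inner, function(lo) {
    d > lo & d <= lo + step_mm & !tumor
  })
  structure(list(annuli = annuli, inner_edges_mm = inner,
                 step_mm = step_mm, max_mm = max_mm,
                 tumor = tumor, affine = affine),
            class = "annulus_series")
}

#' Restrict annuli to grey matter
#'
#' Intersects every annulus with a grey-matter mask; annuli left empty are
#' retained (with zero voxels) so band indexing is stable.
#'
#' @param annuli An [dilate_annuli()] series.
#' @param gm 3D logical grey-matter mask on the same grid.
#' @return The restricted `annulus_series`.
#' @export
restrict_to_gm <- function(annuli, gm) {
  stopifnot(inherits(annuli, "annulus_series"), is.logical(gm))
  if (!identical(dim(gm), dim(annuli$annuli[[1]])))
    stop("grey-matter mask grid does not match annulus grid")
  annuli$annuli <- lapply(annuli$annuli, function(a) a & gm)
  annuli$gm_restricted <- TRUE
  annuli
}

#' Homologous-region Hurst gradient profile
#'
#' For each (grey-matter-restricted) annulus, averages the valid Hurst
#' values ipsilaterally and in the annulus reflected across the
#' interhemispheric fissure, and expresses the peritumoral effect as the
#' ratio of H in homologous regions. Bands with no valid voxels on either
#' side yield an undefined (NA) ratio. Midline tumors, whose mask overlaps
#' its own mirror image, are not supported.
#'
#' @param hmap A [hurst_map()].
#' @param annuli An [dilate_annuli()] series (GM-restricted).
#' @param affine 4x4 voxel-to-world affine.
#' @return An object of class `gradient_profile`: a data frame with columns
#'   `distance_mm` (band midpoint), `mean_h_ipsi`, `mean_h_contra`, `ratio`,
#'   `n_voxels`.
#' @export
gradient_profile <- function(hmap, annuli, affine) {
  stopifnot(inherits(hmap, "hurst_map"), inherits(annuli, "annulus_series"))
  if (!identical(dim(hmap$values), dim(annuli$annuli[[1]])))
    stop("Hurst map grid does not match annulus grid")
  if (any(annuli$tumor & mirror_mask(annuli$tumor, affine)))
    stop("tumor mask overlaps its own mirror image; midline tumors are ",
         "not supported by the homologous-region analysis")
  vals <- hmap$values
  vals[!hmap$validity] <- NA_real_
  rows <- lapply(seq_along(annuli$annuli), function(k) {
    a <- annuli$annuli[[k]]
    m <- mirror_mask(a, affine)
    hi <- vals[a]; hc <- vals[m]
    hi <- hi[!is.na(hi)]; hc <- hc[!is.na(hc)]
    mean_i <- if (length(hi)) mean(hi) else NA_real_
    mean_c <- if (length(hc)) mean(hc) else NA_real_
    ratio <- if (!is.na(mean_i) && !is.na(mean_c) && mean_c != 0)
      mean_i / mean_c else NA_real_
    data.frame(distance_mm = annuli$inner_edges_mm[k] + annuli$step_mm / 2,
               mean_h_ipsi = mean_i, mean_h_contra = mean_c,
               ratio = ratio, n_voxels = length(hi))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("gradient_profile", "data.frame")
  out
}
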