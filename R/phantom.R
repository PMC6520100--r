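#' Phantom cohort specification
#'
#' Parameters of the synthetic bilateral "brain" used to exercise every
#' pipeline stage without patient data. The phantom consists of two mirrored
#' cortical slabs separated by a mid-sagittal CSF gap, a white-matter slab,
#' and a spherical tumor implanted in right-hemisphere grey matter. Each
#' grey-matter voxel carries exact fractional Gaussian noise whose Hurst
#' exponent follows a quadratic profile of distance from the tumor margin
#' ipsilaterally (`H(d) = a + b d + c d^2`, clipped to (0.05, 0.95), up to
#' `gradient_extent_mm`, baseline beyond) and the baseline value
#' contralaterally.
#'
#' Defaults mirror the acquisition being emulated (269 volumes at
#' TR = 2.42 s) and implant a suppression-then-overshoot profile: trough
#' `H(0) = 0.632` at the tumor margin, baseline crossings at 12 and 28 mm,
#' peak `H(20) = 0.832`, against a contralateral baseline of 0.8.
#'
#' @param grid_shape 3 positive integers (default `c(48, 40, 40)`).
#' @param voxel_size_mm Isotropic voxel size in mm (default 2).
#' @param n_timepoints Time points per voxel series (default 269).
#' @param tr_s Repetition time in seconds (default 2.42).
#' @param tumor_center_mm Tumor centre in world mm (default `c(37, 0, 0)`,
#'   right hemisphere).
#' @param tumor_radius_mm Tumor sphere radius in mm (default 6).
#' @param h_baseline Contralateral / far-field grey-matter Hurst exponent
#'   (default 0.8).
#' @param h_quad_coeffs Quadratic profile coefficients `c(a, b, c)` of
#'   `H(d) = a + b d + c d^2` (default `c(0.632, 0.02, -5e-4)`).
#' @param gradient_extent_mm Distance beyond which ipsilateral grey matter
#'   reverts to `h_baseline` (default 30).
#' @param n_subjects Number of subjects to generate (default 11).
#' @param seed Base RNG seed; subject `i` uses `seed + i`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48L, 40L, 40L),
                         voxel_size_mm = 2,
                         n_timepoints = 269L,
                         tr_s = 2.42,
                         tumor_center_mm = c(37, 0, 0),
                         tumor_radius_mm = 6,
                         h_baseline = 0.8,
                         h_quad_coeffs = c(0.632, 0.02, -5e-4),
                         gradient_extent_mm = 30,
                         n_subjects = 11L,
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8),
            voxel_size_mm > 0, n_timepoints >= 32, tr_s > 0,
            length(tumor_center_mm) == 3L, tumor_radius_mm > 0,
            h_baseline > 0, h_baseline < 1,
            length(h_quad_coeffs) == 3L, gradient_extent_mm > 0,
            n_subjects >= 1)
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm,
                 n_timepoints = as.integer(n_timepoints), tr_s = tr_s,
                 tumor_center_mm = tumor_center_mm,
                 tumor_radius_mm = tumor_radius_mm,
                 h_baseline = h_baseline, h_quad_coeffs = h_quad_coeffs,
                 gradient_extent_mm = gradient_extent_mm,
                 n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

## Fixed non-GM tissue Hurst values (distinct from the GM gradient so tissue
## contrasts are testable) and segmentation label codes.
PHANTOM_H_WM <- 0.65
PHANTOM_H_CSF <- 0.5
PHANTOM_H_TUMOR <- 0.3
SEG_CSF <- 1L; SEG_GM <- 2L; SEG_WM <- 3L; SEG_TUMOR <- 4L

## Deterministic anatomy shared by all subjects of a spec: segmentation,
## tumor mask, and ground-truth H volume.
phantom_anatomy <- function(spec) {
  dim3 <- spec$grid_shape
  affine <- centered_affine(dim3, spec$voxel_size_mm)
  xyz <- voxel_world(seq_len(prod(dim3)), dim3, affine)
  x <- xyz[, 1]; y <- xyz[, 2]; z <- xyz[, 3]
  ext <- (dim3 * spec$voxel_size_mm) / 2   # half-extents in mm
  gap <- 1.5 * spec$voxel_size_mm          # CSF half-gap at the midline
  bx <- ext[1] - 2.5 * spec$voxel_size_mm  # hemisphere outer margin
  by <- ext[2] - 2.5 * spec$voxel_size_mm
  bz <- ext[3] - 2.5 * spec$voxel_size_mm
  wm_top <- -by + 0.3 * 2 * by             # WM occupies the lower y band
  in_hemi <- abs(x) >= gap & abs(x) <= bx & abs(y) <= by & abs(z) <= bz
  seg <- integer(prod(dim3))
  seg[abs(x) < gap & abs(y) <= by & abs(z) <= bz] <- SEG_CSF
  seg[in_hemi & y <= wm_top] <- SEG_WM
  seg[in_hemi & y > wm_top] <- SEG_GM
  d2tum <- sqrt((x - spec$tumor_center_mm[1])^2 +
                (y - spec$tumor_center_mm[2])^2 +
                (z - spec$tumor_center_mm[3])^2)
  tumor <- d2tum <= spec$tumor_radius_mm
  if (spec$tumor_center_mm[1] - spec$tumor_radius_mm <= gap)
    stop("tumor sphere crosses the midline; lateralised tumors only")
  if (any(tumor & seg != SEG_GM))
    stop("tumor sphere is not fully inside right-hemisphere grey matter; ",
         "adjust tumor_center_mm/tumor_radius_mm")
  seg[tumor] <- SEG_TUMOR
  seg <- array(seg, dim3)
  tumor <- array(tumor, dim3)
  ## Ground-truth H field.
  dist_mm <- distance_transform_mm(tumor, affine)
  a <- spec$h_quad_coeffs[1]; b <- spec$h_quad_coeffs[2]
  cc <- spec$h_quad_coeffs[3]
  d <- as.vector(dist_mm)
  h_grad <- pmin(0.95, pmax(0.05, a + b * d + cc * d^2))
  truth <- array(NA_real_, dim3)
  gm <- seg == SEG_GM
  ipsi <- gm & array(x > 0, dim3)
  truth[gm] <- spec$h_baseline
  sel <- ipsi & array(d <= spec$gradient_extent_mm, dim3)
  truth[sel] <- h_grad[sel]
  truth[seg == SEG_WM] <- PHANTOM_H_WM
  truth[seg == SEG_CSF] <- PHANTOM_H_CSF
  truth[seg == SEG_TUMOR] <- PHANTOM_H_TUMOR
  list(affine = affine, segmentation = seg, tumor = tumor, truth_h = truth)
}

#' Simulate one phantom subject
#'
#' Generates the 4D BOLD array for a subject: every voxel with a defined
#' ground-truth Hurst exponent receives an exact fGn series with that H
#' (voxels are grouped by H rounded to 0.001 and batch-simulated);
#' background voxels are zero.
#'
#' @param spec A [phantom_spec()].
#' @param subject Subject index in `1:spec$n_subjects`.
#' @return A list (class `phantom_subject`) with `bold` (4D array),
#'   `affine`, `segmentation` (3D integer: 1 CSF, 2 GM, 3 WM, 4 tumor),
#'   `tumor` (3D logical), `truth_h` (3D), `tr_s`, `subject`, `seed`.
#' @export
simulate_phantom_subject <- function(spec, subject = 1L) {
  stopifnot(inherits(spec, "phantom_spec"),
            subject >= 1L, subject <= spec$n_subjects)
  anat <- phantom_anatomy(spec)
  dim3 <- spec$grid_shape
  N <- spec$n_timepoints
  bold <- matrix(0, prod(dim3), N)
  hv <- round(as.vector(anat$truth_h), 3)
  with_preserved_rng({
    set.seed(spec$seed + as.integer(subject))
    for (h in sort(unique(hv[!is.na(hv)]))) {
      idx <- which(!is.na(hv) & hv == h)
      ## chunk very large batches to bound memory
      for (s in seq(1L, length(idx), by = 8192L)) {
        ii <- idx[s:min(s + 8191L, length(idx))]
        bold[ii, ] <- t(fgn_draw_matrix(h, N, length(ii)))
      }
    }
  })
  structure(list(bold = array(bold, c(dim3, N)), affine = anat$affine,
                 segmentation = anat$segmentation, tumor = anat$tumor,
                 truth_h = anat$truth_h, tr_s = spec$tr_s,
                 subject = as.integer(subject),
                 seed = spec$seed + as.integer(subject)),
            class = "phantom_subject")
}

#' Simulate a phantom cohort
#'
#' @param spec A [phantom_spec()].
#' @return List of [simulate_phantom_subject()] results, length
#'   `spec$n_subjects`.
#' @export
simulate_phantom_cohort <- function(spec) {
  lapply(seq_len(spec$n_subjects), function(i)
    simulate_phantom_subject(spec, i))
}

#' Write a phantom subject to NIfTI
#'
#' Writes the 4D BOLD volume plus 3D segmentation, tumor mask, and
#' ground-truth H volume, all sharing one affine, and a plain-text snapshot
#' of the generating spec.
#'
#' @param subject A `phantom_subject`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix (default `"sub-<k>"`).
#' @return Invisibly, the vector of files written.
#' @export
write_phantom_subject <- function(subject, dir,
                                  prefix = sprintf("sub-%02d",
                                                   subject$subject)) {
  stopifnot(inherits(subject, "phantom_subject"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(prefix, "_",
    c("bold.nii.gz", "seg.nii.gz", "tumor.nii.gz", "truthH.nii.gz")))
  write_nifti_vol(subject$bold, subject$affine, paths[1],
                  pixdim4 = subject$tr_s)
  write_nifti_vol(subject$segmentation, subject$affine, paths[2])
  write_nifti_vol(subject$tumor * 1L, subject$affine, paths[3])
  tr <- subject$truth_h
  tr[is.na(tr)] <- 0
  write_nifti_vol(tr, subject$affine, paths[4])
  invisible(paths)
}
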