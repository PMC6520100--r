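#' Map a log2 wavelet-variance slope to a Hurst exponent
#'
#' The regression slope `gamma` of log2 wavelet variance on scale index
#' relates to the Hurst exponent by `H = (gamma + 1) / 2`: a flat spectrum
#' (`gamma = 0`) is white noise with `H = 0.5`, and persistent long-range
#' correlated signals have positive slopes.
#'
#' @param gamma Fitted slope of log2 variance versus scale index.
#' @return Hurst exponent `(gamma + 1) / 2`.
#' @export
hurst_from_slope <- function(gamma) (gamma + 1) / 2

#' Fractal dimension from a Hurst exponent
#'
#' For a self-affine time series the fractal (roughness) dimension is
#' `D = 2 - H`.
#'
#' @param hurst Hurst exponent.
#' @return Fractal dimension.
#' @export
fractal_dimension <- function(hurst) 2 - hurst

#' Estimator configuration
#'
#' @param wavelet Wavelet family passed to [modwt()] (default `"db8"`).
#' @param n_levels Number of wavelet scales entering the regression
#'   (default 5). Automatically reduced, with a warning, when the series is
#'   too short.
#' @param threshold Hurst threshold below which voxels are marked invalid in
#'   maps (default 0.5, the white-noise reference).
#' @return A list of class `hurst_config`.
#' @export
hurst_config <- function(wavelet = "db8", n_levels = 5L, threshold = 0.5) {
  structure(list(wavelet = wavelet, n_levels = as.integer(n_levels),
                 threshold = threshold),
            class = "hurst_config")
}

## OLS of y on x returning slope, intercept, r.squared; assumes length >= 2.
ols_line <- function(x, y) {
  xm <- mean(x); ym <- mean(y)
  sxx <- sum((x - xm)^2)
  slope <- sum((x - xm) * (y - ym)) / sxx
  res <- y - ym - slope * (x - xm)
  tss <- sum((y - ym)^2)
  r2 <- if (tss > 0) max(0, 1 - sum(res^2) / tss) else 0
  list(slope = slope, intercept = ym - slope * xm, r_squared = r2)
}

#' Estimate the Hurst exponent of a time series
#'
#' Wavelet-based estimator: the series is decomposed with a shift-invariant
#' MODWT, the per-scale (boundary-free, unbiased) wavelet variance is
#' computed, and an ordinary least-squares line is fitted to log2 variance
#' as a function of scale index. The slope `gamma` gives `H = (gamma + 1)/2`
#' and the fractal dimension `D = 2 - H`.
#'
#' Degenerate input (zero variance, or fewer than two usable scales) yields
#' a result with `valid = FALSE` rather than an error; non-finite input is
#' an error.
#'
#' @param series Finite numeric vector, length at least 32.
#' @param config A [hurst_config()].
#' @return An object of class `hurst_fit` with fields `hurst`, `slope`,
#'   `fractal_dim`, `per_scale_log_var` (data frame of scale and log2
#'   variance), `r_squared`, and `valid`.
#' @examples
#' fit <- estimate_hurst(simulate_fgn(fgn_spec(0.7, 1024, seed = 1)))
#' fit$hurst
#' @export
estimate_hurst <- function(series, config = hurst_config()) {
  if (!is.numeric(series) || anyNA(series) || any(!is.finite(series)))
    stop("'series' must be a finite numeric vector")
  if (length(series) < 32L) stop("series must have at least 32 samples")
  n_levels <- config$n_levels
  max_lev <- max_modwt_level(length(series))
  if (n_levels > max_lev) {
    warning("series length ", length(series), " supports only ", max_lev,
            " levels; reducing from ", n_levels)
    n_levels <- max_lev
  }
  invalid <- function() structure(
    list(hurst = NA_real_, slope = NA_real_, fractal_dim = NA_real_,
         per_scale_log_var = data.frame(scale = integer(), log2_variance =
                                          numeric()),
         r_squared = NA_real_, valid = FALSE),
    class = "hurst_fit")
  if (stats::var(series) == 0) return(invalid())
  dec <- modwt(series, wavelet = config$wavelet, n_levels = n_levels)
  wv <- suppressWarnings(wavelet_variance(dec))
  wv <- wv[is.finite(wv$variance) & wv$variance > 0, , drop = FALSE]
  if (is.null(wv) || nrow(wv) < 2L) return(invalid())
  fit <- ols_line(wv$scale, log2(wv$variance))
  h <- hurst_from_slope(fit$slope)
  structure(
    list(hurst = h, slope = fit$slope, fractal_dim = fractal_dimension(h),
         per_scale_log_var = data.frame(scale = wv$scale,
                                        log2_variance = log2(wv$variance)),
         r_squared = fit$r_squared, valid = TRUE),
    class = "hurst_fit"
  )
}

#' @export
print.hurst_fit <- function(x, ...) {
  cat("Wavelet Hurst fit: H =", format(x$hurst, digits = 4),
      " D =", format(x$fractal_dim, digits = 4),
      " slope =", format(x$slope, digits = 4),
      " R2 =", format(x$r_squared, digits = 3),
      if (!x$valid) " [INVALID]" else "", "\n")
  invisible(x)
}

#' Voxelwise Hurst exponent map
#'
#' Applies [estimate_hurst()] to every voxel time series inside a mask and
#' thresholds the result: voxels with `H < threshold` (default 0.5, i.e.
#' indistinguishable from white noise) or with a degenerate fit are marked
#' invalid. Invalid voxels keep their estimated value in `values` but are
#' excluded from any downstream averaging via the `validity` grid.
#'
#' @param image 4D numeric array (x, y, z, time) of BOLD data.
#' @param mask 3D logical array on the same grid; voxels outside are NA.
#' @param config A [hurst_config()].
#' @return An object of class `hurst_map`: `values` (3D array, NA outside
#'   mask), `validity` (3D logical), and `threshold`.
#' @export
hurst_map <- function(image, mask, config = hurst_config()) {
  stopifnot(length(dim(image)) == 4L, is.logical(mask))
  if (!identical(dim(image)[1:3], dim(mask)))
    stop("mask grid ", paste(dim(mask), collapse = "x"),
         " does not match image grid ",
         paste(dim(image)[1:3], collapse = "x"))
  vox <- which(mask)
  if (!length(vox)) stop("mask is empty")
  N <- dim(image)[4]
  n_levels <- config$n_levels
  max_lev <- max_modwt_level(N)
  if (n_levels > max_lev) {
    warning("time dimension ", N, " supports only ", max_lev,
            " levels; reducing from ", n_levels)
    n_levels <- max_lev
  }
  nvox3 <- prod(dim(mask))
  tsmat <- matrix(image, nrow = nvox3, ncol = N)
  values <- array(NA_real_, dim(mask))
  valid <- array(FALSE, dim(mask))
  chunk <- 4096L
  for (start in seq(1L, length(vox), by = chunk)) {
    idx <- vox[start:min(start + chunk - 1L, length(vox))]
    X <- t(tsmat[idx, , drop = FALSE])        # N x m
    vm <- modwt_variance_matrix(X, config$wavelet, n_levels)  # J x m
    usable <- is.finite(vm) & vm > 0
    scales <- seq_len(n_levels)
    h <- rep(NA_real_, length(idx))
    ok <- colSums(usable) >= 2L
    ## Fast path: voxels where every globally-usable scale is usable
    ## (scales that are all-boundary at this series length are NA for all
    ## voxels; per-voxel drops beyond that are rare degenerate cases).
    gscale <- which(rowSums(usable) > 0)
    fast <- ok & colSums(usable[gscale, , drop = FALSE]) == length(gscale)
    if (any(fast)) {
      y <- log2(vm[gscale, fast, drop = FALSE])
      x <- gscale
      xc <- x - mean(x)
      slope <- colSums(y * xc) / sum(xc^2)
      h[fast] <- hurst_from_slope(slope)
    }
    slow <- which(ok & !fast)
    for (i in slow) {
      u <- usable[, i]
      fit <- ols_line(scales[u], log2(vm[u, i]))
      h[i] <- hurst_from_slope(fit$slope)
    }
    values[idx] <- h
    valid[idx] <- !is.na(h) & h >= config$threshold
  }
  structure(list(values = values, validity = valid,
                 threshold = config$threshold),
            class = "hurst_map")
}
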