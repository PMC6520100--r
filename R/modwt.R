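## Daubechies "db8" scaling filter (16 taps, 8 vanishing moments), natural
## order, sum = sqrt(2). The wavelet filter is derived by quadrature mirror.
db8_scaling <- c(
  0.054415842243104008, 0.31287159091429995, 0.67563073629728976,
  0.58535468365420673, -0.015829105256349306, -0.28401554296154691,
  0.00047248457391328279, 0.12874742662047847, -0.017369301001807547,
  -0.044088253930794755, 0.013981027917398282, 0.0087460940474057766,
  -0.0048703529934515741, -0.00039174037337694705, 0.00067544940645056933,
  -0.00011747678412476953
)

wavelet_filters <- function(wavelet = "db8") {
  g <- switch(wavelet,
    db8 = db8_scaling,
    haar = c(1, 1) / sqrt(2),
    stop("unknown wavelet '", wavelet, "' (available: db8, haar)")
  )
  L <- length(g)
  h <- (-1)^(seq_len(L) - 1) * rev(g)   # quadrature mirror wavelet filter
  list(g = g / sqrt(2), h = h / sqrt(2), L = L)   # MODWT rescaling
}

## Width of the level-j equivalent filter; coefficients with index < Lj are
## influenced by the circular boundary.
modwt_filter_width <- function(L, j) as.integer((2^j - 1) * (L - 1) + 1)

max_modwt_level <- function(n) max(0L, floor(log2(n)))

## Core pyramid: X is an N x m matrix (series in columns). Returns a list of
## detail-coefficient matrices per level plus the final smooth.
modwt_pyramid <- function(X, wavelet, n_levels) {
  f <- wavelet_filters(wavelet)
  N <- nrow(X)
  V <- X
  W <- vector("list", n_levels)
  idx0 <- 0:(N - 1L)
  for (j in seq_len(n_levels)) {
    shift <- 2^(j - 1L)
    Wj <- matrix(0, N, ncol(X))
    Vj <- matrix(0, N, ncol(X))
    for (l in seq_len(f$L)) {
      rows <- ((idx0 - (l - 1L) * shift) %% N) + 1L
      Wj <- Wj + f$h[l] * V[rows, , drop = FALSE]
      Vj <- Vj + f$g[l] * V[rows, , drop = FALSE]
    }
    W[[j]] <- Wj
    V <- Vj
  }
  list(W = W, V = V)
}

#' Maximal-overlap discrete wavelet transform
#'
#' Shift-invariant (non-decimated) wavelet decomposition of a time series:
#' every scale carries as many coefficients as the input, and the transform
#' satisfies the energy decomposition
#' `sum(x^2) = sum_j sum(W_j^2) + sum(V_J^2)` under circular (periodic)
#' boundary treatment. Coefficients whose circular filter support wraps the
#' boundary are flagged so variance estimation can exclude them.
#'
#' @param series Numeric vector of finite values, length at least
#'   `2^n_levels`.
#' @param wavelet Wavelet family; `"db8"` (Daubechies, 8 vanishing moments,
#'   16 taps, the default) or `"haar"`.
#' @param n_levels Number of decomposition scales `J >= 2`.
#' @return An object of class `wavelet_decomposition`: per-scale detail
#'   coefficients (`detail_coeffs`, a list of numeric vectors), the final
#'   smooth (`smooth_coeffs`), the per-scale count of boundary-affected
#'   coefficients (`n_boundary`), and the transform metadata.
#' @export
modwt <- function(series, wavelet = "db8", n_levels = 5L) {
  if (!is.numeric(series) || anyNA(series) || any(!is.finite(series)))
    stop("'series' must be a finite numeric vector")
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("'n_levels' must be at least 2")
  N <- length(series)
  if (N < 2^n_levels)
    stop("series of length ", N, " is too short for ", n_levels,
         " levels; maximum feasible level is ", max_modwt_level(N))
  f <- wavelet_filters(wavelet)
  pyr <- modwt_pyramid(matrix(series, ncol = 1L), wavelet, n_levels)
  nb <- vapply(seq_len(n_levels),
               function(j) min(modwt_filter_width(f$L, j) - 1L, N),
               integer(1))
  structure(
    list(detail_coeffs = lapply(pyr$W, drop),
         smooth_coeffs = drop(pyr$V),
         n_boundary = nb,
         wavelet_name = wavelet,
         boundary_rule = "periodic",
         n_levels = n_levels,
         n_samples = N),
    class = "wavelet_decomposition"
  )
}

#' Per-scale wavelet variance
#'
#' Unbiased wavelet variance at each scale: the mean square of the
#' boundary-free detail coefficients, rescaled by `2^j` so that the variance
#' of white noise is flat across scales and the log2-variance slope of
#' fractional Gaussian noise is `2H - 1`. This is the normalisation whose
#' zero-slope reference point corresponds to `H = 0.5` (white noise). Scales
#' where every coefficient is boundary-affected are omitted with a warning.
#'
#' @param decomp A [modwt()] decomposition.
#' @return A data frame with columns `scale` and `variance` (strictly
#'   positive for non-degenerate input).
#' @export
wavelet_variance <- function(decomp) {
  stopifnot(inherits(decomp, "wavelet_decomposition"))
  N <- decomp$n_samples
  out <- lapply(seq_len(decomp$n_levels), function(j) {
    nb <- decomp$n_boundary[j]
    if (nb >= N) return(NULL)
    w <- decomp$detail_coeffs[[j]][(nb + 1L):N]
    data.frame(scale = j, variance = 2^j * mean(w^2))
  })
  dropped <- which(vapply(out, is.null, logical(1)))
  if (length(dropped))
    warning("scale(s) ", paste(dropped, collapse = ", "),
            " omitted: all coefficients are boundary-affected at series ",
            "length ", N)
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

## Vectorised interior wavelet variances for an N x m matrix of series.
## Returns a J x m matrix with NA rows for all-boundary scales.
modwt_variance_matrix <- function(X, wavelet = "db8", n_levels = 5L) {
  f <- wavelet_filters(wavelet)
  N <- nrow(X)
  pyr <- modwt_pyramid(X, wavelet, n_levels)
  out <- matrix(NA_real_, n_levels, ncol(X))
  for (j in seq_len(n_levels)) {
    nb <- min(modwt_filter_width(f$L, j) - 1L, N)
    if (nb >= N) next
    Wj <- pyr$W[[j]][(nb + 1L):N, , drop = FALSE]
    out[j, ] <- 2^j * colMeans(Wj^2)
  }
  out
}
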