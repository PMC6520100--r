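#' Akaike Information Criterion for least-squares fits
#'
#' Gaussian least-squares form `AIC = n * ln(rss/n) + 2 * (k + 1)`, where
#' the error variance counts as one estimated parameter. This is the
#' standard form for comparing curve fits of differing complexity on the
#' same data. A perfect fit (`rss = 0`) returns `-Inf` with a `degenerate`
#' attribute set.
#'
#' @param rss Residual sum of squares (non-negative).
#' @param n Number of observations (`n > k_params + 1`).
#' @param k_params Number of mean-model parameters.
#' @return AIC value (possibly `-Inf`).
#' @export
aic <- function(rss, n, k_params) {
  stopifnot(rss >= 0, n > k_params + 1)
  if (rss == 0)
    return(structure(-Inf, degenerate = TRUE))
  n * log(rss / n) + 2 * (k_params + 1)
}

gradient_families <- c("linear", "quadratic", "cubic", "exponential",
                       "exponential_intersect")

model_fit <- function(family, coefficients, rss, tss, n, k, converged = TRUE) {
  ## An interpolating fit leaves only rounding noise in the residuals; snap
  ## it to an exact zero so AIC comparisons fall back to the parameter-count
  ## tie rule instead of ranking floating-point dust.
  if (converged && is.finite(rss) && rss <= 1e-12 * max(tss, 0)) rss <- 0
  r2 <- if (tss > 0 && converged) max(0, min(1, 1 - rss / tss)) else 0
  p <- NA_real_
  if (converged && k >= 2 && n > k && rss >= 0 && tss > rss) {
    f <- ((tss - rss) / (k - 1)) / (rss / (n - k))
    p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  } else if (converged && tss <= rss) {
    p <- 1
  }
  structure(list(family = family, coefficients = coefficients,
                 r_squared = r2,
                 aic = if (converged) aic(rss, n, k) else NA_real_,
                 rss = if (converged) rss else NA_real_,
                 n_obs = n, k_params = k, p_value = p,
                 converged = converged),
            class = "model_fit")
}

fit_poly <- function(d, y, degree, family) {
  X <- stats::poly(d, degree, raw = TRUE)
  fit <- stats::lm.fit(cbind(1, X), y)
  model_fit(family, stats::setNames(fit$coefficients,
                                    c("a", "b", "c", "d")[1:(degree + 1)]),
            sum(fit$residuals^2), sum((y - mean(y))^2),
            length(y), degree + 1L)
}

## Multi-start bounded exponential fits. 8 fixed starts cover the sign
## patterns of (b, c) at two curvature magnitudes; |c| is bounded so the
## exponential cannot overflow over the observed distance range.
fit_exponential <- function(d, y, intercept, seed = 1L) {
  family <- if (intercept) "exponential_intersect" else "exponential"
  k <- if (intercept) 3L else 2L
  cmax <- 20 / max(max(abs(d)), 1)
  starts <- expand.grid(sb = c(-1, 1), sc = c(-1, 1),
                        cm = c(0.25, 0.025) * cmax)
  b0 <- max(abs(y), 1e-8)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- if (intercept)
      list(a = mean(y), b = starts$sb[i] * b0, c = starts$sc[i] * starts$cm[i])
    else list(b = starts$sb[i] * b0, c = starts$sc[i] * starts$cm[i])
    fml <- if (intercept) y ~ a + b * exp(c * d) else y ~ b * exp(c * d)
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        fml, data = data.frame(d = d, y = y), start = st,
        lower = c(if (intercept) -Inf, -Inf, -cmax),
        upper = c(if (intercept) Inf, Inf, cmax),
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(rss = rss, coef = stats::coef(fit))
    }
  }
  if (is.null(best))
    return(model_fit(family, NULL, NA, NA, length(y), k, converged = FALSE))
  model_fit(family, best$coef, best$rss, sum((y - mean(y))^2), length(y), k)
}

#' Fit the distance-gradient model families
#'
#' Least-squares fits of a peritumoral value (e.g. a homologous-region
#' Hurst ratio) on distance for five families: polynomials of degree 1-3,
#' a pure exponential `b * exp(c * d)`, and an exponential with intercept
#' `a + b * exp(c * d)`. Nonlinear families use bounded multi-start
#' Levenberg-Marquardt with fixed starts; a family that fails to converge
#' is flagged and the others are returned. Pairs with undefined values are
#' dropped.
#'
#' @param distance Numeric distances (mm).
#' @param value Numeric response, same length.
#' @return A list of `model_fit` objects (class `gradient_fits`), one per
#'   family, each with `r_squared`, `aic`, `p_value`, and coefficients.
#' @export
fit_gradient_models <- function(distance, value) {
  keep <- is.finite(distance) & is.finite(value)
  d <- distance[keep]; y <- value[keep]
  if (length(y) < 6L) stop("need at least 6 finite (distance, value) pairs")
  fits <- list(
    linear = fit_poly(d, y, 1L, "linear"),
    quadratic = fit_poly(d, y, 2L, "quadratic"),
    cubic = fit_poly(d, y, 3L, "cubic"),
    exponential = fit_exponential(d, y, intercept = FALSE),
    exponential_intersect = fit_exponential(d, y, intercept = TRUE)
  )
  class(fits) <- "gradient_fits"
  fits
}

#' Select the best-fitting gradient model by AIC
#'
#' Returns the converged family with minimal AIC; exact ties are broken
#' toward the family with fewer parameters.
#'
#' @param fits A [fit_gradient_models()] result (at least one converged
#'   fit).
#' @return The winning `model_fit`.
#' @export
select_best <- function(fits) {
  stopifnot(inherits(fits, "gradient_fits") || is.list(fits))
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(conv)) stop("no converged fits to select from")
  aics <- vapply(conv, function(f) as.numeric(f$aic), numeric(1))
  ks <- vapply(conv, function(f) f$k_params, integer(1))
  ord <- order(aics, ks)
  conv[[ord[1]]]
}

#' Summarise gradient fits as a table
#'
#' @param fits A `gradient_fits` list.
#' @return Data frame with one row per family: `family`, `r_squared`,
#'   `aic`, `p_value`, `converged`.
#' @export
gradient_fit_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f)
    data.frame(family = f$family, r_squared = f$r_squared,
               aic = as.numeric(f$aic), p_value = f$p_value,
               converged = f$converged)))
}

#' One-way ANOVA from sums of squares
#'
#' Between/within decomposition of tissue-grouped values: F is the ratio of
#' the between-group to within-group mean squares.
#'
#' @param values Numeric vector.
#' @param groups Grouping factor/vector (at least 2 groups of at least 2
#'   values).
#' @return List with `F`, `p`, `df_between`, `df_within`, and
#'   `degenerate` (TRUE when all groups have zero within-group variance).
#' @export
tissue_anova <- function(values, groups) {
  groups <- as.factor(groups)
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(groups[keep])
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 values")
  gm <- tapply(values, groups, mean)
  n_g <- tapply(values, groups, length)
  grand <- mean(values)
  ssb <- sum(n_g * (gm - grand)^2)
  ssw <- sum((values - gm[groups])^2)
  dfb <- nlevels(groups) - 1L
  dfw <- length(values) - nlevels(groups)
  if (ssw == 0) {
    warning("zero within-group variance in all groups; F degenerate")
    return(list(F = if (ssb > 0) Inf else 0, p = if (ssb > 0) 0 else 1,
                df_between = dfb, df_within = dfw, degenerate = TRUE))
  }
  F_ <- (ssb / dfb) / (ssw / dfw)
  list(F = F_, p = stats::pf(F_, dfb, dfw, lower.tail = FALSE),
       df_between = dfb, df_within = dfw, degenerate = FALSE)
}

#' ANCOVA for cohort differences in the distance gradient
#'
#' Fits `log_h ~ cohort + distance + cohort:distance` by least squares from
#' the explicit design matrix and tests the interaction (cohort-specific
#' slopes) with a nested-model F test. Pairwise slope contrasts between
#' cohorts are t-tested and Bonferroni-corrected.
#'
#' @param log_h Log-transformed Hurst values.
#' @param distance Tumor distances (mm).
#' @param cohort Cohort labels (at least 2 cohorts with >= 3 points each).
#' @return List with `F`, `p`, `df`, per-cohort `slopes`, and `pairwise`
#'   (data frame of contrasts with raw and Bonferroni-corrected p).
#' @export
cohort_ancova <- function(log_h, distance, cohort) {
  cohort <- as.factor(cohort)
  keep <- is.finite(log_h) & is.finite(distance) & !is.na(cohort)
  y <- log_h[keep]; d <- distance[keep]
  cohort <- droplevels(cohort[keep])
  if (nlevels(cohort) < 2L)
    stop("ANCOVA requires at least 2 cohorts")
  if (any(table(cohort) < 3L))
    stop("each cohort needs at least 3 observations")
  lv <- levels(cohort)
  ## Treatment-coded design: intercept, cohort dummies, distance, and
  ## cohort-specific slope offsets.
  dummies <- sapply(lv[-1], function(l) as.numeric(cohort == l))
  X_full <- cbind(`(Intercept)` = 1, dummies, distance = d,
                  dummies * d)
  colnames(X_full) <- c("(Intercept)", paste0("cohort_", lv[-1]),
                        "distance", paste0("cohort_", lv[-1], ":distance"))
  X_red <- X_full[, seq_len(nlevels(cohort) + 1L), drop = FALSE]
  solve_ls <- function(X) {
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
      stop("rank-deficient ANCOVA design; collinear term(s): ",
           paste(bad, collapse = ", "))
    }
    beta <- qr.coef(qrX, y)
    res <- y - X %*% beta
    list(beta = beta, rss = sum(res^2), qr = qrX)
  }
  full <- solve_ls(X_full)
  red <- solve_ls(X_red)
  df_num <- ncol(X_full) - ncol(X_red)
  df_den <- length(y) - ncol(X_full)
  F_ <- ((red$rss - full$rss) / df_num) / (full$rss / df_den)
  p <- stats::pf(F_, df_num, df_den, lower.tail = FALSE)
  ## Cohort-specific slopes and pairwise contrasts.
  sigma2 <- full$rss / df_den
  XtXinv <- chol2inv(qr.R(full$qr))
  slope_idx <- c(which(colnames(X_full) == "distance"),
                 which(grepl(":distance$", colnames(X_full))))
  slope_of <- function(l) {
    v <- numeric(ncol(X_full))
    v[slope_idx[1]] <- 1
    if (l != lv[1])
      v[which(colnames(X_full) == paste0("cohort_", l, ":distance"))] <- 1
    v
  }
  pairs <- utils::combn(lv, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    cvec <- slope_of(pairs[1, i]) - slope_of(pairs[2, i])
    est <- sum(cvec * full$beta)
    se <- sqrt(sigma2 * drop(t(cvec) %*% XtXinv %*% cvec))
    t_ <- est / se
    data.frame(cohort_a = pairs[1, i], cohort_b = pairs[2, i],
               slope_diff = est, se = se, t = t_,
               p_raw = 2 * stats::pt(abs(t_), df_den, lower.tail = FALSE))
  }))
  pw$p_bonferroni <- pmin(1, nrow(pw) * pw$p_raw)
  slopes <- vapply(lv, function(l) sum(slope_of(l) * full$beta), numeric(1))
  list(F = F_, p = p, df = c(df_num, df_den),
       slopes = stats::setNames(slopes, lv), pairwise = pw)
}

#' Correlations between node metrics and the Hurst exponent
#'
#' Product-moment correlation of each metric column with per-node H, with
#' Bonferroni correction over the number of metrics tested. Zero-variance
#' metrics yield NA and are flagged.
#'
#' @param h_per_node Numeric vector of per-node Hurst values.
#' @param metrics A data frame (e.g. [node_centralities()]); all numeric
#'   columns except `node` are tested unless `columns` is given.
#' @param columns Optional character vector of columns to test.
#' @return A data frame (class `correlation_report`) with columns `metric`,
#'   `r`, `p_raw`, `p_bonferroni`, `n`, `flagged`.
#' @export
metric_hurst_correlations <- function(h_per_node, metrics, columns = NULL) {
  if (is.null(columns))
    columns <- setdiff(names(metrics)[vapply(metrics, is.numeric,
                                             logical(1))], "node")
  stopifnot(length(h_per_node) == nrow(metrics), length(columns) >= 1)
  m <- length(columns)
  rows <- lapply(columns, function(nm) {
    x <- metrics[[nm]]
    keep <- is.finite(x) & is.finite(h_per_node)
    n <- sum(keep)
    if (n < 4L || stats::sd(x[keep]) == 0 || stats::sd(h_per_node[keep]) == 0)
      return(data.frame(metric = nm, r = NA_real_, p_raw = NA_real_,
                        p_bonferroni = NA_real_, n = n, flagged = TRUE))
    ct <- stats::cor.test(x[keep], h_per_node[keep])
    data.frame(metric = nm, r = unname(ct$estimate), p_raw = ct$p.value,
               p_bonferroni = min(1, m * ct$p.value), n = n,
               flagged = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("correlation_report", "data.frame")
  out
}
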