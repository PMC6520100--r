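test_that("AIC obeys its defining algebra", {
  expect_equal(aic(2, 50, 2) - aic(1, 50, 2), 50 * log(2))
  expect_equal(aic(1, 50, 3) - aic(1, 50, 2), 2)
  ## hand-computed 4-point regression: y = (1, 2, 2, 4) on x = 1:4 gives
  ## slope 4.5/5 = 0.9, intercept 0, residuals (0.1, 0.2, -0.7, 0.4),
  ## rss = 0.7; AIC = 4*ln(0.7/4) + 2*(2 + 1)
  expect_equal(aic(0.7, 4, 2), 4 * log(0.175) + 6)
  a0 <- aic(0, 10, 2)
  expect_identical(as.numeric(a0), -Inf)
  expect_true(isTRUE(attr(a0, "degenerate")))
  expect_error(aic(-1, 10, 2))
  expect_error(aic(1, 3, 3))
})

test_that("exact-family data is recovered exactly", {
  set.seed(71)
  d <- stats::runif(100, 0, 30)
  y <- 1 - 0.1 * d + 0.003 * d^2
  fits <- fit_gradient_models(d, y)
  q <- fits$quadratic
  expect_equal(q$r_squared, 1)
  expect_equal(unname(q$coefficients), c(1, -0.1, 0.003), tolerance = 1e-6)
  expect_identical(select_best(fits)$family, "quadratic")
  ## noiseless linear: linear and quadratic both perfect, AIC tie-broken
  ## toward fewer parameters
  fl <- fit_gradient_models(d, 2 + 0.5 * d)
  expect_equal(fl$linear$r_squared, 1)
  expect_equal(fl$quadratic$r_squared, 1)
  expect_identical(select_best(fl)$family, "linear")
  ## constant response: no variance explained anywhere
  fc <- fit_gradient_models(d, rep(2, 100))
  expect_true(all(vapply(fc, function(f) f$r_squared == 0, logical(1))))
})

test_that("noisy linear data prefers linear by the AIC penalty", {
  set.seed(72)
  d <- stats::runif(200, 0, 30)
  y <- 2 + 0.05 * d + stats::rnorm(200, 0, 0.1)
  fits <- fit_gradient_models(d, y)
  expect_lt(fits$linear$aic, fits$quadratic$aic)
  ## quadratic can reduce RSS only trivially; penalty dominates:
  n <- 200
  expect_lt(n * log(fits$quadratic$rss / fits$linear$rss) + 2, 2 + 1e-9)
})

test_that("exponential families are fitted and reported", {
  set.seed(73)
  d <- stats::runif(150, 0, 30)
  y <- 0.3 + 0.5 * exp(-0.15 * d) + stats::rnorm(150, 0, 0.01)
  fits <- fit_gradient_models(d, y)
  ei <- fits$exponential_intersect
  expect_true(ei$converged)
  expect_gt(ei$r_squared, 0.95)
  expect_equal(unname(ei$coefficients["a"]), 0.3, tolerance = 0.05)
  expect_equal(unname(ei$coefficients["c"]), -0.15, tolerance = 0.05)
  expect_identical(select_best(fits)$family, "exponential_intersect")
  ## pure exponential data
  y2 <- 0.9 * exp(-0.1 * d) + stats::rnorm(150, 0, 0.005)
  f2 <- fit_gradient_models(d, y2)
  expect_gt(f2$exponential$r_squared, 0.95)
})

test_that("observation order does not change the fits", {
  set.seed(74)
  d <- stats::runif(80, 0, 30)
  y <- 0.8 + 0.02 * d - 5e-4 * d^2 + stats::rnorm(80, 0, 0.02)
  f1 <- fit_gradient_models(d, y)
  o <- sample(80)
  f2 <- fit_gradient_models(d[o], y[o])
  for (fam in c("linear", "quadratic", "cubic"))
    expect_equal(f1[[fam]]$aic, f2[[fam]]$aic, tolerance = 1e-9)
})

test_that("tissue ANOVA reproduces hand-computed sums of squares", {
  out <- tissue_anova(c(1, 2, 3, 4, 5, 6), rep(c("gm", "wm"), each = 3))
  expect_equal(out$F, 13.5)
  ## cross-check against the built-in ANOVA on fresh data
  set.seed(75)
  v <- stats::rnorm(30)
  g <- rep(letters[1:3], each = 10)
  ref <- summary(stats::aov(v ~ g))[[1]]
  mine <- tissue_anova(v, g)
  expect_equal(mine$F, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(mine$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)
  ## two-group identity F = t^2
  v2 <- stats::rnorm(20); g2 <- rep(c("a", "b"), each = 10)
  tt <- stats::t.test(v2 ~ g2, var.equal = TRUE)
  expect_equal(tissue_anova(v2, g2)$F, unname(tt$statistic)^2,
               tolerance = 1e-10)
  ## identical groups -> F = 0
  expect_equal(tissue_anova(c(1, 2, 3, 1, 2, 3),
                            rep(c("a", "b"), each = 3))$F, 0)
})

test_that("ANCOVA matches lm() and detects slope differences", {
  set.seed(76)
  n <- 50
  coh <- rep(c("A", "B"), each = n)
  d <- stats::runif(2 * n, 0, 30)
  y <- 0.1 + ifelse(coh == "A", 0.01, 0.02) * d + stats::rnorm(2 * n, 0, 0.05)
  mine <- cohort_ancova(y, d, coh)
  ref <- stats::anova(stats::lm(y ~ coh + d, data.frame(coh, d)),
                      stats::lm(y ~ coh * d, data.frame(coh, d)))
  expect_equal(mine$F, ref$F[2], tolerance = 1e-10)
  expect_equal(mine$p, ref$`Pr(>F)`[2], tolerance = 1e-10)
  expect_equal(mine$pairwise$p_bonferroni,
               pmin(1, nrow(mine$pairwise) * mine$pairwise$p_raw))
  expect_error(cohort_ancova(y, d, rep("A", 2 * n)), "2 cohorts")
})

test_that("ANCOVA power and null behave as expected over seeds", {
  pvals_null <- vapply(1:40, function(s) {
    set.seed(200 + s)
    n <- 30
    coh <- rep(c("A", "B"), each = n)
    d <- stats::runif(2 * n, 0, 30)
    y <- 0.1 + 0.02 * d + stats::rnorm(2 * n, 0, 0.05)
    cohort_ancova(y, d, coh)$p
  }, numeric(1))
  ## roughly uniform: no mass collapse at either end
  expect_gt(mean(pvals_null > 0.05), 0.7)
  ## strong slope difference: nearly always significant
  pvals_alt <- vapply(1:20, function(s) {
    set.seed(300 + s)
    n <- 30
    coh <- rep(c("A", "B"), each = n)
    d <- stats::runif(2 * n, 0, 30)
    y <- 0.1 + ifelse(coh == "A", 0.01, 0.05) * d +
      stats::rnorm(2 * n, 0, 0.05)
    cohort_ancova(y, d, coh)$p
  }, numeric(1))
  expect_gte(mean(pvals_alt < 0.05), 0.95)
})

test_that("metric-H correlations report r, Bonferroni, and flags", {
  set.seed(77)
  h <- stats::rnorm(250, 0.7, 0.1)
  metrics <- data.frame(node = 1:250,
                        same = h,
                        anti = -h,
                        noise = stats::rnorm(250),
                        flat = rep(1, 250))
  rep_ <- metric_hurst_correlations(h, metrics)
  expect_equal(rep_$r[rep_$metric == "same"], 1)
  expect_equal(rep_$r[rep_$metric == "anti"], -1)
  expect_lt(abs(rep_$r[rep_$metric == "noise"]), 0.2)
  expect_true(rep_$flagged[rep_$metric == "flat"])
  m <- sum(!is.na(rep_$p_raw))
  ok <- !is.na(rep_$p_raw)
  expect_equal(rep_$p_bonferroni[ok], pmin(1, 4 * rep_$p_raw[ok]))
})
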