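# OLS fits with bands, ANOVA + Tukey + letters, paired t, linkage recovery.

test_that("exact linear data recover slope and unit r-squared; degenerate
           designs are handled", {
  f <- suppressWarnings(fit_ols(1:10, 2 * (1:10), degree = 1))
  expect_equal(unname(f$coefficients), c(0, 2), tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  fc <- suppressWarnings(fit_ols(1:10, rep(3, 10), degree = 1))
  expect_equal(fc$r_squared, 0)
  expect_error(fit_ols(rep(2, 10), rnorm(10), degree = 1), "rank deficient")
  expect_error(fit_ols(1:3, c(1, 2, NA), 1), "finite")
})

test_that("coefficients match a brute-force normal-equations oracle", {
  set.seed(5)
  x <- c(0.3, 1.1, 1.9, 2.2, 3.0, 3.8, 4.1, 5.0, 5.6, 6.2, 7.0, 7.7)
  y <- 1.5 - 0.8 * x + 0.12 * x^2 + rnorm(12, 0, 0.3)
  f <- fit_ols(x, y, degree = 2)
  X <- cbind(1, x, x^2)
  beta <- solve(t(X) %*% X, t(X) %*% y)[, 1L]
  expect_equal(unname(f$coefficients), unname(beta), tolerance = 1e-10)
  # residuals consistent with the fit
  expect_equal(f$residuals, unname(y - X %*% beta)[, 1L], tolerance = 1e-10)
})

test_that("confidence bands widen away from the predictor mean", {
  set.seed(6)
  x <- seq(0, 10, length.out = 25)
  f <- fit_ols(x, 1 + 0.5 * x + rnorm(25, 0, 0.4), degree = 1)
  w <- f$band$upr - f$band$lwr
  centre_dist <- abs(f$band$x - mean(x))
  # width is a monotone (not linear) function of distance from the mean
  expect_gt(cor(w, centre_dist, method = "spearman"), 0.999)
  expect_equal(which.min(w), which.min(centre_dist))
})

test_that("identical groups share a letter; two-group Tukey equals the
           pooled t test", {
  g <- anova_tukey(list(a = c(1, 2, 3), b = c(1, 2, 3),
                        c = c(1, 2, 3), d = c(1, 2, 3)))
  expect_lt(g$f, 1e-10)
  expect_equal(unique(unname(g$letters)), "a")
  set.seed(7)
  a <- rnorm(8); b <- rnorm(8, 1)
  g2 <- anova_tukey(list(a = a, b = b))
  tt <- t.test(a, b, var.equal = TRUE)
  # ptukey's quadrature is accurate to ~1e-4, not machine precision
  expect_equal(g2$tukey[["p adj"]], tt$p.value, tolerance = 1e-3)
  expect_error(anova_tukey(list(a = 1, b = c(1, 2))), "at least 2")
})

test_that("letters are consistent with the pairwise matrix and adjusted p
           never undercuts unadjusted p", {
  set.seed(8)
  vals <- list(a = rnorm(6, 0), b = rnorm(6, 0.3), c = rnorm(6, 3))
  g <- anova_tukey(vals)
  for (r in rownames(g$tukey)) {
    pr <- strsplit(r, "-", fixed = TRUE)[[1L]]
    share <- any(strsplit(g$letters[[pr[1L]]], "")[[1L]] %in%
                   strsplit(g$letters[[pr[2L]]], "")[[1L]])
    expect_equal(share, g$tukey[r, "p adj"] >= 0.05)
    un <- t.test(vals[[pr[1L]]], vals[[pr[2L]]], var.equal = TRUE)$p.value
    expect_gte(g$tukey[r, "p adj"], un - 5e-4)
  }
})

test_that("ANOVA p agrees with a permutation oracle on a small instance", {
  set.seed(9)
  x <- c(rnorm(5, 0), rnorm(5, 0.8), rnorm(5, 0.4))
  lab <- rep(1:3, each = 5)
  g <- anova_tukey(x, lab)
  fstat <- function(x, lab) {
    m <- tapply(x, lab, mean)
    n <- tapply(x, lab, length)
    ssb <- sum(n * (m - mean(x))^2)
    ssw <- sum((x - m[lab])^2)
    (ssb / 2) / (ssw / 12)
  }
  f0 <- fstat(x, lab)
  perm <- vapply(seq_len(1e5), function(i) fstat(x[sample.int(15)], lab), 0)
  p_perm <- mean(perm >= f0 - 1e-12)
  expect_lt(abs(g$p - p_perm), 0.02)
})

test_that("paired t matches the textbook formula and handles degenerate
           differences", {
  a <- c(1.2, 0.8, 1.5, 2.0, 1.1, 0.9, 1.7, 1.3)
  b <- c(1.0, 0.9, 1.2, 1.6, 1.2, 0.7, 1.4, 1.1)
  res <- paired_t(a, b)
  d <- a - b
  t_manual <- mean(d) / (sd(d) / sqrt(8))
  p_manual <- 2 * stats::pt(-abs(t_manual), 7)
  expect_equal(res$statistic, t_manual, tolerance = 1e-12)
  expect_equal(res$p_value, p_manual, tolerance = 1e-12)
  # antisymmetry
  res2 <- paired_t(b, a)
  expect_equal(res2$statistic, -res$statistic, tolerance = 1e-12)
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-12)
  # degenerate cases
  same <- paired_t(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  shift <- paired_t(a + 1, a)
  expect_equal(shift$statistic, Inf)
  expect_equal(shift$p_value, 0)
})

test_that("procedures are invariant to observation order", {
  set.seed(10)
  x <- runif(20); y <- 1 + x + rnorm(20, 0, 0.2)
  o <- sample.int(20)
  f1 <- fit_ols(x, y, 1); f2 <- fit_ols(x[o], y[o], 1)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-12)
  lab <- rep(c("a", "b"), each = 10)
  g1 <- anova_tukey(y, lab); g2 <- anova_tukey(y[o], lab[o])
  expect_equal(g1$p, g2$p, tolerance = 1e-12)
})

test_that("noise-free linkage cohorts are recovered exactly and shuffled
           labels destroy the fit", {
  co <- generate_linkage_cohort(40, coefs = c(-0.1, 0.5, 0.6),
                                noise_sd = 0, seed = 2)
  f <- suppressWarnings(recover_linkage(co))   # exact fit warns in summary.lm
  expect_equal(unname(f$coefficients), c(-0.1, 0.5, 0.6), tolerance = 1e-8)
  set.seed(11)
  r2s <- vapply(1:20, function(i) {
    co2 <- generate_linkage_cohort(25, noise_sd = 0.05, seed = i)
    co2$rel_fi <- sample(co2$rel_fi)
    recover_linkage(co2)$r_squared
  }, 0)
  expect_lt(mean(r2s), 0.2)
})
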