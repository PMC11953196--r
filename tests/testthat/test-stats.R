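test_that("describe matches the interpolated-quantile definition", {
  d <- describe(c(1, 2, 3, 4, 5))
  expect_equal(unlist(d[c("median", "q1", "q3", "min", "max")]),
               c(median = 3, q1 = 2, q3 = 4, min = 1, max = 5))
  expect_equal(describe(c(1, 2, 3, 4))$q1, 1.75)
  expect_equal(describe(c(1, 2, 3, 4))$q3, 3.25)
  cst <- describe(c(1, 1, 1, 1))
  expect_true(all(unlist(cst[c("median", "q1", "q3", "min", "max")]) == 1))
  expect_equal(describe(c(NA, 2, NA, 4))$n_nonmissing, 2L)
  expect_error(describe(c(NA_real_, NA_real_)), "all values are missing")
})

test_that("spearman_cor agrees with oracles and handles deletion and errors", {
  expect_equal(spearman_cor(1:5, c(2, 4, 6, 8, 10))$rho, 1)
  expect_equal(spearman_cor(1:5, 5:1)$rho, -1)
  r <- spearman_cor(1:4, c(2, 1, 4, 3))
  expect_equal(r$rho, 0.6)
  # brute-force formula check to 1e-12 on random short vectors (with ties)
  set.seed(4)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    x <- sample(1:6, n, replace = TRUE) + runif(n, 0, 0.01)
    y <- sample(1:6, n, replace = TRUE)
    expect_equal(spearman_cor(x, y)$rho, oracle_spearman_rho(x, y),
                 tolerance = 1e-12)
  }
  # listwise deletion: missing pairs do not affect rho or n_used
  x <- c(1, 2, 3, 4, 5, NA, 7)
  y <- c(2, 1, 4, 3, 5, 6, NA)
  r2 <- spearman_cor(x, y)
  expect_equal(r2$n_used, 5L)
  expect_equal(r2$rho, spearman_cor(x[1:5], y[1:5])$rho)
  expect_error(spearman_cor(1:3, 1:3), "fewer than 4")
  expect_error(spearman_cor(1:5, rep(1, 5)), "zero variance")
})

test_that("spearman_cor is invariant under strictly monotone transforms", {
  set.seed(9)
  x <- rnorm(30); y <- rnorm(30)
  base <- spearman_cor(x, y)
  expect_equal(spearman_cor(exp(x), y)$rho, base$rho)
  expect_equal(spearman_cor(x, qlogis(plogis(y)))$rho, base$rho)
  expect_equal(spearman_cor(rank(x), y^3 + 5 * y)$rho, base$rho)
  expect_equal(spearman_cor(exp(x), y)$p_value, base$p_value)
})

test_that("wilcoxon rank-sum exact p matches exhaustive enumeration", {
  w <- wilcoxon_change_test(c(1, 2, 3), c(4, 5, 6))
  expect_true(w$exact)
  expect_equal(w$p_value, 0.1)  # 2/20 assignments as extreme
  set.seed(21)
  for (n1 in 3:6) for (n2 in 3:6) {
    a <- rnorm(n1); b <- rnorm(n2)
    expect_equal(wilcoxon_change_test(a, b)$p_value,
                 oracle_ranksum_exact(a, b), tolerance = 1e-12)
  }
  # two-sided symmetry under group swap
  a <- rnorm(5); b <- rnorm(7)
  expect_equal(wilcoxon_change_test(a, b)$p_value,
               wilcoxon_change_test(b, a)$p_value)
})

test_that("signed-rank mode handles pairing and degenerate differences", {
  t0 <- c(5, 7, 9, 11, 13); t1 <- c(4, 9, 6, 16, 5)
  v <- wilcoxon_change_test(t0, t1, mode = "signed-rank")
  expect_true(v$exact)
  # agrees with the reference implementation when exact and tie-free
  ref <- stats::wilcox.test(t1, t0, paired = TRUE, exact = TRUE)
  expect_equal(v$p_value, ref$p.value, tolerance = 1e-12)
  expect_error(wilcoxon_change_test(c(1, 2, 3), c(1, 2, 3),
                                    mode = "signed-rank"), "nonzero")
})

test_that("jarque_bera uses population moments and the chi-squared reference", {
  jb <- jarque_bera(c(1, 2, 3, 4, 5))
  expect_equal(jb$skewness, 0)
  expect_equal(jb$kurtosis, 1.7)
  expect_equal(jb$statistic, 5 / 6 * (1.3^2 / 4), tolerance = 1e-12)
  sym <- jarque_bera(rep(c(-1, 1), 4))
  expect_equal(sym$skewness, 0)
  expect_error(jarque_bera(rep(2, 10)), "zero variance")
  expect_error(jarque_bera(1:4), "at least 5")
  # level check: standard-normal samples rarely rejected
  ok <- 0
  for (s in 1:100) { set.seed(s); ok <- ok + (jarque_bera(rnorm(5000))$p_value > 0.05) }
  expect_gte(ok, 95)
})

test_that("univariate_regression recovers closed-form OLS and adjusted R2", {
  f <- univariate_regression(1:5, 2 * (1:5) + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$adjusted_r2, 1)
  expect_equal(univariate_regression(1:4, rep(5, 4))$slope, 0)
  g <- univariate_regression(c(0, 1, 2, 3), c(1, 2, 2, 4))
  expect_equal(g$slope, 0.9)
  expect_equal(g$intercept, 0.9)
  # agreement with the reference fitter, and adjusted R2 <= R2
  set.seed(3)
  x <- rnorm(20); y <- 1 + 0.5 * x + rnorm(20)
  h <- univariate_regression(x, y)
  lmf <- summary(stats::lm(y ~ x))
  expect_equal(h$slope, unname(coef(lmf)[2, 1]), tolerance = 1e-12)
  expect_equal(h$adjusted_r2, lmf$adj.r.squared, tolerance = 1e-12)
  expect_equal(h$slope_p_value, unname(coef(lmf)[2, 4]), tolerance = 1e-12)
  expect_lt(h$adjusted_r2, h$r2)
  expect_error(univariate_regression(rep(1, 5), 1:5), "constant")
})

test_that("concordance reproduces Lin's formula, CI ordering and bounds", {
  x <- c(1, 2, 3); y <- c(2, 3, 4)
  expect_equal(concordance(x, y)$ccc, 4 / 7, tolerance = 1e-12)
  set.seed(8)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    a <- rnorm(n); b <- rnorm(n)
    cc <- concordance(a, b)
    expect_equal(cc$ccc, oracle_ccc(a, b), tolerance = 1e-12)
    expect_lte(abs(cc$ccc), abs(cc$pearson_r) + 1e-12)
    expect_lte(cc$ci_low, cc$ccc)
    expect_gte(cc$ci_high, cc$ccc)
  }
  v <- rnorm(10)
  expect_equal(concordance(v, v)$ccc, 1)
  # scale bias penalized: CCC < r
  w <- abs(rnorm(10)) + 1
  cs <- concordance(w, 2 * w)
  expect_lt(cs$ccc, cs$pearson_r)
  expect_error(concordance(rep(1, 5), rep(2, 5)), "zero variance")
})
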