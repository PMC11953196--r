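#' Five-number descriptive summary
#'
#' Median, first and third quartile, minimum and maximum, after dropping
#' missing values.  Quartiles use linear interpolation between order
#' statistics (the usual default of mainstream statistical software), so
#' printed-table comparisons are reproducible.
#'
#' @param values Numeric vector; `NA` allowed and dropped.
#' @return List with `median`, `q1`, `q3`, `min`, `max`, `n_nonmissing`.
#' @examples
#' describe(c(1, 2, 3, 4))  # q1 = 1.75, q3 = 3.25
#' @export
describe <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("describe: all values are missing")
  q <- unname(stats::quantile(v, c(0.25, 0.5, 0.75), type = 7))
  list(median = q[2L], q1 = q[1L], q3 = q[3L],
       min = min(v), max = max(v), n_nonmissing = length(v))
}

avg_rank <- function(x) rank(x, ties.method = "average")

# all permutations of 1..n as an n! x n matrix (small n only)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- all_perms(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    q <- matrix(0L, nrow(p), n)
    q[, k] <- n
    q[, -k] <- p
    out[[k]] <- q
  }
  do.call(rbind, out)
}

#' Spearman rank correlation with listwise deletion
#'
#' Pairs with a missing member are deleted before ranking; ties get average
#' ranks.  The two-sided p-value uses the t approximation for
#' `n_used >= 10` and exact permutation enumeration below that.
#'
#' @param x,y Paired numeric vectors (same length); `NA` allowed.
#' @return List with `rho`, `p_value`, `n_used`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("spearman_cor: fewer than 4 complete pairs")
  rx <- avg_rank(x); ry <- avg_rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    stop("spearman_cor: zero variance in ranks, correlation undefined")
  rho <- stats::cor(rx, ry)
  if (n >= 10L) {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  } else {
    # exact permutation null: permute y ranks against fixed x ranks
    pm <- all_perms(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rhos <- as.numeric(matrix(ryc[pm], nrow(pm)) %*% rxc) / denom
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  }
  list(rho = rho, p_value = min(p, 1), n_used = n)
}

#' Wilcoxon test for baseline-to-follow-up change
#'
#' Default mode is the two-sample rank-sum test applied to the T0 and T1
#' samples; a paired signed-rank mode is available via
#' `mode = "signed-rank"`.  Exact p-values are computed by complete
#' enumeration for small samples without ties, otherwise the normal
#' approximation with continuity and tie correction is used.  Two-sided.
#'
#' @param t0,t1 Numeric vectors (paired in signed-rank mode); `NA` dropped
#'   (pairwise in signed-rank mode).
#' @param mode `"rank-sum"` (default) or `"signed-rank"`.
#' @return List with `statistic` (Mann-Whitney U, resp. signed-rank V),
#'   `p_value`, `mode`, `exact` (logical).
#' @export
wilcoxon_change_test <- function(t0, t1, mode = c("rank-sum", "signed-rank")) {
  mode <- match.arg(mode)
  if (mode == "rank-sum") {
    a <- t0[!is.na(t0)]; b <- t1[!is.na(t1)]
    n1 <- length(a); n2 <- length(b)
    if (n1 < 3L || n2 < 3L) stop("rank-sum mode needs >= 3 values per group")
    r <- avg_rank(c(a, b))
    u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    ties <- any(duplicated(c(a, b)))
    if (!ties && choose(n1 + n2, n1) <= 50000) {
      idx <- utils::combn(n1 + n2, n1)
      rall <- avg_rank(c(a, b))
      us <- colSums(matrix(rall[idx], nrow = n1)) - n1 * (n1 + 1) / 2
      p <- 2 * min(mean(us <= u + 1e-12), mean(us >= u - 1e-12))
      exact <- TRUE
    } else {
      n <- n1 + n2
      tie_tab <- table(c(a, b))
      mu <- n1 * n2 / 2
      sig2 <- n1 * n2 / 12 * (n + 1 - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
      p <- 2 * stats::pnorm(-abs(z))
      exact <- FALSE
    }
    return(list(statistic = u, p_value = min(p, 1), mode = mode, exact = exact))
  }
  # signed-rank on paired differences
  ok <- !(is.na(t0) | is.na(t1))
  d <- (t1 - t0)[ok]
  d <- d[d != 0]
  m <- length(d)
  if (m < 3L) stop("signed-rank mode needs >= 3 nonzero paired differences")
  r <- avg_rank(abs(d))
  v <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (!ties && m <= 14L) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    vs <- as.numeric(signs %*% r)
    p <- 2 * min(mean(vs <= v + 1e-12), mean(vs >= v - 1e-12))
    exact <- TRUE
  } else {
    mu <- m * (m + 1) / 4
    tie_tab <- table(r)
    sig2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  list(statistic = v, p_value = min(p, 1), mode = mode, exact = exact)
}

#' Jarque-Bera normality test
#'
#' `JB = n/6 * (S^2 + (K - 3)^2 / 4)` with skewness `S` and kurtosis `K`
#' computed from population (1/n) moments; the p-value comes from the
#' chi-squared distribution with 2 degrees of freedom.
#'
#' @param values Numeric vector, `NA` dropped; needs `n >= 5` and nonzero
#'   variance.
#' @return List with `statistic`, `p_value`, `skewness`, `kurtosis`, `n`.
#' @export
jarque_bera <- function(values) {
  v <- values[!is.na(values)]
  n <- length(v)
  if (n < 5L) stop("jarque_bera: need at least 5 values")
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 == 0) stop("jarque_bera: zero variance")
  s <- mean((v - m)^3) / m2^1.5
  k <- mean((v - m)^4) / m2^2
  jb <- n / 6 * (s^2 + (k - 3)^2 / 4)
  list(statistic = jb, p_value = stats::pchisq(jb, df = 2, lower.tail = FALSE),
       skewness = s, kurtosis = k, n = n)
}

#' Univariate linear regression (ordinary least squares)
#'
#' Fits `y = intercept + slope * x` by OLS after listwise deletion; reports
#' the adjusted R-squared `1 - (1 - R^2)(n - 1)/(n - 2)` and the two-sided
#' p-value for the slope.
#'
#' @param x Predictor (e.g. the index).
#' @param y Response (e.g. absolute BCVA change in logMAR).
#' @return List with `slope`, `intercept`, `r2`, `adjusted_r2`,
#'   `slope_p_value`, `n_used`.
#' @export
univariate_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("univariate_regression: fewer than 3 complete pairs")
  if (stats::var(x) == 0) stop("univariate_regression: constant predictor")
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(res^2) / sst
  adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  se <- sqrt(sum(res^2) / (n - 2) / sxx)
  p <- if (se == 0) 0 else 2 * stats::pt(-abs(slope / se), df = n - 2)
  list(slope = slope, intercept = intercept, r2 = r2, adjusted_r2 = adj,
       slope_p_value = p, n_used = n)
}

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with population
#' (1/n) moments, per Lin's original definition.  The 95% confidence
#' interval applies the Fisher z-transform with Lin's asymptotic variance.
#'
#' @param x,y Paired measurements (e.g. two graders); `NA` pairs dropped.
#' @param conf_level Confidence level, default 0.95.
#' @return List with `ccc`, `ci_low`, `ci_high`, `pearson_r`, `n`.
#' @export
concordance <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("concordance: fewer than 3 pairs")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  if (sx2 == 0 && sy2 == 0) stop("concordance: zero variance in both vectors")
  sxy <- mean((x - mx) * (y - my))
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- if (sx2 > 0 && sy2 > 0) sxy / sqrt(sx2 * sy2) else 0
  if (abs(ccc) >= 1 - 1e-12 || abs(r) < 1e-12) {
    # degenerate CI (perfect agreement or no correlation): collapse interval
    return(list(ccc = ccc, ci_low = ccc, ci_high = ccc, pearson_r = r, n = n))
  }
  u <- (mx - my) / sqrt(sqrt(sx2) * sqrt(sy2))
  z <- atanh(ccc)
  sz2 <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
            2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
            ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
  zcrit <- stats::qnorm(1 - (1 - conf_level) / 2)
  lo <- tanh(z - zcrit * sqrt(max(sz2, 0)))
  hi <- tanh(z + zcrit * sqrt(max(sz2, 0)))
  list(ccc = ccc, ci_low = lo, ci_high = hi, pearson_r = r, n = n)
}
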