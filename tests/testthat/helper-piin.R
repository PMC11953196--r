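# small cohort data frame with known areas
toy_cohort <- function() {
  data.frame(
    eye_id = sprintf("eye%02d", 1:5),
    la_mm2 = c(0.03, 0.10, 0.15, 0.28, 0.53),
    ta_mm2 = c(0.06, 0.22, 0.30, 0.45, 0.82),
    minimum_diameter_um = c(226, 300, 492, 520, 741),
    bcva_t0_logmar = c(0.30, 0.70, 0.80, 1.00, 1.50),
    bcva_t1_logmar = c(0.20, 0.30, 0.30, 0.40, 1.50),
    ez_t0_um = c(520, 830, 1234, 1759, 2456),
    ez_t1_um = c(100, 400, 700, 900, NA),
    elm_t0_um = c(214, 291, 578, 670, 948),
    elm_t1_um = c(214, 100, 300, 200, 15),
    stringsAsFactors = FALSE)
}

# quick circular phantom: lumen radius r, ring width w (mm)
quick_phantom <- function(r = 0.2, w = 0.1, ...) {
  generate_phantom(phantom_spec(lumen_a_mm = r, lumen_b_mm = r,
                                ring_width_mm = w, ...))
}

rel_err <- function(x, truth) abs(x / truth - 1)

# independent Spearman oracle: Pearson on average ranks, via raw sums
oracle_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# independent CCC oracle from the definition, population moments
oracle_ccc <- function(x, y) {
  n <- length(x)
  sx2 <- sum((x - mean(x))^2) / n
  sy2 <- sum((y - mean(y))^2) / n
  sxy <- sum((x - mean(x)) * (y - mean(y))) / n
  2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)
}

# independent exact rank-sum oracle: enumerate all group assignments and
# count pairwise wins (Mann-Whitney U by pair counting)
oracle_ranksum_exact <- function(a, b) {
  u_stat <- function(g1, g2)
    sum(outer(g1, g2, ">")) + 0.5 * sum(outer(g1, g2, "=="))
  pool <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pool), n1)
  u_obs <- u_stat(a, b)
  us <- apply(idx, 2, function(ii) u_stat(pool[ii], pool[-ii]))
  min(1, 2 * min(mean(us <= u_obs + 1e-12), mean(us >= u_obs - 1e-12)))
}
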