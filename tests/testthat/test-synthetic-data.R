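test_that("phantom ground truth is analytic and deterministic", {
  ph <- quick_phantom(0.2, 0.1)
  expect_equal(ph$truth$luminal_area, pi * 0.04)
  expect_equal(ph$truth$total_area, pi * 0.09)
  expect_equal(ph$truth$photoreceptor_area, pi * 0.05)
  a <- generate_phantom(phantom_spec(speckle_sigma = 0.15, seed = 7))
  b <- generate_phantom(phantom_spec(speckle_sigma = 0.15, seed = 7))
  expect_identical(a$image$pixels, b$image$pixels)
  c2 <- generate_phantom(phantom_spec(speckle_sigma = 0.15, seed = 8))
  expect_false(identical(a$image$pixels, c2$image$pixels))
})

test_that("bumpy-border truth converges under quadrature refinement", {
  sp <- phantom_spec(lumen_a_mm = 0.2, ring_width_mm = 0.1,
                     bump_amplitude_mm = 0.03, bump_lobes = 8)
  a2048 <- piin:::outer_polygon_area(sp, 2048L)
  a4096 <- piin:::outer_polygon_area(sp, 4096L)
  expect_lt(abs(a2048 / a4096 - 1), 0.005)
  # smooth case: polygon quadrature matches the analytic ellipse area
  sm <- phantom_spec(lumen_a_mm = 0.2, lumen_b_mm = 0.15, ring_width_mm = 0.1)
  expect_equal(piin:::outer_polygon_area(sm, 4096L), pi * 0.3 * 0.25,
               tolerance = 1e-5)
})

test_that("phantom specs that leave the field or break the ring are rejected", {
  expect_error(phantom_spec(lumen_a_mm = 1.3, ring_width_mm = 0.3), "field")
  expect_error(phantom_spec(bump_amplitude_mm = 0.2, ring_width_mm = 0.1),
               "bump amplitude")
  expect_error(phantom_spec(lumen_a_mm = -1), "semi-axes")
  expect_error(phantom_spec(ring_width_mm = 0), "ring width")
})

test_that("spearman_to_pearson is the exact sine transform", {
  expect_equal(spearman_to_pearson(0), 0)
  expect_equal(spearman_to_pearson(1), 1)
  expect_equal(spearman_to_pearson(-1), -1)
  expect_equal(spearman_to_pearson(0.5), 2 * sin(pi / 12))
  expect_equal(round(spearman_to_pearson(0.5), 4), 0.5176)
  expect_equal(spearman_to_pearson(-0.3), -spearman_to_pearson(0.3))
  expect_error(spearman_to_pearson(1.2), "<= 1")
})

test_that("nearest_psd repairs an indefinite matrix into a correlation matrix", {
  m <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_lt(min(eigen(m, symmetric = TRUE)$values), 0)
  r <- nearest_psd(m)
  expect_gte(min(eigen(r, symmetric = TRUE)$values), 0)
  expect_equal(diag(r), rep(1, 3))
  # PSD input is returned untouched
  ok <- diag(3)
  expect_identical(nearest_psd(ok), ok)
})

test_that("piecewise margins reproduce all five printed statistics", {
  for (m in default_margins()) {
    expect_equal(m$qfun(0), m$min)
    expect_equal(m$qfun(0.25), m$q1)
    expect_equal(m$qfun(0.5), m$median)
    expect_equal(m$qfun(0.75), m$q3)
    expect_equal(m$qfun(1), m$max)
    # monotone
    p <- seq(0, 1, length.out = 101)
    expect_true(all(diff(m$qfun(p)) >= 0))
  }
  expect_error(cohort_margin(1, 2, 3, 0, 10), "ordered")
})

test_that("lognormal margins match the quartiles and respect the range", {
  for (nm in c("la_mm2", "ez_t0_um", "minimum_diameter_um",
               "abs_delta_bcva_logmar")) {
    m <- default_margins("lognormal")[[nm]]
    expect_equal(m$qfun(0.5), m$median, tolerance = 1e-9)
    expect_equal(m$qfun(0.25), m$q1, tolerance = 1e-9)
    expect_equal(m$qfun(0.75), m$q3, tolerance = 1e-9)
    p <- seq(0.001, 0.999, length.out = 200)
    v <- m$qfun(p)
    expect_true(all(v >= m$min - 1e-12 & v <= m$max + 1e-12))
  }
})

test_that("generated cohorts conserve areas, respect bounds and are reproducible", {
  spec <- cohort_spec(n = 300, seed = 42)
  co <- generate_cohort(spec)
  expect_equal(nrow(co), 300L)
  expect_identical(co, generate_cohort(spec))
  expect_false(identical(co$la_mm2,
                         generate_cohort(cohort_spec(n = 300, seed = 43))$la_mm2))
  # conservation is exact by construction
  pra <- co$ta_mm2 - co$la_mm2
  m <- default_margins()
  expect_true(all(co$la_mm2 >= m$la_mm2$min & co$la_mm2 <= m$la_mm2$max))
  expect_true(all(pra >= m$pra_mm2$min & pra <= m$pra_mm2$max))
  expect_true(all(co$minimum_diameter_um >= m$minimum_diameter_um$min &
                    co$minimum_diameter_um <= m$minimum_diameter_um$max))
  expect_true(all(co$bcva_t1_logmar >= 0))
  expect_true(all(co$ez_t1_um >= 0))
  expect_true(all(co$elm_t1_um >= 0))
  expect_true(all(co$sex %in% c("F", "M")))
})

test_that("grader stream is isolated from the primary measurements", {
  a <- generate_cohort(cohort_spec(n = 50, seed = 5))
  b <- generate_cohort(cohort_spec(n = 50, seed = 5, grader_seed = 99))
  prim <- setdiff(names(a), c("grader2_la_mm2", "grader2_ta_mm2"))
  expect_identical(a[prim], b[prim])
  expect_false(identical(a$grader2_la_mm2, b$grader2_la_mm2))
})

test_that("grader-noise calibration: Monte-Carlo agrees with the closed form", {
  m <- default_margins()$la_mm2
  mc <- calibrate_grader_sigma(m, 0.997, method = "monte-carlo", seed = 2)
  cf <- calibrate_grader_sigma(m, 0.997, method = "closed-form", seed = 2)
  expect_lt(abs(mc / cf - 1), 0.05)
  p <- default_margins()$pra_mm2
  mc2 <- calibrate_grader_sigma(p, 0.962, method = "monte-carlo", seed = 2)
  cf2 <- calibrate_grader_sigma(p, 0.962, method = "closed-form", seed = 2)
  expect_lt(abs(mc2 / cf2 - 1), 0.05)
  expect_error(calibrate_grader_sigma(m, 1.5), "strictly inside")
})

test_that("cohort-derived phantoms match the tabulated areas within 1%", {
  co <- generate_cohort(cohort_spec(n = 12, seed = 3))
  rc <- render_cohort_phantoms(co, seed = 3)
  expect_true(all(rc$truth$rendered))
  expect_true(all(abs(rc$truth$la_true / co$la_mm2 - 1) < 0.01))
  expect_true(all(abs(rc$truth$ta_true / co$ta_mm2 - 1) < 0.01))
  # deterministic per seed
  rc2 <- render_cohort_phantoms(co, seed = 3)
  expect_identical(rc$truth, rc2$truth)
  expect_identical(rc$phantoms[[1]]$image$pixels, rc2$phantoms[[1]]$image$pixels)
  # infeasible pair is skipped with a warning
  bad <- data.frame(la_mm2 = c(0.15, 0.15), ta_mm2 = c(0.30, 8.5))
  expect_warning(rcb <- render_cohort_phantoms(bad, seed = 1), "infeasible")
  expect_equal(rcb$truth$rendered, c(TRUE, FALSE))
})

test_that("measurement of a cohort phantom closes the loop within 5%", {
  co <- generate_cohort(cohort_spec(n = 4, seed = 11))
  rc <- render_cohort_phantoms(co, speckle_sigma = 0.1, seed = 11)
  for (id in names(rc$phantoms)) {
    res <- measure_eye(rc$phantoms[[id]]$image)
    tr <- rc$phantoms[[id]]$truth
    expect_lt(rel_err(res$area_set$total_area, tr$total_area), 0.05)
    expect_lt(rel_err(res$area_set$luminal_area, tr$luminal_area), 0.05)
  }
})
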