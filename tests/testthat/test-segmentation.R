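test_that("mask_area is exact pixel-count arithmetic", {
  img <- enface_image(matrix(0.5, 300, 300))
  m <- matrix(FALSE, 300, 300)
  expect_equal(mask_area(m, img), 0)
  m[1:100, 1:100] <- TRUE
  expect_equal(mask_area(m, img), 1)
  expect_equal(mask_area(matrix(TRUE, 300, 300), img), 9)
  expect_error(mask_area(matrix(TRUE, 10, 10), img), "dimensions differ")
})

test_that("mask_area is additive over disjoint masks and translation-invariant", {
  img <- enface_image(matrix(0.5, 120, 120))
  a <- matrix(FALSE, 120, 120); a[10:30, 10:30] <- TRUE
  b <- matrix(FALSE, 120, 120); b[60:90, 50:80] <- TRUE
  expect_equal(mask_area(a | b, img), mask_area(a, img) + mask_area(b, img))
  shifted <- matrix(FALSE, 120, 120); shifted[40:60, 70:90] <- TRUE
  expect_equal(mask_area(shifted, img), mask_area(a, img))
})

test_that("enface_image validates geometry and intensities", {
  expect_error(enface_image(matrix(0.5, 100, 200)), "non-square pixels")
  expect_error(enface_image(matrix(2, 10, 10)), "\\[0, 1\\]")
  expect_error(enface_image(matrix(0.5, 10, 10), field_width_mm = -1),
               "positive")
  img <- enface_image(matrix(0.5, 300, 300))
  expect_equal(img$pixel_size_mm, 0.01)
})

test_that("noise-free circular phantom is recovered within 2%", {
  ph <- quick_phantom(0.2, 0.1)
  res <- measure_eye(ph$image)
  expect_lt(rel_err(res$area_set$total_area, pi * 0.09), 0.02)
  expect_lt(rel_err(res$area_set$luminal_area, pi * 0.04), 0.02)
  expect_lt(rel_err(res$area_set$photoreceptor_area, pi * 0.05), 0.02)
})

test_that("speckled phantom is recovered within 5% and is deterministic", {
  ph <- generate_phantom(phantom_spec(lumen_a_mm = 0.2, ring_width_mm = 0.1,
                                      speckle_sigma = 0.15, seed = 5))
  r1 <- measure_eye(ph$image)
  expect_lt(rel_err(r1$area_set$total_area, pi * 0.09), 0.05)
  expect_lt(rel_err(r1$area_set$luminal_area, pi * 0.04), 0.05)
  r2 <- measure_eye(ph$image)
  expect_identical(r1$total_mask, r2$total_mask)
  expect_identical(r1$lumen_mask, r2$lumen_mask)
  expect_identical(r1$area_set, r2$area_set)
})

test_that("elliptical lumen area is recovered within 2%", {
  ph <- generate_phantom(phantom_spec(lumen_a_mm = 0.25, lumen_b_mm = 0.15,
                                      ring_width_mm = 0.1))
  res <- measure_eye(ph$image)
  expect_lt(rel_err(res$area_set$luminal_area, pi * 0.25 * 0.15), 0.02)
})

test_that("bumpy-border phantom recovers the polygon-integrated truth within 5%", {
  ph <- generate_phantom(phantom_spec(lumen_a_mm = 0.2, ring_width_mm = 0.1,
                                      bump_amplitude_mm = 0.03,
                                      bump_lobes = 8))
  res <- measure_eye(ph$image)
  expect_lt(rel_err(res$area_set$total_area, ph$truth$total_area), 0.05)
})

test_that("lumen mask is strictly inside the total mask", {
  for (r in c(0.12, 0.25, 0.35)) {
    ph <- quick_phantom(r, 0.08)
    res <- measure_eye(ph$image)
    expect_true(all(res$total_mask[res$lumen_mask]))
    expect_identical(res$photoreceptor_mask, res$total_mask & !res$lumen_mask)
    # masks are filled single components
    lab <- piin:::.cc_label(res$total_mask, 8L)
    expect_equal(max(lab), 1L)
  }
})

test_that("segmentation failures are reported with the failing stage", {
  blank <- enface_image(matrix(0.5, 300, 300))
  expect_error(segment_total_area(blank), "segmentation failed \\[total area\\]")
  # bright disk without a dark core: no lumen
  px <- matrix(0.4, 300, 300)
  ctr <- expand.grid(r = 1:300, c = 1:300)
  d <- sqrt((ctr$r - 150.5)^2 + (ctr$c - 150.5)^2)
  px[d <= 30] <- 0.9
  img <- enface_image(px)
  tm <- segment_total_area(img)
  expect_error(segment_lumen(img, tm), "no lumen detected")
  # manual-override path: supplying masks skips the automatic stages
  ph <- quick_phantom()
  auto <- measure_eye(ph$image)
  manual <- measure_eye(ph$image, total_mask = auto$total_mask,
                        lumen_mask = auto$lumen_mask)
  expect_identical(manual$area_set, auto$area_set)
})

test_that("recovered areas are scale-equivariant between 5 and 10 um/px", {
  r10 <- measure_eye(quick_phantom(0.2, 0.1, pixel_size_um = 10)$image)
  r5 <- measure_eye(quick_phantom(0.2, 0.1, pixel_size_um = 5)$image)
  expect_lt(rel_err(r5$area_set$total_area, r10$area_set$total_area), 0.02)
  expect_lt(rel_err(r5$area_set$luminal_area, r10$area_set$luminal_area), 0.02)
})

test_that("otsu_threshold separates a well-split bimodal sample", {
  v <- c(rnorm(400, 0.2, 0.02), rnorm(100, 0.8, 0.02))
  thr <- otsu_threshold(v)
  expect_gt(thr, 0.3)
  expect_lt(thr, 0.7)
})
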