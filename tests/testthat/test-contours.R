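test_that("uniform positive counts threshold to the entire VOI", {
  g <- make_test_grid(10L, 5)
  counts <- count_volume(array(3, rep(10, 3)), g)
  voi <- contour_mask(array(rep(c(TRUE, FALSE), each = 500), rep(10, 3)), g)
  thr <- threshold_contour(counts, voi, 0.10)
  expect_identical(thr$values, voi$values)
})

test_that("threshold contours are invariant to positive count rescaling", {
  g <- make_test_grid(10L, 5)
  v <- array(runif(1000), rep(10, 3))
  voi <- full_mask(g)
  a <- threshold_contour(count_volume(v, g), voi, 0.10)
  b <- threshold_contour(count_volume(v * 7.3, g), voi, 0.10)
  expect_identical(a$values, b$values)
})

test_that("larger threshold fractions give subset masks (monotonicity)", {
  g <- make_test_grid(12L, 5)
  v <- array(runif(12^3), rep(12, 3))
  voi <- full_mask(g)
  frac <- c(0.05, 0.1, 0.3, 0.6)
  masks <- lapply(frac, function(f) threshold_contour(count_volume(v, g), voi, f))
  for (k in seq_along(frac)[-1]) {
    expect_true(all(masks[[k]]$values <= masks[[k - 1]]$values))
  }
})

test_that("ties at exactly the threshold level are excluded (strict >)", {
  g <- make_test_grid(4L, 5)
  v <- array(0, rep(4, 3))
  v[1, 1, 1] <- 100; v[2, 1, 1] <- 10; v[3, 1, 1] <- 10.001
  thr <- threshold_contour(count_volume(v, g), full_mask(g), 0.10)
  expect_false(thr$values[2, 1, 1])
  expect_true(thr$values[3, 1, 1])
})

test_that("empty VOI errors; all-zero counts warn and return an empty mask", {
  g <- make_test_grid(6L, 5)
  counts <- count_volume(array(0, rep(6, 3)), g)
  empty <- contour_mask(array(FALSE, rep(6, 3)), g)
  expect_error(threshold_contour(counts, empty), "empty")
  expect_warning(thr <- threshold_contour(counts, full_mask(g)), "zero")
  expect_equal(sum(thr$values), 0L)
})

test_that("on a blurred hot-tumor phantom the threshold target exceeds the tumor", {
  ph <- make_phantom(small_phantom_spec(tnr_true = 10))
  cts <- simulate_counts(ph, psf_fwhm_mm = 15, total_counts = 5e6, seed = 5)
  voi <- sirtdose:::voi_box(ph$liver, 2L)
  thr <- threshold_contour(cts, voi, 0.10)
  expect_gt(mask_volume_ml(thr), mask_volume_ml(ph$tumor))
})

test_that("normal liver is the set difference and volumes add up", {
  g <- make_test_grid(12L, 5)
  liver <- array(FALSE, rep(12, 3)); liver[2:11, 2:11, 2:11] <- TRUE
  tumor <- array(FALSE, rep(12, 3)); tumor[4:7, 4:7, 4:7] <- TRUE
  lm <- contour_mask(liver, g, "liver"); tm <- contour_mask(tumor, g, "tumor")
  nl <- normal_liver(lm, tm)
  expect_equal(mask_volume_ml(lm), mask_volume_ml(tm) + mask_volume_ml(nl))
  expect_false(any(nl$values & tm$values))
  # empty tumor -> normal liver is the whole liver
  none <- contour_mask(array(FALSE, rep(12, 3)), g, "tumor")
  expect_identical(normal_liver(lm, none)$values, lm$values)
})

test_that("tumor equal to liver leaves no normal liver and TNR must error", {
  g <- make_test_grid(8L, 5)
  lm <- full_mask(g, "liver")
  nl <- normal_liver(lm, lm)
  expect_equal(sum(nl$values), 0L)
  counts <- count_volume(array(1, rep(8, 3)), g)
  expect_error(tnr(counts, lm, nl), "non-empty")
})

test_that("tumor voxels outside the liver are clipped with warning or rejected", {
  g <- make_test_grid(8L, 5)
  liver <- array(FALSE, rep(8, 3)); liver[1:4, , ] <- TRUE
  tumor <- array(FALSE, rep(8, 3)); tumor[3:6, 1:2, 1:2] <- TRUE
  lm <- contour_mask(liver, g); tm <- contour_mask(tumor, g)
  expect_warning(nl <- normal_liver(lm, tm), "clipped")
  expect_true(all(!nl$values[!liver]))
  expect_error(normal_liver(lm, tm, outside = "error"), "outside")
})

test_that("Dice matches hand arithmetic and is symmetric", {
  g <- make_test_grid(10L, 5)
  a <- array(FALSE, rep(10, 3)); a[1:100] <- TRUE             # 100 voxels
  b <- array(FALSE, rep(10, 3)); b[21:120] <- TRUE            # 100, overlap 80
  ma <- contour_mask(a, g); mb <- contour_mask(b, g)
  expect_equal(dice(ma, mb), 2 * 80 / 200)
  expect_equal(dice(ma, mb), dice(mb, ma))
  expect_equal(dice(ma, ma), 1)
  disjoint <- contour_mask(array(c(rep(FALSE, 500), rep(TRUE, 500)),
                                 rep(10, 3)), g)
  first_half <- contour_mask(array(c(rep(TRUE, 500), rep(FALSE, 500)),
                                   rep(10, 3)), g)
  expect_equal(dice(first_half, disjoint), 0)
  empty <- contour_mask(array(FALSE, rep(10, 3)), g)
  expect_error(dice(empty, empty), "empty")
})

test_that("registration QA gate is inclusive at 0.85", {
  expect_true(registration_qa(0.93))
  expect_true(registration_qa(0.85))
  expect_warning(fail <- registration_qa(0.70, patient_id = "P007"), "P007")
  expect_false(fail)
  expect_error(registration_qa(1.2), "\\[0, 1\\]")
})

test_that("inter-operator RMS-CV matches hand arithmetic", {
  expect_equal(interoperator_rms_cv(cbind(c(100, 50), c(100, 50))), 0)
  expect_equal(interoperator_rms_cv(cbind(95, 105)),
               100 * (sd(c(95, 105)) / 100), tolerance = 1e-12)
  expect_equal(interoperator_rms_cv(cbind(95, 105)), 7.0711, tolerance = 1e-4)
  expect_error(interoperator_rms_cv(cbind(-1, 5)), "positive")
})

test_that("contour sets enforce the partition invariants", {
  g <- make_test_grid(10L, 5)
  liver <- array(FALSE, rep(10, 3)); liver[2:9, 2:9, 2:9] <- TRUE
  tumor <- array(FALSE, rep(10, 3)); tumor[4:6, 4:6, 4:6] <- TRUE
  cs <- contour_set(contour_mask(liver, g), contour_mask(tumor, g),
                    provenance = "C_MRI")
  expect_true(all(cs$tumor$values <= cs$liver$values))
  expect_identical(cs$normal_liver$values, liver & !tumor)
})
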