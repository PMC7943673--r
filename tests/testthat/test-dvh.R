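uniform_dose <- function(value, n = 6L, spacing = 10) {
  g <- make_test_grid(n, spacing)
  raw_dose_map(array(value, rep(n, 3)), g)
}

test_that("a uniform 50 Gy contour gives a step DVH with Dm = D70 = 50", {
  d <- uniform_dose(50)
  m <- full_mask(d$grid)
  dvh <- cumulative_dvh(d, m)
  expect_equal(dvh$volume_fraction[dvh$dose_gy <= 50], rep(1, sum(dvh$dose_gy <= 50)))
  expect_equal(mean_dose(d, m), 50)
  expect_equal(d_percent(dvh, 70), 50)
  expect_equal(d_percent(dvh, 30), 50)
})

test_that("two equal-volume dose levels behave per the exact curve", {
  g <- voxel_grid(c(2L, 1L, 1L), 10)
  d <- raw_dose_map(array(c(10, 30), c(2, 1, 1)), g)
  m <- full_mask(g)
  dvh <- cumulative_dvh(d, m)
  # volume fraction at 20 Gy is 0.5; mean is 20; D70 needs the cooler voxel
  coverage_at <- function(x) dvh$volume_fraction[min(which(dvh$dose_gy >= x))]
  expect_equal(coverage_at(20), 0.5)
  expect_equal(mean_dose(d, m), 20)
  expect_equal(d_percent(dvh, 70), oracle_d_percent(c(10, 30), 70))
  expect_equal(d_percent(dvh, 70), 10)
  expect_equal(d_percent(dvh, 50), 30)
})

test_that("d_percent matches the brute-force subset oracle on random tiny maps", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(2:10, 1)
    doses <- round(runif(n, 0, 100), 1)
    g <- voxel_grid(c(n, 1L, 1L), 10)
    dvh <- cumulative_dvh(raw_dose_map(array(doses, c(n, 1, 1)), g),
                          full_mask(g))
    for (p in c(20, 50, 70, 90)) {
      expect_equal(d_percent(dvh, p), oracle_d_percent(doses, p),
                   info = sprintf("n=%d p=%d", n, p))
    }
  }
})

test_that("DVH is non-increasing, starts at 1, and integrates to the mean", {
  set.seed(12)
  g <- make_test_grid(10L, 6)
  d <- raw_dose_map(array(rgamma(1000, 2, 0.02), rep(10, 3)), g)
  m <- full_mask(g)
  dvh <- cumulative_dvh(d, m)
  expect_true(all(diff(dvh$volume_fraction) <= 0))
  expect_equal(dvh$volume_fraction[1], 1)
  expect_equal(dvh_integral(dvh), mean_dose(d, m), tolerance = 1e-9)
})

test_that("binned DVH agrees with the exact curve to within one bin width", {
  set.seed(13)
  g <- make_test_grid(8L, 6)
  d <- raw_dose_map(array(rgamma(512, 2, 0.02), rep(8, 3)), g)
  m <- full_mask(g)
  exact <- cumulative_dvh(d, m)
  bw <- 0.5
  binned <- cumulative_dvh(d, m, bin_width_gy = bw)
  doses <- d$values[m$values]
  # binned curve is the true coverage evaluated at the bin edges
  expect_equal(binned$volume_fraction,
               vapply(binned$dose_gy, function(x) mean(doses >= x), numeric(1)))
  for (p in seq(10, 90, by = 10)) {
    expect_lte(abs(d_percent(binned, p) - d_percent(exact, p)), bw)
  }
})

test_that("d_percent is monotone decreasing in the percent and bounded by Dmax", {
  set.seed(14)
  g <- make_test_grid(6L, 6)
  d <- raw_dose_map(array(runif(216, 0, 120), rep(6, 3)), g)
  dvh <- cumulative_dvh(d, full_mask(g))
  ps <- c(10, 30, 50, 70, 90)
  vals <- vapply(ps, function(p) d_percent(dvh, p), numeric(1))
  expect_true(all(diff(vals) <= 0))
  expect_lte(vals[1], max(d$values))
  expect_error(d_percent(dvh, 0), "percent")
  expect_error(d_percent(dvh, 100), "percent")
})

test_that("empty contours are rejected by DVH and mean dose", {
  d <- uniform_dose(10)
  empty <- contour_mask(array(FALSE, d$grid$shape), d$grid)
  expect_error(cumulative_dvh(d, empty), "empty")
  expect_error(mean_dose(d, empty), "empty")
})

test_that("TNR matches hand arithmetic on exact volumes and rescales away", {
  g <- make_test_grid(10L, 10)  # 1 mL voxels
  v <- array(0, rep(10, 3))
  tum <- array(FALSE, rep(10, 3)); tum[1:100] <- TRUE       # 100 mL
  nl <- array(FALSE, rep(10, 3)); nl[101:600] <- TRUE       # 500 mL
  v[tum] <- 10   # 1000 counts total in tumor
  v[nl] <- 1     # 500 counts total in normal liver
  counts <- count_volume(v, g)
  tm <- contour_mask(tum, g); nm <- contour_mask(nl, g)
  expect_equal(tnr(counts, tm, nm), (1000 / 100) / (500 / 500))
  expect_equal(tnr(counts, tm, nm), 10)
  counts3 <- count_volume(v * 3, g)
  expect_equal(tnr(counts3, tm, nm), 10, tolerance = 1e-12)
})

test_that("equal concentrations give TNR 1; overlap and zero NL counts error", {
  g <- make_test_grid(8L, 10)
  v <- array(2, rep(8, 3))
  a <- array(FALSE, rep(8, 3)); a[1:100] <- TRUE
  b <- array(FALSE, rep(8, 3)); b[101:400] <- TRUE
  counts <- count_volume(v, g)
  expect_equal(tnr(counts, contour_mask(a, g), contour_mask(b, g)), 1)
  overlap <- array(FALSE, rep(8, 3)); overlap[50:200] <- TRUE
  expect_error(tnr(counts, contour_mask(a, g), contour_mask(overlap, g)),
               "overlap")
  zero <- count_volume(array(c(rep(1, 100), rep(0, 412)), rep(8, 3)), g)
  expect_error(tnr(zero, contour_mask(a, g), contour_mask(b, g)), "zero counts")
})

test_that("tumor burden is the volume percentage with its guard rails", {
  expect_equal(tumor_burden(203, 1813), 100 * 203 / 1813)
  expect_equal(tumor_burden(203, 1813), 11.2, tolerance = 1e-2)
  expect_equal(tumor_burden(100, 100), 100)
  expect_equal(tumor_burden(1, 100), 1)
  expect_error(tumor_burden(120, 100), "exceeds")
  expect_error(tumor_burden(0, 100), "positive")
})

test_that("noiseless unblurred phantoms recover truth: TNR 1e-9, Dm/D70 1e-6", {
  ph <- make_phantom(small_phantom_spec(tnr_true = 6.5))
  cts <- noiseless_counts(ph, scale = 3.7e5)
  expect_equal(tnr(cts, ph$tumor, ph$normal_liver), 6.5, tolerance = 1e-9)
  act <- relative_calibration(cts, ph$liver, ph$spec$injected_activity_gbq)
  d <- ldm_dose(act)
  truth <- ph$true_metrics
  for (region in c("tumor", "normal_liver")) {
    mask <- ph[[region]]
    row <- truth[truth$region == region, ]
    expect_equal(mean_dose(d, mask), row$Dm, tolerance = 1e-6)
    expect_equal(d_percent(cumulative_dvh(d, mask), 70), row$D70,
                 tolerance = 1e-6)
  }
})

test_that("dose_metrics emits the self-describing Table-style names", {
  ph <- make_phantom(small_phantom_spec())
  cts <- noiseless_counts(ph)
  d <- ldm_dose(relative_calibration(cts, ph$liver, 1.6))
  cs <- contour_set(ph$liver, ph$tumor, provenance = "C_MRI")
  m <- dose_metrics(d, cts, cs, "Pre")
  expect_setequal(m$metric,
                  c("Dm-Pre-C_MRI", "D70-Pre-C_MRI", "TNR-Pre-C_MRI"))
  voi <- sirtdose:::voi_box(ph$liver)
  thr <- threshold_contour(cts, voi, 0.10)
  cs2 <- contour_set(ph$liver, ph$tumor, target_threshold = thr,
                     provenance = "C_PET")
  m2 <- dose_metrics(d, cts, cs2, "Post")
  expect_setequal(m2$metric, c("Dm-Post-C_PET", "D70-Post-C_PET"))
})
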