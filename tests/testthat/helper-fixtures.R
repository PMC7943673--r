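# Shared fixtures and independent oracles. Oracles are deliberately naive
# (enumeration / direct definition) and never call the code paths they check.

make_test_grid <- function(n = 16L, spacing = 4, origin = NULL) {
  voxel_grid(rep(n, 3L), spacing, origin_mm = origin)
}

# dose_map from a bare array without running the calibration chain
raw_dose_map <- function(values, grid) {
  structure(list(values = values, grid = grid, constants = y90_constants()),
            class = "dose_map")
}

full_mask <- function(grid, label = "roi") {
  contour_mask(array(TRUE, grid$shape), grid, label)
}

# brute-force D_p oracle: over all voxel subsets covering at least p of the
# volume, the best achievable minimum dose. Equivalent closed form: take the
# ceil(p*n) hottest voxels and report their minimum. Enumerates subsets for
# tiny n to keep the oracle independent of that closed form.
oracle_d_percent <- function(doses, percent) {
  n <- length(doses)
  p <- percent / 100
  if (n <= 12) {
    best <- -Inf
    for (m in 0:(2^n - 1)) {
      sel <- as.logical(bitwAnd(m, bitwShiftL(1L, 0:(n - 1))))
      if (sum(sel) / n >= p) best <- max(best, min(doses[sel]))
    }
    best
  } else {
    sort(doses, decreasing = TRUE)[ceiling(p * n)]
  }
}

# empirical survivor function at each event time (no censoring allowed)
oracle_empirical_survival <- function(times, at) {
  vapply(at, function(t) mean(times > t), numeric(1))
}

# cross-product odds ratio of a 2x2 table (a,b,c,d) laid out as
# rows = covariate (FALSE, TRUE), cols = outcome (FALSE, TRUE)
oracle_or <- function(a, b, c, d) (a * d) / (b * c)

# expand a 2x2 table into covariate/outcome vectors
table_to_vectors <- function(a, b, c, d) {
  list(
    label = rep(c(FALSE, FALSE, TRUE, TRUE), times = c(a, b, c, d)),
    outcome = rep(c(FALSE, TRUE, FALSE, TRUE), times = c(a, b, c, d))
  )
}

small_phantom_spec <- function(seed = 1L, tnr_true = 7.7, ...) {
  phantom_spec(grid_shape = c(28L, 28L, 28L), voxel_size_mm = 7,
               liver_semiaxes_mm = c(80, 70, 55),
               tumors = data.frame(x = 10, y = 0, z = 0, radius_mm = 30,
                                   necrotic_fraction = 0),
               tnr_true = tnr_true, seed = seed, ...)
}

# noiseless counts proportional to the true activity (arbitrary scale)
noiseless_counts <- function(truth, scale = 1e6, modality = "SPECT") {
  count_volume(truth$activity$values * scale, truth$grid, modality)
}
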