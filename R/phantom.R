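#' Specification of a synthetic liver phantom
#'
#' Describes an ellipsoidal liver containing one or more spherical tumors on
#' a regular voxel grid, with a prescribed tumor-to-normal activity
#' concentration ratio and injected activity. Tumors may carry a necrotic
#' core (a concentric sphere holding zero activity). The phantom stands in
#' for the patient anatomy (MRI-delineated liver/tumor) and its microsphere
#' activity distribution.
#'
#' @param grid_shape integer triple, voxels per axis (default 48^3).
#' @param voxel_size_mm voxel spacing in mm (default 4.42, cubic).
#' @param liver_center_mm,liver_semiaxes_mm ellipsoid centre and semi-axes in
#'   mm. Defaults give a liver of roughly 1.8 L.
#' @param tumors data frame with columns `x`, `y`, `z`, `radius_mm` (one row
#'   per spherical tumor, centres in mm) and optional `necrotic_fraction`
#'   (fraction of the radius occupied by a zero-activity core, in \[0, 1)).
#'   Default: a single 36.6 mm sphere (~205 mL) at the liver centre.
#' @param tnr_true prescribed tumor:normal activity-concentration ratio (> 0).
#' @param injected_activity_gbq injected activity in GBq (default 1.6, a
#'   typical administered activity).
#' @param lung_shunt_fraction fraction of activity shunted away from the
#'   liver, default 0.
#' @param psf_fwhm_mm default PSF for count simulation (15 mm, SPECT-like).
#' @param total_counts default expected total counts for simulation.
#' @param seed integer seed driving all randomness derived from this spec.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48L, 48L, 48L),
                         voxel_size_mm = 4.42,
                         liver_center_mm = c(0, 0, 0),
                         liver_semiaxes_mm = c(95, 80, 57),
                         tumors = data.frame(x = 0, y = 0, z = 0,
                                             radius_mm = 36.6,
                                             necrotic_fraction = 0),
                         tnr_true = 7.7,
                         injected_activity_gbq = 1.6,
                         lung_shunt_fraction = 0,
                         psf_fwhm_mm = 15,
                         total_counts = 5e6,
                         seed = 1L) {
  stopifnot(tnr_true > 0, injected_activity_gbq > 0,
            lung_shunt_fraction >= 0, lung_shunt_fraction < 1,
            psf_fwhm_mm >= 0, total_counts > 0,
            all(liver_semiaxes_mm > 0))
  tumors <- as.data.frame(tumors)
  if (!all(c("x", "y", "z", "radius_mm") %in% names(tumors))) {
    stop("`tumors` needs columns x, y, z, radius_mm", call. = FALSE)
  }
  if (is.null(tumors$necrotic_fraction)) tumors$necrotic_fraction <- 0
  stopifnot(all(tumors$radius_mm > 0),
            all(tumors$necrotic_fraction >= 0),
            all(tumors$necrotic_fraction < 1))
  structure(
    list(grid_shape = as.integer(grid_shape), voxel_size_mm = voxel_size_mm,
         liver_center_mm = liver_center_mm,
         liver_semiaxes_mm = liver_semiaxes_mm, tumors = tumors,
         tnr_true = tnr_true, injected_activity_gbq = injected_activity_gbq,
         lung_shunt_fraction = lung_shunt_fraction,
         psf_fwhm_mm = psf_fwhm_mm, total_counts = total_counts,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Realise a phantom: labels, activity and true dose
#'
#' Voxelises the geometry and builds the ground truth every downstream stage
#' is checked against. Activity concentration is uniform within the normal
#' liver and within viable tumor, with the prescribed concentration ratio
#' `tnr_true`; necrotic cores hold zero activity; total liver activity equals
#' `injected_activity_gbq * (1 - lung_shunt_fraction)` exactly. The true dose
#' map is computed from the noiseless activity by the same local deposition
#' method as the measurement pipeline, and true Dm/D70 are read per region
#' from that map.
#'
#' @param spec a [phantom_spec()].
#' @param constants [y90_constants()] for the true dose map.
#' @return A list of class `phantom_truth`: `grid`, `labels` (0 background,
#'   1 normal liver, 2 viable tumor, 3 necrosis), masks (`liver`, `tumor`,
#'   `normal_liver`), `activity` (activity_map, GBq/voxel), `dose`
#'   (dose_map, Gy), `tnr_true`, and a tibble `true_metrics` with Dm/D70 per
#'   region, plus the `spec`.
#' @export
make_phantom <- function(spec, constants = y90_constants()) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- voxel_grid(spec$grid_shape, spec$voxel_size_mm)
  cx <- axis_coords(grid, 1); cy <- axis_coords(grid, 2); cz <- axis_coords(grid, 3)
  sh <- grid$shape

  # ellipsoid liver: sum of squared scaled axis distances <= 1
  ex <- ((cx - spec$liver_center_mm[1]) / spec$liver_semiaxes_mm[1])^2
  ey <- ((cy - spec$liver_center_mm[2]) / spec$liver_semiaxes_mm[2])^2
  ez <- ((cz - spec$liver_center_mm[3]) / spec$liver_semiaxes_mm[3])^2
  liver <- outer(outer(ex, ey, `+`), ez, `+`) <= 1
  if (!any(liver)) stop("degenerate geometry: liver has zero volume", call. = FALSE)

  tumor <- array(FALSE, sh)
  necro <- array(FALSE, sh)
  for (k in seq_len(nrow(spec$tumors))) {
    tu <- spec$tumors[k, ]
    r2 <- outer(outer((cx - tu$x)^2, (cy - tu$y)^2, `+`), (cz - tu$z)^2, `+`)
    sph <- r2 <= tu$radius_mm^2
    if (any(sph & !liver)) {
      stop("geometry error: tumor sphere ", k, " extends outside the liver",
           call. = FALSE)
    }
    tumor <- tumor | sph
    if (tu$necrotic_fraction > 0) {
      necro <- necro | (r2 <= (tu$necrotic_fraction * tu$radius_mm)^2)
    }
  }
  if (!any(tumor)) stop("degenerate geometry: tumor has zero volume", call. = FALSE)

  labels <- array(0L, sh)
  labels[liver] <- 1L
  labels[tumor] <- 2L
  labels[necro] <- 3L

  # uniform concentrations with ratio tnr_true; necrosis carries none.
  # c_nl * (V_nl + tnr * V_viable) = A_liver  (per-voxel volumes cancel)
  n_nl <- sum(labels == 1L)
  n_viable <- sum(labels == 2L)
  a_liver <- spec$injected_activity_gbq * (1 - spec$lung_shunt_fraction)
  if (n_nl == 0L && n_viable == 0L) {
    stop("degenerate geometry: no activity-bearing voxels", call. = FALSE)
  }
  a_nl_voxel <- a_liver / (n_nl + spec$tnr_true * n_viable)
  activity <- array(0, sh)
  activity[labels == 1L] <- a_nl_voxel
  activity[labels == 2L] <- a_nl_voxel * spec$tnr_true
  activity <- structure(list(values = activity, grid = grid,
                             injected_gbq = a_liver),
                        class = "activity_map")
  dose <- ldm_dose(activity, constants)

  liver_mask <- contour_mask(liver, grid, "liver")
  tumor_mask <- contour_mask(tumor, grid, "tumor")
  nl_mask <- contour_mask(liver & !tumor, grid, "normal_liver")

  region_metrics <- function(mask, region) {
    dvh <- cumulative_dvh(dose, mask)
    tibble::tibble(region = region,
                   Dm = mean_dose(dose, mask),
                   D70 = d_percent(dvh, 70),
                   volume_ml = mask_volume_ml(mask))
  }
  true_metrics <- dplyr::bind_rows(
    region_metrics(tumor_mask, "tumor"),
    region_metrics(nl_mask, "normal_liver"),
    region_metrics(liver_mask, "liver")
  )

  # true TNR from the activity volume (equals tnr_true when no necrosis)
  vv <- voxel_volume_ml(grid)
  conc_tum <- sum(activity$values[tumor]) / (sum(tumor) * vv)
  conc_nl <- sum(activity$values[nl_mask$values]) / (sum(nl_mask$values) * vv)
  structure(
    list(grid = grid, labels = labels, liver = liver_mask,
         tumor = tumor_mask, normal_liver = nl_mask,
         activity = activity, dose = dose,
         tnr_true = conc_tum / conc_nl,
         true_metrics = true_metrics, spec = spec),
    class = "phantom_truth"
  )
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth> liver ", signif(mask_volume_ml(x$liver), 4), " mL, tumor ",
      signif(mask_volume_ml(x$tumor), 4), " mL, true TNR ",
      signif(x$tnr_true, 4), "\n", sep = "")
  invisible(x)
}

# Separable Gaussian blur via 3-D FFT circular convolution. The kernel is
# built wrapped and normalised to sum 1, so the total of the blurred volume
# equals the total of the input exactly (activity near the grid edge is ~0 in
# all phantoms, so wraparound leakage is negligible).
gaussian_blur3d <- function(values, voxel_size_mm, fwhm_mm) {
  if (fwhm_mm == 0) return(values)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  sh <- dim(values)
  k1 <- lapply(1:3, function(ax) {
    n <- sh[ax]
    d <- (0:(n - 1))
    wrapped <- pmin(d, n - d) * voxel_size_mm[min(ax, length(voxel_size_mm))]
    g <- exp(-wrapped^2 / (2 * sigma^2))
    g / sum(g)
  })
  kern <- outer(outer(k1[[1]], k1[[2]]), k1[[3]])
  out <- Re(stats::fft(stats::fft(values) * stats::fft(kern), inverse = TRUE)) /
    length(values)
  pmax(out, 0)
}

#' Simulate a scintigraphy-like count volume
#'
#' Emulates the imaging chain downstream of reconstruction: the activity
#' distribution is blurred with an isotropic Gaussian point-spread function
#' (FWHM in mm; ~15 mm SPECT-like, ~8 mm PET-like), scaled so the expected
#' total equals `total_counts`, and Poisson noise is drawn per voxel. The
#' draw is deterministic given `seed`. With `psf_fwhm_mm = 0` and counts
#' large the counts recover the activity shape up to one global scale factor.
#'
#' @param truth a [make_phantom()] result.
#' @param psf_fwhm_mm PSF full width at half maximum, mm (>= 0). Defaults to
#'   the value in the phantom spec.
#' @param total_counts expected total counts over the volume (> 0).
#' @param seed integer seed. Defaults to the spec seed.
#' @param modality tag for the output volume.
#' @return A [count_volume()].
#' @export
simulate_counts <- function(truth, psf_fwhm_mm = NULL, total_counts = NULL,
                            seed = NULL, modality = "SPECT") {
  stopifnot(inherits(truth, "phantom_truth"))
  if (is.null(psf_fwhm_mm)) psf_fwhm_mm <- truth$spec$psf_fwhm_mm
  if (is.null(total_counts)) total_counts <- truth$spec$total_counts
  if (is.null(seed)) seed <- truth$spec$seed
  if (psf_fwhm_mm < 0) stop("`psf_fwhm_mm` must be >= 0", call. = FALSE)
  if (total_counts <= 0) stop("`total_counts` must be > 0", call. = FALSE)
  lambda <- gaussian_blur3d(truth$activity$values,
                            truth$grid$voxel_size_mm, psf_fwhm_mm)
  lambda <- lambda * (total_counts / sum(lambda))
  counts <- withr::with_seed(as.integer(seed), {
    stats::rpois(length(lambda), lambda)
  })
  count_volume(array(as.numeric(counts), dim = dim(lambda)), truth$grid,
               modality = modality)
}
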