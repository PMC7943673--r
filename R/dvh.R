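#' Cumulative dose-volume histogram
#'
#' The cumulative DVH of a contour maps each dose level d to the fraction of
#' the contour volume receiving at least d Gy. The exact, sort-based curve —
#' one point per distinct voxel dose — is the reference used by all metric
#' computations; an optional fixed `bin_width_gy` regrids it onto bin edges
#' for export and plotting only, never for metric extraction (binning would
#' make D70 sensitive to the bin width).
#'
#' @param dose a `dose_map` from [ldm_dose()].
#' @param contour a non-empty [contour_mask()] on the same grid.
#' @param bin_width_gy optional bin width in Gy; `NULL` (default) returns the
#'   exact curve.
#' @return A `dvh_curve`: tibble with columns `dose_gy` (increasing) and
#'   `volume_fraction` (non-increasing, starting at 1 for dose 0), plus
#'   attributes `volume_ml` and `exact`.
#' @export
cumulative_dvh <- function(dose, contour, bin_width_gy = NULL) {
  stopifnot(inherits(dose, "dose_map"), inherits(contour, "contour_mask"))
  assert_aligned(dose, contour, "dose map and contour")
  if (!any(contour$values)) stop("contour is empty", call. = FALSE)
  d <- dose$values[contour$values]
  n <- length(d)
  if (is.null(bin_width_gy)) {
    # coverage(x) = fraction of voxels with dose >= x, evaluated at each
    # distinct dose via run lengths of the sorted doses (exact, O(n log n));
    # prepend dose 0 so the curve always starts at (0, 1)
    r <- rle(sort(d))
    dose_gy <- r$values
    vf <- (n - cumsum(r$lengths) + r$lengths) / n
    if (dose_gy[1] > 0) { dose_gy <- c(0, dose_gy); vf <- c(1, vf) }
    exact <- TRUE
  } else {
    stopifnot(bin_width_gy > 0)
    edges <- seq(0, max(d) + bin_width_gy, by = bin_width_gy)
    # voxels with dose >= edge, counted from the sorted doses
    below <- findInterval(edges, sort(d), left.open = TRUE)
    vf <- (n - below) / n
    dose_gy <- edges
    exact <- FALSE
  }
  curve <- tibble::tibble(dose_gy = dose_gy, volume_fraction = vf)
  structure(curve,
            class = c("dvh_curve", class(curve)),
            volume_ml = sum(contour$values) * voxel_volume_ml(contour$grid),
            exact = exact)
}

#' Mean absorbed dose over a contour
#'
#' Arithmetic mean of the voxel doses inside the contour (Gy). Equals the
#' integral of the cumulative DVH over dose, which [dvh_integral()] computes
#' exactly from the step curve.
#'
#' @inheritParams cumulative_dvh
#' @return Mean dose in Gy.
#' @export
mean_dose <- function(dose, contour) {
  stopifnot(inherits(dose, "dose_map"), inherits(contour, "contour_mask"))
  assert_aligned(dose, contour, "dose map and contour")
  if (!any(contour$values)) stop("contour is empty", call. = FALSE)
  mean(dose$values[contour$values])
}

#' Integral of a cumulative DVH over dose
#'
#' For the exact step curve this is \eqn{\int_0^\infty VF(d)\,dd}, which
#' equals the mean dose; useful as an internal consistency check.
#'
#' @param dvh a `dvh_curve`.
#' @return The integral in Gy.
#' @export
dvh_integral <- function(dvh) {
  stopifnot(inherits(dvh, "dvh_curve"))
  d <- dvh$dose_gy; vf <- dvh$volume_fraction
  # VF(x) = vf[j] on (d[j-1], d[j]]: right-continuous-from-the-left step curve
  sum(vf[-1] * diff(d)) + vf[1] * d[1]
}

#' Dose covering a given fraction of the volume (D70 and kin)
#'
#' D_p is the minimal absorbed dose delivered to the best-covered p% of the
#' contour volume: the largest dose level whose coverage (volume fraction
#' receiving at least that dose) still reaches p/100. On the exact sort-based
#' curve this is a voxel dose, e.g. two equal-volume voxels at 10 and 30 Gy
#' give D70 = 10 Gy (covering 70% of the volume requires the cooler voxel),
#' and a uniform region returns its dose. At ties the smallest qualifying
#' dose is returned. Set `interpolate = TRUE` to interpolate dose linearly in
#' volume fraction between curve points (only meaningful on binned curves).
#'
#' @param dvh a `dvh_curve` from [cumulative_dvh()].
#' @param percent coverage percentage in (0, 100); default 70.
#' @param interpolate linear interpolation between curve points, default
#'   `FALSE` (step convention).
#' @return Dose in Gy.
#' @export
d_percent <- function(dvh, percent = 70, interpolate = FALSE) {
  stopifnot(inherits(dvh, "dvh_curve"))
  if (percent <= 0 || percent >= 100) {
    stop("`percent` must lie strictly between 0 and 100", call. = FALSE)
  }
  d <- dvh$dose_gy; vf <- dvh$volume_fraction
  if (is.unsorted(d) || any(diff(vf) > 1e-12) || vf[1] < 1 - 1e-12 ||
      (length(d) && d[1] < 0)) {
    stop("malformed DVH curve", call. = FALSE)
  }
  p <- percent / 100
  ok <- which(vf >= p)
  if (!length(ok)) return(d[1])  # degenerate: nothing reaches p, floor dose
  # largest dose whose coverage still reaches p; on the exact curve the
  # volume fractions at distinct doses are strictly decreasing, so ties in
  # vf cannot occur there
  j <- max(ok)
  if (!interpolate || j == length(d) || vf[j] == p) return(d[j])
  # linear interpolation of dose as a function of volume fraction
  d[j] + (vf[j] - p) / (vf[j] - vf[j + 1]) * (d[j + 1] - d[j])
}

#' Tumor-to-normal-liver uptake ratio (TNR)
#'
#' Ratio of activity concentrations between tumor and healthy liver,
#' \deqn{TNR = \frac{CNTS_{tum}/V_{tum}}{CNTS_{NL}/V_{NL}},}
#' where CNTS is the total number of counts in a contour and V its volume in
#' mL. Reflects tumor hypervascularization and targeting selectivity; it is
#' invariant to count rescaling, and by convention evaluated on
#' anatomy-derived (MRI-based) contours only.
#'
#' @param counts a [count_volume()].
#' @param tumor,normal_liver disjoint non-empty [contour_mask()] objects on
#'   the counts grid.
#' @return TNR, dimensionless.
#' @export
tnr <- function(counts, tumor, normal_liver) {
  stopifnot(inherits(counts, "count_volume"),
            inherits(tumor, "contour_mask"),
            inherits(normal_liver, "contour_mask"))
  assert_aligned(counts, tumor, "counts and tumor")
  assert_aligned(counts, normal_liver, "counts and normal liver")
  if (!any(tumor$values) || !any(normal_liver$values)) {
    stop("tumor and normal-liver contours must be non-empty", call. = FALSE)
  }
  if (any(tumor$values & normal_liver$values)) {
    stop("tumor and normal-liver contours overlap", call. = FALSE)
  }
  vv <- voxel_volume_ml(counts$grid)
  cnts_tum <- sum(counts$values[tumor$values])
  cnts_nl <- sum(counts$values[normal_liver$values])
  if (cnts_nl <= 0) {
    stop("zero counts in the normal liver: TNR undefined", call. = FALSE)
  }
  (cnts_tum / (sum(tumor$values) * vv)) / (cnts_nl / (sum(normal_liver$values) * vv))
}

#' Tumor burden
#'
#' Tumor volume as a percentage of the whole liver volume.
#'
#' @param tumor_ml tumor volume in mL (> 0).
#' @param liver_ml liver volume in mL (>= tumor_ml).
#' @return Burden in percent.
#' @export
tumor_burden <- function(tumor_ml, liver_ml) {
  if (any(tumor_ml <= 0) || any(liver_ml <= 0)) {
    stop("volumes must be positive", call. = FALSE)
  }
  if (any(tumor_ml > liver_ml)) {
    stop("tumor volume exceeds liver volume", call. = FALSE)
  }
  100 * tumor_ml / liver_ml
}

#' Dose metrics for one contour set
#'
#' Computes the three dose metrics — mean dose (Dm), D70 and, for
#' anatomy-based contours, TNR — for a contour set on one timepoint's dose
#' map and count volume, named in the self-describing
#' `<metric>-<Pre|Post>-<C_MRI|C_SPECT|C_PET>` scheme.
#'
#' @param dose a `dose_map`.
#' @param counts the [count_volume()] the dose derived from (for TNR).
#' @param contours a [contour_set()].
#' @param timepoint `"Pre"` or `"Post"`.
#' @return A tibble with columns `metric`, `value`, `contour`, `timepoint`,
#'   `volume_ml`.
#' @export
dose_metrics <- function(dose, counts, contours, timepoint = c("Pre", "Post")) {
  stopifnot(inherits(contours, "contour_set"))
  timepoint <- match.arg(timepoint)
  prov <- contours$provenance
  tgt <- if (prov == "C_MRI") contours$tumor else contours$target_threshold
  if (is.null(tgt)) {
    stop("scintigraphic contour sets need a threshold target mask", call. = FALSE)
  }
  dvh <- cumulative_dvh(dose, tgt)
  out <- tibble::tibble(
    metric = paste0(c("Dm-", "D70-"), timepoint, "-", prov),
    value = c(mean_dose(dose, tgt), d_percent(dvh, 70)),
    contour = prov, timepoint = timepoint,
    volume_ml = mask_volume_ml(tgt)
  )
  if (prov == "C_MRI") {
    out <- dplyr::bind_rows(out, tibble::tibble(
      metric = paste0("TNR-", timepoint, "-", prov),
      value = tnr(counts, contours$tumor, contours$normal_liver),
      contour = prov, timepoint = timepoint,
      volume_ml = mask_volume_ml(contours$tumor)
    ))
  }
  out
}
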