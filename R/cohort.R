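#' Generative parameters for a synthetic SIRT cohort
#'
#' Defaults are calibrated loosely to the published characteristics of a
#' typical advanced-HCC radioembolization cohort: about half resin / half
#' glass microspheres; median liver ~1813 mL; median tumor volume ~203 mL;
#' median injected activity 1.3 GBq (resin) and 2.3 GBq (glass); median TNR
#' 7.7 (resin) and 5.0 (glass); median mean tumor dose 115 Gy (resin) and
#' 153 Gy (glass) on anatomy contours. Dispersions are log-normal. Outcomes
#' follow a documented generative model so that the statistical layer has
#' recoverable ground truth: 6-month tumor control is Bernoulli with
#' log-odds `qlogis(control_baseline_p) + log(control_or) * supramedian(TNR)`
#' (supramedian within sphere type), and overall survival is exponential
#' with baseline median `os_median_inframedian_mo` and hazard ratio
#' `os_hr_supramedian_dm` for supramedian post-treatment mean tumor dose,
#' with independent exponential censoring.
#'
#' @param p_resin probability of resin (vs glass) microspheres.
#' @param liver_ml_median,liver_ml_sdlog log-normal liver volume (mL).
#' @param tumor_ml_median,tumor_ml_sdlog log-normal tumor volume (mL),
#'   truncated to at most half the liver.
#' @param tnr_median named (resin/glass) medians of true TNR.
#' @param tnr_sdlog log-sd of TNR.
#' @param activity_gbq_median named medians of injected activity (GBq).
#' @param activity_gbq_sdlog named log-sds.
#' @param dm_mri_median named medians of the anatomy-contour mean tumor dose
#'   (Gy) used by the metric-level generator.
#' @param dm_sdlog log-sd of Dm.
#' @param d70_frac_range D70 is drawn as Dm times a uniform factor in this
#'   range (dose heterogeneity).
#' @param scint_sdlog log-normal factor linking threshold-contour metrics to
#'   anatomy-contour metrics.
#' @param postpre_sdlog log-normal factor linking post- to pre-treatment
#'   metrics.
#' @param control_baseline_p control probability for inframedian TNR.
#' @param control_or true odds ratio of tumor control for supramedian TNR.
#' @param p_missing_control fraction with unknown 6-month status (too short
#'   or no follow-up), excluded listwise from the logistic analysis.
#' @param os_median_inframedian_mo baseline median OS, months.
#' @param os_hr_supramedian_dm true hazard ratio for supramedian Dm
#'   (protective when < 1).
#' @param censor_rate rate of the independent exponential censoring process
#'   (per month).
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(p_resin = 25 / 48,
                          liver_ml_median = 1813, liver_ml_sdlog = 0.3,
                          tumor_ml_median = 203, tumor_ml_sdlog = 1.2,
                          tnr_median = c(resin = 7.7, glass = 5.0),
                          tnr_sdlog = 0.7,
                          activity_gbq_median = c(resin = 1.3, glass = 2.3),
                          activity_gbq_sdlog = c(resin = 0.45, glass = 0.6),
                          dm_mri_median = c(resin = 115, glass = 153),
                          dm_sdlog = 0.5,
                          d70_frac_range = c(0.4, 0.85),
                          scint_sdlog = 0.3,
                          postpre_sdlog = 0.35,
                          control_baseline_p = 0.4,
                          control_or = 5.9,
                          p_missing_control = 10 / 48,
                          os_median_inframedian_mo = 14,
                          os_hr_supramedian_dm = 14 / 23,
                          censor_rate = log(2) / 40) {
  structure(as.list(environment()), class = "cohort_params")
}

# split one user seed into k reproducible sub-seeds (all < 2^31)
split_seed <- function(seed, k) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, k))
}

#' Generate a synthetic patient cohort
#'
#' Draws per-patient characteristics and dose metrics from the generative
#' model in [cohort_params()], then draws outcomes (6-month tumor control,
#' overall survival with censoring) from the stated logistic and
#' proportional-hazards models. All generative parameters, the sub-seeds and
#' the supramedian indicators actually used for outcome generation are
#' recorded in the result's attributes so recovery tests can compare
#' estimates against truth.
#'
#' @param n number of patients (>= 2).
#' @param params a [cohort_params()] object.
#' @param seed integer seed; every random draw derives from it through a
#'   fixed splitting scheme.
#' @return A tibble of class `sirt_cohort`, one row per patient: `id`,
#'   `sphere_type`, `injected_gbq`, `liver_ml`, `tumor_ml`, the ten dose
#'   metrics named `Dm-Pre-C_MRI`, `D70-Pre-C_SPECT`, `TNR-Post-C_MRI`, ...,
#'   and outcome columns `tumor_control_6mo` (logical, `NA` when follow-up
#'   is missing), `os_months`, `death_observed`. Attributes: `params`,
#'   `generative` (medians and labels used to draw outcomes), `seed`.
#' @export
make_cohort <- function(n, params = cohort_params(), seed = 1L) {
  if (n < 2) stop("cohort error: need at least 2 patients", call. = FALSE)
  stopifnot(inherits(params, "cohort_params"))
  seeds <- split_seed(seed, 3L)

  rec <- withr::with_seed(seeds[1], {
    sphere_type <- ifelse(stats::runif(n) < params$p_resin, "resin", "glass")
    liver_ml <- stats::rlnorm(n, log(params$liver_ml_median),
                              params$liver_ml_sdlog)
    tumor_ml <- pmin(stats::rlnorm(n, log(params$tumor_ml_median),
                                   params$tumor_ml_sdlog), 0.5 * liver_ml)
    tumor_ml <- pmax(tumor_ml, 5)
    tnr_pre <- stats::rlnorm(n, log(params$tnr_median[sphere_type]),
                             params$tnr_sdlog)
    injected_gbq <- stats::rlnorm(n, log(params$activity_gbq_median[sphere_type]),
                                  params$activity_gbq_sdlog[sphere_type])
    dm_pre_mri <- stats::rlnorm(n, log(params$dm_mri_median[sphere_type]),
                                params$dm_sdlog)
    d70_frac <- stats::runif(n, params$d70_frac_range[1], params$d70_frac_range[2])
    ln <- function(sdlog) stats::rlnorm(n, 0, sdlog)
    tibble::tibble(
      id = sprintf("P%03d", seq_len(n)),
      sphere_type = sphere_type,
      injected_gbq = injected_gbq,
      liver_ml = liver_ml, tumor_ml = tumor_ml,
      `Dm-Pre-C_MRI` = dm_pre_mri,
      `D70-Pre-C_MRI` = dm_pre_mri * d70_frac,
      `Dm-Pre-C_SPECT` = dm_pre_mri * ln(params$scint_sdlog),
      `D70-Pre-C_SPECT` = dm_pre_mri * d70_frac * ln(params$scint_sdlog),
      `TNR-Pre-C_MRI` = tnr_pre,
      `Dm-Post-C_MRI` = dm_pre_mri * ln(params$postpre_sdlog),
      `D70-Post-C_MRI` = dm_pre_mri * d70_frac * ln(params$postpre_sdlog),
      `Dm-Post-C_PET` = dm_pre_mri * ln(params$scint_sdlog) *
        ln(params$postpre_sdlog),
      `D70-Post-C_PET` = dm_pre_mri * d70_frac * ln(params$scint_sdlog) *
        ln(params$postpre_sdlog),
      `TNR-Post-C_MRI` = tnr_pre * ln(params$postpre_sdlog)
    )
  })

  # per-sphere-type medians drive the generative supramedian indicators
  med_by_type <- function(x) {
    m <- c(tapply(x, rec$sphere_type, stats::median))
    m[rec$sphere_type]
  }
  supra_tnr <- as.vector(rec$`TNR-Pre-C_MRI` > med_by_type(rec$`TNR-Pre-C_MRI`))
  supra_dm <- as.vector(rec$`Dm-Post-C_MRI` > med_by_type(rec$`Dm-Post-C_MRI`))

  outcomes <- withr::with_seed(seeds[2], {
    p_control <- stats::plogis(stats::qlogis(params$control_baseline_p) +
                                 log(params$control_or) * supra_tnr)
    control <- stats::rbinom(n, 1, p_control) == 1
    control[stats::runif(n) < params$p_missing_control] <- NA
    base_rate <- log(2) / params$os_median_inframedian_mo
    rate <- base_rate * ifelse(supra_dm, params$os_hr_supramedian_dm, 1)
    t_event <- stats::rexp(n, rate)
    t_cens <- if (params$censor_rate > 0) stats::rexp(n, params$censor_rate)
              else rep(Inf, n)
    tibble::tibble(tumor_control_6mo = control,
                   os_months = pmin(t_event, t_cens),
                   death_observed = t_event <= t_cens)
  })

  out <- dplyr::bind_cols(rec, outcomes)
  structure(out,
            class = c("sirt_cohort", class(out)),
            params = params,
            generative = list(supra_tnr = supra_tnr, supra_dm = supra_dm,
                              seeds = seeds),
            seed = as.integer(seed))
}

#' Build imaging phantoms for cohort patients
#'
#' Realises one phantom per patient from the cohort's sampled liver volume,
#' tumor volume, TNR and injected activity, and simulates paired pre- and
#' post-treatment count volumes (SPECT-like and PET-like PSFs). Intended for
#' modest cohort sizes; the statistical layer works on the metric-level
#' cohort directly.
#'
#' @param cohort a [make_cohort()] tibble (or any tibble with `id`,
#'   `sphere_type`, `injected_gbq`, `liver_ml`, `tumor_ml`, `TNR-Pre-C_MRI`).
#' @param grid_shape,voxel_size_mm phantom grid (smaller grids run faster).
#' @param psf_pre_mm,psf_post_mm PSF FWHMs for the SPECT-like pre and
#'   PET-like post channels.
#' @param total_counts expected counts per simulated volume.
#' @param seed integer seed for the image chain.
#' @return A named list (by patient id) of lists with elements `truth`
#'   ([make_phantom()] output), `pre` and `post` ([count_volume()]s).
#' @export
cohort_images <- function(cohort, grid_shape = c(40L, 40L, 40L),
                          voxel_size_mm = 5.5, psf_pre_mm = 15,
                          psf_post_mm = 8, total_counts = 2e6, seed = 1L) {
  n <- nrow(cohort)
  seeds <- split_seed(seed, 2L * n)
  base_semi <- c(95, 80, 57)
  base_ml <- 4 / 3 * pi * prod(base_semi) / 1000
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- (cohort$liver_ml[i] / base_ml)^(1 / 3)
    semi <- base_semi * s
    r_mm <- (3 * cohort$tumor_ml[i] * 1000 / (4 * pi))^(1 / 3)
    r_mm <- min(r_mm, 0.85 * min(semi))  # keep the sphere inside the liver
    spec <- phantom_spec(
      grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
      liver_semiaxes_mm = semi,
      tumors = data.frame(x = 0, y = 0, z = 0, radius_mm = r_mm,
                          necrotic_fraction = 0),
      tnr_true = cohort[["TNR-Pre-C_MRI"]][i],
      injected_activity_gbq = cohort$injected_gbq[i],
      seed = seeds[2 * i - 1]
    )
    truth <- make_phantom(spec)
    out[[i]] <- list(
      truth = truth,
      pre = simulate_counts(truth, psf_fwhm_mm = psf_pre_mm,
                            total_counts = total_counts,
                            seed = seeds[2 * i - 1], modality = "SPECT"),
      post = simulate_counts(truth, psf_fwhm_mm = psf_post_mm,
                             total_counts = total_counts,
                             seed = seeds[2 * i], modality = "PET")
    )
  }
  names(out) <- cohort$id
  out
}
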