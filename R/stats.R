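#' Agreement between paired pre- and post-treatment metrics
#'
#' Compares two paired measurement series with the standard trio: Spearman's
#' rank correlation (tie-corrected), the two-sided Wilcoxon signed-rank test,
#' and Bland-Altman analysis reporting the mean difference (post minus pre)
#' with its t-based 95% confidence interval and paired-t p value.
#'
#' @param data optional data frame holding the paired columns.
#' @param pre,post column names (tidy-evaluated) when `data` is given, or
#'   bare numeric vectors when it is not.
#' @param conf_level confidence level for the Bland-Altman CI.
#' @return A one-row tibble: `n`, `spearman_rho`, `spearman_p`, `wilcoxon_p`,
#'   `mean_diff`, `ci_low`, `ci_high`, `bland_altman_p`.
#' @examples
#' agreement_suite(pre = c(1, 2, 3, 4), post = c(2, 4, 6, 9))
#' @export
agreement_suite <- function(data = NULL, pre, post, conf_level = 0.95) {
  if (!is.null(data)) {
    pre <- dplyr::pull(data, {{ pre }})
    post <- dplyr::pull(data, {{ post }})
  }
  keep <- stats::complete.cases(pre, post)
  pre <- pre[keep]; post <- post[keep]
  n <- length(pre)
  if (n < 3) stop("insufficient data: need at least 3 complete pairs",
                  call. = FALSE)
  sp <- suppressWarnings(stats::cor.test(pre, post, method = "spearman",
                                         exact = FALSE))
  wx <- suppressWarnings(stats::wilcox.test(post, pre, paired = TRUE,
                                            exact = FALSE))
  diffs <- post - pre
  md <- mean(diffs)
  se <- stats::sd(diffs) / sqrt(n)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  p_t <- if (se > 0) 2 * stats::pt(-abs(md / se), df = n - 1) else 1
  tibble::tibble(n = n,
                 spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
                 wilcoxon_p = wx$p.value,
                 mean_diff = md, ci_low = md - tq * se, ci_high = md + tq * se,
                 bland_altman_p = p_t)
}

#' Dichotomize a dose metric at the per-sphere-type median
#'
#' Within each microsphere subgroup (resin, glass) separately, the median of
#' the metric is computed and each patient is labelled `supramedian` when the
#' value strictly exceeds that subgroup's median, `inframedian` otherwise
#' (values exactly at the median are inframedian). Stratifying by sphere type
#' respects the different tolerated dose ranges of resin and glass spheres
#' without splitting the cohort for the outcome models.
#'
#' @param records a cohort tibble with columns `sphere_type` and the metric.
#' @param metric metric column name, e.g. `"TNR-Pre-C_MRI"`.
#' @return A tibble of class `dichotomized_metric` with `id` (if present),
#'   `sphere_type`, `value`, `label` (factor inframedian/supramedian) and
#'   `supramedian` (logical); attributes `metric` and `medians` (tibble of
#'   the per-type medians used).
#' @export
dichotomize <- function(records, metric) {
  if (!metric %in% names(records)) {
    stop("metric '", metric, "' not found in the records", call. = FALSE)
  }
  v <- records[[metric]]
  if (all(is.na(v))) stop("metric '", metric, "' is all missing", call. = FALSE)
  st <- records$sphere_type
  ok_n <- tapply(!is.na(v), st, sum)
  if (any(ok_n < 2)) {
    stop("need the metric on >= 2 patients per sphere type", call. = FALSE)
  }
  med <- c(tapply(v, st, stats::median, na.rm = TRUE))
  supra <- as.vector(v > med[st])
  out <- tibble::tibble(
    sphere_type = st, value = v,
    supramedian = unname(supra),
    label = factor(ifelse(supra, "supramedian", "inframedian"),
                   levels = c("inframedian", "supramedian"))
  )
  if (!is.null(records[["id"]])) out <- dplyr::bind_cols(
    tibble::tibble(id = records$id), out)
  structure(out, class = c("dichotomized_metric", class(out)),
            metric = metric,
            medians = tibble::tibble(sphere_type = names(med),
                                     median = unname(med)))
}

#' Univariate logistic regression for 6-month tumor control
#'
#' Maximum-likelihood logistic fit of a binary outcome on a single (usually
#' dichotomized) covariate, reporting the odds ratio with its Wald 95%
#' confidence interval and p value. For a binary covariate the fitted OR
#' equals the 2x2 cross-product ratio ad/bc. Complete separation (a zero
#' cell in the 2x2 table) is flagged and the confidence interval reported as
#' unbounded. Missing outcomes are excluded listwise.
#'
#' @param label covariate: logical/two-level factor (e.g. the `supramedian`
#'   column of [dichotomize()]), or a numeric covariate.
#' @param outcome logical (or 0/1) outcome, `NA` allowed.
#' @param conf_level Wald confidence level.
#' @return An object of class `sirt_logistic`; see [tidy.sirt_logistic()].
#' @export
logistic_univariate <- function(label, outcome, conf_level = 0.95) {
  if (is.factor(label)) label <- label == levels(label)[2]
  keep <- stats::complete.cases(label, outcome)
  label <- label[keep]; outcome <- as.logical(outcome)[keep]
  if (length(unique(label)) < 2 || length(unique(outcome)) < 2) {
    stop("both covariate classes and both outcomes must be present",
         call. = FALSE)
  }
  separation <- FALSE
  if (is.logical(label)) {
    tab <- table(factor(label, c(FALSE, TRUE)),
                 factor(outcome, c(FALSE, TRUE)))
    separation <- any(tab == 0)
  }
  fit <- suppressWarnings(
    stats::glm(outcome ~ label, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 200))
  )
  co <- stats::coef(summary(fit))[2, ]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(or = exp(co[["Estimate"]]),
         ci = if (separation) c(0, Inf)
              else exp(co[["Estimate"]] + c(-1, 1) * z * co[["Std. Error"]]),
         p = co[["Pr(>|z|)"]],
         separation = separation, n = length(outcome),
         events = sum(outcome), fit = fit, conf_level = conf_level),
    class = "sirt_logistic"
  )
}

#' @export
print.sirt_logistic <- function(x, ...) {
  cat(sprintf("OR = %.3g (%.0f%% CI %.3g-%.3g; p = %.3g)%s\n",
              x$or, 100 * x$conf_level, x$ci[1], x$ci[2], x$p,
              if (x$separation) " [separation: CI unbounded]" else ""))
  invisible(x)
}

#' Tidy a univariate logistic fit
#'
#' @param x a `sirt_logistic` object.
#' @param ... unused.
#' @return One-row tibble: `term`, `estimate` (odds ratio), `conf.low`,
#'   `conf.high`, `p.value`, `separation`.
#' @export
tidy.sirt_logistic <- function(x, ...) {
  tibble::tibble(term = "supramedian", estimate = x$or,
                 conf.low = x$ci[1], conf.high = x$ci[2],
                 p.value = x$p, separation = x$separation)
}

#' @rdname tidy.sirt_logistic
#' @return For `glance()`: one-row tibble with `n`, `events`, `separation`.
#' @export
glance.sirt_logistic <- function(x, ...) {
  tibble::tibble(n = x$n, events = x$events, separation = x$separation)
}

# Kaplan-Meier median under the "smallest time with S(t) <= 0.5" rule,
# computed from the survfit step curve per stratum (NA when never reached).
km_median_from_fit <- function(fit) {
  s <- summary(fit, censored = FALSE)
  strata <- if (is.null(s$strata)) factor(rep("all", length(s$time))) else s$strata
  vapply(levels(strata), function(g) {
    i <- strata == g
    t <- s$time[i]; surv <- s$surv[i]
    hit <- which(surv <= 0.5 + 1e-12)
    if (length(hit)) t[min(hit)] else NA_real_
  }, numeric(1))
}

#' Survival analysis of a dichotomized dose metric
#'
#' Kaplan-Meier product-limit estimation with right censoring (group medians
#' reported under the convention: smallest time at which the survival curve
#' reaches 0.5 or below; undefined when never reached), a two-group log-rank
#' test, and univariate Cox proportional-hazards regression with Breslow tie
#' handling reporting the hazard ratio of the second group level versus the
#' first with Wald CI and p value.
#'
#' @param time follow-up times (months, >= 0).
#' @param event logical/0-1 event (death) indicator.
#' @param group two-level factor or logical (e.g. supramedian indicator).
#' @param conf_level Wald confidence level for the hazard ratio.
#' @return An object of class `sirt_survival` with elements `km_median`
#'   (named per group), `logrank_p`, `hr`, `hr_ci`, `hr_p`, `n`, `events`,
#'   plus the underlying `survfit` and `coxph` fits.
#' @export
survival_suite <- function(time, event, group, conf_level = 0.95) {
  if (is.logical(group)) {
    group <- factor(ifelse(group, "supramedian", "inframedian"),
                    levels = c("inframedian", "supramedian"))
  }
  group <- droplevels(as.factor(group))
  keep <- stats::complete.cases(time, event, group)
  time <- time[keep]; event <- as.logical(event)[keep]; group <- group[keep]
  if (any(time < 0)) stop("negative follow-up time", call. = FALSE)
  df <- data.frame(time = time, event = event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  med <- km_median_from_fit(fit)
  names(med) <- if (is.null(fit$strata)) levels(group)[1]
                else sub("^group=", "", names(med))
  ev_per_group <- tapply(event, group, sum)
  if (any(ev_per_group == 0)) {
    warning("no events in group(s) ",
            paste(names(ev_per_group)[ev_per_group == 0], collapse = ", "),
            ": KM median undefined there")
  }
  logrank_p <- NA_real_
  hr <- hr_ci <- hr_p <- NA
  if (nlevels(group) == 2) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
    logrank_p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
    cox <- survival::coxph(survival::Surv(time, event) ~ group, data = df,
                           ties = "breslow")
    sc <- summary(cox, conf.int = conf_level)
    hr <- unname(sc$coefficients[1, "exp(coef)"])
    hr_ci <- unname(sc$conf.int[1, 3:4])
    hr_p <- unname(sc$coefficients[1, "Pr(>|z|)"])
  } else {
    cox <- NULL
  }
  structure(
    list(km_median = med, logrank_p = logrank_p,
         hr = hr, hr_ci = hr_ci, hr_p = hr_p,
         n = length(time), events = sum(event),
         survfit = fit, coxph = cox, conf_level = conf_level),
    class = "sirt_survival"
  )
}

#' @export
print.sirt_survival <- function(x, ...) {
  cat("Kaplan-Meier medians (months):\n")
  print(round(x$km_median, 2))
  if (!is.na(x$logrank_p)) {
    cat(sprintf("log-rank p = %.3g; Cox HR = %.3g (%.0f%% CI %.3g-%.3g; p = %.3g)\n",
                x$logrank_p, x$hr, 100 * x$conf_level,
                x$hr_ci[1], x$hr_ci[2], x$hr_p))
  }
  invisible(x)
}

#' Tidy a survival suite result
#'
#' @param x a `sirt_survival` object.
#' @param ... unused.
#' @return One-row tibble: `term`, `estimate` (hazard ratio), `conf.low`,
#'   `conf.high`, `p.value`, `logrank_p`.
#' @export
tidy.sirt_survival <- function(x, ...) {
  tibble::tibble(term = "supramedian", estimate = x$hr,
                 conf.low = x$hr_ci[1], conf.high = x$hr_ci[2],
                 p.value = x$hr_p, logrank_p = x$logrank_p)
}

#' @rdname tidy.sirt_survival
#' @return For `glance()`: `n`, `events` and the KM medians per group.
#' @export
glance.sirt_survival <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n = x$n, events = x$events),
    tibble::as_tibble(as.list(stats::setNames(
      x$km_median, paste0("km_median_", names(x$km_median)))))
  )
}

#' Gate covariates into the multivariate model
#'
#' Retains covariates significant in univariate analysis (strict p < alpha)
#' and drops declared-redundant companions: within each redundancy group only
#' the first listed (representative) covariate is kept when several are
#' significant.
#'
#' @param univariate a tibble with columns `metric` and `p.value` (or `p`).
#' @param alpha significance level, default 0.05 (p = alpha is excluded).
#' @param redundant list of character vectors naming redundant metric groups,
#'   representative first.
#' @return Character vector of retained metric names (possibly empty, with a
#'   message).
#' @export
multivariate_gate <- function(univariate, alpha = 0.05, redundant = list()) {
  p <- univariate[["p.value"]]
  if (is.null(p)) p <- univariate[["p"]]
  if (is.null(p)) stop("`univariate` needs a p.value column", call. = FALSE)
  kept <- univariate$metric[!is.na(p) & p < alpha]
  for (grp in redundant) {
    hits <- intersect(grp, kept)
    if (length(hits) > 1) kept <- setdiff(kept, setdiff(hits, grp[1]))
  }
  if (!length(kept)) message("no covariate passed the univariate gate; ",
                             "multivariate step skipped")
  kept
}

#' Univariate predictor table over a set of dose metrics
#'
#' For each metric: dichotomize at the per-sphere-type median, fit the
#' univariate logistic model for 6-month tumor control (patients with
#' missing status excluded) and the survival suite for overall survival,
#' and collect one row per metric and endpoint in the layout of a
#' predictive-factor table (estimate, CI, p).
#'
#' @param records a [make_cohort()]-style tibble.
#' @param metrics character vector of metric column names.
#' @param conf_level confidence level.
#' @return A tibble: `metric`, `endpoint` (`tumor_control` / `overall
#'   survival`), `estimate_type` (`OR`/`HR`), `estimate`, `conf.low`,
#'   `conf.high`, `p.value`.
#' @export
predictor_table <- function(records, metrics, conf_level = 0.95) {
  purrr::map_dfr(metrics, function(m) {
    di <- dichotomize(records, m)
    lg <- logistic_univariate(di$supramedian, records$tumor_control_6mo,
                              conf_level)
    sv <- survival_suite(records$os_months, records$death_observed,
                         di$supramedian, conf_level)
    tibble::tibble(
      metric = m,
      endpoint = c("tumor_control_6mo", "overall_survival"),
      estimate_type = c("OR", "HR"),
      estimate = c(lg$or, sv$hr),
      conf.low = c(lg$ci[1], sv$hr_ci[1]),
      conf.high = c(lg$ci[2], sv$hr_ci[2]),
      p.value = c(lg$p, sv$hr_p)
    )
  })
}
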