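#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a cumulative DVH
#'
#' @param object a `dvh_curve` from [cumulative_dvh()].
#' @param ... unused.
#' @return A ggplot: volume fraction receiving at least each dose.
#' @export
autoplot.dvh_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$dose_gy, y = .data$volume_fraction)) +
    ggplot2::geom_step(direction = "vh", colour = "#2166ac") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Minimal absorbed dose (Gy)",
                  y = "Relative volume receiving ≥ dose",
                  title = "Cumulative dose-volume histogram") +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves of a survival suite
#'
#' @param object a `sirt_survival` from [survival_suite()].
#' @param ... unused.
#' @return A ggplot of the per-group product-limit curves with censor marks.
#' @export
autoplot.sirt_survival <- function(object, ...) {
  fit <- object$survfit
  strata <- if (is.null(fit$strata)) {
    rep("all", length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  df <- tibble::tibble(time = fit$time, surv = fit$surv,
                       censored = fit$n.censor > 0, group = strata)
  start <- dplyr::distinct(df, .data$group) |>
    dplyr::mutate(time = 0, surv = 1, censored = FALSE)
  df <- dplyr::bind_rows(start, df) |> dplyr::arrange(.data$group, .data$time)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = dplyr::filter(df, .data$censored), shape = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Overall survival",
                  colour = NULL, title = "Kaplan-Meier estimate") +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot of paired metrics
#'
#' Scatter of difference against mean with the mean-difference line and its
#' 95% limits of agreement.
#'
#' @param data data frame with the paired columns.
#' @param pre,post tidy-evaluated column names.
#' @return A ggplot.
#' @export
plot_bland_altman <- function(data, pre, post) {
  pre_v <- dplyr::pull(data, {{ pre }})
  post_v <- dplyr::pull(data, {{ post }})
  d <- post_v - pre_v
  m <- (post_v + pre_v) / 2
  md <- mean(d); loa <- md + c(-1.96, 1.96) * stats::sd(d)
  ggplot2::ggplot(tibble::tibble(mean = m, diff = d),
                  ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = md, colour = "#b2182b") +
    ggplot2::geom_hline(yintercept = loa, linetype = "dashed") +
    ggplot2::labs(x = "Mean of paired measurements",
                  y = "Difference (post - pre)",
                  title = "Bland-Altman agreement") +
    ggplot2::theme_minimal()
}
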