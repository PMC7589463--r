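#' Kaplan-Meier plot
#'
#' Step curves per risk group, with censoring implicit in the plateaus.
#'
#' @param object a [kaplan_meier()] tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.rimcore_km <- function(object, ...) {
  start <- object |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(time = 0, surv = 1, .groups = "drop")
  dat <- dplyr::bind_rows(
    start, object[, c("group", "time", "surv")]
  ) |>
    dplyr::arrange(.data$group, .data$time)
  ggplot2::ggplot(
    dat,
    ggplot2::aes(.data$time, .data$surv, colour = .data$group)
  ) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "time (months)", y = "tumour control probability",
      colour = "risk group"
    ) +
    ggplot2::theme_minimal()
}

#' Sub-volume performance plot
#'
#' Validation C-index distribution across model combinations per ROI.
#'
#' @param object a `rimcore_experiment`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.rimcore_experiment <- function(object, ...) {
  dat <- object$results
  dat$roi <- factor(dat$roi, levels = object$config$rois)
  ggplot2::ggplot(
    dat,
    ggplot2::aes(.data$roi, .data$c_index_valid)
  ) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(
      x = "tumour (sub-)volume", y = "validation C-index"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Risk-group KM curves for a fitted model
#'
#' Convenience: predicts risks, stratifies at the exploratory median and
#' plots validation KM curves.
#'
#' @param model a [train_risk_model()] fit.
#' @param features raw feature tibble.
#' @param outcomes outcome tibble.
#' @param cohorts tibble `patient_id`, `cohort`.
#' @return A ggplot object.
#' @export
plot_risk_groups <- function(model, features, outcomes, cohorts) {
  pred <- stats::predict(model, features) |>
    dplyr::left_join(cohorts, by = "patient_id") |>
    dplyr::left_join(outcomes, by = "patient_id")
  ex <- pred[pred$cohort == "exploratory", ]
  va <- pred[pred$cohort == "validation", ]
  grp <- stratify_risk(ex$risk, va$risk)
  km <- kaplan_meier(va$time_months, va$event, grp$valid)
  autoplot.rimcore_km(km)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
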