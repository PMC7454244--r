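#' Plot a simulated patient trajectory
#'
#' Tumor diameter over time with the plasma concentrations of both drugs on
#' a secondary panel-free scale (concentrations are rescaled to the diameter
#' axis and shown as dashed/dotted lines).
#'
#' @param object a `tcevct_trajectory` from [simulate_patient()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.tcevct_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_days)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$diameter_cm), linewidth = 0.8) +
    ggplot2::labs(x = "Time since first dose (days)",
                  y = "Tumor diameter (cm)") +
    ggplot2::theme_bw()
}

#' Waterfall plot of per-patient responses in one arm
#'
#' Patients ordered by percent diameter change; bars colored by RECIST
#' class; dashed reference lines at -30 and +20 percent. Optionally colored
#' by a sampled biomarker instead of class.
#'
#' @param trial a `tcevct_trial`.
#' @param arm_id arm to plot.
#' @param color_by optional cohort column (e.g. `"n_clones"`) mapped to
#'   fill on a log10 scale.
#' @return A ggplot object.
#' @export
plot_waterfall <- function(trial, arm_id = "combination", color_by = NULL) {
  df <- dplyr::filter(trial$responses, .data$arm_id == !!arm_id)
  df <- dplyr::arrange(df, dplyr::desc(.data$pct_change))
  df$rank <- seq_len(nrow(df))
  df$pct_shown <- pmin(df$pct_change, 100)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$pct_shown))
  if (is.null(color_by)) {
    gg <- gg + ggplot2::geom_col(ggplot2::aes(fill = .data$recist), width = 1)
  } else {
    co <- trial$cohort[, c("patient_id", color_by)]
    df2 <- dplyr::left_join(df, co, by = "patient_id")
    gg <- ggplot2::ggplot(df2, ggplot2::aes(x = .data$rank, y = .data$pct_shown)) +
      ggplot2::geom_col(ggplot2::aes(fill = log10(.data[[color_by]])), width = 1) +
      ggplot2::labs(fill = paste0("log10 ", color_by))
  }
  gg +
    ggplot2::geom_hline(yintercept = c(-30, 20), linetype = "dashed") +
    ggplot2::labs(x = "Patients (ordered)",
                  y = "Change in tumor diameter at day 400 (%, capped at 100)",
                  title = arm_id) +
    ggplot2::theme_bw()
}

#' Spider plot of tumor-size change over time
#'
#' Requires a trial run with `keep_trajectories = TRUE`.
#'
#' @param trial a `tcevct_trial` with stored trajectories.
#' @param arm_id arm to plot.
#' @return A ggplot object.
#' @export
plot_spider <- function(trial, arm_id = "combination") {
  if (is.null(trial$trajectories)) {
    rlang::abort("trial was run without keep_trajectories = TRUE.",
                 class = "tcevct_validation_error")
  }
  df <- trial$trajectories |>
    dplyr::filter(.data$arm_id == !!arm_id) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(pct = 100 * (.data$diameter_cm / .data$diameter_cm[1] - 1)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_days, y = pmin(.data$pct, 100),
                                   group = .data$patient_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = c(-30, 20), linetype = "dashed") +
    ggplot2::labs(x = "Time since first dose (days)",
                  y = "Change in tumor diameter (%, capped at 100)",
                  title = arm_id) +
    ggplot2::theme_bw()
}

#' Plot a ROC curve
#'
#' @param object a `tcevct_roc` from [roc_auc()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.tcevct_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  subtitle = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_bw()
}

#' Plot a binned response-rate curve
#'
#' @param binned output of [orr_by_bins()].
#' @param axis_label x-axis label (biomarker name).
#' @return A ggplot object.
#' @export
plot_binned_orr <- function(binned, axis_label = "normalized biomarker") {
  ggplot2::ggplot(binned, ggplot2::aes(x = .data$mean_normalized, y = .data$orr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$short_bin)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                guide = "none") +
    ggplot2::labs(x = axis_label, y = "ORR per 20-patient bin") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
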