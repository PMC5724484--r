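# ggplot2 displays for the evaluation results.

#' Calibration plot
#'
#' Observed (Kaplan-Meier) versus mean predicted risk per group with the
#' identity line; well-calibrated predictions lie on the diagonal.
#'
#' @param object A [calibration_table()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot calibration_table
#' @export
autoplot.calibration_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$mean_predicted,
                               y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(.data$observed - 1.96 * .data$km_se, 0),
      ymax = pmin(.data$observed + 1.96 * .data$km_se, 1))) +
    ggplot2::labs(x = "Mean predicted risk", y = "Observed risk (KM)") +
    ggplot2::theme_minimal()
}

#' Dynamic C-index / Brier curves from a simulation study
#'
#' Mean metric against prediction time, one line per model, panelled by
#' scenario and evaluation sample.
#'
#' @param object A `study_results` object.
#' @param metric `"cindex"` or `"brier"`.
#' @param ... Unused.
#' @return A ggplot, or `NULL` (with a message) if the metric was not
#'   computed.
#' @method autoplot study_results
#' @export
autoplot.study_results <- function(object, metric = c("cindex", "brier"),
                                   ...) {
  metric <- match.arg(metric)
  tb <- if (metric == "cindex") object$cindex_summary else
    object$brier_summary
  if (is.null(tb) || nrow(tb) == 0) {
    inform(paste("no", metric, "results in this study run"))
    return(invisible(NULL))
  }
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$t_p, y = .data$mean_value,
                                   colour = .data$model)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_grid(.data$sample ~ .data$scenario,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Prediction time (years)",
                  y = if (metric == "cindex") "Mean dynamic C-index" else
                    "Mean Brier score") +
    ggplot2::theme_minimal()
}

#' Predictor track display
#'
#' Step plot of the piecewise-constant predictor for a handful of subjects.
#'
#' @param tracks A track tibble.
#' @param x The cohort (supplies follow-up ends).
#' @param subjects Subject ids to display (default: first 6).
#' @return A ggplot.
#' @export
plot_tracks <- function(tracks, x, subjects = NULL) {
  subjects <- subjects %||% head(unique(tracks$subject_id), 6)
  tr <- tracks[tracks$subject_id %in% subjects, , drop = FALSE]
  val <- setdiff(names(tr), c("subject_id", "start", "out_of_risk_set"))[1]
  fu <- x$survival[x$survival$subject_id %in% subjects,
                   c("subject_id", "followup_time")]
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$start, y = .data[[val]],
                                   colour = .data$subject_id)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_vline(data = fu,
                        ggplot2::aes(xintercept = .data$followup_time,
                                     colour = .data$subject_id),
                        linetype = 3, show.legend = FALSE) +
    ggplot2::labs(x = "Years from baseline", y = val) +
    ggplot2::theme_minimal()
}
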