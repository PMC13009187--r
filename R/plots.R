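# ggplot2 views of the main result types.

#' Plot interpolated SBP, threshold and AD labels
#'
#' @param labels Output of [ad_labels()].
#' @param bp Optional BP reference tibble, drawn as points.
#' @return A ggplot.
#' @export
plot_ad_labels <- function(labels, bp = NULL) {
  p <- ggplot2::ggplot(labels, ggplot2::aes(x = .data$t_s)) +
    ggplot2::geom_ribbon(
      data = dplyr::mutate(labels, ymin = ifelse(.data$label == 1, -Inf, NA_real_)),
      ggplot2::aes(ymin = .data$ymin, ymax = Inf), fill = "tomato", alpha = 0.12
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$sbp_interp), color = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$threshold), linetype = "dashed") +
    ggplot2::facet_wrap(~subject_id, scales = "free_x") +
    ggplot2::labs(x = "time (s)", y = "SBP (mmHg)",
                  title = "Interpolated SBP and AD threshold")
  if (!is.null(bp)) {
    p <- p + ggplot2::geom_point(data = bp, ggplot2::aes(y = .data$sbp), size = 1)
  }
  p
}

#' Importance quadrant plot (global vs local z-scores)
#'
#' @param quadrants Output of [importance_quadrants()].
#' @return A ggplot.
#' @export
plot_importance_quadrants <- function(quadrants) {
  ggplot2::ggplot(quadrants,
                  ggplot2::aes(x = .data$global_z, y = .data$local_z)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_point(ggplot2::aes(color = .data$scope), alpha = 0.8) +
    ggplot2::labs(x = "global importance (z)", y = "local importance (z)",
                  title = "Global vs local SHAP importance")
}

#' Per-component macro-F1 plot of an evaluation
#'
#' @param object An `ad_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ad_eval <- function(object, ...) {
  m <- object$metrics
  m$kind <- dplyr::case_when(
    grepl("^kvote", m$component) ~ "k-vote",
    m$component == "stacked_meta" ~ "stacked",
    TRUE ~ "weak learner"
  )
  ggplot2::ggplot(m, ggplot2::aes(x = stats::reorder(.data$component, .data$macro_f1_mean),
                                  y = .data$macro_f1_mean, fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$macro_f1_mean - .data$macro_f1_sd,
                                        ymax = .data$macro_f1_mean + .data$macro_f1_sd),
                           width = 0.3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "macro F1 (mean +/- sd over repeats)",
                  title = "Ensemble components")
}

#' Prediction timeline heatmap
#'
#' @param eval_result An `ad_eval`.
#' @param which_repeat Repeat to draw.
#' @return A ggplot.
#' @export
plot_prediction_timeline <- function(eval_result, which_repeat = 1L) {
  m <- prediction_timeline(eval_result, which_repeat)
  d <- tibble(
    row = factor(rep(rownames(m), ncol(m)), levels = rev(rownames(m))),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick", na.value = "grey85") +
    ggplot2::labs(x = "window (ordered by subject, time)", y = NULL,
                  fill = "P(AD) / decision",
                  title = "Held-out predictions over time")
}

#' Window-sweep summary plot
#'
#' @param sweep Output of [window_sweep()].
#' @return A ggplot.
#' @export
plot_window_sweep <- function(sweep) {
  ggplot2::ggplot(sweep$f1, ggplot2::aes(x = .data$config, y = .data$f1)) +
    ggplot2::geom_boxplot(ggplot2::aes(fill = .data$config), show.legend = FALSE) +
    ggplot2::facet_wrap(~scope) +
    ggplot2::labs(x = "(duration, step) in seconds", y = "macro F1",
                  title = "Window configuration sweep")
}
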