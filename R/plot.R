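#' Plot experiment summaries
#'
#' Median curves with central 99.7-percentile ribbons versus inverse
#' temperature, one colour per shot budget, faceted by ground-state mode.
#'
#' @param object a `qeom_summary` (or `qeom_runs`, summarized on the fly).
#' @param metric `"trace_distance"` or `"delta_e"`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot qeom_summary
#' @export
autoplot.qeom_summary <- function(object, metric = c("trace_distance",
                                                     "delta_e"), ...) {
  metric <- match.arg(metric)
  cols <- if (metric == "trace_distance") c("td_median", "td_lo", "td_hi")
          else c("de_median", "de_lo", "de_hi")
  df <- dplyr::mutate(object,
                      budget = ifelse(is.na(.data$shots), "infinite",
                                      format(.data$shots, scientific = TRUE)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta,
                                   y = .data[[cols[1]]],
                                   colour = .data$budget,
                                   fill = .data$budget)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data[[cols[2]]],
                                      ymax = .data[[cols[3]]]),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~gs_mode, labeller = ggplot2::label_both) +
    ggplot2::labs(x = expression(beta ~ "(1/Ha)"),
                  y = if (metric == "trace_distance")
                    "trace distance" else expression(Delta * E ~ "(Ha)"),
                  colour = "shots", fill = "shots") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.qeom_summary
#' @method autoplot qeom_runs
#' @export
autoplot.qeom_runs <- function(object, metric = c("trace_distance",
                                                  "delta_e"), ...) {
  autoplot.qeom_summary(summarize_runs(object), metric = metric, ...)
}

#' Excitation-spectrum plot for a solved EOM system
#'
#' @param object a solved `eom_system`.
#' @param ... unused.
#' @method autoplot eom_system
#' @export
autoplot.eom_system <- function(object, ...) {
  df <- tidy.eom_system(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$state,
                                   y = .data$excitation_energy)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$state, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "solution index", y = "excitation energy (Ha)") +
    ggplot2::theme_minimal()
}
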