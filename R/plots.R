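#' Plot a time series with its moving average
#'
#' @param object A `traj_timeseries`.
#' @param window_ps Optional moving-average window (ps) overlaid as a line;
#'   `NULL` for none.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot traj_timeseries
#' @export
autoplot.traj_timeseries <- function(object, window_ps = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ps,
                                            y = .data$value)) +
    ggplot2::geom_line(colour = "grey60", linewidth = 0.3) +
    ggplot2::labs(x = "time (ps)",
                  y = attr(object, "unit") %||% "value")
  if (!is.null(window_ps)) {
    sm <- moving_average(object, window_ps)
    p <- p + ggplot2::geom_line(data = sm, colour = "black",
                                linewidth = 0.6)
  }
  p
}

#' Plot a pair-force table as a signed bar chart
#'
#' Negative (attractive) forces point down, repulsive up, pairs ordered by
#' magnitude.
#'
#' @param object A `pair_force_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pair_force_table
#' @export
autoplot.pair_force_table <- function(object, ...) {
  df <- tidy(object)
  df$pair <- factor(paste(df$residue_a, df$residue_b, sep = " / "),
                    levels = paste(df$residue_a, df$residue_b,
                                   sep = " / ")[order(-abs(df$F_mean))])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair, y = .data$F_mean)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$F_mean < 0)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$F_mean - .data$F_err,
                                        ymax = .data$F_mean + .data$F_err),
                           width = 0.25) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#3366aa",
                                          `FALSE` = "#aa3333"),
                               labels = c(`TRUE` = "attractive",
                                          `FALSE` = "repulsive"),
                               name = NULL) +
    ggplot2::labs(x = NULL, y = "mean pairwise force (pN)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot an entropy decomposition
#'
#' @param object An `entropy_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot entropy_result
#' @export
autoplot.entropy_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$selection,
                                   y = .data$S_config)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$S_config - .data$uncertainty,
                                        ymax = .data$S_config + .data$uncertainty),
                           width = 0.25, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "S_config (J K^-1 mol^-1)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
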