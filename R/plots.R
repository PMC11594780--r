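#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the six channels of a trace set
#'
#' Line plot of all six absorbance curves over the point axis, optionally
#' shaded by electrophoretic zone.
#'
#' @param ts A [trace_set()] or `czeis_sim_case`.
#' @param zones Optional [zone_map()] for zone shading.
#' @return A ggplot object.
#' @export
plot_traces <- function(ts, zones = NULL) {
  if (inherits(ts, "czeis_sim_case")) ts <- ts$traceset
  df <- as_traces_tbl(ts)
  df$channel <- factor(df$channel, levels = CHANNELS)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$absorbance,
                                        colour = .data$channel))
  if (!is.null(zones)) {
    zd <- as_tibble(zones)
    p <- p + ggplot2::geom_rect(
      data = zd, inherit.aes = FALSE, alpha = 0.08,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf, fill = .data$zone)
    ) + ggplot2::guides(fill = "none")
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "point (time)", y = "absorbance (a.u.)",
                  colour = "channel", title = ts$case_id)
}

#' Plot a reference-interval table
#'
#' One panel per zone: the interval as a segment, the limit confidence
#' intervals as whiskers.
#'
#' @param object A `czeis_ri_tbl` from [establish_ri_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot czeis_ri_tbl
#' @export
autoplot.czeis_ri_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(y = .data$index)) +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$lower_ci_lo,
                                         xmax = .data$lower_ci_hi),
                            colour = "forestgreen", linewidth = 2, alpha = 0.5) +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$upper_ci_lo,
                                         xmax = .data$upper_ci_hi),
                            colour = "firebrick", linewidth = 2, alpha = 0.5) +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$lower, xmax = .data$upper)) +
    ggplot2::geom_point(ggplot2::aes(x = .data$lower)) +
    ggplot2::geom_point(ggplot2::aes(x = .data$upper)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$zone), scales = "free_x") +
    ggplot2::labs(x = "index value (a.u.)", y = NULL,
                  title = "Reference intervals with 90% limit CIs")
}

#' Plot index panels by case type
#'
#' Boxplots of each index by zone; when `labels` is supplied, coloured by
#' true case type.
#'
#' @param panel Index panel from [compute_panels()].
#' @param labels Optional [sim_labels()] tibble.
#' @return A ggplot object.
#' @export
plot_panel <- function(panel, labels = NULL) {
  df <- tidyr::pivot_longer(panel[, c("case_id", "zone", INDEX_NAMES)],
                            dplyr::all_of(INDEX_NAMES),
                            names_to = "index", values_to = "value")
  if (!is.null(labels)) {
    df <- dplyr::left_join(df, labels[, c("case_id", "case_type")], by = "case_id")
    aes <- ggplot2::aes(.data$zone, .data$value, fill = .data$case_type)
  } else {
    aes <- ggplot2::aes(.data$zone, .data$value)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$index), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "index value (a.u.)")
}
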