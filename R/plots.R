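#' Display one cross-sectional B-scan
#'
#' @param volume An [oct_volume()].
#' @param y Slice index along the slow axis (default: middle slice).
#' @param log Log-compress for display.
#' @return A ggplot object (depth increasing downward, as OCT images are
#'   conventionally shown).
#' @export
plot_bscan <- function(volume, y = NULL, log = TRUE) {
  stopifnot(inherits(volume, "oct_volume"))
  d <- dim(volume$intensity)
  y <- y %||% ((d[3] + 1L) %/% 2L)
  sl <- volume$intensity[, , y]
  df <- tidyr::expand_grid(z = seq_len(d[1]), x = seq_len(d[2]))
  df$intensity <- as.vector(sl)
  if (log) df$intensity <- log1p(df$intensity)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x * volume$pitch[2],
                                   y = .data$z * volume$pitch[1],
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = if (log) "log intensity" else "intensity") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "depth (µm)",
                  title = paste0("B-scan at y = ", y))
}

#' Box plots of a metric per treatment arm
#'
#' Boxes are drawn from [summarize_group()] rows so the whisker rule (1.5 IQR
#' fences clamped to the data) matches the reported summaries exactly;
#' outliers are overplotted as points.
#'
#' @param records Tidy per-well tibble with `treatment`, `day` and the metric.
#' @param metric Metric column name.
#' @param quantile_type Passed to [summarize_group()].
#' @return A ggplot object, faceted by day when several days are present.
#' @export
plot_group_boxes <- function(records, metric, quantile_type = 7) {
  s <- summarize_arms(records, metric, quantile_type = quantile_type)
  outl <- tidyr::unnest(select(s, "treatment", "day", "outliers"),
                        "outliers")
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$treatment)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$whisker_low, lower = .data$q1,
                   middle = .data$median, upper = .data$q3,
                   ymax = .data$whisker_high),
      stat = "identity", width = 0.6) +
    ggplot2::labs(x = NULL, y = metric)
  if (nrow(outl)) {
    p <- p + ggplot2::geom_point(data = outl,
                                 ggplot2::aes(y = .data$outliers), shape = 1)
  }
  if (length(unique(s$day)) > 1L) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$day), labeller = "label_both")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a synergy table
#'
#' Shows the per-day difference between the combination arm and the best
#' monotherapy for each metric, with significant synergy days filled.
#'
#' @param object An `oct_synergy` table from [synergy_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oct_synergy <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$day, y = .data$difference)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(fill = .data$synergy), shape = 21, size = 3) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "white", `TRUE` = "black"),
                               name = "synergy (p < α)") +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "day post-treatment",
                  y = "combination − best monotherapy")
}
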