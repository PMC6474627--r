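#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point
#'   geom_histogram geom_errorbar geom_raster labs theme_minimal
#'   scale_fill_viridis_c facet_wrap after_stat
NULL

#' @export
ggplot2::autoplot

#' Plot the spots-versus-threshold curve
#'
#' Spot count against detection threshold with the selected plateau
#' threshold marked; the knee-then-plateau shape is what the automatic
#' selection rule exploits.
#'
#' @param object An `smfish_threshold_scan`.
#' @param ... Unused.
#' @export
autoplot.smfish_threshold_scan <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$threshold, y = .data$n_spots)) +
    geom_line() +
    ggplot2::geom_vline(xintercept = object$selected,
                        linetype = "dashed", colour = "red") +
    labs(x = "detection threshold (LoG response)",
         y = "spots detected",
         title = sprintf("threshold scan (selected %.3g%s)",
                         object$selected,
                         if (object$fallback) ", fallback" else "")) +
    theme_minimal()
}

#' Histogram of counts with the fitted distribution overlaid
#'
#' @param object An `smfish_fit`.
#' @param counts The counts the fit was computed from.
#' @param bins Histogram bins (default 40).
#' @param ... Unused.
#' @export
autoplot.smfish_fit <- function(object, counts, bins = 40, ...) {
  counts <- counts[!is.na(counts)]
  if (object$family != "poisson") counts <- counts[counts > 0]
  grid <- seq(max(min(counts), 0.5), max(counts), length.out = 400)
  dens <- switch(object$family,
    poisson = dpois(round(grid), object$parameters$lambda),
    lognormal = dlnorm(grid, object$parameters$mu,
                       object$parameters$sigma),
    gamma = dgamma(grid, shape = object$parameters$shape,
                   scale = object$parameters$scale))
  ggplot(tibble(count = counts), aes(x = .data$count)) +
    geom_histogram(aes(y = after_stat(.data$density)), bins = bins,
                   fill = "grey70", colour = "grey40") +
    geom_line(data = tibble(count = grid, density = dens),
              aes(y = .data$density), colour = "red") +
    labs(title = sprintf("%s fit (AIC %.1f, n = %d)", object$family,
                         object$aic, object$n_cells),
         x = "per-cell count", y = "density") +
    theme_minimal()
}

#' Time-course plot with scan-level error bars
#'
#' Mean content per time point; error bars are the standard deviation
#' of the scan means (not the single-cell spread).
#'
#' @param summary_tbl Output of [timecourse_summary()], possibly
#'   row-bound over several variables.
#' @export
plot_timecourse <- function(summary_tbl) {
  ggplot(summary_tbl,
         aes(x = .data$time_minutes, y = .data$mean,
             colour = .data$variable, group = .data$variable)) +
    geom_line() + geom_point() +
    geom_errorbar(aes(ymin = .data$mean - .data$scan_sd,
                      ymax = .data$mean + .data$scan_sd), width = 5) +
    labs(x = "time after stimulation (min)", y = "mean per cell",
         colour = NULL) +
    theme_minimal()
}

#' Correlation-over-time plot
#'
#' @param corr_tbl Output of [correlate()] over several time points.
#' @export
plot_correlation_timecourse <- function(corr_tbl) {
  ggplot(corr_tbl, aes(x = .data$time_minutes, y = .data$r)) +
    geom_line() + geom_point() +
    ggplot2::ylim(-1, 1) +
    labs(x = "time after stimulation (min)", y = "Pearson r",
         title = sprintf("%s vs %s", corr_tbl$var_x[1],
                         corr_tbl$var_y[1])) +
    theme_minimal()
}

#' Segmentation overlay plot
#'
#' Cell boundaries and nucleus masks over a chosen channel, for visual
#' QC of the watershed result.
#'
#' @param object An `smfish_segmentation`.
#' @param image Optional background image matrix (e.g. the DAPI
#'   channel); label maps alone are shown otherwise.
#' @param ... Unused.
#' @export
autoplot.smfish_segmentation <- function(object, image = NULL, ...) {
  lab <- object$cell_labels
  df <- tibble(
    row = rep(seq_len(nrow(lab)), ncol(lab)),
    col = rep(seq_len(ncol(lab)), each = nrow(lab)),
    value = if (is.null(image)) as.vector(lab) else as.vector(image),
    cell = as.vector(lab))
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    labs(title = sprintf("%d cells", object$n_cells), fill = NULL) +
    theme_minimal()
}

#' Single-cell scatter of two variables
#'
#' The per-cell scatter (one dot per cell) behind a correlation
#' estimate, faceted by time point.
#'
#' @param cell_table A cell-table tibble.
#' @param var_x,var_y Column names.
#' @export
plot_cell_scatter <- function(cell_table, var_x, var_y) {
  ggplot(cell_table,
         aes(x = .data[[var_x]], y = .data[[var_y]])) +
    geom_point(alpha = 0.5) +
    facet_wrap(~time_minutes, labeller = ggplot2::label_both) +
    labs(x = var_x, y = var_y) +
    theme_minimal()
}
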