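# ggplot2 figure methods for the result objects: a polar rose of
# translational deviations, a deviation histogram for rotational polarity,
# an ordered heat map for signature similarity, and a raster view of
# kymographs.

#' @export
autoplot.translational_summary <- function(object, ...) {
  h <- object$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = h$bin_hi[1] - h$bin_lo[1],
                      fill = "steelblue", colour = "grey30",
                      linewidth = 0.2) +
    ggplot2::coord_polar(start = pi) +
    ggplot2::scale_x_continuous(limits = c(-180, 180),
                                breaks = seq(-180, 135, by = 45)) +
    ggplot2::labs(
      x = "deviation from mean direction (deg)", y = "cells",
      title = sprintf("Translational PCP: %.0f%% of vectors within %g deg",
                      100 * object$fraction_within, object$bound_deg)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rotational_summary <- function(object, ...) {
  ggplot2::ggplot(object$deviations,
                  ggplot2::aes(x = .data$deviation_deg)) +
    ggplot2::geom_histogram(
      breaks = seq(0, max(object$histogram$bin_hi),
                   by = object$histogram$bin_hi[1] - object$histogram$bin_lo[1]),
      fill = "indianred", colour = "grey30", linewidth = 0.2) +
    ggplot2::labs(
      x = "deviation from image mean (deg)", y = "cilia",
      title = sprintf("Rotational PCP: mean deviation %.2f +/- %.2f deg",
                      object$grand_mean_dev, object$sem_dev)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.similarity_result <- function(object, ...) {
  ord <- object$cluster_order
  df <- tidy(object)
  df2 <- dplyr::bind_rows(
    df,
    dplyr::rename(df, pop1 = "pop2", pop2 = "pop1"),
    tibble(pop1 = object$labels, pop2 = object$labels,
           distance = 0, correlation = 1)
  )
  df2$pop1 <- factor(df2$pop1, levels = ord)
  df2$pop2 <- factor(df2$pop2, levels = ord)
  ggplot2::ggplot(df2, ggplot2::aes(x = .data$pop1, y = .data$pop2,
                                    fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$correlation)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1), name = "|cosθ|") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Signature correlation (cluster-ordered)") +
    ggplot2::theme_minimal()
}

#' Plot a kymograph as a space-time raster
#'
#' @param kymo A `kymograph`.
#' @param ... Unused.
#' @return A ggplot object (time in seconds on x, position along the ROI
#'   on y).
#' @export
plot_kymograph <- function(kymo, ...) {
  if (!inherits(kymo, "kymograph")) abort("`kymo` must be a kymograph.")
  df <- tidyr::expand_grid(t = seq_len(ncol(kymo$values)),
                           s = seq_len(nrow(kymo$values)))
  df$intensity <- as.vector(kymo$values)
  df$time_s <- (df$t - 1) / kymo$fps
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$s,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::labs(x = "time (s)", y = "position along ROI (px)") +
    ggplot2::theme_minimal()
}
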