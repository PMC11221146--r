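# Rotational planar cell polarity: per-cilium deviation of the central
# microtubule pair's orientation from the mean angle of the grouped cilia
# in the same image.

.periodicity_to_period <- function(periodicity) {
  switch(periodicity,
         directional_360 = 360,
         axial_180 = 180,
         abort("`periodicity` must be 'directional_360' or 'axial_180'."))
}

#' Per-cilium angular deviations within one image
#'
#' Circular mean of the image's angles under the declared periodicity, then
#' the absolute wrapped difference of each cilium's angle to that mean, in
#' `[0, period/2]`.
#'
#' @param angles Numeric vector of central-pair orientations in degrees
#'   (at least 2).
#' @param periodicity `"directional_360"` (directed central-pair arrows,
#'   default) or `"axial_180"` (undirected axes).
#' @return Numeric vector of deviations in degrees.
#' @examples
#' per_cilium_deviation(c(0, 20))    # 10, 10
#' per_cilium_deviation(c(350, 10))  # 10, 10 (wrap-around)
#' @export
per_cilium_deviation <- function(angles, periodicity = "directional_360") {
  .check_angles(angles)
  period <- .periodicity_to_period(periodicity)
  if (length(angles) < 2) {
    abort("At least 2 angles are needed to measure deviation from the image mean.")
  }
  m <- .circ_stats(angles, period)$mean_deg
  angular_deviation(angles, m, period)
}

#' Deviation table for a set of orientation images
#'
#' Applies [per_cilium_deviation()] image by image.
#'
#' @param angles Tibble with columns `image_id` and `angle_deg` (e.g. from
#'   [sim_orientation_field()] or [read_angles()]).
#' @inheritParams per_cilium_deviation
#' @return Input tibble with a `deviation_deg` column appended.
#' @export
cilium_deviations <- function(angles, periodicity = "directional_360") {
  stopifnot(is.data.frame(angles),
            all(c("image_id", "angle_deg") %in% names(angles)))
  angles |>
    dplyr::group_by(.data$image_id) |>
    dplyr::mutate(deviation_deg = per_cilium_deviation(.data$angle_deg,
                                                       periodicity)) |>
    dplyr::ungroup()
}

#' Summarise rotational polarity
#'
#' Pools per-cilium deviations over images; the grand mean and its standard
#' error are computed across pooled cilia (the reporting convention for this
#' assay: at least 10 images and 100 cilia per animal). Per-image-first
#' aggregation is available as an option.
#'
#' @inheritParams cilium_deviations
#' @param min_cilia,min_images Minimum pooled cilia and images expected;
#'   fewer raises a warning.
#' @param pooling `"cilia"` (default; sem across pooled cilia) or
#'   `"image_first"` (mean per image, then mean +/- sem across images).
#' @param bin_width Histogram bin width in degrees (default 10 over
#'   `[0, period/2]`).
#' @return A `rotational_summary`: list with `deviations` (tibble),
#'   `grand_mean_dev`, `sem_dev`, `per_image` (tibble `image_id`,
#'   `mean_dev`, `n`), `histogram`, `n_cilia`, `n_images`, `periodicity`,
#'   `pooling`. Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
summarize_rotational <- function(angles, periodicity = "directional_360",
                                 min_cilia = 100, min_images = 10,
                                 pooling = c("cilia", "image_first"),
                                 bin_width = 10) {
  pooling <- match.arg(pooling)
  period <- .periodicity_to_period(periodicity)
  dev <- cilium_deviations(angles, periodicity)
  per_image <- dev |>
    dplyr::group_by(.data$image_id) |>
    dplyr::summarise(mean_dev = mean(.data$deviation_deg),
                     n = dplyr::n(), .groups = "drop")
  n_cilia <- nrow(dev)
  n_images <- nrow(per_image)
  if (n_cilia < min_cilia || n_images < min_images) {
    warn(sprintf(
      "Only %d cilia in %d image(s); reporting practice expects >= %d cilia and >= %d images.",
      n_cilia, n_images, min_cilia, min_images))
  }
  if (pooling == "cilia") {
    gm <- mean(dev$deviation_deg)
    sem <- sd(dev$deviation_deg) / sqrt(n_cilia)
  } else {
    gm <- mean(per_image$mean_dev)
    sem <- sd(per_image$mean_dev) / sqrt(n_images)
  }
  breaks <- seq(0, period / 2, by = bin_width)
  counts <- hist(dev$deviation_deg, breaks = breaks, plot = FALSE)$counts
  structure(
    list(deviations = dev, grand_mean_dev = gm, sem_dev = sem,
         per_image = per_image,
         histogram = tibble(bin_lo = head(breaks, -1), bin_hi = breaks[-1],
                            count = counts),
         n_cilia = n_cilia, n_images = n_images,
         periodicity = periodicity, pooling = pooling),
    class = "rotational_summary"
  )
}

#' @export
print.rotational_summary <- function(x, ...) {
  cat("Rotational PCP summary\n")
  cat(sprintf("  %d cilia in %d image(s), periodicity %s\n",
              x$n_cilia, x$n_images, x$periodicity))
  cat(sprintf("  mean deviation from image mean: %.2f +/- %.2f deg (mean +/- sem, %s pooling)\n",
              x$grand_mean_dev, x$sem_dev, x$pooling))
  invisible(x)
}

#' @export
tidy.rotational_summary <- function(x, ...) x$deviations

#' @export
glance.rotational_summary <- function(x, ...) {
  tibble(grand_mean_dev = x$grand_mean_dev, sem_dev = x$sem_dev,
         n_cilia = x$n_cilia, n_images = x$n_images,
         periodicity = x$periodicity, pooling = x$pooling)
}
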