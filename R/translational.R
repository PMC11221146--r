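# Translational planar cell polarity: per-cell vectors from the apical
# centre (area-weighted polygon centroid) to the basal-body patch centroid,
# apical-area statistics, and deviation-around-the-mean summaries.

.shoelace <- function(poly) {
  # signed area in px^2; poly is an n x 2 matrix, vertices in order
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

.polygon_area_px <- function(poly) abs(.shoelace(poly))

.check_polygon <- function(poly) {
  if (!is.matrix(poly) || ncol(poly) != 2 || nrow(poly) < 3 ||
      !all(is.finite(poly))) {
    abort("A polygon must be a finite n x 2 vertex matrix with n >= 3.")
  }
  invisible(poly)
}

# segment-intersection test for simplicity checking (small n only)
.segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

.is_simple_polygon <- function(poly) {
  n <- nrow(poly)
  seg <- function(i) list(poly[i, ], poly[if (i == n) 1 else i + 1, ])
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 2, n)) {
      if (i == 1 && j == n) next  # adjacent through the wrap-around
      si <- seg(i); sj <- seg(j)
      if (.segments_cross(si[[1]], si[[2]], sj[[1]], sj[[2]])) return(FALSE)
    }
  }
  TRUE
}

#' Area-weighted centroid of a polygon
#'
#' Shoelace-based centroid of a simple polygon given as an ordered vertex
#' matrix (pixel coordinates). Works for any vertex orientation.
#'
#' @param poly Numeric `n x 2` matrix of vertices, `n >= 3`.
#' @return Length-2 numeric vector `(x, y)`.
#' @examples
#' polygon_centroid(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))  # (0.5, 0.5)
#' @export
polygon_centroid <- function(poly) {
  .check_polygon(poly)
  A <- .shoelace(poly)
  if (abs(A) < 1e-12) abort("Degenerate polygon: zero area.")
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  c(x = sum((x + xn) * cr) / (6 * A), y = sum((y + yn) * cr) / (6 * A))
}

#' Apical area of a cell polygon
#'
#' Shoelace area scaled by the pixel calibration. Self-intersecting outlines
#' are rejected because their shoelace area is meaningless.
#'
#' @inheritParams polygon_centroid
#' @param pixel_size Micrometres per pixel (> 0).
#' @return Area in square micrometres.
#' @examples
#' apical_area(cbind(c(0, 2, 0), c(0, 0, 2)), pixel_size = 0.5)  # 0.5 um^2
#' @export
apical_area <- function(poly, pixel_size = 1) {
  .check_polygon(poly)
  if (pixel_size <= 0) abort("`pixel_size` must be positive.")
  if (!.is_simple_polygon(poly)) {
    abort("Self-intersecting polygon: area is undefined.")
  }
  a <- .polygon_area_px(poly)
  if (a < 1e-12) abort("Degenerate polygon: zero area.")
  a * pixel_size^2
}

#' Per-cell translational-polarity vectors
#'
#' For every cell with a recorded basal-body patch centroid, computes the
#' vector from the apical-surface centre (area-weighted polygon centroid) to
#' that centroid. Input coordinates are image-convention pixels (origin
#' top-left, y down); reported angles are mathematical convention
#' (counter-clockwise from +x) after flipping the y axis, in `[0, 360)`.
#' Vectors shorter than `epsilon` micrometres are flagged degenerate. Cells
#' without a basal-body centroid are skipped and counted in the
#' `n_missing_bb` attribute.
#'
#' @param map An `apical_map` (see [new_apical_map()], [sim_apical_map()]).
#' @param epsilon Degeneracy threshold on vector magnitude, micrometres.
#' @return Tibble with one row per eligible cell: `cell_id`, `image_id`,
#'   `centre_x`, `centre_y`, `angle_deg`, `magnitude_um`, `area_um2`,
#'   `degenerate`.
#' @export
translational_vectors <- function(map, epsilon = 0.1) {
  if (!inherits(map, "apical_map")) abort("`map` must be an apical_map.")
  cells <- map$cells
  if (nrow(cells) == 0) abort("Empty map: no cells to analyse.")
  has_bb <- is.finite(cells$bb_x) & is.finite(cells$bb_y)
  n_missing <- sum(!has_bb)
  cells <- cells[has_bb, , drop = FALSE]
  if (nrow(cells) == 0) abort("No cell in the map has a basal-body centroid.")
  cen <- t(vapply(cells$polygon, polygon_centroid, numeric(2)))
  dx <- cells$bb_x - cen[, 1]
  dy <- -(cells$bb_y - cen[, 2])  # flip y: image rows grow downwards
  mag_um <- sqrt(dx^2 + dy^2) * map$pixel_size
  out <- tibble(
    cell_id = cells$cell_id,
    image_id = map$image_id,
    centre_x = cen[, 1], centre_y = cen[, 2],
    angle_deg = (rad2deg(atan2(dy, dx))) %% 360,
    magnitude_um = mag_um,
    area_um2 = vapply(cells$polygon, .polygon_area_px, numeric(1)) *
      map$pixel_size^2,
    degenerate = mag_um < epsilon
  )
  attr(out, "n_missing_bb") <- n_missing
  out
}

#' Summarise translational polarity
#'
#' Deviation of each cell's polarity-vector angle from a reference
#' direction: the per-image circular mean by default, or a fixed angle.
#' Degenerate vectors (magnitude below the epsilon used upstream) are
#' excluded and counted. The headline statistic is the share of cells whose
#' absolute wrapped deviation is at most `bound_deg` (default 45 degrees).
#'
#' @param vectors Tibble from [translational_vectors()]; rows from several
#'   images may be pooled (reference is computed per `image_id`).
#' @param reference `"per_image_mean"` (default) or `"fixed_angle"`.
#' @param ref_angle Reference direction in degrees when
#'   `reference = "fixed_angle"`.
#' @param bound_deg Deviation bound for the headline fraction, degrees.
#' @param min_cells Minimum cells per image expected for a reliable
#'   summary; fewer raises a warning (quantification practice in this field
#'   uses at least 30 cells per image).
#' @param bin_width Histogram bin width in degrees for the signed-deviation
#'   histogram (default 15, i.e. 24 bins around the circle).
#' @return A `translational_summary`: list with `deviations` (tibble
#'   `cell_id`, `image_id`, `angle_deg`, `deviation_deg` signed,
#'   `abs_deviation_deg`), `fraction_within` and `bound_deg`,
#'   `mean_area_um2` and `sem_area_um2`, `n_cells`, `n_degenerate`,
#'   `histogram`, `reference`. Has [tidy()], [glance()] and [autoplot()]
#'   methods.
#' @export
summarize_translational <- function(vectors,
                                    reference = c("per_image_mean",
                                                  "fixed_angle"),
                                    ref_angle = NULL, bound_deg = 45,
                                    min_cells = 30, bin_width = 15) {
  reference <- match.arg(reference)
  stopifnot(is.data.frame(vectors),
            all(c("angle_deg", "degenerate") %in% names(vectors)))
  if (reference == "fixed_angle" && is.null(ref_angle)) {
    abort("`ref_angle` is required when reference = 'fixed_angle'.")
  }
  n_degenerate <- sum(vectors$degenerate)
  ok <- vectors[!vectors$degenerate, , drop = FALSE]
  if (nrow(ok) == 0) abort("All vectors are degenerate; nothing to summarise.")
  if (!"image_id" %in% names(ok)) ok$image_id <- "image"

  per_image_n <- table(ok$image_id)
  if (any(per_image_n < min_cells)) {
    low <- names(per_image_n)[per_image_n < min_cells]
    warn(sprintf("Image(s) %s have fewer than %d cells; summary may be unstable.",
                 paste(low, collapse = ", "), min_cells))
  }

  dev <- ok |>
    dplyr::group_by(.data$image_id) |>
    dplyr::mutate(
      ref_deg = if (reference == "per_image_mean") {
        .circ_stats(.data$angle_deg)$mean_deg
      } else {
        ref_angle
      }
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      deviation_deg = wrap_difference(.data$angle_deg, .data$ref_deg),
      abs_deviation_deg = abs(.data$deviation_deg)
    ) |>
    dplyr::select("cell_id", "image_id", "angle_deg", "deviation_deg",
                  "abs_deviation_deg")

  breaks <- seq(-180, 180, by = bin_width)
  counts <- hist(dev$deviation_deg, breaks = breaks, plot = FALSE)$counts
  histogram <- tibble(bin_lo = head(breaks, -1), bin_hi = breaks[-1],
                      count = counts)
  areas <- if ("area_um2" %in% names(ok)) ok$area_um2 else NULL
  structure(
    list(
      deviations = dev,
      fraction_within = mean(dev$abs_deviation_deg <= bound_deg),
      bound_deg = bound_deg,
      mean_area_um2 = if (!is.null(areas)) mean(areas) else NA_real_,
      sem_area_um2 = if (!is.null(areas) && length(areas) > 1) {
        sd(areas) / sqrt(length(areas))
      } else {
        NA_real_
      },
      n_cells = nrow(dev),
      n_images = length(unique(dev$image_id)),
      n_degenerate = n_degenerate,
      histogram = histogram,
      reference = reference
    ),
    class = "translational_summary"
  )
}

#' @importFrom graphics hist
NULL

#' @export
print.translational_summary <- function(x, ...) {
  cat("Translational PCP summary\n")
  cat(sprintf("  %d cells in %d image(s); %d degenerate vector(s) excluded\n",
              x$n_cells, x$n_images, x$n_degenerate))
  cat(sprintf("  fraction within %g deg of the %s: %.3f\n",
              x$bound_deg, gsub("_", " ", x$reference), x$fraction_within))
  if (is.finite(x$mean_area_um2)) {
    cat(sprintf("  apical area: %.2f +/- %.2f um^2 (mean +/- sem)\n",
                x$mean_area_um2, x$sem_area_um2))
  }
  invisible(x)
}

#' @export
tidy.translational_summary <- function(x, ...) x$deviations

#' @export
glance.translational_summary <- function(x, ...) {
  tibble(fraction_within = x$fraction_within, bound_deg = x$bound_deg,
         mean_area_um2 = x$mean_area_um2, sem_area_um2 = x$sem_area_um2,
         n_cells = x$n_cells, n_images = x$n_images,
         n_degenerate = x$n_degenerate)
}
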