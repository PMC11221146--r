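# File formats: plain-text CSV tables for cell maps, angle lists and
# profiles; multi-page TIFF plus a JSON sidecar for recordings. Every
# writer's output is re-parseable by the matching reader. Angles are always
# degrees in files.

.fmt_polygon <- function(poly) {
  paste(sprintf("%.6g,%.6g", poly[, 1], poly[, 2]), collapse = ";")
}

.parse_polygon <- function(s, row) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  xy <- strsplit(parts, ",", fixed = TRUE)
  ok <- lengths(xy) == 2
  if (!all(ok) || length(xy) < 3) {
    abort(sprintf("Row %d: polygon must list >= 3 'x,y' vertices separated by ';'.",
                  row))
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(xy))), ncol = 2, byrow = TRUE)
  if (!all(is.finite(m))) {
    abort(sprintf("Row %d: non-numeric polygon vertex.", row))
  }
  colnames(m) <- c("x", "y")
  m
}

#' Write / read an apical cell map as CSV
#'
#' Columns: `image_id`, `cell_id`, `polygon` (semicolon-separated `x,y`
#' vertices, pixels), `bb_x`, `bb_y`. The pixel calibration is supplied to
#' the reader, not stored in the table.
#'
#' @param map An `apical_map`.
#' @param path Output CSV path.
#' @return `write_cell_map` returns `path` invisibly; `read_cell_map`
#'   returns an `apical_map`.
#' @export
write_cell_map <- function(map, path) {
  if (!inherits(map, "apical_map")) abort("`map` must be an apical_map.")
  df <- data.frame(
    image_id = map$image_id,
    cell_id = map$cells$cell_id,
    polygon = vapply(map$cells$polygon, .fmt_polygon, character(1)),
    bb_x = map$cells$bb_x, bb_y = map$cells$bb_y
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_map
#' @param pixel_size Micrometres per pixel (> 0).
#' @export
read_cell_map <- function(path, pixel_size) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "polygon", "bb_x", "bb_y")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(sprintf("Cell-map file lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  polys <- purrr::imap(df$polygon, function(s, i) .parse_polygon(s, i))
  cells <- tibble(cell_id = as.character(df$cell_id), polygon = polys,
                  bb_x = suppressWarnings(as.numeric(df$bb_x)),
                  bb_y = suppressWarnings(as.numeric(df$bb_y)))
  image_id <- if ("image_id" %in% names(df)) as.character(df$image_id[1]) else "image"
  new_apical_map(cells, pixel_size = pixel_size, image_id = image_id)
}

#' Write / read angle tables (CSV: image_id, angle_deg)
#'
#' @param angles Tibble with `image_id` and `angle_deg` columns; the
#'   `periodicity` attribute, if present, travels through the writer/reader
#'   pair via the `periodicity` argument of the reader.
#' @param path CSV path.
#' @export
write_angles <- function(angles, path) {
  stopifnot(is.data.frame(angles),
            all(c("image_id", "angle_deg") %in% names(angles)))
  write.csv(as.data.frame(angles[c("image_id", "angle_deg")]), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_angles
#' @param periodicity Declared periodicity of the stored angles.
#' @export
read_angles <- function(path, periodicity = "directional_360") {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  .periodicity_to_period(periodicity)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("image_id", "angle_deg") %in% names(df))) {
    abort("Angle file must have columns image_id, angle_deg.")
  }
  ang <- suppressWarnings(as.numeric(df$angle_deg))
  if (!all(is.finite(ang))) {
    abort(sprintf("Non-numeric angle(s) at row(s): %s",
                  paste(which(!is.finite(ang)), collapse = ", ")))
  }
  out <- tibble(image_id = as.character(df$image_id), angle_deg = ang)
  attr(out, "periodicity") <- periodicity
  out
}

#' Write / read an image stack as multi-page TIFF + JSON sidecar
#'
#' Intensities are min-max scaled to 16-bit for storage; the affine scale
#' and offset are recorded in the sidecar (`<path>.json`, alongside `fps`
#' and `pixel_size`) and undone on read. A missing sidecar or a sidecar
#' without `fps` is an error - the frame rate is never silently defaulted.
#'
#' @param stack An `image_stack`.
#' @param path TIFF path (the sidecar is written next to it).
#' @export
write_stack <- function(stack, path) {
  if (!inherits(stack, "image_stack")) abort("`stack` must be an image_stack.")
  d <- dim(stack$frames)
  lo <- min(stack$frames); hi <- max(stack$frames)
  scale <- if (hi > lo) hi - lo else 1
  pages <- purrr::map(seq_len(d[1]), function(t) {
    (stack$frames[t, , ] - lo) / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  jsonlite::write_json(
    list(fps = stack$fps, pixel_size = stack$pixel_size,
         intensity_offset = lo, intensity_scale = scale,
         n_frames = d[1], height = d[2], width = d[3]),
    .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.sidecar_path <- function(path) paste0(path, ".json")

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  sc_path <- .sidecar_path(path)
  if (!file.exists(sc_path)) {
    abort(sprintf("Missing JSON sidecar '%s': frame rate metadata is required.",
                  sc_path))
  }
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  if (is.null(sc$fps)) {
    abort("Sidecar lacks `fps`; the frame rate is never defaulted.")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (t in seq_along(pages)) {
    arr[t, , ] <- pages[[t]] * (sc$intensity_scale %||% 1) +
      (sc$intensity_offset %||% 0)
  }
  new_image_stack(arr, fps = sc$fps,
                  pixel_size = sc$pixel_size %||% NA_real_)
}

#' Write / read population profile tables (CSV: gene, one column per
#' population)
#'
#' @param profiles Tibble with a `gene` column and numeric population
#'   columns.
#' @param path CSV path.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(is.data.frame(profiles), "gene" %in% names(profiles))
  write.csv(as.data.frame(profiles), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"gene" %in% names(df)) names(df)[1] <- "gene"
  as_tibble(df)
}

#' Write / read a ground-truth record as JSON
#'
#' @param truth A `ground_truth` (from the simulators).
#' @param path JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "ground_truth")
}
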