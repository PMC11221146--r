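# Ciliary beat-frequency estimation: kymograph extraction from time-lapse
# stacks, peak counting on the intensity trace, and an independent spectral
# (FFT) estimator used as a cross-check.

#' Extract a kymograph along a line ROI
#'
#' Samples each frame's intensity along a straight line, averaging over a
#' band of configurable width perpendicular to the line to reduce noise.
#' Column `t` of the kymograph is frame `t`.
#'
#' @param stack An `image_stack` (see [new_image_stack()]).
#' @param roi Numeric `c(x0, y0, x1, y1)`, 1-based pixel coordinates of the
#'   line endpoints; both must lie inside the frame.
#' @param band_px Width of the averaging band in pixels (odd; default 3).
#' @param interpolation `"linear"` (bilinear, default) or `"nearest"`.
#' @return A `kymograph`: list with `values` (space x time matrix), `fps`,
#'   `roi`.
#' @export
extract_kymograph <- function(stack, roi, band_px = 3,
                              interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (!inherits(stack, "image_stack")) abort("`stack` must be an image_stack.")
  roi <- as.numeric(roi)
  if (length(roi) != 4 || !all(is.finite(roi))) {
    abort("`roi` must be c(x0, y0, x1, y1).")
  }
  d <- dim(stack$frames)  # T, H, W
  if (any(roi[c(1, 3)] < 1) || any(roi[c(1, 3)] > d[3]) ||
      any(roi[c(2, 4)] < 1) || any(roi[c(2, 4)] > d[2])) {
    abort("ROI endpoints must lie inside the frame bounds.")
  }
  len <- sqrt((roi[3] - roi[1])^2 + (roi[4] - roi[2])^2)
  n_s <- max(2L, ceiling(len) + 1L)
  sx <- seq(roi[1], roi[3], length.out = n_s)
  sy <- seq(roi[2], roi[4], length.out = n_s)
  # unit normal for the averaging band
  if (len < 1e-9) {
    nx <- 0; ny <- 1
  } else {
    nx <- -(roi[4] - roi[2]) / len
    ny <- (roi[3] - roi[1]) / len
  }
  offs <- seq(-(band_px %/% 2), band_px %/% 2)

  sample_plane <- function(frame, px, py) {
    px <- pmin(pmax(px, 1), d[3])
    py <- pmin(pmax(py, 1), d[2])
    if (interpolation == "nearest") {
      frame[cbind(round(py), round(px))]
    } else {
      x0 <- floor(px); y0 <- floor(py)
      x1 <- pmin(x0 + 1, d[3]); y1 <- pmin(y0 + 1, d[2])
      fx <- px - x0; fy <- py - y0
      frame[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
        frame[cbind(y0, x1)] * fx * (1 - fy) +
        frame[cbind(y1, x0)] * (1 - fx) * fy +
        frame[cbind(y1, x1)] * fx * fy
    }
  }

  values <- matrix(0, nrow = n_s, ncol = d[1])
  for (t in seq_len(d[1])) {
    frame <- stack$frames[t, , ]
    acc <- numeric(n_s)
    for (o in offs) {
      acc <- acc + sample_plane(frame, sx + o * nx, sy + o * ny)
    }
    values[, t] <- acc / length(offs)
  }
  structure(list(values = values, fps = stack$fps, roi = roi,
                 band_px = band_px, interpolation = interpolation),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph: %d px x %d frames at %g fps>\n",
              nrow(x$values), ncol(x$values), x$fps))
  invisible(x)
}

#' Mean intensity trace of a kymograph
#'
#' Averages over the space axis, giving one intensity value per frame.
#' @param kymo A `kymograph`.
#' @return Numeric vector of length T.
#' @export
kymograph_trace <- function(kymo) {
  if (!inherits(kymo, "kymograph")) abort("`kymo` must be a kymograph.")
  colMeans(kymo$values)
}

# local maxima with topographic prominence; returns indices
.find_peaks <- function(x, min_prominence_abs, min_sep = 1L) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    lmin <- x[i]; j <- i
    while (j > 1 && x[j] <= x[i]) { j <- j - 1; lmin <- min(lmin, x[j]) }
    if (x[j] <= x[i]) lmin <- min(x[seq_len(i)])  # no higher point leftward
    rmin <- x[i]; j <- i
    while (j < n && x[j] <= x[i]) { j <- j + 1; rmin <- min(rmin, x[j]) }
    if (x[j] <= x[i]) rmin <- min(x[i:n])
    x[i] - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= min_prominence_abs]
  if (min_sep > 1 && length(keep) > 1) {
    ord <- keep[order(x[keep], decreasing = TRUE)]
    chosen <- integer(0)
    for (i in ord) {
      if (!length(chosen) || all(abs(chosen - i) >= min_sep)) {
        chosen <- c(chosen, i)
      }
    }
    keep <- sort(chosen)
  }
  keep
}

#' Beat frequency by peak counting
#'
#' Counts intensity peaks along the trace (each peak one beat) and divides
#' by the recording duration. Peaks must have topographic prominence of at
#' least `min_prominence` times the trace range; an optional minimum
#' separation of `0.3 / max_freq` seconds suppresses double counting when a
#' maximum expected frequency is supplied.
#'
#' @param trace Numeric intensity series (one value per frame, >= 3).
#' @param fps Frame rate in Hz.
#' @param min_prominence Prominence threshold as a fraction of the trace
#'   range (default 0.2).
#' @param max_freq Maximum physiologically expected frequency, Hz; defaults
#'   to the Nyquist limit `fps/2` (no separation constraint).
#' @return One-row tibble: `freq_hz`, `n_peaks`, `low_snr` (flat-trace
#'   flag).
#' @export
peak_frequency <- function(trace, fps, min_prominence = 0.2,
                           max_freq = fps / 2) {
  if (length(trace) < 3) abort("`trace` needs at least 3 samples.")
  if (fps <= 0) abort("`fps` must be positive.")
  rng <- diff(range(trace))
  if (rng < 1e-12) {
    return(tibble(freq_hz = 0, n_peaks = 0L, low_snr = TRUE))
  }
  min_sep <- max(1L, floor(0.3 / max_freq * fps))
  pk <- .find_peaks(trace, min_prominence_abs = min_prominence * rng,
                    min_sep = min_sep)
  duration <- length(trace) / fps
  tibble(freq_hz = length(pk) / duration, n_peaks = length(pk),
         low_snr = FALSE)
}

#' Beat frequency from the intensity spectrum
#'
#' Frequency of the dominant non-zero component of the mean-detrended
#' discrete Fourier transform of the trace. Serves as an estimator
#' independent of peak counting.
#'
#' @inheritParams peak_frequency
#' @return One-row tibble: `freq_hz` (`NA` with `low_snr = TRUE` for a flat
#'   trace), `bin_width_hz`.
#' @export
spectral_frequency <- function(trace, fps) {
  if (length(trace) < 3) abort("`trace` needs at least 3 samples.")
  if (fps <= 0) abort("`fps` must be positive.")
  n <- length(trace)
  bw <- fps / n
  if (diff(range(trace)) < 1e-12) {
    return(tibble(freq_hz = NA_real_, bin_width_hz = bw, low_snr = TRUE))
  }
  sp <- abs(fft(trace - mean(trace)))
  k <- seq(2L, floor(n / 2) + 1L)  # positive non-zero frequencies
  kmax <- k[which.max(sp[k])]
  tibble(freq_hz = (kmax - 1) * bw, bin_width_hz = bw, low_snr = FALSE)
}

#' Estimate beat frequency from a kymograph
#'
#' Runs both the peak-counting and spectral estimators on the kymograph's
#' mean trace and flags disagreement beyond `agree_tol_hz`.
#'
#' @param kymo A `kymograph`.
#' @inheritParams peak_frequency
#' @param agree_tol_hz Estimator disagreement threshold, Hz (default 0.5).
#' @param roi_id Identifier carried into the output.
#' @return One-row tibble: `roi_id`, `freq_peaks`, `freq_spectral`,
#'   `n_peaks`, `low_snr`, `disagreement`.
#' @export
estimate_beat <- function(kymo, min_prominence = 0.2, max_freq = NULL,
                          agree_tol_hz = 0.5, roi_id = "roi") {
  trace <- kymograph_trace(kymo)
  if (is.null(max_freq)) max_freq <- kymo$fps / 2
  pk <- peak_frequency(trace, kymo$fps, min_prominence, max_freq)
  sp <- spectral_frequency(trace, kymo$fps)
  disagree <- is.finite(pk$freq_hz) && is.finite(sp$freq_hz) &&
    abs(pk$freq_hz - sp$freq_hz) > agree_tol_hz
  tibble(roi_id = roi_id, freq_peaks = pk$freq_hz,
         freq_spectral = sp$freq_hz, n_peaks = pk$n_peaks,
         low_snr = pk$low_snr || isTRUE(sp$low_snr),
         disagreement = disagree)
}

#' Hierarchical summary of beat-frequency estimates
#'
#' Aggregates ROI-level frequency estimates bottom-up: ROIs are averaged
#' within each image, images within each animal, and the animal means are
#' reported with their standard error, matching how beat-frequency
#' experiments are reported (several ROIs per area, several images per
#' animal).
#'
#' @param estimates Tibble with columns `animal_id`, `image_id`, `freq_hz`
#'   (one row per ROI). Missing grouping columns default to a single group.
#' @return List with `per_animal` (tibble `animal_id`, `mean_freq_hz`,
#'   `n_images`, `n_rois`), `grand_mean_hz`, `sem_hz`, `n_animals`.
#' @export
summarize_recording <- function(estimates) {
  stopifnot(is.data.frame(estimates), "freq_hz" %in% names(estimates))
  if (nrow(estimates) == 0) abort("No estimates to summarise.")
  if (!"image_id" %in% names(estimates)) estimates$image_id <- "image"
  if (!"animal_id" %in% names(estimates)) estimates$animal_id <- "animal"
  per_image <- estimates |>
    dplyr::group_by(.data$animal_id, .data$image_id) |>
    dplyr::summarise(image_mean = mean(.data$freq_hz), n_rois = dplyr::n(),
                     .groups = "drop")
  per_animal <- per_image |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(mean_freq_hz = mean(.data$image_mean),
                     n_images = dplyr::n(), n_rois = sum(.data$n_rois),
                     .groups = "drop")
  list(per_animal = per_animal,
       grand_mean_hz = mean(per_animal$mean_freq_hz),
       sem_hz = if (nrow(per_animal) > 1) {
         sd(per_animal$mean_freq_hz) / sqrt(nrow(per_animal))
       } else {
         0
       },
       n_animals = nrow(per_animal))
}
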