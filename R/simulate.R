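# Synthetic-data generators. Each returns the simulated input plus a
# `ground_truth` record (kind, parameters, per-item truths) so downstream
# estimators can be validated end to end. Regeneration with the same
# parameters and seed is bit-for-bit identical.

.with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    abort("`seed` is mandatory and must be a single integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

.ground_truth <- function(kind, parameters, truths) {
  structure(list(kind = kind, parameters = parameters, truths = truths),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth: %s>\n", x$kind))
  cat("  parameters:",
      paste(names(x$parameters),
            vapply(x$parameters, function(p) paste(format(p), collapse = ","),
                   character(1)),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Apical-surface map (translational-polarity substrate)

#' Simulate an ependymal apical-surface map
#'
#' Builds a tessellated field of cells as a jitter-perturbed rectangular grid
#' (interior grid vertices displaced, boundary fixed, so the cell polygons
#' tile the region exactly) and places each cell's basal-body patch centroid
#' at a fraction of the effective cell radius `sqrt(area/pi)` away from the
#' polygon centroid, along a direction drawn from von Mises(`mu`, `kappa`).
#' Coordinates are image-convention pixels (origin top-left, y down); the
#' drawn angles are the angles [translational_vectors()] recovers.
#'
#' @param n_cells Number of cells (>= 1).
#' @param mean_area Mean apical area in square micrometres.
#' @param area_cv Approximate coefficient of variation of cell areas,
#'   controlled through the vertex jitter amplitude.
#' @param mu Mean displacement direction, degrees.
#' @param kappa von Mises concentration of displacement directions (>= 0).
#' @param displacement_frac Basal-body displacement as a fraction of the
#'   cell radius, in `[0, 1)`; 0 leaves every centroid on the cell centre.
#' @param pixel_size Pixel calibration, micrometres per pixel (> 0).
#' @param seed Integer seed (mandatory).
#' @param image_id Identifier stored on the map.
#' @return A list with `map` (an `apical_map`: tibble of cells with a
#'   polygon list-column plus `pixel_size`) and `truth` (a `ground_truth`
#'   recording each drawn displacement angle).
#' @export
sim_apical_map <- function(n_cells, mean_area = 120, area_cv = 0.15,
                           mu = 0, kappa = 2, displacement_frac = 0.4,
                           pixel_size = 0.2, seed, image_id = "sim") {
  if (n_cells < 1) abort("`n_cells` must be >= 1.")
  if (mean_area <= 0 || pixel_size <= 0) {
    abort("`mean_area` and `pixel_size` must be positive.")
  }
  if (kappa < 0) abort("`kappa` must be >= 0.")
  if (displacement_frac < 0 || displacement_frac >= 1) {
    abort("`displacement_frac` must lie in [0, 1).")
  }
  .with_seed(seed, {
    ncg <- ceiling(sqrt(n_cells))
    nrg <- ceiling(n_cells / ncg)
    L <- sqrt(mean_area) / pixel_size  # grid pitch, px
    # vertex jitter giving roughly the requested area CV (first-order
    # shoelace sensitivity); capped so quads stay simple polygons
    jit <- min(0.3, area_cv * sqrt(3 / 2)) * L
    vx <- outer(rep(1, nrg + 1), 0:ncg) * L
    vy <- outer(0:nrg, rep(1, ncg + 1)) * L
    if (nrg > 1 && ncg > 1) {
      ii <- 2:nrg; jj <- 2:ncg
      vx[ii, jj] <- vx[ii, jj] + runif(length(ii) * length(jj), -jit, jit)
      vy[ii, jj] <- vy[ii, jj] + runif(length(ii) * length(jj), -jit, jit)
    }
    idx <- seq_len(n_cells)
    ci <- ((idx - 1) %/% ncg) + 1
    cj <- ((idx - 1) %% ncg) + 1
    polys <- purrr::map2(ci, cj, function(i, j) {
      cbind(x = c(vx[i, j], vx[i, j + 1], vx[i + 1, j + 1], vx[i + 1, j]),
            y = c(vy[i, j], vy[i, j + 1], vy[i + 1, j + 1], vy[i + 1, j]))
    })
    theta <- rvonmises(n_cells, mu = mu, kappa = kappa)
    cen <- t(vapply(polys, polygon_centroid, numeric(2)))
    area_px <- vapply(polys, .polygon_area_px, numeric(1))
    r_px <- sqrt(area_px / pi)
    # y-down image coordinates: a reported (math-convention) angle theta
    # corresponds to an offset (cos, -sin)
    bb_x <- cen[, 1] + displacement_frac * r_px * cos(deg2rad(theta))
    bb_y <- cen[, 2] - displacement_frac * r_px * sin(deg2rad(theta))
    cells <- tibble(
      cell_id = sprintf("c%04d", idx),
      polygon = polys, bb_x = bb_x, bb_y = bb_y
    )
    map <- new_apical_map(cells, pixel_size = pixel_size, image_id = image_id)
    truth <- .ground_truth(
      "polarity_map",
      list(n_cells = n_cells, mean_area = mean_area, area_cv = area_cv,
           mu = mu, kappa = kappa, displacement_frac = displacement_frac,
           pixel_size = pixel_size, seed = seed),
      list(angle_deg = theta)
    )
    list(map = map, truth = truth)
  })
}

#' Construct an apical map from a cell table
#'
#' @param cells Tibble with columns `cell_id`, `polygon` (list of n x 2
#'   vertex matrices, pixel coordinates), `bb_x`, `bb_y` (basal-body patch
#'   centroid, px; `NA` if absent).
#' @param pixel_size Micrometres per pixel (> 0).
#' @param image_id Identifier.
#' @export
new_apical_map <- function(cells, pixel_size, image_id = "image") {
  stopifnot(is.data.frame(cells),
            all(c("cell_id", "polygon", "bb_x", "bb_y") %in% names(cells)))
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    abort("`pixel_size` must be a positive number (micrometres per pixel).")
  }
  if (anyDuplicated(cells$cell_id)) abort("`cell_id` values must be unique.")
  bad <- which(vapply(cells$polygon,
                      function(p) !is.matrix(p) || nrow(p) < 3, logical(1)))
  if (length(bad)) {
    abort(sprintf("Polygons must have >= 3 vertices (offending cells: %s).",
                  paste(cells$cell_id[bad], collapse = ", ")))
  }
  structure(list(cells = as_tibble(cells), pixel_size = pixel_size,
                 image_id = image_id),
            class = "apical_map")
}

#' @export
print.apical_map <- function(x, ...) {
  cat(sprintf("<apical_map '%s': %d cells, pixel_size = %g um/px>\n",
              x$image_id, nrow(x$cells), x$pixel_size))
  print(x$cells, n = 5)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Cilium orientation fields (rotational-polarity substrate)

#' Simulate per-image cilium orientation fields
#'
#' Draws, for each image, the central-pair orientation of its cilia from a
#' von Mises distribution with an image-specific mean direction (uniform
#' over the circle, emulating unrelated section orientations) and shared
#' concentration `kappa`. Per-image sub-seeds are derived deterministically
#' from `seed`.
#'
#' @param n_images Number of images (>= 1).
#' @param cilia_per_image Cilia per image (>= 1).
#' @param mu Optional common mean direction in degrees; if `NULL` (default)
#'   each image gets its own uniform-random mean, which is what deviation-
#'   from-image-mean analyses assume.
#' @param kappa von Mises concentration (>= 0).
#' @param seed Integer seed (mandatory).
#' @return List with `angles` (tibble `image_id`, `angle_deg`, with a
#'   `periodicity` attribute `"directional_360"`) and `truth`.
#' @export
sim_orientation_field <- function(n_images = 10, cilia_per_image = 12,
                                  mu = NULL, kappa = 4, seed) {
  if (n_images < 1 || cilia_per_image < 1) abort("Counts must be >= 1.")
  if (kappa < 0) abort("`kappa` must be >= 0.")
  .with_seed(seed, {
    image_mu <- if (is.null(mu)) runif(n_images, 0, 360) else rep(mu, n_images)
    sub_seed <- (as.integer(seed) + 1000003 * seq_len(n_images)) %% 2147483647L
    angles <- purrr::map_dfr(seq_len(n_images), function(k) {
      .with_seed(sub_seed[k], {
        tibble(image_id = sprintf("img%03d", k),
               angle_deg = rvonmises(cilia_per_image, mu = image_mu[k],
                                     kappa = kappa))
      })
    })
    attr(angles, "periodicity") <- "directional_360"
    truth <- .ground_truth(
      "orientation_field",
      list(n_images = n_images, cilia_per_image = cilia_per_image,
           mu = mu %||% NA_real_, kappa = kappa, seed = seed),
      list(image_mu_deg = image_mu)
    )
    list(angles = angles, truth = truth)
  })
}

# ---------------------------------------------------------------------------
# Beat recordings (kymograph substrate)

#' Simulate a time-lapse recording of beating cilia
#'
#' Produces a `T x H x W` image stack in which a horizontal band of pixels
#' (the recorded ROI) oscillates sinusoidally at `freq_hz` with additive
#' Gaussian noise, over a constant background. The true ROI line and clean
#' trace are recorded in the ground truth.
#'
#' @param freq_hz Beat frequency, Hz; must satisfy `freq_hz < fps/2`.
#' @param fps Frame rate, Hz (default 60, typical of resonance-scanned
#'   confocal recordings).
#' @param duration_s Recording length in seconds (> 0).
#' @param line_len ROI line length in pixels.
#' @param amplitude Oscillation amplitude (arbitrary intensity units).
#' @param noise_sd Gaussian noise standard deviation (same units).
#' @param height Frame height in pixels.
#' @param seed Integer seed (mandatory).
#' @return List with `stack` (an `image_stack`) and `truth` (includes the
#'   ROI as `c(x0, y0, x1, y1)` in 1-based pixel coordinates and the clean
#'   trace).
#' @export
sim_beat_recording <- function(freq_hz, fps = 60, duration_s = 2,
                               line_len = 40, amplitude = 1, noise_sd = 0.1,
                               height = 16, seed) {
  if (duration_s <= 0) abort("`duration_s` must be positive.")
  if (freq_hz <= 0) abort("`freq_hz` must be positive.")
  if (freq_hz >= fps / 2) {
    abort(sprintf(
      "`freq_hz` = %g violates the Nyquist limit fps/2 = %g: the beat would alias.",
      freq_hz, fps / 2))
  }
  .with_seed(seed, {
    T_ <- round(duration_s * fps)
    W <- line_len + 8L
    H <- as.integer(height)
    t_s <- (seq_len(T_) - 1) / fps
    clean <- amplitude * sin(2 * pi * freq_hz * t_s)
    y0 <- H %/% 2
    x_roi <- seq(5L, 5L + line_len - 1L)
    frames <- array(rnorm(T_ * H * W, mean = 0.5, sd = noise_sd),
                    dim = c(T_, H, W))
    for (dy in -1:1) {
      frames[, y0 + dy, x_roi] <- frames[, y0 + dy, x_roi] + clean
    }
    stack <- new_image_stack(frames, fps = fps, pixel_size = 0.2)
    truth <- .ground_truth(
      "beat_recording",
      list(freq_hz = freq_hz, fps = fps, duration_s = duration_s,
           line_len = line_len, amplitude = amplitude, noise_sd = noise_sd,
           seed = seed),
      list(roi = c(x0 = x_roi[1], y0 = y0, x1 = x_roi[length(x_roi)], y1 = y0),
           clean_trace = clean)
    )
    list(stack = stack, truth = truth)
  })
}

#' Construct an image stack
#'
#' @param frames Numeric `T x H x W` array of finite intensities.
#' @param fps Frame rate in Hz (> 0).
#' @param pixel_size Micrometres per pixel.
#' @export
new_image_stack <- function(frames, fps, pixel_size = NA_real_) {
  if (!is.array(frames) || length(dim(frames)) != 3 || dim(frames)[1] < 2) {
    abort("`frames` must be a T x H x W array with T >= 2.")
  }
  if (!all(is.finite(frames))) abort("Stack intensities must be finite.")
  if (!is.numeric(fps) || length(fps) != 1 || !is.finite(fps) || fps <= 0) {
    abort("`fps` must be a single positive number.")
  }
  structure(list(frames = frames, fps = fps, pixel_size = pixel_size),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack: %d frames of %d x %d px at %g fps>\n",
              d[1], d[2], d[3], x$fps))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Expression-profile sets (signature-similarity substrate)

#' Simulate population expression profiles with block signature structure
#'
#' Each signature block owns a disjoint set of `block_size` genes; every
#' population assigned to a block has differential-expression value `effect`
#' on that block's genes and 0 elsewhere, plus Gaussian noise everywhere.
#' Populations sharing a block therefore have high absolute-cosine
#' correlation; populations in different blocks are near-orthogonal.
#'
#' @param blocks Named list mapping block name to a character vector of
#'   population labels; a population may appear in exactly one block
#'   (overlap is a misspecification and raises an error).
#' @param n_genes Total number of genes (>= number of blocks x
#'   `block_size`).
#' @param block_size Genes per signature block.
#' @param effect Signature magnitude (differential-expression units, e.g.
#'   log2 fold change).
#' @param noise_sd Gaussian noise standard deviation, same units.
#' @param seed Integer seed (mandatory).
#' @return List with `profiles` (tibble: `gene` column then one numeric
#'   column per population) and `truth` (block assignment and the pairs
#'   designed to be similar).
#' @export
sim_population_profiles <- function(blocks, n_genes = 500, block_size = 50,
                                    effect = 1, noise_sd = 0.2, seed) {
  if (!is.list(blocks) || is.null(names(blocks)) || any(names(blocks) == "")) {
    abort("`blocks` must be a named list of population-label vectors.")
  }
  pops <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(pops)) {
    abort(sprintf(
      "Overlapping block design: population(s) %s assigned to more than one block.",
      paste(unique(pops[duplicated(pops)]), collapse = ", ")))
  }
  if (effect <= 0) abort("`effect` must be positive.")
  n_blocks <- length(blocks)
  if (n_genes < n_blocks * block_size) {
    abort("`n_genes` must be at least n_blocks * block_size.")
  }
  .with_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    block_genes <- split(seq_len(n_blocks * block_size),
                         rep(seq_len(n_blocks), each = block_size))
    names(block_genes) <- names(blocks)
    vals <- matrix(rnorm(n_genes * length(pops), sd = noise_sd),
                   nrow = n_genes, ncol = length(pops),
                   dimnames = list(genes, pops))
    for (b in names(blocks)) {
      vals[block_genes[[b]], blocks[[b]]] <-
        vals[block_genes[[b]], blocks[[b]], drop = FALSE] + effect
    }
    profiles <- dplyr::bind_cols(tibble(gene = genes), as_tibble(vals))
    pair_block <- function(b) {
      ps <- blocks[[b]]
      if (length(ps) < 2) return(NULL)
      cmb <- utils::combn(sort(ps), 2)
      tibble(pop1 = cmb[1, ], pop2 = cmb[2, ], block = b)
    }
    shared_pairs <- purrr::map_dfr(names(blocks), pair_block)
    truth <- .ground_truth(
      "profile_set",
      list(n_genes = n_genes, block_size = block_size, effect = effect,
           noise_sd = noise_sd, seed = seed),
      list(blocks = blocks, block_genes = block_genes,
           shared_pairs = shared_pairs)
    )
    list(profiles = profiles, truth = truth)
  })
}
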