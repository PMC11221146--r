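test_that("polygon centroid: exact anchors and Monte-Carlo oracle", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(unname(polygon_centroid(sq)), c(0.5, 0.5))
  tri <- cbind(c(0, 3, 0), c(0, 0, 3))
  expect_equal(unname(polygon_centroid(tri)), c(1, 1))

  set.seed(13)
  # random convex polygon: hull of random points
  pts <- matrix(runif(20), ncol = 2)
  hull <- pts[grDevices::chull(pts), ]
  mc <- centroid_oracle(hull, n = 3e5)
  expect_equal(unname(polygon_centroid(hull)), mc, tolerance = 1e-2)

  expect_error(polygon_centroid(cbind(c(0, 1, 2), c(0, 1, 2))), "zero area")
})

test_that("apical area: calibration scaling and rasterisation oracle", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(apical_area(sq, pixel_size = 1), 1.0)
  tri <- cbind(c(0, 2, 0), c(0, 0, 2))
  expect_equal(apical_area(tri, pixel_size = 0.5), 0.5)

  set.seed(14)
  pts <- matrix(runif(16), ncol = 2)
  hull <- pts[grDevices::chull(pts), ]
  expect_equal(apical_area(hull, 1), area_oracle(hull, h = 0.005),
               tolerance = 0.01)

  bowtie <- cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))
  expect_error(apical_area(bowtie), "Self-intersecting")
})

test_that("tessellated map conserves total area", {
  s <- sim_apical_map(100, mean_area = 120, pixel_size = 0.2, seed = 5)
  areas <- vapply(s$map$cells$polygon, apical_area, numeric(1),
                  pixel_size = 0.2)
  # 10 x 10 perturbed grid tiles a rectangle of exactly 100 mean areas
  expect_equal(sum(areas), 100 * 120, tolerance = 1e-6)
})

test_that("vector angles follow the documented image-coordinate convention", {
  cells <- tibble::tibble(
    cell_id = c("a", "b", "c"),
    polygon = list(cbind(c(-1, 1, 1, -1), c(-1, -1, 1, 1)),
                   cbind(c(-1, 1, 1, -1), c(-1, -1, 1, 1)),
                   cbind(c(-1, 1, 1, -1), c(-1, -1, 1, 1))),
    bb_x = c(1, 0, 0), bb_y = c(0, 1, 0)
  )
  map <- new_apical_map(cells, pixel_size = 0.5)
  v <- translational_vectors(map, epsilon = 0.1)
  # centre (0,0); bb (1,0) -> 0 deg; bb (0,1) with y down -> 270 deg
  expect_equal(v$angle_deg[1], 0)
  expect_equal(v$magnitude_um[1], 0.5)
  expect_equal(v$angle_deg[2], 270)
  expect_true(v$degenerate[3])
})

test_that("cells without a basal-body centroid are skipped and counted", {
  cells <- tibble::tibble(
    cell_id = c("a", "b"),
    polygon = list(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
                   cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))),
    bb_x = c(0.9, NA), bb_y = c(0.5, NA)
  )
  v <- translational_vectors(new_apical_map(cells, pixel_size = 1))
  expect_equal(nrow(v), 1)
  expect_equal(attr(v, "n_missing_bb"), 1)
})

test_that("deviation summary: equal angles, uniform limit, and exclusions", {
  mk <- function(angles) {
    tibble::tibble(cell_id = as.character(seq_along(angles)),
                   image_id = "i1", angle_deg = angles,
                   magnitude_um = 1, degenerate = FALSE)
  }
  s <- suppressWarnings(summarize_translational(mk(rep(30, 5))))
  expect_equal(s$fraction_within, 1.0)
  expect_lt(max(abs(s$deviations$deviation_deg)), 1e-9)

  set.seed(15)
  su <- summarize_translational(mk(runif(20000, 0, 360)))
  # three-sigma binomial band around the uniform expectation 45/180
  expect_lt(abs(su$fraction_within - 0.25), 0.01)

  vecs <- mk(c(0, 10, 20))
  vecs$degenerate <- c(FALSE, FALSE, TRUE)
  sd3 <- suppressWarnings(summarize_translational(vecs))
  expect_equal(sd3$n_cells, 2)
  expect_equal(sd3$n_degenerate, 1)
  vecs$degenerate <- TRUE
  expect_error(suppressWarnings(summarize_translational(vecs)), "degenerate")
})

test_that("rotating all basal bodies about cell centres leaves the fraction unchanged", {
  s <- sim_apical_map(200, kappa = 3, seed = 16)
  v0 <- translational_vectors(s$map)
  f0 <- summarize_translational(v0)$fraction_within
  # rotate every vector by a common angle by editing the map's bb positions
  rot <- 73
  cen <- t(vapply(s$map$cells$polygon, polygon_centroid, numeric(2)))
  dx <- s$map$cells$bb_x - cen[, 1]; dy <- s$map$cells$bb_y - cen[, 2]
  cs <- cos(rot * pi / 180); sn <- sin(rot * pi / 180)
  cells <- s$map$cells
  cells$bb_x <- cen[, 1] + cs * dx - sn * dy
  cells$bb_y <- cen[, 2] + sn * dx + cs * dy
  v1 <- translational_vectors(new_apical_map(cells, s$map$pixel_size))
  f1 <- summarize_translational(v1)$fraction_within
  expect_equal(f1, f0, tolerance = 1e-12)
})

test_that("fraction within 45 deg is monotone in concentration", {
  kappas <- c(0, 1, 2, 4, 8)
  mean_frac <- vapply(kappas, function(k) {
    mean(vapply(1:50, function(s) {
      sim <- sim_apical_map(150, kappa = k, seed = 1000 * k + s)
      summarize_translational(translational_vectors(sim$map))$fraction_within
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_frac) > 0))
})

test_that("a low cell count triggers the quantification-practice warning", {
  s <- sim_apical_map(20, kappa = 2, seed = 17)
  expect_warning(summarize_translational(translational_vectors(s$map)),
                 "fewer than 30")
})
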