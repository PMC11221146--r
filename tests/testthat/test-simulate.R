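test_that("generators are bit-for-bit deterministic given parameters + seed", {
  m1 <- sim_apical_map(50, kappa = 3, seed = 42)
  m2 <- sim_apical_map(50, kappa = 3, seed = 42)
  expect_identical(m1, m2)

  o1 <- sim_orientation_field(4, 20, kappa = 2, seed = 9)
  o2 <- sim_orientation_field(4, 20, kappa = 2, seed = 9)
  expect_identical(o1, o2)

  b1 <- sim_beat_recording(8, seed = 5)
  b2 <- sim_beat_recording(8, seed = 5)
  expect_identical(b1, b2)

  p1 <- sim_population_profiles(list(a = c("x", "y")), n_genes = 50,
                                block_size = 10, seed = 3)
  p2 <- sim_population_profiles(list(a = c("x", "y")), n_genes = 50,
                                block_size = 10, seed = 3)
  expect_identical(p1, p2)
})

test_that("apical map: degenerate concentration collapses all angles onto mu", {
  s <- sim_apical_map(40, mu = 0, kappa = 1e6, seed = 1)
  v <- translational_vectors(s$map)
  expect_true(all(abs(wrap_difference(v$angle_deg, 0)) < 0.5))
})

test_that("apical map: zero displacement gives degenerate vectors", {
  s <- sim_apical_map(40, displacement_frac = 0, seed = 2)
  v <- translational_vectors(s$map)
  expect_true(all(v$degenerate))
  expect_true(all(v$magnitude_um < 1e-9))
})

test_that("apical map: recovered circular mean falls in the Monte-Carlo CI of mu", {
  s <- sim_apical_map(100, mu = 40, kappa = 2, seed = 7)
  v <- translational_vectors(s$map)
  got_dev <- abs(wrap_difference(circ_mean_resultant(v$angle_deg)$mean_deg, 40))
  # 95% CI half-width of the circular mean from an independent sampler
  set.seed(70)
  devs <- replicate(400, {
    abs(wrap_difference(
      circ_mean_resultant(rvm_oracle(100, 40, 2))$mean_deg, 40))
  })
  expect_lte(got_dev, stats::quantile(devs, 0.95))
})

test_that("apical map: invalid parameters are rejected", {
  expect_error(sim_apical_map(10, mean_area = -5, seed = 1), "positive")
  expect_error(sim_apical_map(10, pixel_size = 0, seed = 1), "positive")
  expect_error(sim_apical_map(10, displacement_frac = 1, seed = 1), "\\[0, 1\\)")
  expect_error(sim_apical_map(10, kappa = 2), "seed")
})

test_that("orientation field: concentration limits behave analytically", {
  s <- sim_orientation_field(10, 50, kappa = 1e6, seed = 3)
  dev <- cilium_deviations(s$angles)$deviation_deg
  expect_lt(mean(dev), 0.2)

  u <- sim_orientation_field(10, 200, kappa = 0, seed = 4)
  devu <- cilium_deviations(u$angles)$deviation_deg
  # uniform wrapped deviations: mean 90, spread over [0, 180]
  expect_equal(mean(devu), 90, tolerance = 0.05 * 90)
  expect_gt(max(devu), 150)
})

test_that("beat recording: construction and Nyquist guard", {
  s <- sim_beat_recording(10, fps = 60, duration_s = 2, noise_sd = 0, seed = 1)
  roi <- s$truth$truths$roi
  trace <- s$truth$truths$clean_trace
  expect_length(trace, 120)
  # exactly 20 maxima in the clean trace
  pf <- peak_frequency(trace, 60)
  expect_equal(pf$n_peaks, 20L)
  expect_error(sim_beat_recording(30, fps = 60, seed = 1), "Nyquist")
  expect_error(sim_beat_recording(45, fps = 60, seed = 1), "Nyquist")
})

test_that("beat recording: spectral estimator recovers the truth under noise", {
  errs <- vapply(1:20, function(i) {
    s <- sim_beat_recording(10, fps = 60, duration_s = 2, amplitude = 1,
                            noise_sd = 0.2, seed = i)
    kym <- extract_kymograph(s$stack, s$truth$truths$roi)
    abs(spectral_frequency(kymograph_trace(kym), 60)$freq_hz - 10)
  }, numeric(1))
  expect_true(all(errs <= 0.5))
})

test_that("profile set: block design controls the correlation structure", {
  # identical blocks, no noise -> C = 1
  p <- sim_population_profiles(list(b = c("x", "y")), n_genes = 100,
                               block_size = 20, effect = 1, noise_sd = 0,
                               seed = 1)
  m <- as.matrix(p$profiles[-1])
  expect_equal(cosine_correlation(m[, "x"], m[, "y"]), 1)

  # disjoint blocks, no noise -> orthogonal vectors, C = 0
  q <- sim_population_profiles(list(b1 = "x", b2 = "y"), n_genes = 100,
                               block_size = 20, effect = 1, noise_sd = 0,
                               seed = 2)
  mq <- as.matrix(q$profiles[-1])
  expect_equal(cosine_correlation(mq[, "x"], mq[, "y"]), 0)

  # overlapping assignment is a misspecification
  expect_error(
    sim_population_profiles(list(b1 = c("x", "y"), b2 = c("y", "z")),
                            n_genes = 100, block_size = 10, seed = 1),
    "Overlapping")
  expect_error(
    sim_population_profiles(list(b1 = "x", b2 = "y"), n_genes = 15,
                            block_size = 10, seed = 1),
    "n_genes")
})
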