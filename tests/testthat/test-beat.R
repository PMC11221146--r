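test_that("kymograph extraction reproduces whole-frame time signals", {
  # every pixel equals f(t): each kymograph row is f(t)
  T_ <- 30; H <- 8; W <- 20
  f_t <- sin(2 * pi * 3 * (0:(T_ - 1)) / 60)
  frames <- array(rep(f_t, H * W), dim = c(T_, H, W))
  stack <- new_image_stack(frames, fps = 60)
  kym <- extract_kymograph(stack, c(3, 4, 15, 4))
  expect_equal(dim(kym$values)[2], T_)
  for (r in c(1, nrow(kym$values))) {
    expect_equal(kym$values[r, ], f_t, tolerance = 1e-12)
  }
  # constant stack -> constant kymograph
  stack2 <- new_image_stack(array(0.7, dim = c(10, 8, 20)), fps = 60)
  kym2 <- extract_kymograph(stack2, c(3, 4, 15, 4))
  expect_equal(max(abs(kym2$values - 0.7)), 0, tolerance = 1e-12)
  expect_error(extract_kymograph(stack, c(0, 4, 15, 4)), "inside")
})

test_that("kymograph of a synthetic recording matches the generator's trace", {
  s <- sim_beat_recording(8, fps = 60, duration_s = 2, noise_sd = 0.05,
                          seed = 31)
  kym <- extract_kymograph(s$stack, s$truth$truths$roi)
  trace <- kymograph_trace(kym)
  clean <- s$truth$truths$clean_trace + 0.5
  # band-averaged noise at sd 0.05 leaves residuals well under the amplitude
  expect_lt(max(abs(trace - clean)), 0.2)
  expect_gt(stats::cor(trace, clean), 0.99)
})

test_that("peak counting: construction anchors and flat-trace flag", {
  t_s <- (0:119) / 60
  pf <- peak_frequency(sin(2 * pi * 10 * t_s), fps = 60)
  expect_equal(pf$n_peaks, 20L)
  expect_equal(pf$freq_hz, 10)

  flat <- peak_frequency(rep(1, 50), fps = 60)
  expect_equal(flat$freq_hz, 0)
  expect_true(flat$low_snr)
})

test_that("spectral estimator: anchors and dominant-component selection", {
  t_s <- (0:119) / 60
  expect_equal(spectral_frequency(sin(2 * pi * 10 * t_s), 60)$freq_hz, 10)
  mix <- sin(2 * pi * 5 * t_s) + 0.3 * sin(2 * pi * 10 * t_s)
  expect_equal(spectral_frequency(mix, 60)$freq_hz, 5)
  expect_true(spectral_frequency(rep(2, 30), 60)$low_snr)
})

test_that("noisy sinusoids are recovered within half a hertz", {
  set.seed(32)
  errs <- vapply(1:20, function(i) {
    tr <- sin(2 * pi * 8 * (0:239) / 60) + rnorm(240, sd = 0.2)
    abs(peak_frequency(tr, 60)$freq_hz - 8)
  }, numeric(1))
  expect_true(all(errs <= 0.5))
})

test_that("estimates are invariant to affine intensity rescaling", {
  set.seed(33)
  tr <- sin(2 * pi * 7 * (0:179) / 60) + rnorm(180, sd = 0.1)
  tr2 <- 250 * tr + 1000
  expect_equal(peak_frequency(tr2, 60)$freq_hz, peak_frequency(tr, 60)$freq_hz)
  expect_equal(spectral_frequency(tr2, 60)$freq_hz,
               spectral_frequency(tr, 60)$freq_hz)
})

test_that("doubling the frame rate leaves the estimated frequency unchanged", {
  t1 <- sin(2 * pi * 6 * (0:119) / 60)
  t2 <- sin(2 * pi * 6 * (0:239) / 120)
  expect_equal(peak_frequency(t1, 60)$freq_hz, peak_frequency(t2, 120)$freq_hz)
  expect_equal(spectral_frequency(t1, 60)$freq_hz,
               spectral_frequency(t2, 120)$freq_hz)
})

test_that("estimate_beat flags disagreement between the two estimators", {
  s <- sim_beat_recording(9, fps = 60, duration_s = 2, noise_sd = 0.1,
                          seed = 34)
  est <- estimate_beat(extract_kymograph(s$stack, s$truth$truths$roi))
  expect_false(est$disagreement)
  expect_lt(abs(est$freq_peaks - est$freq_spectral), 0.5 + 1e-9)
})

test_that("hierarchical recording summary: ROI -> image -> animal", {
  ests <- tibble::tibble(
    animal_id = "m1", image_id = rep(c("i1", "i2"), c(3, 1)),
    freq_hz = c(6, 8, 10, 9)
  )
  sm <- summarize_recording(ests)
  expect_equal(sm$per_animal$mean_freq_hz, mean(c(8, 9)))  # image means 8, 9
  expect_equal(sm$n_animals, 1)

  same <- summarize_recording(tibble::tibble(freq_hz = rep(8, 5)))
  expect_equal(same$grand_mean_hz, 8)
  expect_equal(same$sem_hz, 0)
  expect_error(summarize_recording(tibble::tibble(freq_hz = numeric(0))),
               "No estimates")
})

test_that("a simulated animal's mean frequency is recovered", {
  set.seed(35)
  gms <- vapply(1:20, function(i) {
    ests <- purrr::map_dfr(1:5, function(img) {
      tibble::tibble(animal_id = "m1", image_id = paste0("i", img),
                     freq_hz = 9 + rnorm(4, sd = 0.4))
    })
    summarize_recording(ests)$per_animal$mean_freq_hz
  }, numeric(1))
  expect_true(all(abs(gms - 9) < 0.5))
  expect_lt(abs(mean(gms) - 9), 0.2)
})
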