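test_that("distance and cosine kernels: exact anchors", {
  expect_equal(euclidean_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(cosine_correlation(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_correlation(c(1, 1), c(-1, -1)), 1)
  expect_equal(cosine_correlation(c(1, 2, 2), c(2, 1, 2)), 8 / 9)
  expect_error(euclidean_distance(1:3, 1:4), "same positive length")
  expect_error(cosine_correlation(c(0, 0), c(1, 1)), "zero vector")
})

test_that("kernels agree exactly with element-by-element loop oracles", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(2:50, 1)
    v <- rnorm(n); w <- rnorm(n)
    expect_equal(euclidean_distance(v, w), euclid_oracle(v, w),
                 tolerance = 1e-14)
    expect_equal(cosine_correlation(v, w), cosine_oracle(v, w),
                 tolerance = 1e-14)
  }
})

test_that("cosine correlation is scale-invariant and permutation-stable", {
  set.seed(42)
  v <- rnorm(30); w <- rnorm(30)
  c0 <- cosine_correlation(v, w)
  for (ab in list(c(2, 5), c(-3, 0.1), c(-1, -1))) {
    expect_equal(cosine_correlation(ab[1] * v, ab[2] * w), c0,
                 tolerance = 1e-12)
  }
  perm <- sample(30)
  expect_equal(cosine_correlation(v[perm], w[perm]), c0, tolerance = 1e-12)
  expect_equal(euclidean_distance(v[perm], w[perm]), euclidean_distance(v, w),
               tolerance = 1e-12)
})

test_that("Euclidean distance satisfies the metric axioms on random triples", {
  set.seed(43)
  for (i in 1:1000) {
    v <- rnorm(10); w <- rnorm(10); u <- rnorm(10)
    dvw <- euclidean_distance(v, w)
    expect_gte(dvw, 0)
    expect_equal(dvw, euclidean_distance(w, v), tolerance = 1e-14)
    expect_lte(dvw, euclidean_distance(v, u) + euclidean_distance(u, w) + 1e-12)
  }
  z <- rnorm(5)
  expect_equal(euclidean_distance(z, z), 0)
})

test_that("gene alignment keeps the intersection and logs drops", {
  prof <- tibble::tibble(gene = c("g1", "g2", "g3"),
                         a = c(1, 2, 3), b = c(4, NA, 6))
  al <- suppressMessages(align_genes(prof))
  expect_equal(al$gene, c("g1", "g3"))
  expect_equal(attr(al, "n_dropped"), 1)

  full <- tibble::tibble(gene = c("g1", "g2"), a = 1:2, b = 3:4)
  expect_equal(align_genes(full), full, ignore_attr = TRUE)

  p <- sim_population_profiles(list(b1 = c("x", "y")), n_genes = 200,
                               block_size = 30, seed = 1)
  prof2 <- p$profiles
  prof2$x[1:80] <- NA  # known overlap of 120 genes
  expect_equal(nrow(suppressMessages(align_genes(prof2))), 120)

  none <- tibble::tibble(gene = "g1", a = NA_real_, b = 1)
  expect_error(align_genes(none), "No gene")
})

test_that("similarity matrices honour symmetry and diagonal contracts", {
  p <- sim_population_profiles(list(b1 = c("PAM", "CD11c"),
                                    b2 = c("DAM1", "DAM2")),
                               n_genes = 300, block_size = 40,
                               effect = 1, noise_sd = 0.2, seed = 44)
  r <- similarity_matrix(p$profiles)
  expect_equal(r$distance, t(r$distance))
  expect_equal(r$correlation, t(r$correlation))
  expect_equal(unname(diag(r$distance)), rep(0, 4))
  expect_equal(unname(diag(r$correlation)), rep(1, 4))
  expect_true(all(r$correlation >= 0 & r$correlation <= 1))
  # pairwise distances agree with stats::dist as an independent route
  m <- as.matrix(align_genes(p$profiles)[-1])
  D_ref <- as.matrix(stats::dist(t(m)))
  expect_equal(r$distance, D_ref[r$labels, r$labels], tolerance = 1e-12)
})

test_that("noise-free block designs give the designed 0/1 correlations", {
  p <- sim_population_profiles(list(b1 = c("x", "y"), b2 = c("u", "v")),
                               n_genes = 120, block_size = 30,
                               effect = 2, noise_sd = 0, seed = 45)
  r <- similarity_matrix(p$profiles)
  expect_equal(r$correlation["x", "y"], 1)
  expect_equal(r$correlation["u", "v"], 1)
  expect_equal(r$correlation["x", "u"], 0)
  expect_equal(r$distance["x", "y"], 0)
})

test_that("zero-vector populations are excluded with a warning", {
  prof <- tibble::tibble(gene = c("g1", "g2"),
                         a = c(1, 2), b = c(2, 1), z = c(0, 0))
  expect_warning(r <- similarity_matrix(prof), "zero-vector")
  expect_equal(sort(r$labels), c("a", "b"))
  expect_equal(r$dropped_populations, "z")
})

test_that("clustering puts designed block-mates next to each other", {
  blocks <- list(dev = c("PAM", "ATM", "CD11c"),
                 dis = c("DAM1", "DAM2", "MGnD"))
  ok <- vapply(1:30, function(i) {
    p <- sim_population_profiles(blocks, n_genes = 500, block_size = 50,
                                 effect = 1, noise_sd = 0.2, seed = 4500 + i)
    blocks_adjacent(similarity_matrix(p$profiles)$cluster_order, blocks)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
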