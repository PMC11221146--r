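# Independent oracles used to freeze expected values. Each deliberately
# takes a different computational route from the package implementation.

# von Mises sampler by numerical inversion of the CDF (independent of the
# package's Best-Fisher rejection sampler)
rvm_oracle <- function(n, mu_deg = 0, kappa = 1) {
  grid <- seq(-pi, pi, length.out = 8192)
  dens <- exp(kappa * (cos(grid) - 1))
  cdf <- cumsum(dens)
  cdf <- (cdf - cdf[1]) / (cdf[length(cdf)] - cdf[1])
  x <- stats::approx(cdf, grid, xout = runif(n), ties = "ordered")$y
  (x * 180 / pi + mu_deg) %% 360
}

# numerically integrated von Mises CDF on (-pi, pi], for KS checks
pvm_oracle <- function(q_deg, kappa) {
  grid <- seq(-pi, pi, length.out = 8192)
  dens <- exp(kappa * (cos(grid) - 1))
  cdf <- cumsum(dens)
  cdf <- (cdf - cdf[1]) / (cdf[length(cdf)] - cdf[1])
  stats::approx(grid, cdf, xout = q_deg * pi / 180, rule = 2)$y
}

# Watson U2 by direct empirical-CDF evaluation at the distinct combined
# values (loops + stats::ecdf; no shared code with the package's cumsum
# implementation)
u2_oracle <- function(a, b) {
  x <- sort(unique(c(a, b)))
  F1 <- stats::ecdf(a); F2 <- stats::ecdf(b)
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  d <- numeric(length(x)); w <- numeric(length(x))
  for (j in seq_along(x)) {
    d[j] <- F1(x[j]) - F2(x[j])
    w[j] <- sum(a == x[j]) + sum(b == x[j])
  }
  dbar <- sum(w * d) / N
  (n1 * n2 / N^2) * sum(w * (d - dbar)^2)
}

# even-odd ray-crossing point-in-polygon test
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly); inside <- FALSE; j <- n
  for (i in seq_len(n)) {
    if (((poly[i, 2] > py) != (poly[j, 2] > py)) &&
        (px < (poly[j, 1] - poly[i, 1]) * (py - poly[i, 2]) /
           (poly[j, 2] - poly[i, 2]) + poly[i, 1])) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

# Monte-Carlo centroid by rejection sampling inside the bounding box
centroid_oracle <- function(poly, n = 2e5) {
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  px <- runif(n, xr[1], xr[2]); py <- runif(n, yr[1], yr[2])
  keep <- mapply(point_in_polygon, px, py, MoreArgs = list(poly = poly))
  c(mean(px[keep]), mean(py[keep]))
}

# pixel-rasterisation area oracle
area_oracle <- function(poly, h = 0.01) {
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  gx <- seq(xr[1] + h / 2, xr[2], by = h)
  gy <- seq(yr[1] + h / 2, yr[2], by = h)
  g <- expand.grid(x = gx, y = gy)
  inside <- mapply(point_in_polygon, g$x, g$y, MoreArgs = list(poly = poly))
  sum(inside) * h^2
}

# element-by-element loop versions of the similarity kernels
euclid_oracle <- function(v, w) {
  s <- 0
  for (k in seq_along(v)) s <- s + (v[k] - w[k])^2
  sqrt(s)
}

cosine_oracle <- function(v, w) {
  dot <- 0; nv <- 0; nw <- 0
  for (k in seq_along(v)) {
    dot <- dot + v[k] * w[k]
    nv <- nv + v[k]^2
    nw <- nw + w[k]^2
  }
  abs(dot) / sqrt(nv * nw)
}

# check that every group of block-mates is contiguous in an ordering
blocks_adjacent <- function(order_labels, blocks) {
  all(vapply(blocks, function(pops) {
    pos <- match(pops, order_labels)
    max(pos) - min(pos) == length(pos) - 1
  }, logical(1)))
}
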