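# Circular-statistics kernel: means, wrapped differences, von Mises tools,
# and the Watson two-sample U2 homogeneity test.
#
# Convention: user-facing angles are degrees; directional data live on a
# 360-degree period, axial data (undirected lines, e.g. microtubule axes
# read without polarity) on a 180-degree period and are angle-doubled for
# all trigonometric statistics.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

.check_period <- function(period) {
  if (!(is.numeric(period) && length(period) == 1 && period %in% c(360, 180))) {
    abort("`period` must be 360 (directional) or 180 (axial).")
  }
  period
}

.check_angles <- function(angles, what = "angles") {
  if (length(angles) < 1 || !is.numeric(angles) || !all(is.finite(angles))) {
    abort(sprintf("`%s` must be a non-empty finite numeric vector.", what))
  }
  invisible(angles)
}

#' Circular mean direction and resultant length
#'
#' Computes the mean direction and mean resultant length \eqn{R} of a sample
#' of angles. Axial samples (`period = 180`) are angle-doubled before
#' averaging and the mean is halved afterwards, the standard treatment for
#' undirected orientation data.
#'
#' @param angles Numeric vector of angles in degrees.
#' @param period Angular period in degrees: 360 for directional data,
#'   180 for axial data.
#' @param undefined_tol Resultant length below which the mean direction is
#'   reported as `NA` (e.g. perfectly balanced or uniform samples).
#' @return A one-row tibble with columns `mean_deg` (in `[0, period)`, `NA`
#'   when undefined), `R` (in `[0, 1]`), `n`, and `undefined`.
#' @examples
#' circ_mean_resultant(c(0, 90))    # mean 45, R = cos(45 deg)
#' circ_mean_resultant(c(10, 350))  # mean 0
#' @export
circ_mean_resultant <- function(angles, period = 360, undefined_tol = 1e-8) {
  .check_angles(angles)
  .check_period(period)
  st <- .circ_stats(angles, period)
  undef <- st$R < undefined_tol
  tibble(
    mean_deg = if (undef) NA_real_ else st$mean_deg,
    R = st$R, n = length(angles), undefined = undef
  )
}

# internal scalar version (always returns the atan2 mean, even if R ~ 0)
.circ_stats <- function(angles, period = 360) {
  fold <- 360 / period
  th <- deg2rad(angles * fold)
  C <- mean(cos(th))
  S <- mean(sin(th))
  R <- sqrt(C^2 + S^2)
  mean_deg <- (rad2deg(atan2(S, C)) / fold) %% period
  if (period - mean_deg < 1e-9) mean_deg <- 0  # snap the wrap seam
  list(mean_deg = mean_deg, R = R)
}

#' Minimal signed angular difference
#'
#' Wrapped difference `a - b` mapped into `(-period/2, period/2]`.
#'
#' @inheritParams circ_mean_resultant
#' @param a,b Angles in degrees (vectorised, recycled).
#' @return Signed differences in degrees.
#' @examples
#' wrap_difference(350, 10)              # -20
#' wrap_difference(179, 1, period = 180) # -2
#' @export
wrap_difference <- function(a, b, period = 360) {
  .check_period(period)
  d <- (a - b) %% period
  ifelse(d > period / 2, d - period, d)
}

#' Absolute wrapped angular deviation
#'
#' Convenience wrapper: `abs(wrap_difference(a, b, period))`, in
#' `[0, period/2]`.
#' @inheritParams wrap_difference
#' @export
angular_deviation <- function(a, b, period = 360) {
  abs(wrap_difference(a, b, period))
}

# ---------------------------------------------------------------------------
# von Mises distribution

#' Sample from a von Mises distribution
#'
#' Best--Fisher rejection sampler. `kappa = 0` reduces to the uniform
#' distribution on the period. For axial data the doubled angles follow the
#' von Mises law and results are halved back onto `[0, 180)`.
#'
#' @param n Number of draws.
#' @param mu Mean direction in degrees.
#' @param kappa Concentration parameter (>= 0); larger is tighter.
#' @inheritParams circ_mean_resultant
#' @return Numeric vector of angles in `[0, period)` degrees.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1, period = 360) {
  .check_period(period)
  if (!is.numeric(kappa) || length(kappa) != 1 || !is.finite(kappa) || kappa < 0) {
    abort("`kappa` must be a single finite number >= 0.")
  }
  fold <- 360 / period
  if (kappa < 1e-12) {
    return(runif(n, 0, period))
  }
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(32L, ceiling((n - length(out)) * 1.5))
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    out <- c(out, sign(u3[ok] - 0.5) * acos(pmin(1, pmax(-1, f[ok]))))
  }
  th <- out[seq_len(n)]
  ((rad2deg(th) + mu * fold) %% 360) / fold
}

# A1(kappa) = I1(kappa)/I0(kappa), computed with scaled Bessel functions so
# it stays finite for very large kappa.
.vm_A1 <- function(kappa) {
  if (kappa == 0) return(0)
  if (kappa > 1e4) {
    # uniform asymptotic expansion; besselI loses precision up here
    return(1 - 1 / (2 * kappa) - 1 / (8 * kappa^2))
  }
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

#' Fit a von Mises distribution by maximum likelihood
#'
#' The mean direction is the circular mean; the concentration is obtained by
#' numerically inverting \eqn{A_1(\kappa) = I_1(\kappa)/I_0(\kappa) = R}.
#' Samples so concentrated that \eqn{R} exceeds \eqn{A_1(\kappa_{max})} get
#' `kappa = kappa_max` with `capped = TRUE`.
#'
#' @inheritParams circ_mean_resultant
#' @param kappa_max Cap on the fitted concentration.
#' @return One-row tibble: `mu_deg`, `kappa`, `R`, `n`, `capped`.
#' @export
vonmises_fit <- function(angles, period = 360, kappa_max = 1e6) {
  .check_angles(angles)
  .check_period(period)
  if (length(angles) < 10) {
    warn("von Mises fit on fewer than 10 angles is unreliable.")
  }
  st <- .circ_stats(angles, period)
  R <- st$R
  if (R <= 0) {
    kappa <- 0; capped <- FALSE
  } else if (R >= .vm_A1(kappa_max)) {
    kappa <- kappa_max; capped <- TRUE
  } else {
    kappa <- uniroot(function(k) .vm_A1(k) - R,
                     lower = 1e-12, upper = kappa_max, tol = 1e-10)$root
    capped <- FALSE
  }
  tibble(mu_deg = st$mean_deg, kappa = kappa, R = R, n = length(angles),
         capped = capped)
}

#' Expected absolute deviation from the mean under a von Mises law
#'
#' \eqn{E|\Delta|} where \eqn{\Delta} is the wrapped deviation of a von
#' Mises draw from its mean direction, in degrees. `kappa = 0` gives the
#' uniform value 90.
#' @param kappa Concentration parameter (>= 0).
#' @return Expected absolute deviation in degrees (directional period).
#' @export
vm_expected_absdev <- function(kappa) {
  stopifnot(is.numeric(kappa), length(kappa) == 1, kappa >= 0)
  if (kappa == 0) return(90)
  if (kappa > 1e4) {
    # half-normal limit: deviations ~ N(0, 1/kappa) folded at zero
    return(rad2deg(sqrt(2 / (pi * kappa))))
  }
  num <- integrate(function(x) x * exp(kappa * (cos(x) - 1)),
                   0, pi, rel.tol = 1e-10)$value
  rad2deg(num / (pi * besselI(kappa, 0, expon.scaled = TRUE)))
}

#' Probability that a von Mises deviation falls within a bound
#'
#' \eqn{P(|\Delta| \le b)} for the wrapped deviation from the mean
#' direction. `kappa = 0` gives `bound_deg / 180`.
#' @inheritParams vm_expected_absdev
#' @param bound_deg Bound in degrees, in `[0, 180]`.
#' @export
vm_prob_within <- function(kappa, bound_deg = 45) {
  stopifnot(kappa >= 0, bound_deg >= 0, bound_deg <= 180)
  if (kappa == 0) return(bound_deg / 180)
  if (kappa > 1e4) {
    # wrapped-normal limit with sd 1/sqrt(kappa)
    return(min(1, 2 * stats::pnorm(deg2rad(bound_deg) * sqrt(kappa)) - 1))
  }
  num <- integrate(function(x) exp(kappa * (cos(x) - 1)),
                   0, deg2rad(bound_deg), rel.tol = 1e-10)$value
  num / (pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Concentration giving a target expected absolute deviation
#'
#' Numerically inverts [vm_expected_absdev()].
#' @param target_deg Target expected absolute deviation, degrees in (0, 90).
#' @export
vm_kappa_for_absdev <- function(target_deg) {
  stopifnot(target_deg > 0, target_deg < 90)
  lk <- uniroot(function(lk) vm_expected_absdev(10^lk) - target_deg,
                lower = -6, upper = 6, tol = 1e-10)$root
  10^lk
}

# ---------------------------------------------------------------------------
# Watson two-sample U2

# Statistic on the combined ordered sample. Ties are handled by evaluating
# both empirical CDFs at the distinct combined values and weighting each by
# its multiplicity (mid-rank treatment):
#   U2 = n1 n2 / N^2 * sum_j t_j (d_j - dbar)^2,  dbar = sum_j t_j d_j / N
# which reduces to the classical per-point sum when all values are distinct.
.u2_stat <- function(lab1_sorted, ends, weights, n1, n2) {
  N <- n1 + n2
  cum1 <- cumsum(lab1_sorted)[ends]
  d <- cum1 / n1 - (ends - cum1) / n2
  dbar <- sum(weights * d) / N
  (n1 * n2 / N^2) * sum(weights * (d - dbar)^2)
}

# Asymptotic tail P(U2 > u) = 2 * sum_{m>=1} (-1)^(m-1) exp(-2 m^2 pi^2 u)
.u2_asymptotic_p <- function(u2, terms = 12) {
  m <- seq_len(terms)
  p <- 2 * sum((-1)^(m - 1) * exp(-2 * m^2 * pi^2 * u2))
  min(1, max(0, p))
}

#' Watson two-sample U2 homogeneity test for circular data
#'
#' Nonparametric test of whether two samples of angles come from the same
#' distribution on the circle, based on squared differences of the two
#' empirical CDFs over the combined ordered sample. The statistic is
#' origin-invariant. Significance is assessed by random relabelling
#' permutation, with p = (1 + #\{U2_perm >= U2_obs\}) / (1 + n_permutations)
#' so that p is never zero; the classical asymptotic tail probability is
#' reported as a secondary value.
#'
#' @param a,b Numeric vectors of angles in degrees (each of length >= 4).
#' @inheritParams circ_mean_resultant
#' @param n_permutations Number of random relabellings for the permutation
#'   null (default 9999).
#' @param seed Optional integer seed making the permutation p reproducible;
#'   the caller's RNG state is preserved.
#' @return An object of class `watson_u2`: list with `u2`, `p_permutation`,
#'   `p_asymptotic`, `n1`, `n2`, `n_permutations`, `seed`, `ties` (number of
#'   tied combined values), `period`. Has [tidy()] and [glance()] methods.
#' @examples
#' x <- rvonmises(40, mu = 0, kappa = 2)
#' y <- rvonmises(40, mu = 90, kappa = 2)
#' watson_u2(x, y, n_permutations = 199, seed = 1)
#' @export
watson_u2 <- function(a, b, period = 360, n_permutations = 9999, seed = NULL) {
  .check_angles(a, "a"); .check_angles(b, "b")
  .check_period(period)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 4 || n2 < 4) abort("Each sample needs at least 4 angles.")
  if (n_permutations < 1) abort("`n_permutations` must be >= 1.")

  x <- c(a %% period, b %% period)
  N <- n1 + n2
  ord <- order(x)
  xs <- x[ord]
  lab <- c(rep(1, n1), rep(0, n2))[ord]
  r <- rle(xs)
  ends <- cumsum(r$lengths)
  w <- r$lengths
  n_ties <- N - length(w)

  u2 <- .u2_stat(lab, ends, w, n1, n2)

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  B <- as.integer(n_permutations)
  # permuting labels over the fixed sorted values; distinct-value structure
  # (ends, w) is invariant, so each permutation is one cumsum pass
  exceed <- 0L
  chunk <- 2000L
  done <- 0L
  while (done < B) {
    m <- min(chunk, B - done)
    L <- vapply(seq_len(m), function(i) sample(lab), numeric(N))
    cs <- apply(L, 2, cumsum)[ends, , drop = FALSE]
    d <- cs / n1 - (ends - cs) / n2
    dbar <- colSums(w * d) / N
    u2b <- (n1 * n2 / N^2) * colSums(w * sweep(d, 2, dbar)^2)
    exceed <- exceed + sum(u2b >= u2 - 1e-12)
    done <- done + m
  }
  p_perm <- (1 + exceed) / (1 + B)

  structure(
    list(u2 = u2, p_permutation = p_perm,
         p_asymptotic = .u2_asymptotic_p(u2),
         n1 = n1, n2 = n2, n_permutations = B,
         seed = seed, ties = n_ties, period = period),
    class = "watson_u2"
  )
}

#' @export
print.watson_u2 <- function(x, ...) {
  cat("Watson two-sample U2 test (permutation null)\n")
  cat(sprintf("  U2 = %.5f, p (permutation, B = %d) = %.4g\n",
              x$u2, x$n_permutations, x$p_permutation))
  cat(sprintf("  p (asymptotic) = %.4g; n1 = %d, n2 = %d; period = %d deg\n",
              x$p_asymptotic, x$n1, x$n2, x$period))
  if (x$ties > 0) cat(sprintf("  note: %d tied combined values (mid-rank handling)\n", x$ties))
  invisible(x)
}

#' @export
tidy.watson_u2 <- function(x, ...) {
  tibble(statistic = x$u2, p.value = x$p_permutation,
         p.asymptotic = x$p_asymptotic,
         method = "Watson two-sample U2 (permutation)")
}

#' @export
glance.watson_u2 <- function(x, ...) {
  tibble(statistic = x$u2, p.value = x$p_permutation,
         p.asymptotic = x$p_asymptotic, n1 = x$n1, n2 = x$n2,
         n.permutations = x$n_permutations, ties = x$ties,
         period = x$period)
}
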