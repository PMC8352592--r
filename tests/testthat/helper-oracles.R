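# Independent oracles used across the suite.  These deliberately use naive,
# brute-force formulations so they share no code path with the package.

# Population variance over the circular neighborhood of (i, j), by explicit
# double loop with bounds checking (and optional mask).
brute_variance_at <- function(img, radius, i, j, mask = NULL) {
  r <- floor(radius)
  nb <- c()
  for (di in -r:r) for (dj in -r:r) {
    if (di^2 + dj^2 > radius^2) next
    ii <- i + di; jj <- j + dj
    if (ii < 1 || ii > nrow(img) || jj < 1 || jj > ncol(img)) next
    if (!is.null(mask) && !mask[ii, jj]) next
    nb <- c(nb, img[ii, jj])
  }
  mean((nb - mean(nb))^2)
}

# Half-time by bisection on a dense bracket of the double-exponential model.
# The width floor respects double-precision spacing at the bracket magnitude,
# so very slow second components (half-times of ~1e5 s) cannot stall it.
bisect_t_half <- function(a, b, k1, k2, tol = 1e-12) {
  f <- function(t) a * (1 - exp(-k1 * t)) + b * (1 - exp(-k2 * t)) - (a + b) / 2
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  lo <- 0
  width <- max(tol, 8 * .Machine$double.eps * hi)
  while (hi - lo > width) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Two-compartment exchange by explicit fine-step (RK4 via deSolve) ODE
# integration of the mobile amounts; returns compartment mean intensities.
ode_flip_curves <- function(spec, times) {
  fi <- spec$immobile_fraction
  m0 <- c(m1 = (1 - fi) * spec$v1 * (1 - spec$bleach_fraction),
          m2 = (1 - fi) * spec$v2)
  rhs <- function(t, y, p) {
    flux <- spec$k_ex * (y["m2"] / spec$v2 - y["m1"] / spec$v1)
    list(c(flux, -flux))
  }
  sol <- deSolve::rk4(m0, times, rhs, parms = NULL)
  imm1 <- fi * spec$v1 * (1 - spec$bleach_fraction)
  imm2 <- fi * spec$v2
  data.frame(time = sol[, "time"],
             bleached = (sol[, "m1"] + imm1) / spec$v1,
             unbleached = (sol[, "m2"] + imm2) / spec$v2)
}

# Direct-summation Manders coefficients.
brute_manders <- function(a, b, tau_a, tau_b) {
  a <- as.numeric(a); b <- as.numeric(b)
  c(M1 = sum(a * (b > tau_b)) / sum(a),
    M2 = sum(b * (a > tau_a)) / sum(b))
}

# A noiseless normalized curve straight from the model (bypasses the
# normalization path).
model_curve <- function(a, b, k1, k2, times, n_pre = 1) {
  all_t <- c(-rev(seq_len(n_pre)) * (times[2] - times[1]), times)
  structure(data.frame(time = all_t,
                       value = c(rep(1, n_pre),
                                 a * (1 - exp(-k1 * times)) +
                                   b * (1 - exp(-k2 * times)))),
            n_pre = n_pre, class = c("normalized_curve", "data.frame"))
}
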