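#' Acquisition protocol for a simulated photobleaching experiment
#'
#' Frame counts, frame interval, bleach depth and curve-level noise for the
#' curve generators.  The defaults mirror a strip-FRAP protocol on cultured
#' cells (20 pre-bleach and 200 post-bleach frames at 70 ms); salivary-gland
#' band FRAP uses 10 pre-bleach and 250 post-bleach frames at 648 ms.
#'
#' @param n_pre Number of pre-bleach frames (>= 1).
#' @param n_post Number of post-bleach frames (>= 2).
#' @param interval Seconds between frames (> 0).
#' @param bleach_depth Fraction of the ROI signal destroyed by the bleach
#'   pulse, in (0, 1].
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   normalized fluorescence, in normalized units (>= 0).
#' @param seed Integer RNG seed; every generator call is a pure function of
#'   its spec and this seed.
#' @return An `acquisition_spec` list.
#' @examples
#' acquisition_spec(n_pre = 20, n_post = 200, interval = 0.070)
#' @export
acquisition_spec <- function(n_pre = 10, n_post = 250, interval = 0.648,
                             bleach_depth = 0.8, noise_sd = 0.02, seed = 1L) {
  check_that(is.numeric(n_pre) && n_pre >= 1, "n_pre", "must be >= 1")
  check_that(is.numeric(n_post) && n_post >= 2, "n_post", "must be >= 2")
  check_that(is.numeric(interval) && interval > 0, "interval", "must be > 0")
  check_that(is.numeric(bleach_depth) && bleach_depth > 0 && bleach_depth <= 1,
             "bleach_depth", "must be in (0, 1]")
  check_that(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd", "must be >= 0")
  check_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
             "seed", "must be a single finite integer")
  structure(list(n_pre = as.integer(n_pre), n_post = as.integer(n_post),
                 interval = interval, bleach_depth = bleach_depth,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "acquisition_spec")
}

#' Double-exponential recovery kinetics
#'
#' Parameters of the recovery model
#' \deqn{F(t) = a(1 - e^{-k_1 t}) + b(1 - e^{-k_2 t})}
#' with mobile fraction \eqn{a + b} and half-time \eqn{t_{1/2}} defined by
#' \eqn{F(t_{1/2}) = (a+b)/2}.
#'
#' @param a,b Amplitudes of the fast and slow components (>= 0, `a + b <= 1`).
#' @param k1,k2 Rates in 1/s with `k1 >= k2 >= 0`.
#' @return A `kinetic_params` list.
#' @export
kinetic_params <- function(a, b = 0, k1 = 1, k2 = 0) {
  check_that(is.numeric(a) && a >= 0, "a", "must be >= 0")
  check_that(is.numeric(b) && b >= 0, "b", "must be >= 0")
  check_that(a + b <= 1 + 1e-12, "a", "mobile fraction a + b must be <= 1")
  check_that(is.numeric(k1) && k1 >= 0, "k1", "must be >= 0")
  check_that(is.numeric(k2) && k2 >= 0, "k2", "must be >= 0")
  check_that(k1 >= k2, "k1", "must satisfy k1 >= k2")
  structure(list(a = a, b = b, k1 = k1, k2 = k2), class = "kinetic_params")
}

#' Evaluate the double-exponential recovery model
#'
#' @param t Time since bleach, seconds (vectorized).
#' @param params A [kinetic_params()] object.
#' @return Normalized recovery `F(t)`.
#' @export
frap_model <- function(t, params) {
  params$a * (1 - exp(-params$k1 * t)) + params$b * (1 - exp(-params$k2 * t))
}

#' Kinetic parameters with a prescribed half-time of recovery
#'
#' Convenience constructor for simulation studies: fixes the curve shape
#' (amplitude split and rate ratio) and solves for the fast rate so that the
#' model's half-time equals `t_half`.
#'
#' @param t_half Target half-time, seconds.
#' @param mobile Total mobile fraction `a + b`.
#' @param split Fraction of the mobile pool in the fast component.
#' @param rate_ratio `k1 / k2`.
#' @return A [kinetic_params()] object whose [solve_t_half()] equals `t_half`.
#' @export
kinetic_params_for_t_half <- function(t_half, mobile = 1, split = 0.75,
                                      rate_ratio = 10) {
  check_that(t_half > 0, "t_half", "must be > 0")
  check_that(mobile > 0 && mobile <= 1, "mobile", "must be in (0, 1]")
  a <- mobile * split
  b <- mobile * (1 - split)
  # model half-time scales as 1/k1 at fixed shape
  unit <- solve_t_half(list(a = a, b = b, k1 = 1, k2 = 1 / rate_ratio))
  k1 <- unit / t_half
  kinetic_params(a = a, b = b, k1 = k1, k2 = k1 / rate_ratio)
}

new_frap_curve <- function(time, roi, whole, background, n_pre) {
  df <- data.frame(time_s = time, roi = roi, whole = whole,
                   background = background)
  structure(df, n_pre = as.integer(n_pre),
            class = c("frap_curve", "data.frame"))
}

#' @export
print.frap_curve <- function(x, ...) {
  cat(sprintf("<frap_curve> %d frames (%d pre-bleach), t = %.3g..%.3g s\n",
              nrow(x), attr(x, "n_pre"), min(x$time_s), max(x$time_s)))
  invisible(x)
}

# Frame times: bleach is instantaneous at frame n_pre and the first
# post-bleach frame is the model's t = 0.
acq_times <- function(acq) {
  (seq_len(acq$n_pre + acq$n_post) - acq$n_pre - 1L) * acq$interval
}

# Shared wrapper: a normalized recovery F(tau) becomes a raw-like trace
#   roi(t) = decay(t) * [1 - bleach_depth * (1 - F(tau))]       (post-bleach)
#   roi(t) = decay(t)                                           (pre-bleach)
# with whole-nucleus channel decay(t) and zero background.  `whole_decay` is
# the total fractional loss of whole-cell signal over the acquisition
# (linear observational photobleaching; off by default).
simulate_from_model <- function(fmodel, acq, whole_decay = 0) {
  check_that(inherits(acq, "acquisition_spec"), "acq",
             "must be an acquisition_spec")
  check_that(is.numeric(whole_decay) && whole_decay >= 0 && whole_decay < 1,
             "whole_decay", "must be in [0, 1)")
  t_all <- acq_times(acq)
  n <- length(t_all)
  decay <- 1 - whole_decay * (seq_len(n) - 1L) / (n - 1L)
  post <- t_all >= 0
  expectation <- ifelse(post, 1 - acq$bleach_depth * (1 - fmodel(pmax(t_all, 0))), 1)
  roi <- expectation * decay
  if (acq$noise_sd > 0)
    roi <- roi + with_seed(acq$seed, rnorm(n, 0, acq$noise_sd))
  new_frap_curve(t_all, roi, decay, numeric(n), acq$n_pre)
}

#' Simulate a FRAP recovery curve
#'
#' Forward model for a strip/band FRAP experiment: a flat pre-bleach baseline
#' at 1, an instantaneous bleach removing `bleach_depth` of the ROI signal,
#' and a double-exponential recovery.  The noiseless ROI expectation after the
#' bleach is `1 - bleach_depth * (1 - F(t))` where `F` is [frap_model()].
#'
#' @param params A [kinetic_params()] object (ground-truth kinetics).
#' @param acq An [acquisition_spec()].
#' @param whole_decay Optional total fractional linear decay of the
#'   whole-nucleus channel over the acquisition, emulating observational
#'   photobleaching (the normalization stage corrects for it).  Default 0.
#' @return A `frap_curve` data frame with columns `time_s`, `roi`, `whole`,
#'   `background` and attribute `n_pre`.  Identical spec and seed give a
#'   bitwise-identical trace.
#' @examples
#' acq <- acquisition_spec(n_pre = 20, n_post = 200, interval = 0.07,
#'                         noise_sd = 0)
#' cur <- simulate_frap_curve(kinetic_params(0.9, 0, 0.5), acq)
#' @export
simulate_frap_curve <- function(params, acq, whole_decay = 0) {
  check_that(inherits(params, "kinetic_params"), "params",
             "must be a kinetic_params object")
  simulate_from_model(function(t) frap_model(t, params), acq, whole_decay)
}

#' Simulate a slow single-exponential recovery
#'
#' Long-timebase histone-turnover regime: recovery rises toward `plateau`
#' as `plateau * (1 - exp(-k t))`.  Supports multi-minute time bases.
#'
#' @param plateau Mobile fraction reached at infinite time, in \[0, 1\].
#' @param k Rate in 1/s (>= 0; `k = 0` gives a flat zero recovery).
#' @inheritParams simulate_frap_curve
#' @return A `frap_curve`.
#' @export
simulate_slow_recovery <- function(plateau, k, acq, whole_decay = 0) {
  check_that(is.numeric(plateau) && plateau >= 0 && plateau <= 1,
             "plateau", "must be in [0, 1]")
  check_that(is.numeric(k) && k >= 0, "k", "must be >= 0")
  simulate_from_model(function(t) plateau * (1 - exp(-k * t)), acq, whole_decay)
}

#' Simulate a biphasic (exponential + linear) recovery
#'
#' Emulates the recovery profile of elongating RNA polymerase II: an initial
#' rapid exponential phase followed by a prolonged linear phase.  The
#' noiseless expectation is `fast_amp * (1 - exp(-fast_k t)) + slope * t`,
#' capped at 1.
#'
#' @param fast_amp Amplitude of the fast exponential phase (>= 0).
#' @param fast_k Rate of the fast phase, 1/s (>= 0).
#' @param slope Linear-phase slope in normalized units per second (>= 0).
#' @inheritParams simulate_frap_curve
#' @return A `frap_curve`.
#' @export
simulate_biphasic_curve <- function(fast_amp, fast_k, slope, acq,
                                    whole_decay = 0) {
  check_that(fast_amp >= 0, "fast_amp", "must be >= 0")
  check_that(fast_k >= 0, "fast_k", "must be >= 0")
  check_that(slope >= 0, "slope", "must be >= 0")
  simulate_from_model(
    function(t) pmin(fast_amp * (1 - exp(-fast_k * t)) + slope * t, 1),
    acq, whole_decay)
}

#' Two-compartment exchange model for half-nucleus FLIP-FRAP
#'
#' @param v1,v2 Compartment volumes (arbitrary units; compartment 1 is
#'   bleached).  Half-nucleus bleaching corresponds to `v1 = v2`.
#' @param k_ex Exchange rate constant (amount per unit concentration
#'   difference per second, >= 0).
#' @param bleach_fraction Fraction of compartment-1 fluorescence destroyed.
#' @param immobile_fraction Fraction of fluorophores excluded from exchange.
#' @return A `two_compartment_spec` list.
#' @export
two_compartment_spec <- function(v1 = 1, v2 = 1, k_ex = 0.05,
                                 bleach_fraction = 1, immobile_fraction = 0) {
  check_that(v1 > 0, "v1", "must be > 0")
  check_that(v2 > 0, "v2", "must be > 0")
  check_that(k_ex >= 0, "k_ex", "must be >= 0")
  check_that(bleach_fraction >= 0 && bleach_fraction <= 1,
             "bleach_fraction", "must be in [0, 1]")
  check_that(immobile_fraction >= 0 && immobile_fraction <= 1,
             "immobile_fraction", "must be in [0, 1]")
  structure(list(v1 = v1, v2 = v2, k_ex = k_ex,
                 bleach_fraction = bleach_fraction,
                 immobile_fraction = immobile_fraction),
            class = "two_compartment_spec")
}

# Noiseless mean intensities (concentration) of both compartments at model
# time tau >= 0 after the bleach.  Mobile pools relax exponentially toward a
# common concentration with rate k_ex * (1/v1 + 1/v2); immobile pools stay
# where the bleach left them.  Pre-bleach concentration is 1 everywhere.
flip_expectation <- function(spec, tau) {
  fi <- spec$immobile_fraction
  m1_0 <- (1 - fi) * spec$v1 * (1 - spec$bleach_fraction)
  m2_0 <- (1 - fi) * spec$v2
  m_tot <- m1_0 + m2_0
  m1_eq <- m_tot * spec$v1 / (spec$v1 + spec$v2)
  lambda <- spec$k_ex * (1 / spec$v1 + 1 / spec$v2)
  m1 <- m1_eq + (m1_0 - m1_eq) * exp(-lambda * tau)
  m2 <- m_tot - m1
  imm1 <- fi * spec$v1 * (1 - spec$bleach_fraction)
  imm2 <- fi * spec$v2
  list(bleached = (m1 + imm1) / spec$v1,
       unbleached = (m2 + imm2) / spec$v2,
       lambda = lambda)
}

#' Simulate a half-nucleus FLIP-FRAP experiment
#'
#' Two well-mixed compartments exchange fluorophores; at frame `n_pre` a
#' fraction of compartment-1 fluorescence is destroyed.  In the noiseless
#' model total fluorescence (volume-weighted sum of the two mean intensities)
#' is exactly conserved after the bleach: the rise of the bleached half
#' mirrors the loss of the unbleached half.
#'
#' @param spec A [two_compartment_spec()].
#' @param acq An [acquisition_spec()]; `bleach_depth` is taken from `spec`,
#'   not from `acq`.
#' @return A list with `frap_curve` elements `bleached` and `unbleached`
#'   (mean intensity per compartment; pre-bleach level 1), plus the
#'   analytical exchange relaxation rate `lambda` (1/s) and its
#'   half-equilibration time `t_half_exchange = log(2)/lambda`.
#' @export
simulate_flip_frap <- function(spec, acq) {
  check_that(inherits(spec, "two_compartment_spec"), "spec",
             "must be a two_compartment_spec")
  check_that(inherits(acq, "acquisition_spec"), "acq",
             "must be an acquisition_spec")
  t_all <- acq_times(acq)
  n <- length(t_all)
  post <- t_all >= 0
  exp_post <- flip_expectation(spec, pmax(t_all, 0))
  b <- ifelse(post, exp_post$bleached, 1)
  u <- ifelse(post, exp_post$unbleached, 1)
  if (acq$noise_sd > 0) {
    eps <- with_seed(acq$seed, matrix(rnorm(2 * n, 0, acq$noise_sd), ncol = 2))
    b <- b + eps[, 1]
    u <- u + eps[, 2]
  }
  list(bleached = new_frap_curve(t_all, b, rep(1, n), numeric(n), acq$n_pre),
       unbleached = new_frap_curve(t_all, u, rep(1, n), numeric(n), acq$n_pre),
       lambda = exp_post$lambda,
       t_half_exchange = if (exp_post$lambda > 0) log(2) / exp_post$lambda else Inf)
}
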