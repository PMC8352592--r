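test_that("noiseless FRAP simulation follows the closed-form recovery model", {
  # single-exponential with full bleach: curve equals F(t) on the frame grid
  t_half <- log(2) / 0.5
  acq <- acquisition_spec(n_pre = 5, n_post = 40, interval = t_half / 20,
                          bleach_depth = 1, noise_sd = 0)
  cur <- simulate_frap_curve(kinetic_params(0.9, 0, 0.5), acq)
  # frame 20 after the bleach sits exactly at t = ln(2)/k
  expect_equal(cur$roi[5 + 1 + 20], 0.45, tolerance = 1e-12)
  expect_equal(cur$roi[1:5], rep(1, 5))
  expect_equal(cur$roi[6], 0)  # full bleach depth at the bleach frame

  # partial bleach: expectation is 1 - depth * (1 - F(t))
  acq2 <- acquisition_spec(n_pre = 3, n_post = 30, interval = 0.2,
                           bleach_depth = 0.6, noise_sd = 0)
  p <- kinetic_params(0.5, 0.3, 2, 0.2)
  cur2 <- simulate_frap_curve(p, acq2)
  tau <- cur2$time_s[cur2$time_s >= 0]
  expect_equal(cur2$roi[cur2$time_s >= 0],
               1 - 0.6 * (1 - frap_model(tau, p)), tolerance = 1e-12)
})

test_that("curve generators are pure functions of spec and seed", {
  acq <- acquisition_spec(n_pre = 5, n_post = 50, interval = 0.1,
                          noise_sd = 0.05, seed = 42L)
  p <- kinetic_params(0.7, 0.2, 1, 0.1)
  expect_identical(simulate_frap_curve(p, acq), simulate_frap_curve(p, acq))
  acq2 <- acq
  acq2$seed <- 43L
  expect_false(identical(simulate_frap_curve(p, acq)$roi,
                         simulate_frap_curve(p, acq2)$roi))
  # the global RNG stream is untouched
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_frap_curve(p, acq))
  expect_identical(.Random.seed, before)
})

test_that("replicate mean of noisy curves converges to the noiseless expectation", {
  p <- kinetic_params(0.6, 0.3, 2, 0.1)
  acq0 <- acquisition_spec(n_pre = 5, n_post = 60, interval = 0.1,
                           bleach_depth = 0.8, noise_sd = 0)
  noiseless <- simulate_frap_curve(p, acq0)$roi
  acc <- 0
  for (s in 1:500) {
    acq <- acquisition_spec(n_pre = 5, n_post = 60, interval = 0.1,
                            bleach_depth = 0.8, noise_sd = 0.02, seed = s)
    acc <- acc + simulate_frap_curve(p, acq)$roi
  }
  expect_lt(max(abs(acc / 500 - noiseless)), 0.005)
})

test_that("invalid acquisition fields are rejected with the field named", {
  err <- expect_error(acquisition_spec(n_pre = 0),
                      class = "chromodyn_validation_error")
  expect_match(conditionMessage(err), "n_pre")
  expect_error(acquisition_spec(bleach_depth = 0),
               class = "chromodyn_validation_error")
  expect_error(acquisition_spec(noise_sd = -1),
               class = "chromodyn_validation_error")
  expect_error(kinetic_params(0.8, 0.4), class = "chromodyn_validation_error")
  expect_error(kinetic_params(0.5, 0.2, k1 = 0.1, k2 = 0.5),
               class = "chromodyn_validation_error")
})

test_that("slow-recovery generator reproduces its arithmetic and limits", {
  acq <- acquisition_spec(n_pre = 5, n_post = 240, interval = 12,
                          bleach_depth = 1, noise_sd = 0)
  k <- -log(0.1) / 2400       # 90% of plateau at 40 min
  cur <- simulate_slow_recovery(0.2, k, acq)
  i40 <- which(cur$time_s == 2400)
  expect_equal(cur$roi[i40], 0.18, tolerance = 1e-12)

  flat <- simulate_slow_recovery(0.5, 0, acq)
  expect_equal(flat$roi[flat$time_s >= 0], rep(0, 240))

  fast <- simulate_slow_recovery(1, 1, acq)
  expect_gt(min(fast$roi[fast$time_s >= 3]), 0.95)
})

test_that("biphasic generator covers the ramp, exponential and mixed cases", {
  acq <- acquisition_spec(n_pre = 3, n_post = 120, interval = 1,
                          bleach_depth = 1, noise_sd = 0)
  ramp <- simulate_biphasic_curve(0, 1, 0.002, acq)
  tau <- ramp$time_s[ramp$time_s >= 0]
  expect_equal(ramp$roi[ramp$time_s >= 0], 0.002 * tau, tolerance = 1e-12)

  p <- kinetic_params(0.4, 0, 1)
  pure_exp <- simulate_biphasic_curve(0.4, 1, 0, acq)
  expect_equal(pure_exp$roi[pure_exp$time_s >= 0], frap_model(tau, p),
               tolerance = 1e-12)

  mix <- simulate_biphasic_curve(0.4, 1, 0.001, acq)
  expect_equal(mix$roi[mix$time_s == 100], 0.4 * (1 - exp(-100)) + 0.1,
               tolerance = 1e-12)
  # the cap keeps the expectation within the normalized range
  long <- simulate_biphasic_curve(0.9, 1, 0.01, acq)
  expect_lte(max(long$roi), 1)
})

test_that("noiseless FLIP-FRAP conserves total fluorescence and equilibrates", {
  acq <- acquisition_spec(n_pre = 5, n_post = 200, interval = 0.648,
                          noise_sd = 0)
  # symmetric full bleach: both halves converge to 50% of total signal
  sym <- simulate_flip_frap(two_compartment_spec(k_ex = 0.05), acq)
  nb <- length(sym$bleached$roi)
  expect_equal(sym$bleached$roi[nb], 0.5, tolerance = 1e-3)
  expect_equal(sym$unbleached$roi[nb], 0.5, tolerance = 1e-3)

  # conservation (volume-weighted) to machine precision, asymmetric included
  for (spec in list(two_compartment_spec(k_ex = 0.1, bleach_fraction = 0.7),
                    two_compartment_spec(v1 = 2, v2 = 0.5, k_ex = 0.2,
                                         immobile_fraction = 0.3))) {
    sim <- simulate_flip_frap(spec, acq)
    post <- sim$bleached$time_s >= 0
    total <- spec$v1 * sim$bleached$roi[post] +
      spec$v2 * sim$unbleached$roi[post]
    expect_equal(max(total) - min(total), 0, tolerance = 1e-12)
  }
})

test_that("FLIP-FRAP half-equilibration matches an explicit ODE integration", {
  spec <- two_compartment_spec(k_ex = log(2) / 60)  # analytic t_half = 30 s
  acq <- acquisition_spec(n_pre = 5, n_post = 400, interval = 0.5,
                          noise_sd = 0)
  sim <- simulate_flip_frap(spec, acq)
  expect_equal(sim$t_half_exchange, 30, tolerance = 1e-9)

  times <- seq(0, 200, by = 0.01)
  ode <- ode_flip_curves(spec, times)
  eq <- (ode$bleached[1] + ode$bleached[length(times)]) / 2
  t_half_ode <- times[which(ode$bleached >= eq)[1]]

  b <- sim$bleached$roi[sim$bleached$time_s >= 0]
  tb <- sim$bleached$time_s[sim$bleached$time_s >= 0]
  half <- (b[1] + b[length(b)]) / 2
  t_half_emp <- tb[which(b >= half)[1]]
  expect_lt(abs(t_half_emp - t_half_ode) / t_half_ode, 0.05)
})

test_that("phantom label maps hit the target fractions and intensities exactly", {
  sp <- phantom_spec(psf_sigma = 0, photon_gain = 0, read_sd = 0)
  ph <- render_nucleus_phantom(sp)
  n_chr <- sum(ph$labels >= 2L)
  target <- sp$class_fractions * n_chr
  got <- c(white = sum(ph$labels == 2L), gray = sum(ph$labels == 3L),
           black = sum(ph$labels == 4L))
  expect_true(all(abs(got - target) <= 1))  # exact up to integer rounding
  # no blur, no noise: class means equal the configured intensities exactly
  for (cl in c(white = 2L, gray = 3L, black = 4L)) {
    nm <- names(which(c(white = 2L, gray = 3L, black = 4L) == cl))
    expect_equal(mean(ph$image[ph$labels == cl]),
                 unname(sp$class_intensity[nm]))
  }
  expect_equal(unique(as.vector(ph$image[ph$labels == 0L])),
               sp$class_intensity[["background"]])
})

test_that("phantom rendering is seed-reproducible with realistic optics", {
  sp <- phantom_spec(shape = c(5, 48, 48), seed = 11L)
  expect_identical(render_nucleus_phantom(sp)$image,
                   render_nucleus_phantom(sp)$image)
  sp2 <- phantom_spec(shape = c(5, 48, 48), seed = 12L)
  ph1 <- render_nucleus_phantom(sp)
  ph2 <- render_nucleus_phantom(sp2)
  expect_identical(ph1$labels, ph2$labels)    # geometry is seed-independent
  expect_false(identical(ph1$image, ph2$image))
})

test_that("phantom spec validation enforces ordering and ranges", {
  expect_error(phantom_spec(class_fractions = c(white = 0.6, gray = 0.3,
                                                black = 0.3)),
               class = "chromodyn_validation_error")
  expect_error(phantom_spec(class_intensity = c(background = 120,
                                                nucleolus = 40, white = 116,
                                                gray = 186, black = 245)),
               class = "chromodyn_validation_error")
  expect_error(phantom_spec(class_intensity = c(background = 30,
                                                nucleolus = 40, white = 116,
                                                gray = 186, black = 300)),
               class = "chromodyn_validation_error")
})
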