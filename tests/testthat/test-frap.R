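test_that("background correction subtracts, floors at zero and flags floored frames", {
  cur <- frap_curve(time = 0:9, roi = rep(100, 10), whole = rep(200, 10),
                    background = 20, n_pre = 3)
  out <- background_correct(cur)
  expect_equal(out$roi, rep(80, 10))
  expect_equal(out$whole, rep(180, 10))
  expect_length(attr(out, "floored_frames"), 0)

  zero_bg <- frap_curve(time = 0:9, roi = 1:10, whole = rep(5, 10),
                        background = 0, n_pre = 2)
  expect_identical(background_correct(zero_bg)$roi, as.numeric(1:10))

  low <- frap_curve(time = 0:9, roi = rep(10, 10), whole = rep(50, 10),
                    background = 15, n_pre = 2)
  expect_warning(res <- background_correct(low), "floored")
  expect_equal(res$roi, rep(0, 10))
  expect_length(attr(res, "floored_frames"), 10)
})

test_that("full-scale normalization pins the bleach frame to 0 and pre-bleach to 1", {
  # arithmetic oracle: whole constant, roi_pre mean 1, roi(t0)=0.3, roi(t)=0.65
  roi <- c(1, 1, 1, 0.3, 0.65, 0.8)
  cur <- frap_curve(time = 0:5, roi = roi, whole = rep(2, 6), n_pre = 3)
  nc <- full_scale_normalize(cur)
  expect_equal(nc$value[4], 0)
  expect_equal(nc$value[5], (0.65 - 0.3) / 0.7)  # = 0.5
  expect_equal(mean(nc$value[1:3]), 1)
  expect_equal(nc$time[4], 0)
  expect_equal(attr(nc, "bleach_depth_observed"), 0.7)

  # degenerate input: first post-bleach frame at the pre-bleach level
  flat <- frap_curve(time = 0:5, roi = rep(1, 6), whole = rep(1, 6), n_pre = 3)
  expect_error(full_scale_normalize(flat), "no bleach detected",
               class = "chromodyn_analysis_error")
})

test_that("normalization invariants hold for arbitrary positive curves", {
  for (s in 1:25) {
    acq <- acquisition_spec(n_pre = sample(2:10, 1), n_post = 30,
                            interval = 0.1, bleach_depth = runif(1, 0.2, 1),
                            noise_sd = 0.01, seed = s)
    p <- kinetic_params_for_t_half(runif(1, 0.3, 3),
                                   mobile = runif(1, 0.5, 1))
    nc <- full_scale_normalize(simulate_frap_curve(p, acq))
    expect_identical(nc$value[attr(nc, "n_pre") + 1L], 0)
    expect_equal(mean(nc$value[seq_len(attr(nc, "n_pre"))]), 1,
                 tolerance = 1e-12)
  }
  set.seed(1)  # fixed seed for the property loop above
})

test_that("double normalization corrects linear observational photobleaching", {
  p <- kinetic_params(0.6, 0.3, 2, 0.1)
  acq <- acquisition_spec(n_pre = 10, n_post = 200, interval = 0.1,
                          bleach_depth = 0.8, noise_sd = 0)
  plain <- full_scale_normalize(simulate_frap_curve(p, acq))
  decayed <- full_scale_normalize(simulate_frap_curve(p, acq,
                                                      whole_decay = 0.2))
  late <- plain$time >= quantile(plain$time, 0.9)
  expect_lt(abs(mean(decayed$value[late]) - mean(plain$value[late])), 0.01)
})

test_that("noiseless double-exponential curves are recovered to high accuracy", {
  truth <- list(a = 0.6, b = 0.3, k1 = 2, k2 = 0.1)
  acq <- acquisition_spec(n_pre = 10, n_post = 250, interval = 0.1,
                          bleach_depth = 0.8, noise_sd = 0)
  nc <- full_scale_normalize(simulate_frap_curve(
    kinetic_params(truth$a, truth$b, truth$k1, truth$k2), acq))
  fit <- fit_double_exponential(nc)
  expect_true(fit$converged)
  expect_equal(fit$model, "double")
  for (nm in names(truth))
    expect_equal(fit[[nm]], truth[[nm]], tolerance = 1e-4)
  expect_equal(fit$mobile_fraction, 0.9, tolerance = 1e-4)

  # single-exponential truth collapses to the single-exponential model
  nc1 <- full_scale_normalize(simulate_frap_curve(
    kinetic_params(0.9, 0, 0.5), acq))
  fit1 <- fit_double_exponential(nc1)
  expect_equal(fit1$model, "single")
  expect_equal(fit1$mobile_fraction, 0.9, tolerance = 1e-6)
  expect_equal(fit1$t_half, log(2) / 0.5, tolerance = 1e-6)
})

test_that("fitted model is non-decreasing whenever parameters are non-negative", {
  grid <- seq(0, 50, length.out = 400)
  for (s in 1:20) {
    acq <- acquisition_spec(n_pre = 5, n_post = 100, interval = 0.2,
                            bleach_depth = 0.8, noise_sd = 0.03, seed = s)
    p <- kinetic_params_for_t_half(runif(1, 0.5, 5), mobile = runif(1, 0.6, 1))
    fit <- fit_double_exponential(full_scale_normalize(
      simulate_frap_curve(p, acq)))
    vals <- frap_model(grid, list(a = fit$a, b = fit$b,
                                  k1 = fit$k1, k2 = fit$k2))
    expect_true(all(diff(vals) >= -1e-12))
  }
  set.seed(1)
})

test_that("solve_t_half reduces to closed forms and matches bisection", {
  expect_equal(solve_t_half(list(a = 0.8, b = 0, k1 = 2, k2 = 0)),
               log(2) / 2)
  expect_equal(solve_t_half(list(a = 0.4, b = 0.4, k1 = 0.7, k2 = 0.7)),
               log(2) / 0.7)
  expect_equal(solve_t_half(list(a = 0.5, b = 0.5, k1 = 1, k2 = 0.1)),
               bisect_t_half(0.5, 0.5, 1, 0.1), tolerance = 1e-10)
})

test_that("percent recovery reads plateaus and rejects out-of-range times", {
  nc <- model_curve(0.18, 0, 50, 0, times = seq(0, 100, by = 0.5))
  expect_equal(percent_recovery_at(nc, 80), 0.18, tolerance = 1e-6)
  expect_equal(percent_recovery_at(nc, 80, window = 10), 0.18,
               tolerance = 1e-6)
  expect_error(percent_recovery_at(nc, 1000),
               class = "chromodyn_validation_error")

  acq <- acquisition_spec(n_pre = 5, n_post = 240, interval = 12,
                          bleach_depth = 1, noise_sd = 0)
  k <- -log(0.1) / 2400
  nc2 <- full_scale_normalize(simulate_slow_recovery(0.2, k, acq))
  expect_equal(percent_recovery_at(nc2, 2400), 0.18, tolerance = 1e-9)
})

test_that("biphasic fits separate the exponential and linear phases", {
  acq <- acquisition_spec(n_pre = 5, n_post = 300, interval = 1,
                          bleach_depth = 1, noise_sd = 0)
  pure_exp <- full_scale_normalize(simulate_biphasic_curve(0.5, 0.5, 0, acq))
  f1 <- fit_biphasic(pure_exp)
  expect_lt(f1$slope, 1e-6)

  ramp <- full_scale_normalize(simulate_biphasic_curve(0, 1, 0.0015, acq))
  f2 <- fit_biphasic(ramp)
  expect_lt(f2$fast_amp, 1e-3)
  expect_equal(f2$slope, 0.0015, tolerance = 1e-3)

  mix <- full_scale_normalize(simulate_biphasic_curve(0.4, 1, 0.001, acq))
  f3 <- fit_biphasic(mix)
  expect_equal(f3$fast_amp, 0.4, tolerance = 1e-4)
  expect_equal(f3$fast_k, 1, tolerance = 1e-4)
  expect_equal(f3$slope, 0.001, tolerance = 1e-4)
})

test_that("half-time ratios compare two fitted curves", {
  acq <- acquisition_spec(n_pre = 10, n_post = 200, interval = 0.07,
                          bleach_depth = 0.8, noise_sd = 0)
  fit_a <- fit_double_exponential(full_scale_normalize(
    simulate_frap_curve(kinetic_params_for_t_half(1.7), acq)))
  fit_b <- fit_double_exponential(full_scale_normalize(
    simulate_frap_curve(kinetic_params_for_t_half(0.7), acq)))
  cmp <- compare_t_half(fit_a, fit_b)
  expect_equal(cmp$ratio, 1.7 / 0.7, tolerance = 1e-3)
  expect_equal(compare_t_half(fit_a, fit_a)$ratio, 1)
})

test_that("FLIP-FRAP analysis balances gain against loss and flags static pairs", {
  acq <- acquisition_spec(n_pre = 10, n_post = 250, interval = 0.648,
                          bleach_depth = 1, noise_sd = 0.005, seed = 5L)
  sim <- simulate_flip_frap(two_compartment_spec(k_ex = log(2) / 40), acq)
  res <- analyze_flip_frap(sim$bleached, sim$unbleached)
  expect_equal(res$gain_loss_balance, 1, tolerance = 0.02)
  expect_equal(res$equilibration_t_half, 20, tolerance = 0.15)

  # both halves constant: no exchange to analyze
  b <- frap_curve(0:99, c(rep(1, 10), rep(0.4, 90)), n_pre = 10)
  u <- frap_curve(0:99, rep(1, 100), n_pre = 10)
  expect_error(analyze_flip_frap(b, u), "no exchange",
               class = "chromodyn_analysis_error")
})

test_that("histone-like FLIP-FRAP shows essentially no recovery for minutes", {
  acq <- acquisition_spec(n_pre = 10, n_post = 278, interval = 0.648,
                          bleach_depth = 1, noise_sd = 0.005, seed = 8L)
  sim <- simulate_flip_frap(two_compartment_spec(k_ex = 1e-5), acq)
  pre <- mean(sim$bleached$roi[1:10])
  post <- sim$bleached$time_s >= 0
  pct <- 100 * sim$bleached$roi[post] / pre
  late <- mean(pct[sim$bleached$time_s[post] >= 170])
  expect_lt(late - pct[1], 2)   # < 2 percent-point recovery over ~180 s
})
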