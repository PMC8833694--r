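make_tic <- function(t_arrival = 5, mu = 0.5, sigma = 0.5, amplitude = 10,
                     baseline = 1, rate = 20, n = 600, noise = 0,
                     excl = 0, seed = 1) {
  generate_tic(t_arrival, mu, sigma, amplitude, baseline, rate, n,
               noise_sd = noise, excluded_fraction = excl, seed = seed)
}

test_that("the quality gate is inclusive at the excluded-fraction threshold", {
  expect_true(quality_gate(make_tic(excl = 0)))
  expect_false(quality_gate(make_tic(n = 500, excl = 0.6)))
  at_gate <- make_tic(n = 500, excl = 0.4)   # exactly 200 of 500 frames
  expect_equal(mean(at_gate$excluded), 0.4)
  expect_true(quality_gate(at_gate))
})

test_that("arrival is detected within one frame on a noiseless curve and flat curves error", {
  tic <- make_tic(t_arrival = 5, mu = 0, noise = 0)
  ba <- estimate_baseline_and_arrival(tic)
  expect_equal(ba$baseline_au, 1)
  expect_lte(abs(ba$t_arrival_s - 5), 1 / 20 + 1e-9)
  flat <- make_tic(amplitude = 0, noise = 0)
  expect_error(estimate_baseline_and_arrival(flat),
               class = "lnscore_no_enhancement")
})

test_that("arrival detection is nearly unbiased under realistic noise", {
  peak <- 10 * dlnorm(exp(0 - 0.25), 0, 0.5)
  errs <- vapply(1:100, function(s) {
    tic <- make_tic(t_arrival = 5, mu = 0, amplitude = 10,
                    noise = 0.1 * peak, seed = s)
    estimate_baseline_and_arrival(tic, k_sd = 3)$t_arrival_s - 5
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.25)
})

test_that("the bolus fit recovers generator parameters exactly at zero noise", {
  for (par in list(c(mu = 0, sigma = 0.5, A = 10),
                   c(mu = 1.639, sigma = 0.5, A = 12),
                   c(mu = 0.907, sigma = 0.4, A = 8))) {
    tic <- make_tic(t_arrival = 5, mu = par["mu"], sigma = par["sigma"],
                    amplitude = par["A"], n = 1000, noise = 0)
    ba <- estimate_baseline_and_arrival(tic)
    fit <- fit_bolus(tic, ba$baseline_au, ba$t_arrival_s)
    expect_lt(abs(fit$amplitude - par["A"]) / par["A"], 0.01)
    expect_lt(abs(fit$sigma - par["sigma"]) / par["sigma"], 0.01)
    expect_lt(abs(fit$mu - par["mu"]), 0.01 * max(abs(par["mu"]), 1))
    expect_lt(abs(fit$t_arrival_s - 5), 0.02)
    expect_lt(fit$fit_rmse, 1e-6)
  }
})

test_that("TTP is the closed-form lognormal mode of the fit", {
  fit <- structure(list(amplitude = 1, mu = 0, sigma = 0.5, t_arrival_s = 0,
                        baseline_au = 0, fit_rmse = 0, converged = TRUE,
                        n_used = 100L), class = "bolus_fit")
  expect_equal(compute_ttp(fit), exp(-0.25))
  fit$sigma <- 1e-6; fit$mu <- 1.2
  expect_equal(compute_ttp(fit), exp(1.2), tolerance = 1e-5)
})

test_that("wash-in rate is the OLS slope and is positive for a monotone wash-in", {
  t <- seq(0, 5, length.out = 101)
  ramp <- time_intensity_curve(t, 2 * t)
  expect_equal(compute_wir(ramp, NULL, 0, 5, source = "raw"), 2.0,
               tolerance = 1e-12)
  tic <- make_tic(noise = 0)
  p <- analyze_tic(tic)
  expect_gt(p$wir_au_per_s, 0)
  # independent closed-form slope of the clean model over the window
  tt <- tic$time_s[tic$time_s >= p$t_arrival_s & tic$time_s <= p$t_peak_s]
  yy <- clean_bolus(tt, 5, 0.5, 0.5, 10, 1)
  expect_equal(p$wir_au_per_s, ols_slope(tt, yy), tolerance = 0.02)
})

test_that("raw-mode and fitted-mode WiR agree at low noise", {
  rel <- vapply(1:30, function(s) {
    amp <- 10
    peak <- amp * dlnorm(exp(1.0 - 0.25), 1.0, 0.5)
    tic <- make_tic(mu = 1.0, amplitude = amp, noise = 0.05 * peak, seed = s)
    ba <- estimate_baseline_and_arrival(tic)
    fit <- fit_bolus(tic, ba$baseline_au, ba$t_arrival_s)
    tp <- fit$t_arrival_s + compute_ttp(fit)
    w_f <- compute_wir(tic, fit, fit$t_arrival_s, tp, source = "fitted")
    w_r <- compute_wir(tic, fit, fit$t_arrival_s, tp, source = "raw")
    abs(w_r - w_f) / abs(w_f)
  }, numeric(1))
  expect_lt(median(rel), 0.10)
})

test_that("insufficient wash-in samples raise an error", {
  tic <- make_tic(noise = 0)
  p <- analyze_tic(tic)
  expect_error(compute_wir(tic, NULL, 5.0, 5.05, source = "raw"),
               class = "lnscore_insufficient_data")
})

test_that("analysis is time-shift and intensity-scale equivariant", {
  tic <- make_tic(mu = 1.0, noise = 0.02, seed = 4)
  p0 <- analyze_tic(tic)
  shifted <- time_intensity_curve(tic$time_s + 3.7, tic$intensity,
                                  tic$excluded)
  p1 <- analyze_tic(shifted)
  expect_equal(p1$t_arrival_s - p0$t_arrival_s, 3.7, tolerance = 1e-6)
  expect_equal(p1$t_peak_s - p0$t_peak_s, 3.7, tolerance = 1e-4)
  expect_equal(p1$ttp_s, p0$ttp_s, tolerance = 1e-4)
  expect_equal(p1$wir_au_per_s, p0$wir_au_per_s, tolerance = 1e-4)

  scaled <- time_intensity_curve(tic$time_s, 3 * tic$intensity, tic$excluded)
  p2 <- analyze_tic(scaled)
  expect_equal(p2$ttp_s, p0$ttp_s, tolerance = 1e-3)
  expect_equal(p2$wir_au_per_s / p0$wir_au_per_s, 3, tolerance = 1e-3)
  expect_equal(p2$peak_enhancement_au / p0$peak_enhancement_au, 3,
               tolerance = 1e-3)
})

test_that("excluded frames never influence the analysis", {
  tic <- make_tic(noise = 0.05, excl = 0.2, seed = 12)
  corrupted <- tic
  corrupted$intensity[corrupted$excluded] <- 1e6
  expect_identical(analyze_tic(tic)[names(analyze_tic(tic)) != "node_id"],
                   analyze_tic(corrupted)[names(analyze_tic(tic)) != "node_id"])
})

test_that("over-excluded curves are unusable with NA parameters", {
  bad <- make_tic(n = 500, excl = 0.6)
  p <- analyze_tic(bad)
  expect_false(p$usable)
  expect_true(is.na(p$ttp_s) && is.na(p$wir_au_per_s))
  expect_equal(p$excluded_fraction, 0.6)
})

test_that("TTP and WiR recovery stays within tolerance across a parameter grid", {
  # the two bolus shapes of the study design (control and involved nodes)
  # crossed with noise levels spanning up to 10% of peak enhancement
  grid <- expand.grid(mu = c(0.907, 1.639), sigma = 0.5, A = c(8, 12),
                      noise_frac = c(0.02, 0.06, 0.10))
  errs <- t(apply(grid, 1, function(g) {
    ttp_true <- exp(g["mu"] - g["sigma"]^2)
    peak <- g["A"] * dlnorm(ttp_true, g["mu"], g["sigma"])
    tic <- make_tic(mu = g["mu"], sigma = g["sigma"], amplitude = g["A"],
                    n = 800, noise = g["noise_frac"] * peak,
                    seed = 1000 + round(1e3 * g["mu"]) + round(10 * g["A"]) +
                      round(100 * g["noise_frac"]))
    p <- analyze_tic(tic)
    tt <- tic$time_s[tic$time_s >= 5 & tic$time_s <= 5 + ttp_true]
    wir_true <- ols_slope(tt, clean_bolus(tt, 5, g["mu"], g["sigma"], g["A"], 1))
    c(abs(p$ttp_s - ttp_true) / ttp_true,
      abs(p$wir_au_per_s - wir_true) / abs(wir_true))
  }))
  expect_lt(median(errs[, 1]), 0.05)
  expect_lt(median(errs[, 2]), 0.10)
})
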