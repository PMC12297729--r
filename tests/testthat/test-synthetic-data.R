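test_that("cohort generation is deterministic and carries ground truth", {
  a <- make_current_clamp_cohort(c(Quiet = 2), seed = 7)
  b <- make_current_clamp_cohort(c(Quiet = 2), seed = 7)
  expect_identical(a, b)
  expect_length(a, 2L)
  expect_identical(a[[1]]$metadata$true_class, "Quiet")
  # full step family from -10 to +190 pA plus a stimulus-free sweep
  lv <- vapply(a[[1]]$steps[-1], function(s) s$level, numeric(1))
  expect_equal(range(lv), c(-10, 190))
  expect_null(a[[1]]$steps[[1]])
})

test_that("a Single neuron's best sweep has exactly one excursion at the requested peak", {
  coh <- make_current_clamp_cohort(
    c(Single = 1), params = spike_template_params(peak_v = 30),
    seed = 1, noise_sd = 0)
  nr <- coh[[1]]
  top <- n_sweeps(nr)  # highest current step
  exc <- detect_excursions(nr, top)
  expect_equal(nrow(exc), 1L)
  expect_true(exc$overshoots)
  expect_equal(exc$peak_v, 30, tolerance = 0.01)
})

test_that("unachievable class requests raise parameter errors", {
  p_sub <- spike_template_params(threshold_v = -30, peak_v = -5,
                                 sub_peak_v = -20)
  expect_error(make_current_clamp_cohort(c(Single = 1), params = p_sub),
               "parameter error")
  p_over <- spike_template_params(sub_peak_v = 10)
  expect_error(make_current_clamp_cohort(c(AttemptingTrain = 1), params = p_over),
               "parameter error")
  expect_error(make_current_clamp_cohort(c(Quiet = -1)), "non-negative")
})

test_that("generator and classifier agree for every class over random templates", {
  set.seed(99)
  for (cl in induced_levels) {
    for (draw in 1:10) {
      p <- spike_template_params(
        threshold_v = stats::runif(1, -50, -35),
        peak_v = stats::runif(1, 10, 40),
        rise_tau = stats::runif(1, 0.4, 0.8),
        decay_tau = stats::runif(1, 2, 6),
        sub_peak_v = stats::runif(1, -30, -10))
      coh <- make_current_clamp_cohort(
        stats::setNames(1L, cl), params = p,
        seed = sample.int(1e6, 1))
      expect_identical(as.character(classify_induced(coh[[1]])), cl)
    }
  }
})

test_that("noiseless voltage-clamp peaks match the closed form at every step", {
  rec <- make_voltage_clamp_recording(noise_sd = 0, seed = 1)
  iv <- extract_peak_currents(rec$activation)
  cf <- pmin(vc_peak_current(na_gating(), iv$vc), 0)
  expect_lt(max(abs(iv$peak_inward - cf)), 0.01 * max(abs(cf)))
  # per-step 1% where the current is non-negligible
  big <- abs(cf) > 0.02 * max(abs(cf))
  expect_true(all(abs(iv$peak_inward[big] - cf[big]) <= 0.01 * abs(cf[big])))
})

test_that("zero driving force and Boltzmann midpoint behave as closed forms say", {
  # command step at the reversal potential: inward component vanishes
  na <- na_gating()
  rec <- make_voltage_clamp_recording(
    na = na, k = k_gating(1e-9), noise_sd = 0,
    act_steps = c(seq(-120, 60, by = 10), 66.7))
  iv <- extract_peak_currents(rec$activation)
  at_rev <- iv[iv$vc == 66.7, ]
  expect_lt(abs(at_rev$peak_inward), 0.01 * max(abs(iv$peak_inward)))

  # at V50 with inactivation absent, peak conductance is gmax/2
  na_ni <- gating_ground_truth(gmax = 30, v50_act = -30, h_act = 7,
                               e_rev = 66.7, kinetic_tau = 0.5)
  rec2 <- make_voltage_clamp_recording(na = na_ni, k = k_gating(1e-9),
                                       noise_sd = 0)
  iv2 <- extract_peak_currents(rec2$activation)
  g50 <- iv2$peak_inward[iv2$vc == -30] / (-30 - 66.7)
  expect_equal(g50, 15, tolerance = 0.01 * 15)
})

test_that("voltage-clamp and fluorescence generators are seed-deterministic", {
  r1 <- make_voltage_clamp_recording(noise_sd = 5, seed = 3)
  r2 <- make_voltage_clamp_recording(noise_sd = 5, seed = 3)
  expect_identical(r1, r2)
  expect_error(make_voltage_clamp_recording(noise_sd = -1), "parameter error")
  f1 <- make_fluorescence_trace(seed = 5)
  f2 <- make_fluorescence_trace(seed = 5)
  expect_identical(f1, f2)
})

test_that("fluorescence traces honour their ground truth", {
  # constant plus drift when oscillation and noise are off
  gt <- calcium_ground_truth(f0 = 50, osc_amp = 0, noise_sd = 0,
                             drift_slope = 0.01)
  tr <- make_fluorescence_trace(gt, duration = 60, sampling_rate = 5)
  expect_equal(nrow(tr$values), 300L)
  t <- sweep_times(tr)
  expect_equal(unname(tr$values[, 1]), 50 * (1 + 0.01 * t))
  # 0.05 Hz over 60 s: three full cycles -> 3 maxima
  gt2 <- calcium_ground_truth(osc_freq = 0.05, osc_amp = 0.3, noise_sd = 0)
  tr2 <- make_fluorescence_trace(gt2)
  v <- tr2$values[, 1]
  n <- length(v)
  n_max <- sum(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n])
  expect_equal(n_max, 3L)
  # oscillation at/above Nyquist is refused
  expect_error(make_fluorescence_trace(calcium_ground_truth(osc_freq = 2.5),
                                       sampling_rate = 5),
               "Nyquist")
})
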