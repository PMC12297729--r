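test_that("peak extraction reports densities by simple division", {
  rec <- make_voltage_clamp_recording(capacitance = 10, noise_sd = 0)
  iv <- extract_peak_currents(rec$activation)
  expect_equal(iv$inward_density, iv$peak_inward / 10)
  expect_true(all(iv$peak_inward <= 0 & iv$peak_outward >= 0))
  rec$activation$capacitance <- NA_real_
  expect_error(extract_peak_currents(rec$activation, density = TRUE),
               "capacitance")
  iv2 <- extract_peak_currents(rec$activation)
  expect_false("inward_density" %in% names(iv2))
})

test_that("conductance transform is plain driving-force arithmetic", {
  pts <- data.frame(vc = c(-20, 0), peak_inward = c(-1000, 0),
                    peak_outward = c(0, 0))
  gv <- conductance_transform(pts, e_rev = 66.7, branch = "inward")
  expect_equal(gv$g[gv$vc == -20], -1000 / (-20 - 66.7), tolerance = 1e-12)
  expect_equal(gv$g[gv$vc == -20], 11.534, tolerance = 1e-3)
  expect_equal(gv$g[gv$vc == 0], 0)
  # a point at exactly the reversal potential is excluded with a warning
  pts2 <- data.frame(vc = c(-20, 66.7), peak_inward = c(-1000, -5),
                     peak_outward = c(0, 0))
  expect_warning(gv2 <- conductance_transform(pts2, 66.7, "inward"),
                 "zero driving force")
  expect_equal(gv2$vc, -20)
})

test_that("conductance transform is linear in the currents", {
  rec <- make_voltage_clamp_recording(noise_sd = 0)
  iv <- extract_peak_currents(rec$activation)
  gv1 <- conductance_transform(iv, 66.7, "inward")
  fit1 <- fit_boltzmann(gv1, "activation")
  for (c_scale in c(0.5, 3)) {
    ivc <- iv
    ivc$peak_inward <- iv$peak_inward * c_scale
    gvc <- conductance_transform(ivc, 66.7, "inward")
    expect_equal(gvc$g, gv1$g * c_scale)
    fitc <- fit_boltzmann(gvc, "activation")
    expect_equal(fitc$gmax, fit1$gmax * c_scale, tolerance = 1e-6)
    expect_equal(fitc$v50, fit1$v50, tolerance = 1e-6)
    expect_equal(fitc$h, fit1$h, tolerance = 1e-6)
  }
})

test_that("Boltzmann fitting recovers noiseless parameters and the midpoint", {
  gv <- boltz_gv(20, -30, 7, seq(-120, 80, by = 10))
  fit <- fit_boltzmann(gv, "activation")
  expect_equal(fit$v50, -30, tolerance = 0.1)
  expect_equal(fit$h, 7, tolerance = 0.07)
  expect_equal(fit$gmax, 20, tolerance = 0.02)
  expect_equal(boltzmann_curve(fit, fit$v50), fit$gmax / 2, tolerance = 1e-9)
  # mirrored parameterization for inactivation, h reported positive
  gvi <- boltz_gv(20, -60, 7, seq(-120, 80, by = 5), type = "inactivation")
  fiti <- fit_boltzmann(gvi, "inactivation")
  expect_equal(fiti$v50, -60, tolerance = 0.1)
  expect_gt(fiti$h, 0)
  expect_error(fit_boltzmann(data.frame(vc = 1:10, g = rep(2, 10))),
               "degenerate")
  expect_error(fit_boltzmann(boltz_gv(20, -30, 7, c(-40, -30, -20))),
               "at least 5")
})

test_that("simulate -> extract -> transform -> fit round-trips random gating truths", {
  set.seed(31)
  for (r in 1:15) {
    v50a <- stats::runif(1, -45, -15)
    ha <- stats::runif(1, 5, 10)
    v50i <- stats::runif(1, -80, -50)
    hi <- stats::runif(1, 5, 10)
    na <- gating_ground_truth(gmax = stats::runif(1, 10, 60),
                              v50_act = v50a, h_act = ha,
                              v50_inact = v50i, h_inact = -hi,
                              e_rev = 66.7, kinetic_tau = 0.5)
    rec <- make_voltage_clamp_recording(na = na, noise_sd = 0,
                                        seed = 1000 + r)
    res <- fit_na_gating(rec$activation, rec$inactivation)
    expect_equal(res$act$v50, v50a, tolerance = 0.35)
    expect_equal(res$act$h, ha, tolerance = 0.02 * ha)
    expect_equal(res$inact$v50, v50i, tolerance = 0.35)
    expect_equal(res$inact$h, hi, tolerance = 0.02 * hi)
    expect_equal(res$window$va50_minus_vi50, res$act$v50 - res$inact$v50)
  }
})

test_that("availability window geometry follows the fitted curves", {
  mk_fit <- function(v50, h, type) {
    fit_boltzmann(boltz_gv(10, v50, h, seq(-120, 80, by = 5), type = type),
                  type)
  }
  # symmetric case: both curves are 0.5 at the common midpoint
  act <- mk_fit(-30, 7, "activation")
  inact <- mk_fit(-30, 7, "inactivation")
  w <- availability_window(act, inact)
  expect_equal(w$crossing_v, -30, tolerance = 1e-3)
  expect_equal(w$window_max, 0.25, tolerance = 1e-4)
  expect_true(all(w$window_curve >= 0 & w$window_curve <= 1))
  # inactivation far right of activation: window approaches 1
  inact_r <- mk_fit(-30 + 60, 7, "inactivation")
  w2 <- availability_window(act, inact_r)
  expect_gt(w2$window_max, 0.95)
  # the statistic named in availability analyses
  inact_l <- mk_fit(-61.7, 7, "inactivation")
  w3 <- availability_window(act, inact_l)
  expect_equal(w3$va50_minus_vi50, 31.7, tolerance = 1e-6)
  # crossing point equalizes the two curves to 1e-6
  d <- abs(boltzmann_curve(act, w3$crossing_v, normalized = TRUE) -
             boltzmann_curve(inact_l, w3$crossing_v, normalized = TRUE))
  expect_lt(d, 1e-6)
})

test_that("the window maximum shrinks as inactivation moves left of activation", {
  act <- fit_boltzmann(boltz_gv(10, -30, 7, seq(-120, 80, 5)), "activation")
  shifts <- seq(0, -40, by = -10)
  maxima <- vapply(shifts, function(sh) {
    inact <- fit_boltzmann(
      boltz_gv(10, -30 + sh, 7, seq(-120, 80, 5), type = "inactivation"),
      "inactivation")
    availability_window(act, inact)$window_max
  }, numeric(1))
  expect_true(all(diff(maxima) < 0))
})
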