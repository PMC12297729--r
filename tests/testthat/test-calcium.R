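make_trace <- function(values, fs = 5) {
  sweep_set("fluorescence", "au", fs, matrix(values, ncol = 1))
}

test_that("dF/F normalization follows its closed forms", {
  # constant trace: dff identically zero (with f0 equal to the constant)
  d <- delta_f_over_f(make_trace(rep(80, 300)))
  expect_equal(d$f0, 80)
  expect_true(all(d$dff == 0))
  # plateau at twice baseline reads dff = 1
  f <- c(rep(100, 250), rep(200, 50))
  d2 <- delta_f_over_f(make_trace(f))
  expect_equal(d2$f0, 100)
  expect_equal(unique(d2$dff[251:300]), 1)
  # noiseless sinusoid: amplitude equals osc_amp when F0 is the mean
  tr <- make_fluorescence_trace(calcium_ground_truth(osc_amp = 0.3,
                                                     noise_sd = 0))
  d3 <- delta_f_over_f(tr, f0_method = "mean")
  expect_equal((max(d3$dff) - min(d3$dff)) / 2, 0.3, tolerance = 0.02 * 0.3)
  expect_error(delta_f_over_f(make_trace(rep(0, 300))), "F0")
})

test_that("the spectrum locates a pure oscillation and conserves variance", {
  tr <- make_fluorescence_trace(calcium_ground_truth(osc_freq = 0.05,
                                                     osc_amp = 0.3,
                                                     noise_sd = 0))
  d <- delta_f_over_f(tr)
  sp <- compute_spectrum(d)
  df <- d$sampling_rate / length(d$dff)
  expect_equal(sp$band_peak_freq, 0.05, tolerance = df + 1e-12)
  expect_equal(sp$band_peak_psd, max(sp$psd[sp$freqs > 0 & sp$freqs <= 0.1]))
  # Parseval: integral of the one-sided PSD equals the variance of the
  # tapered mean-subtracted signal (recomputed here from scratch)
  x <- d$dff
  n <- length(x)
  x <- stats::residuals(stats::lm(x ~ seq_len(n)))
  x <- x - mean(x)
  y <- x * 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  y <- y - mean(y)
  expect_equal(sum(sp$psd) * df, mean(y^2), tolerance = 0.01 * mean(y^2))
  # degenerate and invalid inputs
  z <- delta_f_over_f(make_trace(rep(10, 300)))
  expect_true(all(compute_spectrum(z)$psd == 0))
  expect_error(compute_spectrum(d, band = c(0, 3)), "Nyquist|band")
  expect_error(compute_spectrum(delta_f_over_f(make_trace(rep(10, 32)))),
               "64")
})

test_that("spectral statistics match an independent periodogram oracle on noise", {
  # white-noise traces: the package's band peak and the oracle's agree
  # bin-for-bin, and the signal/noise contrast on the 3x-band-median bar
  # separates oscillating from noise-only traces
  fs <- 5; n <- 300
  bar_noise <- logical(100); bar_osc <- logical(100)
  for (s in 1:100) {
    tr <- make_fluorescence_trace(
      calcium_ground_truth(osc_amp = 0, noise_sd = 0.05), seed = s)
    d <- delta_f_over_f(tr)
    sp <- compute_spectrum(d)
    # oracle from scratch
    x <- d$dff
    x <- stats::residuals(stats::lm(x ~ seq_len(n)))
    x <- x - mean(x)
    y <- x * 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
    y <- y - mean(y)
    X <- stats::fft(y)
    half <- 1:(n / 2 + 1)
    sc <- rep(2, length(half)); sc[1] <- 1; sc[length(half)] <- 1
    psd_or <- unname(sc * Mod(X[half])^2 / (fs * n))
    freqs_or <- (half - 1) * fs / n
    expect_equal(sp$psd, psd_or, tolerance = 1e-12)
    inb <- freqs_or > 1e-12 & freqs_or <= 0.1 + 1e-12
    bar_noise[s] <- max(psd_or[inb]) > 3 * stats::median(psd_or[inb])
    tro <- make_fluorescence_trace(
      calcium_ground_truth(osc_freq = 0.05, osc_amp = 0.3, noise_sd = 0.05),
      seed = s)
    spo <- compute_spectrum(delta_f_over_f(tro))
    bp <- spo$psd[spo$freqs > 1e-12 & spo$freqs <= 0.1 + 1e-12]
    bar_osc[s] <- max(bp) > 3 * stats::median(bp)
  }
  expect_true(all(bar_osc))
  expect_lt(mean(bar_noise), mean(bar_osc))
})

test_that("event counting converts prominent peaks to events per minute", {
  expect_equal(event_frequency(delta_f_over_f(make_trace(rep(10, 300)))), 0)
  # three clean cycles over 60 s -> 3 events/min
  tr <- make_fluorescence_trace(calcium_ground_truth(osc_freq = 0.05,
                                                     osc_amp = 0.3,
                                                     noise_sd = 0))
  d <- delta_f_over_f(tr, f0_method = "mean")
  expect_equal(event_frequency(d, prominence = 0.2 * 2 * 0.3), 3)
  # noise-only traces with prominence far above the noise: no events
  for (s in 1:100) {
    trn <- make_fluorescence_trace(
      calcium_ground_truth(osc_amp = 0, noise_sd = 0.02), seed = s)
    expect_equal(event_frequency(delta_f_over_f(trn), prominence = 0.5), 0)
  }
  expect_error(event_frequency(d, prominence = 0), "positive")
})

test_that("the calcium pipeline is invariant to fluorescence scaling", {
  tr <- make_fluorescence_trace(calcium_ground_truth(osc_freq = 0.05,
                                                     osc_amp = 0.3,
                                                     noise_sd = 0.05),
                                seed = 9)
  d1 <- delta_f_over_f(tr)
  s1 <- compute_spectrum(d1)
  e1 <- event_frequency(d1)
  for (c_scale in c(0.2, 7)) {
    tr2 <- tr
    tr2$values <- tr$values * c_scale
    d2 <- delta_f_over_f(tr2)
    expect_equal(d2$dff, d1$dff, tolerance = 1e-12)
    expect_equal(compute_spectrum(d2)$psd, s1$psd, tolerance = 1e-10)
    expect_equal(event_frequency(d2), e1)
  }
})
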