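#' Baseline-normalized fluorescence (dF/F)
#'
#' Computes `dF/F = (F - F0) / F0` from a per-cell fluorescence trace. The
#' default baseline estimator is the mean of the lowest decile of the trace,
#' which is robust to calcium transients riding on the baseline.
#'
#' @param trace a fluorescence `sweep_set` (single sweep used unless `sweep`
#'   given), values >= 0.
#' @param f0_method `"lowest_decile"` (default), `"mean"`, `"median"`, or a
#'   single number to use as F0 directly.
#' @param sweep sweep index.
#' @return a list of class `dff_trace`: `sampling_rate` (Hz), `dff`
#'   (unitless, >= -1), `f0`.
#' @export
delta_f_over_f <- function(trace, f0_method = "lowest_decile", sweep = 1L) {
  validate_sweep_set(trace)
  if (trace$mode != "fluorescence" || trace$unit != "au")
    stop("delta_f_over_f needs a fluorescence trace")
  f <- trace$values[, sweep]
  if (any(f < 0)) stop("fluorescence values must be >= 0")
  f0 <- if (is.numeric(f0_method)) {
    f0_method
  } else {
    switch(f0_method,
           lowest_decile = mean(f[f <= stats::quantile(f, 0.1)]),
           mean = mean(f),
           median = stats::median(f),
           stop("unknown f0_method: ", f0_method))
  }
  if (f0 <= 0) stop("normalization error: F0 <= 0")
  structure(list(sampling_rate = trace$sampling_rate,
                 dff = (f - f0) / f0, f0 = f0),
            class = "dff_trace")
}

#' Power spectrum and PSD of a dF/F trace
#'
#' Single tapered periodogram of the (optionally linearly detrended)
#' mean-subtracted trace. The one-sided PSD is normalized so that its
#' integral over frequency equals the variance of the tapered,
#' mean-subtracted signal exactly (Parseval); `power` is the per-bin power
#' (PSD times the bin width). Band-limited peak statistics default to the
#' low-frequency band (0, 0.1] Hz in which slow spontaneous calcium
#' oscillations live.
#'
#' @param dff a `dff_trace` of at least 64 samples.
#' @param band `(lo, hi]` band in Hz for the peak statistics; must lie
#'   within (0, Nyquist].
#' @param window taper: `"hann"` or `"none"`.
#' @param detrend remove a linear trend first (on by default: slow drift
#'   otherwise masquerades as 0-0.02 Hz power).
#' @return a list of class `spectrum_result`: `freqs` (Hz), `power`, `psd`
#'   (power per Hz), `band`, `band_peak_psd`, `band_peak_freq`.
#' @export
compute_spectrum <- function(dff, band = c(0, 0.1), window = "hann",
                             detrend = TRUE) {
  x <- dff$dff
  n <- length(x)
  if (n < 64L) stop("need at least 64 samples for spectral analysis")
  fs <- dff$sampling_rate
  nyq <- fs / 2
  if (band[2L] > nyq + 1e-12 || band[1L] < 0 || band[2L] <= band[1L])
    stop("parameter error: band must lie within (0, Nyquist]")
  if (detrend) {
    t <- seq_len(n)
    x <- stats::residuals(stats::lm.fit(cbind(1, t), x))
  }
  x <- x - mean(x)
  w <- switch(window,
              hann = 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1))),
              none = rep(1, n),
              stop("unknown window: ", window))
  y <- x * w
  y <- y - mean(y)
  X <- stats::fft(y)
  half <- seq_len(floor(n / 2) + 1L)
  freqs <- (half - 1L) * fs / n
  scale <- rep(2, length(half))
  scale[1L] <- 1
  if (n %% 2L == 0L) scale[length(half)] <- 1
  psd <- scale * Mod(X[half])^2 / (fs * n)
  df <- fs / n
  in_band <- freqs > band[1L] + 1e-12 & freqs <= band[2L] + 1e-12
  if (!any(in_band)) stop("parameter error: band contains no frequency bins")
  bk <- which(in_band)[which.max(psd[in_band])]
  structure(list(freqs = freqs, power = psd * df, psd = psd,
                 band = band, band_peak_psd = psd[bk],
                 band_peak_freq = freqs[bk]),
            class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf(paste0("<spectrum_result> %d bins to %.3g Hz; band (%g, %g] ",
                     "Hz peak %.3g /Hz at %.3g Hz\n"),
              length(x$freqs), max(x$freqs), x$band[1L], x$band[2L],
              x$band_peak_psd, x$band_peak_freq))
  invisible(x)
}

# topographic prominence of one local maximum
.peak_prominence <- function(x, p) {
  n <- length(x)
  left_min <- x[p]
  i <- p
  while (i > 1L) {
    i <- i - 1L
    if (x[i] > x[p]) break
    left_min <- min(left_min, x[i])
  }
  right_min <- x[p]
  i <- p
  while (i < n) {
    i <- i + 1L
    if (x[i] > x[p]) break
    right_min <- min(right_min, x[i])
  }
  x[p] - max(left_min, right_min)
}

#' Calcium event frequency
#'
#' Counts local maxima of the dF/F trace with topographic prominence at
#' least `prominence`, expressed as events per minute.
#'
#' @param dff a `dff_trace`.
#' @param prominence minimum peak prominence in dF/F units (> 0).
#' @return events per minute.
#' @export
event_frequency <- function(dff, prominence = 0.2) {
  if (prominence <= 0) stop("prominence must be positive")
  x <- dff$dff
  n <- length(x)
  if (n < 3L) return(0)
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  k <- sum(vapply(cand, function(p) .peak_prominence(x, p), numeric(1L)) >=
             prominence)
  k / (n / dff$sampling_rate / 60)
}
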