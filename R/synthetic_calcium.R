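#' Calcium fluorescence ground truth
#'
#' Parameters of a simulated per-cell fluorescence trace: baseline intensity
#' plus a sinusoidal oscillation, a linear drift, and white Gaussian noise.
#'
#' @param f0 baseline fluorescence (arbitrary units, > 0).
#' @param osc_freq oscillation frequency in Hz.
#' @param osc_amp oscillation amplitude as a fraction of `f0` (>= 0).
#' @param noise_sd noise s.d. as a fraction of `f0` (>= 0).
#' @param drift_slope linear drift as a fraction of `f0` per second.
#' @return a list of class `calcium_ground_truth`.
#' @export
calcium_ground_truth <- function(f0 = 100, osc_freq = 0.05, osc_amp = 0.3,
                                 noise_sd = 0.05, drift_slope = 0) {
  if (f0 <= 0) stop("f0 must be positive")
  if (osc_freq <= 0) stop("osc_freq must be positive")
  if (osc_amp < 0 || noise_sd < 0)
    stop("osc_amp and noise_sd must be >= 0")
  structure(list(f0 = f0, osc_freq = osc_freq, osc_amp = osc_amp,
                 noise_sd = noise_sd, drift_slope = drift_slope),
            class = "calcium_ground_truth")
}

#' Simulate a fluorescence trace with known oscillation parameters
#'
#' `F(t) = f0 (1 + osc_amp sin(2 pi osc_freq t) + drift_slope t) + noise`,
#' with Gaussian noise of s.d. `noise_sd * f0`, clipped at zero. Defaults
#' emulate 60-s recordings imaged at 5 Hz.
#'
#' @param gt a [calcium_ground_truth()].
#' @param duration recording length in seconds.
#' @param sampling_rate imaging rate in Hz; `osc_freq` must stay below the
#'   Nyquist frequency.
#' @param seed integer seed.
#' @param cell_id,group_label identifiers stored on the recording.
#' @return a single-sweep `sweep_set` in arbitrary-fluorescence units with
#'   the ground truth in `metadata$ground_truth`.
#' @export
make_fluorescence_trace <- function(gt = calcium_ground_truth(),
                                    duration = 60, sampling_rate = 5,
                                    seed = 1L, cell_id = "sim_ca_001",
                                    group_label = NA_character_) {
  if (duration <= 0) stop("duration must be positive")
  if (gt$osc_freq >= sampling_rate / 2)
    stop("parameter error: osc_freq at or above the Nyquist frequency")
  set.seed(seed)
  n <- round(duration * sampling_rate)
  t <- (seq_len(n) - 1) / sampling_rate
  f <- gt$f0 * (1 + gt$osc_amp * sin(2 * pi * gt$osc_freq * t) +
                  gt$drift_slope * t) +
    stats::rnorm(n, 0, gt$noise_sd * gt$f0)
  f <- pmax(f, 0)
  sweep_set(
    mode = "fluorescence", unit = "au", sampling_rate = sampling_rate,
    values = matrix(f, ncol = 1L, dimnames = list(NULL, "F")),
    cell_id = cell_id, group_label = group_label,
    metadata = list(ground_truth = unclass(gt))
  )
}
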