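# shared fixture builders -- everything is generated in code at test time

# a current-clamp neuron whose stimulated sweeps contain templated
# excursions with the given peak voltages (one numeric vector per sweep)
neuron_from_peaks <- function(peaks_per_sweep, params = spike_template_params(),
                              fs = 10000, noise_sd = 0) {
  pre_s <- 0.1; step_s <- 1
  n <- round((pre_s + step_s + 0.1) * fs)
  t_ms <- (seq_len(n) - 1) / fs * 1000
  span <- spike_template_span(params)
  vals <- vapply(peaks_per_sweep, function(pks) {
    v <- rep(params$baseline_v, n)
    for (j in seq_along(pks)) {
      rel <- t_ms - pre_s * 1000 - 50 - (j - 1) * max(span + 20, 150)
      use <- rel >= 0 & rel <= span
      v[use] <- spike_waveform(rel[use], params, peak_v = pks[j])
    }
    v + if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
  }, numeric(n))
  colnames(vals) <- paste0("sweep", seq_along(peaks_per_sweep))
  sweep_set(
    mode = "current_clamp", unit = "mV", sampling_rate = fs, values = vals,
    steps = rep(list(list(onset_time = pre_s, duration = step_s,
                          level = 100, pre_level = 0)),
                length(peaks_per_sweep)))
}

# a resting (stimulus-free) recording at the given potential, optionally
# with one spontaneous spike spliced in
resting_neuron <- function(resting_v = -40, spike_peak = NULL, fs = 10000,
                           noise_sd = 0, dur_s = 1.2) {
  n <- round(dur_s * fs)
  v <- rep(resting_v, n)
  if (!is.null(spike_peak)) {
    p <- spike_template_params(threshold_v = resting_v - 10,
                               peak_v = max(spike_peak, resting_v + 1),
                               baseline_v = resting_v - 20)
    rel <- (seq_len(n) - 1) / fs * 1000 - 300
    use <- rel >= 0 & rel <= spike_template_span(p)
    v[use] <- pmax(spike_waveform(rel[use], p, peak_v = spike_peak), resting_v)
  }
  if (noise_sd > 0) v <- v + stats::rnorm(n, 0, noise_sd)
  sweep_set(mode = "current_clamp", unit = "mV", sampling_rate = fs,
            values = matrix(v, ncol = 1), steps = list(NULL))
}

# noiseless Boltzmann conductance table
boltz_gv <- function(gmax, v50, h, vc = seq(-120, 60, by = 10),
                     type = "activation") {
  occ <- if (type == "activation") 1 / (1 + exp((v50 - vc) / h))
  else 1 / (1 + exp((vc - v50) / h))
  data.frame(vc = vc, g = gmax * occ)
}

# per-class census of a cohort as classified by the package
classify_cohort <- function(neurons, min_rise = 15) {
  vapply(neurons, function(n) as.character(classify_induced(n, min_rise)),
         character(1L))
}
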