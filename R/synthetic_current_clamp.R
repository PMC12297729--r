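#' Spike template parameters
#'
#' Parameterizes the templated action-potential waveform used by the
#' current-clamp generator: a slow depolarizing ramp into a logistic
#' (sigmoidal) upstroke, followed by an exponential decay back to baseline.
#' The template is constructed so that the voltage at the maximum of the
#' third time-derivative of the upstroke equals `threshold_v`, which is what
#' the morphometry stage must recover.
#'
#' @param threshold_v spike threshold in mV.
#' @param peak_v peak voltage of an overshooting spike in mV (default +25,
#'   comfortably above the 0-mV overshoot rule).
#' @param rise_tau logistic time constant of the upstroke in ms.
#' @param decay_tau repolarization time constant in ms.
#' @param baseline_v holding baseline during the step in mV.
#' @param sub_peak_v peak voltage of a non-overshooting ("attempting")
#'   excursion in mV (default −20, comfortably below 0 mV).
#' @return a list of class `spike_template_params`.
#' @export
spike_template_params <- function(threshold_v = -40, peak_v = 25,
                                  rise_tau = 0.5, decay_tau = 4,
                                  baseline_v = -80, sub_peak_v = -20) {
  if (!(peak_v > threshold_v && threshold_v > baseline_v))
    stop("need peak_v > threshold_v > baseline_v")
  if (rise_tau <= 0 || decay_tau <= 0) stop("time constants must be positive")
  if (!(sub_peak_v > threshold_v))
    stop("sub_peak_v must exceed threshold_v")
  structure(list(threshold_v = threshold_v, peak_v = peak_v,
                 rise_tau = rise_tau, decay_tau = decay_tau,
                 baseline_v = baseline_v, sub_peak_v = sub_peak_v),
            class = "spike_template_params")
}

# Logistic geometry: the third derivative of 1/(1+exp(-x)) peaks at
# x* = -2.29243, where the logistic has value s* = 0.0917518.  The upstroke
# low point is placed so that the template voltage at x* equals threshold_v.
.LOGIS_XSTAR <- -2.292431
.LOGIS_SSTAR <- 0.09175185
.LOGIS_SPAN <- 6          # upstroke spans x in [-span, +span]
.RAMP_MS <- 20            # slow depolarizing approach before the upstroke

#' Evaluate the spike template waveform
#'
#' Analytic waveform of one templated excursion, as a function of time from
#' excursion onset. Used by the generator and, on a dense grid, as the
#' independent oracle for threshold detection.
#'
#' @param t_ms time from excursion onset in ms (vector).
#' @param params a [spike_template_params()].
#' @param peak_v peak voltage of this excursion (defaults to the template's
#'   overshooting peak).
#' @return voltage in mV at each `t_ms`; baseline outside the excursion.
#' @export
spike_waveform <- function(t_ms, params, peak_v = params$peak_v) {
  thr <- params$threshold_v
  tau_r <- params$rise_tau
  tau_d <- params$decay_tau
  t_j <- .RAMP_MS                       # ramp -> upstroke junction
  t_m <- t_j + .LOGIS_SPAN * tau_r      # logistic midpoint
  t_p <- t_m + .LOGIS_SPAN * tau_r      # nominal peak time
  logis <- function(x) 1 / (1 + exp(-x))
  # smooth ("softplus-gated") exponential decay around t_p: ~1 before the
  # peak, ~exp(-(t - t_p)/tau) after, infinitely differentiable
  soft_decay <- function(t, tau) {
    u <- (t - t_p) / tau_r
    exp(-(tau_r / tau) * log1p(exp(pmin(u, 500))))
  }
  # normalize the rise-fall product to unit maximum so the excursion peak
  # hits peak_v exactly
  xg <- seq(-2, .LOGIS_SPAN + 6, by = 0.02)
  m_norm <- max(logis(xg) * soft_decay(t_m + xg * tau_r, tau_d))
  shape <- function(t) logis((t - t_m) / tau_r) * soft_decay(t, tau_d) / m_norm
  # place the upstroke floor so the voltage at the third-derivative maximum
  # of the logistic equals the nominal threshold
  s_eff <- .LOGIS_SSTAR / m_norm
  v_low <- (thr - peak_v * s_eff) / (1 - s_eff)
  base <- params$baseline_v
  # quintic smoothstep ramp gate (zero 1st/2nd derivatives at both ends) --
  # every term below is at least C^2 in t, so the third derivative of the
  # composite is dominated by the logistic foot, not by junction artifacts
  u <- pmin(pmax(t_ms / t_j, 0), 1)
  s5 <- 6 * u^5 - 15 * u^4 + 10 * u^3
  # the spike rides on a floor that ramps up and then relaxes slowly back
  floor_v <- base + (v_low - base) * s5 * soft_decay(t_ms, 4 * tau_d)
  v <- floor_v + (peak_v - floor_v) * shape(t_ms)
  v[t_ms < 0] <- params$baseline_v
  v
}

#' Duration of one templated excursion
#' @param params a [spike_template_params()].
#' @return approximate excursion footprint in ms (ramp + upstroke + decay).
#' @export
spike_template_span <- function(params) {
  .RAMP_MS + 2 * .LOGIS_SPAN * params$rise_tau + 40 * params$decay_tau
}

#' Activity-class level sets
#'
#' Ordered levels of the induced five-category coding and of the
#' non-induced two-category coding.
#' @name activity_levels
NULL

#' @rdname activity_levels
#' @export
induced_levels <- c("Quiet", "AttemptingSingle", "Single",
                    "AttemptingTrain", "Train")

#' @rdname activity_levels
#' @export
noninduced_levels <- c("Quiet", "Spontaneous")

# excursion peak pattern realizing each induced class under the rules
.class_pattern <- function(class, params) {
  over <- params$peak_v
  sub <- params$sub_peak_v
  switch(class,
         Quiet = numeric(0),
         AttemptingSingle = c(sub),
         Single = c(over),
         AttemptingTrain = c(over, sub, sub),
         Train = c(over, over, over),
         stop("unknown activity class: ", class))
}

#' Simulate a current-clamp cohort with known activity classes
#'
#' Builds one `sweep_set` per simulated neuron, each carrying a 1-s
#' current-injection step family from −10 to +190 pA plus a 1-s
#' stimulus-free resting sweep. Sweeps at or above a per-neuron threshold
#' level carry templated excursions realizing the requested induced activity
#' class by construction; sweeps below it stay at baseline. The true class
#' is recorded in `metadata$true_class`. Output is deterministic for a fixed
#' seed.
#'
#' @param class_counts named integer vector or list mapping induced class
#'   names (see [induced_levels]) to neuron counts.
#' @param params a [spike_template_params()].
#' @param seed integer seed; all randomness derives from it.
#' @param step_levels injected current levels in pA.
#' @param noise_sd recording noise s.d. in mV (Gaussian, white).
#' @param resting_v resting membrane potential of the simulated neurons in
#'   mV (the stimulus-free sweep sits here).
#' @param n_spontaneous number of neurons (chosen at random from the cohort)
#'   whose resting sweep additionally contains a spontaneous overshooting
#'   spike.
#' @param group_label group tag stored on every neuron.
#' @return a list of `sweep_set` objects, one per neuron.
#' @export
make_current_clamp_cohort <- function(class_counts,
                                      params = spike_template_params(),
                                      seed = 1L,
                                      step_levels = seq(-10, 190, by = 20),
                                      noise_sd = 0.5,
                                      resting_v = -35,
                                      n_spontaneous = 0L,
                                      group_label = NA_character_) {
  counts <- unlist(class_counts)
  if (is.null(names(counts)) || !all(names(counts) %in% induced_levels))
    stop("class_counts must be named with induced activity classes")
  if (any(counts < 0) || sum(counts) < 1)
    stop("counts must be non-negative with at least one neuron")
  for (cl in names(counts)[counts > 0]) {
    pat <- .class_pattern(cl, params)
    if (cl %in% c("Single", "AttemptingTrain", "Train") && params$peak_v <= 0)
      stop("parameter error: class ", cl,
           " needs an overshooting template (peak_v > 0)")
    if (cl %in% c("AttemptingSingle", "AttemptingTrain") &&
        params$sub_peak_v > 0)
      stop("parameter error: class ", cl,
           " needs a non-overshooting template (sub_peak_v <= 0)")
    if (length(pat) > 0 && any(pat - params$baseline_v < 15))
      stop("parameter error: template excursions are not significant ",
           "(rise above baseline < 15 mV)")
  }
  fs <- 10000
  pre_s <- 0.1; step_s <- 1; post_s <- 0.1
  n_step_samp <- round((pre_s + step_s + post_s) * fs)
  n_rest_samp <- n_step_samp
  classes <- rep(names(counts), counts)
  set.seed(seed)
  classes <- sample(classes)              # shuffle cohort order
  spont_ids <- if (n_spontaneous > 0)
    sample(seq_along(classes), min(n_spontaneous, length(classes))) else
    integer(0)
  span_ms <- spike_template_span(params)
  lapply(seq_along(classes), function(i) {
    cl <- classes[i]
    pat <- .class_pattern(cl, params)
    # excursions appear on sweeps at/above a random positive "rheobase" level
    pos <- which(step_levels > 0)
    rheo_idx <- if (length(pos)) sample(pos, 1L) else length(step_levels)
    first_ms <- 50 + stats::runif(1, 0, 50)
    gap_ms <- max(span_ms + 20, 150)
    onsets_ms <- first_ms + (seq_along(pat) - 1) * gap_ms
    t_ms <- (seq_len(n_step_samp) - 1) / fs * 1000
    step_on_ms <- pre_s * 1000
    vals <- vapply(seq_along(step_levels), function(k) {
      v <- rep(params$baseline_v, n_step_samp)
      if (length(pat) > 0 && k >= rheo_idx) {
        for (j in seq_along(pat)) {
          rel <- t_ms - step_on_ms - onsets_ms[j]
          use <- rel >= 0 & rel <= span_ms
          v[use] <- spike_waveform(rel[use], params, peak_v = pat[j])
        }
      }
      v + stats::rnorm(n_step_samp, 0, noise_sd)
    }, numeric(n_step_samp))
    rest <- rep(resting_v, n_rest_samp)
    if (i %in% spont_ids) {
      on_ms <- stats::runif(1, 100, 800)
      rel <- (seq_len(n_rest_samp) - 1) / fs * 1000 - on_ms
      use <- rel >= 0 & rel <= span_ms
      # spontaneous spike rides on the resting potential: only the part of
      # the template above rest is spliced in
      rest[use] <- pmax(spike_waveform(rel[use], params), resting_v)
    }
    rest <- rest + stats::rnorm(n_rest_samp, 0, noise_sd)
    vals <- cbind(rest, vals)
    colnames(vals) <- c("rest", paste0("step_", step_levels, "pA"))
    steps <- c(list(NULL), lapply(step_levels, function(lv)
      list(onset_time = pre_s, duration = step_s, level = lv, pre_level = 0)))
    sweep_set(
      mode = "current_clamp", unit = "mV", sampling_rate = fs,
      values = vals, steps = steps,
      cell_id = sprintf("sim_cell_%03d", i),
      group_label = group_label,
      metadata = list(true_class = cl,
                      spontaneous = i %in% spont_ids,
                      template = unclass(params))
    )
  })
}
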