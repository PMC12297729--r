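#' Detect depolarizing excursions during a current step
#'
#' Finds significant excursions from baseline within the stimulus window of
#' one current-clamp sweep. The within-step baseline is the median of the
#' first 10 ms of the step response (after a short settling blank). An
#' excursion is a region whose local peak exceeds baseline by at least
#' `min_rise` mV; successive excursions are separated by a return below
#' baseline + `min_rise`/2 (hysteresis).
#'
#' @param neuron a current-clamp `sweep_set` in mV.
#' @param sweep sweep index to analyse.
#' @param min_rise significance threshold in mV (default 15).
#' @param settle_ms settling blank at step onset, excluded from the baseline
#'   estimate (ms).
#' @return a data.frame with one row per excursion: `onset_index`,
#'   `peak_index` (absolute sample indices), `peak_v` (mV) and `overshoots`
#'   (`peak_v > 0`), ordered by onset.
#' @export
detect_excursions <- function(neuron, sweep = 1L, min_rise = 15,
                              settle_ms = 1) {
  validate_sweep_set(neuron)
  if (neuron$unit != "mV") stop("detect_excursions needs a voltage trace (mV)")
  st <- neuron$steps[[sweep]]
  if (is.null(st)) stop("protocol error: sweep ", sweep, " has no stimulus step")
  fs <- neuron$sampling_rate
  i0 <- round(st$onset_time * fs) + 1L
  i1 <- min(round((st$onset_time + st$duration) * fs), nrow(neuron$values))
  if ((i1 - i0 + 1L) / fs < 0.010)
    stop("protocol error: step window shorter than 10 ms")
  v <- neuron$values[, sweep]
  b0 <- i0 + round(settle_ms / 1000 * fs)
  b1 <- min(b0 + round(0.010 * fs) - 1L, i1)
  baseline <- stats::median(v[b0:b1])
  .find_excursions(v, i0, i1, baseline, min_rise)
}

# hysteresis scan shared by induced and spontaneous detection
.find_excursions <- function(v, i0, i1, baseline, min_rise) {
  hi <- baseline + min_rise
  lo <- baseline + min_rise / 2
  w <- v[i0:i1]
  above_lo <- w > lo
  if (!any(above_lo)) {
    return(data.frame(onset_index = integer(0), peak_index = integer(0),
                      peak_v = numeric(0), overshoots = logical(0)))
  }
  r <- rle(above_lo)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- lapply(which(r$values), function(k) {
    seg <- starts[k]:ends[k]
    pk <- seg[which.max(w[seg])]
    if (w[pk] < hi) return(NULL)
    data.frame(onset_index = i0 + starts[k] - 1L,
               peak_index = i0 + pk - 1L,
               peak_v = w[pk], overshoots = w[pk] > 0)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(out))
    out <- data.frame(onset_index = integer(0), peak_index = integer(0),
                      peak_v = numeric(0), overshoots = logical(0))
  rownames(out) <- NULL
  out
}

.sweep_class <- function(exc) {
  n <- nrow(exc)
  n_over <- sum(exc$overshoots)
  if (n == 0L) "Quiet"
  else if (n_over == 0L) "AttemptingSingle"
  else if (n == 1L) "Single"                 # one excursion, it overshoots
  else if (n_over == 1L) "AttemptingTrain"   # several, exactly one overshoots
  else "Train"                               # several, >= 2 overshoot
}

#' Classify induced action-potential activity of a neuron
#'
#' Applies the five-category induced-activity coding to every stimulated
#' sweep and reduces to a neuron-level class as the maximum under the
#' ordering Quiet < AttemptingSingle < Single < AttemptingTrain < Train.
#' Per sweep: no excursions is Quiet; excursions but none overshooting 0 mV
#' is AttemptingSingle; a single overshooting excursion is Single; several
#' excursions with exactly one overshooting is AttemptingTrain; at least two
#' overshooting is Train. The 0-mV overshoot criterion is absolute, not
#' baseline-relative.
#'
#' @param neuron a current-clamp `sweep_set` with an induced-step protocol.
#' @param min_rise significance threshold in mV passed to
#'   [detect_excursions()].
#' @return an ordered factor of length 1 with levels [induced_levels].
#' @export
classify_induced <- function(neuron, min_rise = 15) {
  validate_sweep_set(neuron)
  if (neuron$mode != "current_clamp")
    stop("classify_induced needs a current-clamp recording")
  stim <- which(!vapply(neuron$steps, is.null, logical(1L)))
  if (length(stim) == 0L)
    stop("protocol error: no sweeps with stimulus steps")
  cls <- vapply(stim, function(i)
    .sweep_class(detect_excursions(neuron, i, min_rise)), character(1L))
  best <- induced_levels[max(match(cls, induced_levels))]
  factor(best, levels = induced_levels, ordered = TRUE)
}

#' Classify non-induced (spontaneous) activity of a neuron
#'
#' A neuron is Spontaneous when at least one overshooting excursion occurs
#' in a stimulus-free recording, else Quiet. The baseline is the median of
#' the stimulus-free trace.
#'
#' @param neuron a current-clamp `sweep_set` containing at least one
#'   stimulus-free sweep.
#' @param min_rise significance threshold in mV.
#' @return an ordered factor of length 1 with levels [noninduced_levels].
#' @export
classify_spontaneous <- function(neuron, min_rise = 15) {
  validate_sweep_set(neuron)
  free <- which(vapply(neuron$steps, is.null, logical(1L)))
  if (length(free) == 0L)
    stop("protocol error: no stimulus-free segment present")
  spont <- any(vapply(free, function(i) {
    v <- neuron$values[, i]
    exc <- .find_excursions(v, 1L, length(v), stats::median(v), min_rise)
    any(exc$overshoots)
  }, logical(1L)))
  factor(if (spont) "Spontaneous" else "Quiet",
         levels = noninduced_levels, ordered = TRUE)
}

#' Resting membrane potential
#'
#' Median voltage over the first stimulus-free segment of at least 1 s.
#' The median is robust to occasional spontaneous spikes.
#'
#' @param neuron a current-clamp `sweep_set`.
#' @return resting membrane potential in mV.
#' @export
resting_vm <- function(neuron) {
  validate_sweep_set(neuron)
  free <- which(vapply(neuron$steps, is.null, logical(1L)))
  if (length(free) == 0L || nrow(neuron$values) / neuron$sampling_rate < 1)
    stop("protocol error: no stimulus-free segment of at least 1 s")
  stats::median(neuron$values[, free[1L]])
}

#' Input resistance from a hyperpolarizing current step
#'
#' `R = (steady-state V - pre-step baseline V) / injected current`, with the
#' steady state taken as the mean of the last 20% of the step. Reported in
#' megaohms (mV / nA).
#'
#' @param neuron a current-clamp `sweep_set`.
#' @param sweep index of the sweep carrying the hyperpolarizing step.
#' @return input resistance in MOhm.
#' @export
input_resistance <- function(neuron, sweep = 1L) {
  validate_sweep_set(neuron)
  st <- neuron$steps[[sweep]]
  if (is.null(st)) stop("protocol error: sweep has no stimulus step")
  if (st$level == 0) stop("step level is zero: cannot divide by zero current")
  if (st$level > 0)
    stop("domain error: input resistance needs a hyperpolarizing step")
  fs <- neuron$sampling_rate
  v <- neuron$values[, sweep]
  i0 <- round(st$onset_time * fs) + 1L
  i1 <- min(round((st$onset_time + st$duration) * fs), length(v))
  pre <- if (i0 > 1L) mean(v[seq_len(i0 - 1L)]) else
    stop("protocol error: no pre-step baseline samples")
  ss0 <- i1 - round(0.2 * (i1 - i0)) + 1L
  dv <- mean(v[ss0:i1]) - pre
  r <- dv / (st$level / 1000)  # mV / nA = MOhm
  if (r == 0) warning("implausible input resistance of 0 MOhm")
  r
}
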