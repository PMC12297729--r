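#' Boltzmann steady-state occupancy
#'
#' `1 / (1 + exp((v50 - v) / h))`: increasing in `v` for `h > 0`
#' (activation), decreasing for `h < 0` (inactivation).
#'
#' @param v membrane voltage in mV (vector).
#' @param v50 half-maximal voltage in mV.
#' @param h slope factor in mV; sign sets the direction.
#' @return occupancy in \[0, 1\].
#' @export
boltzmann <- function(v, v50, h) 1 / (1 + exp((v50 - v) / h))

#' Voltage-gated conductance ground truth
#'
#' Parameters of one simulated conductance: maximal conductance, activation
#' and inactivation Boltzmann curves, reversal potential and activation time
#' constant. A non-inactivating conductance (e.g. a delayed-rectifier
#' K\eqn{^+}-like current) is declared with `v50_inact = NA`.
#'
#' @param gmax maximal conductance in nS.
#' @param v50_act,h_act activation midpoint (mV) and slope (mV, > 0).
#' @param v50_inact,h_inact inactivation midpoint (mV) and slope (mV, < 0:
#'   the curve decreases with voltage); both `NA` for a non-inactivating
#'   conductance.
#' @param e_rev reversal potential in mV.
#' @param kinetic_tau activation time constant in ms.
#' @param inact_tau inactivation relaxation time constant in ms (ignored for
#'   non-inactivating conductances).
#' @return a list of class `gating_ground_truth`.
#' @export
gating_ground_truth <- function(gmax, v50_act, h_act,
                                v50_inact = NA, h_inact = NA,
                                e_rev, kinetic_tau, inact_tau = 5) {
  if (gmax <= 0) stop("gmax must be positive")
  if (h_act <= 0) stop("h_act must be positive (activation increases with V)")
  if (!is.na(h_inact) && h_inact >= 0)
    stop("h_inact must be negative (inactivation decreases with V)")
  if (kinetic_tau <= 0 || inact_tau <= 0)
    stop("time constants must be positive")
  structure(list(gmax = gmax, v50_act = v50_act, h_act = h_act,
                 v50_inact = v50_inact, h_inact = h_inact,
                 e_rev = e_rev, kinetic_tau = kinetic_tau,
                 inact_tau = inact_tau),
            class = "gating_ground_truth")
}

#' Na+-like and K+-like gating defaults
#'
#' Defaults for the simulated transient inward Na\eqn{^+}-like current
#' (fast-activating, inactivating, E\eqn{_{rev}} = +66.7 mV) and the
#' sustained outward K\eqn{^+}-like current (slower, non-inactivating,
#' E\eqn{_{rev}} = −90 mV).
#'
#' @param gmax maximal conductance in nS.
#' @name gating_defaults
NULL

#' @rdname gating_defaults
#' @export
na_gating <- function(gmax = 30) {
  gating_ground_truth(gmax = gmax, v50_act = -30, h_act = 7,
                      v50_inact = -61.7, h_inact = -7,
                      e_rev = 66.7, kinetic_tau = 0.5, inact_tau = 5)
}

#' @rdname gating_defaults
#' @export
k_gating <- function(gmax = 20) {
  gating_ground_truth(gmax = gmax, v50_act = -20, h_act = 10,
                      e_rev = -90, kinetic_tau = 8)
}

# sustained (delayed-rectifier-like) onset: fourth-power activation gives
# the sigmoidal delay that keeps the early inward-peak window clean
.sustained_shape <- function(t_ms, tau) (1 - exp(-t_ms / tau))^4

.avail_at <- function(gt, v) {
  if (is.na(gt$v50_inact)) rep(1, length(v)) else
    boltzmann(v, gt$v50_inact, gt$h_inact)
}

#' Closed-form noiseless peak current of a simulated conductance
#'
#' Peak current at each command potential for the activation protocol:
#' `gmax * act_inf(vc) * inact_inf(v_hold) * (vc - e_rev)`. The availability
#' factor at the holding potential is constant across command steps, so it
#' rescales the apparent maximal conductance without displacing V50 or h.
#'
#' @param gt a [gating_ground_truth()].
#' @param vc command potential(s) in mV.
#' @param v_hold holding potential in mV.
#' @return peak current in pA (negative for inward at `vc < e_rev`).
#' @export
vc_peak_current <- function(gt, vc, v_hold = -70) {
  gt$gmax * boltzmann(vc, gt$v50_act, gt$h_act) *
    .avail_at(gt, v_hold) * (vc - gt$e_rev)
}

#' Choose gmax to hit a target peak current density
#'
#' Solves for the maximal conductance that makes the noiseless peak current
#' density over a command-voltage grid equal `target_density` (pA/pF).
#' Useful for constructing cohorts with a prescribed peak density.
#'
#' @param gt a [gating_ground_truth()] whose `gmax` acts as a placeholder.
#' @param capacitance cell capacitance in pF.
#' @param target_density target peak density in pA/pF (signed: negative for
#'   inward currents).
#' @param vc_grid command potentials over which the peak is taken.
#' @param v_hold holding potential in mV.
#' @return the required gmax in nS.
#' @export
gmax_for_peak_density <- function(gt, capacitance, target_density,
                                  vc_grid = seq(-120, 80, by = 10),
                                  v_hold = -70) {
  per_ns <- vc_peak_current(
    gating_ground_truth(gmax = 1, v50_act = gt$v50_act, h_act = gt$h_act,
                        v50_inact = gt$v50_inact, h_inact = gt$h_inact,
                        e_rev = gt$e_rev, kinetic_tau = gt$kinetic_tau,
                        inact_tau = gt$inact_tau),
    vc_grid, v_hold) / capacitance
  extreme <- if (target_density < 0) min(per_ns) else max(per_ns)
  if (extreme == 0) stop("conductance produces no current on this grid")
  target_density / extreme
}

# transient conductance time course, normalized to unit peak
.transient_shape <- function(t_ms, gt, vc, v_hold) {
  act <- 1 - exp(-t_ms / gt$kinetic_tau)
  if (is.na(gt$v50_inact)) return(act)
  avail0 <- .avail_at(gt, v_hold)
  r <- min(1, .avail_at(gt, vc) / avail0)   # relative steady availability
  shape <- act * (r + (1 - r) * exp(-t_ms / gt$inact_tau))
  peak <- max(shape)
  if (peak > 0) shape / peak else shape
}

#' Simulate voltage-clamp recordings with known gating ground truth
#'
#' Produces the two standard protocols as `sweep_set`s:
#' \describe{
#'   \item{activation}{holding −70 mV, 80-ms steps from −120 to +80 mV.
#'     Current at each command step Vc is
#'     `I(t) = gNa(Vc,t) (Vc − eNa) + gK(Vc,t) (Vc − eK) + noise`, with the
#'     Na-like conductance transiently activating then inactivating
#'     (exponential kinetics) and the K-like conductance sustained. The
#'     noiseless peak inward current equals [vc_peak_current()] exactly.}
#'   \item{inactivation}{200-ms pre-pulses from −120 to +80 mV in 5-mV
#'     increments, then a 200-ms test step to 0 mV; the peak test current is
#'     proportional to the steady-state availability at the pre-pulse
#'     voltage. Step metadata records the pre-pulse as `level`; the test
#'     potential is in `metadata$v_test`.}
#' }
#'
#' @param na [gating_ground_truth()] of the transient inward conductance.
#' @param k [gating_ground_truth()] of the sustained outward conductance.
#' @param capacitance cell capacitance in pF (> 0).
#' @param noise_sd recording noise s.d. in pA (>= 0).
#' @param seed integer seed.
#' @param act_steps command potentials of the activation protocol in mV.
#' @param inact_prepulses pre-pulse potentials of the inactivation protocol
#'   in mV.
#' @param v_hold holding potential in mV.
#' @param cell_id,group_label identifiers stored on the recordings.
#' @return a list with elements `activation` and `inactivation`, each a
#'   `sweep_set` in pA with the ground truth in `metadata`.
#' @export
make_voltage_clamp_recording <- function(na = na_gating(), k = k_gating(),
                                         capacitance = 10, noise_sd = 0,
                                         seed = 1L,
                                         act_steps = seq(-120, 80, by = 10),
                                         inact_prepulses = seq(-120, 80, by = 5),
                                         v_hold = -70,
                                         cell_id = "sim_vc_001",
                                         group_label = NA_character_) {
  if (capacitance <= 0) stop("capacitance must be positive")
  if (noise_sd < 0) stop("parameter error: noise_sd must be >= 0")
  set.seed(seed)
  fs <- 10000
  gt_meta <- list(na = unclass(na), k = unclass(k), v_hold = v_hold)

  ## activation protocol: 20 ms hold, 80 ms step, 20 ms hold
  pre_s <- 0.02; step_s <- 0.08; post_s <- 0.02
  n <- round((pre_s + step_s + post_s) * fs)
  t_ms <- (seq_len(n) - 1) / fs * 1000
  on_ms <- pre_s * 1000; off_ms <- (pre_s + step_s) * 1000
  act_vals <- vapply(act_steps, function(vc) {
    i <- numeric(n)
    in_step <- t_ms >= on_ms & t_ms < off_ms
    ts <- t_ms[in_step] - on_ms
    i_na <- vc_peak_current(na, vc, v_hold) * .transient_shape(ts, na, vc, v_hold)
    i_k <- k$gmax * boltzmann(vc, k$v50_act, k$h_act) *
      .sustained_shape(ts, k$kinetic_tau) * (vc - k$e_rev)
    i[in_step] <- i_na + i_k
    i + stats::rnorm(n, 0, noise_sd)
  }, numeric(n))
  colnames(act_vals) <- paste0("vc_", act_steps, "mV")
  act <- sweep_set(
    mode = "voltage_clamp", unit = "pA", sampling_rate = fs,
    values = act_vals,
    steps = lapply(act_steps, function(vc)
      list(onset_time = pre_s, duration = step_s, level = vc,
           pre_level = v_hold)),
    cell_id = cell_id, capacitance = capacitance, group_label = group_label,
    metadata = c(gt_meta, list(protocol = "activation"))
  )

  ## inactivation protocol: 20 ms hold, 200 ms pre-pulse, 200 ms test at 0 mV
  pre_s2 <- 0.02; prep_s <- 0.2; test_s <- 0.2
  v_test <- 0
  n2 <- round((pre_s2 + prep_s + test_s) * fs)
  t2 <- (seq_len(n2) - 1) / fs * 1000
  prep_on <- pre_s2 * 1000; test_on <- (pre_s2 + prep_s) * 1000
  inact_vals <- vapply(inact_prepulses, function(vp) {
    i <- numeric(n2)
    in_prep <- t2 >= prep_on & t2 < test_on
    tp <- t2[in_prep] - prep_on
    # pre-pulse currents: transient at the pre-pulse potential itself
    i[in_prep] <- vc_peak_current(na, vp, v_hold) *
      .transient_shape(tp, na, vp, v_hold) +
      k$gmax * boltzmann(vp, k$v50_act, k$h_act) *
      .sustained_shape(tp, k$kinetic_tau) * (vp - k$e_rev)
    in_test <- t2 >= test_on
    tt <- t2[in_test] - test_on
    # availability set by the (long) pre-pulse
    i_na <- na$gmax * boltzmann(v_test, na$v50_act, na$h_act) *
      .avail_at(na, vp) * (v_test - na$e_rev) *
      (1 - exp(-tt / na$kinetic_tau)) * exp(-tt / na$inact_tau) /
      max((1 - exp(-tt / na$kinetic_tau)) * exp(-tt / na$inact_tau))
    i_k <- k$gmax * boltzmann(v_test, k$v50_act, k$h_act) *
      .sustained_shape(tt, k$kinetic_tau) * (v_test - k$e_rev)
    i[in_test] <- i_na + i_k
    i + stats::rnorm(n2, 0, noise_sd)
  }, numeric(n2))
  colnames(inact_vals) <- paste0("vpre_", inact_prepulses, "mV")
  inact <- sweep_set(
    mode = "voltage_clamp", unit = "pA", sampling_rate = fs,
    values = inact_vals,
    steps = lapply(inact_prepulses, function(vp)
      list(onset_time = pre_s2 + prep_s, duration = test_s, level = vp,
           pre_level = v_hold)),
    cell_id = cell_id, capacitance = capacitance, group_label = group_label,
    metadata = c(gt_meta, list(protocol = "inactivation", v_test = v_test))
  )
  list(activation = act, inactivation = inact)
}
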