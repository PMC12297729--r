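#' Peak current extraction from a voltage-clamp recording
#'
#' Per command step: the peak inward current is the minimum in an early
#' window (first `inward_ms` after step onset, with the first `blank_ms`
#' blanked to skip the capacitive transient) and the peak (sustained)
#' outward current is the mean of the last 20% of the step. Densities are
#' the peaks divided by the cell capacitance when it is known.
#'
#' @param rec a voltage-clamp `sweep_set` in pA with per-sweep command
#'   levels.
#' @param density report current densities (requires capacitance).
#' @param blank_ms capacitive-transient blanking at step onset (ms).
#' @param inward_ms width of the early inward-peak window (ms).
#' @return a data.frame of I-V points: `vc` (mV), `peak_inward`,
#'   `peak_outward` (pA) and, when requested, `inward_density`,
#'   `outward_density` (pA/pF).
#' @export
extract_peak_currents <- function(rec, density = !is.na(rec$capacitance),
                                  blank_ms = 0.3, inward_ms = 10) {
  validate_sweep_set(rec)
  if (rec$mode != "voltage_clamp")
    stop("extract_peak_currents needs a voltage-clamp recording")
  if (density && is.na(rec$capacitance))
    stop("parameter error: density requested but capacitance is missing")
  fs <- rec$sampling_rate
  rows <- lapply(seq_len(n_sweeps(rec)), function(k) {
    st <- rec$steps[[k]]
    if (is.null(st)) return(NULL)
    i <- rec$values[, k]
    i0 <- round(st$onset_time * fs) + 1L
    i1 <- min(round((st$onset_time + st$duration) * fs), length(i))
    e0 <- min(i0 + round(blank_ms / 1000 * fs), i1)
    e1 <- min(i0 + round(inward_ms / 1000 * fs), i1)
    ss0 <- i1 - round(0.2 * (i1 - i0)) + 1L
    data.frame(vc = st$level,
               peak_inward = min(i[e0:e1]),
               peak_outward = mean(i[ss0:i1]))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("protocol error: no sweeps with command steps")
  # sign convention: inward <= 0 <= outward
  out$peak_inward <- pmin(out$peak_inward, 0)
  out$peak_outward <- pmax(out$peak_outward, 0)
  if (density) {
    out$inward_density <- out$peak_inward / rec$capacitance
    out$outward_density <- out$peak_outward / rec$capacitance
  }
  rownames(out) <- NULL
  out
}

#' Conductance transform of an I-V relation
#'
#' `G(vc) = I(vc) / (vc - e_rev)`: current divided by driving force, the
#' default reversal being E_Na = +66.7 mV for the inward branch. Points at
#' exactly `vc = e_rev` are excluded with a warning (zero driving force).
#' For the inward activation branch only steps with `vc < e_rev` are used:
#' beyond reversal the branch is ill-defined. For inactivation-protocol
#' points the current is measured at a fixed test potential while `vc` is
#' the pre-pulse voltage; pass that test potential as `driving_v`.
#'
#' @param points data.frame from [extract_peak_currents()].
#' @param e_rev reversal potential in mV.
#' @param branch `"inward"` (uses `peak_inward`) or `"outward"`
#'   (uses `peak_outward`).
#' @param driving_v optional fixed potential at which the current was
#'   measured (inactivation protocols); defaults to each point's `vc`.
#' @return a data.frame with `vc` (mV) and `g` (nS); inward currents below
#'   reversal give positive conductance.
#' @export
conductance_transform <- function(points, e_rev = 66.7,
                                  branch = c("inward", "outward"),
                                  driving_v = NULL) {
  branch <- match.arg(branch)
  i <- if (branch == "inward") points$peak_inward else points$peak_outward
  vd <- if (is.null(driving_v)) points$vc else rep(driving_v, nrow(points))
  keep <- rep(TRUE, nrow(points))
  sing <- vd == e_rev
  if (any(sing)) {
    warning("excluding ", sum(sing),
            " point(s) at vc = e_rev (zero driving force)")
    keep <- keep & !sing
  }
  if (branch == "inward" && is.null(driving_v))
    keep <- keep & points$vc < e_rev
  data.frame(vc = points$vc[keep], g = i[keep] / (vd[keep] - e_rev))
}

#' Fit a Boltzmann curve to normalized conductance data
#'
#' Nonlinear least squares of `G = Gmax / (1 + exp((V50 - Vc)/h))` for
#' activation, or the mirrored `G = Gmax / (1 + exp((Vc - V50)/h))` for
#' inactivation, so that the slope factor `h` is reported positive for both
#' branches with the direction carried by `curve_type`. Start values:
#' Gmax = max observed G, V50 = the vc nearest G = Gmax/2, h = 7 mV;
#' Levenberg-Marquardt iterations stop at a relative parameter change of
#' 1e-8 or 500 iterations.
#'
#' @param gv data.frame with columns `vc` (mV) and `g` (nS), at least 5
#'   points spanning both sides of the half-max.
#' @param curve_type `"activation"` or `"inactivation"`.
#' @return a list of class `boltzmann_fit`: `gmax` (nS), `v50` (mV), `h`
#'   (mV, > 0), `rss`, `n_points`, `curve_type`.
#' @export
fit_boltzmann <- function(gv, curve_type = c("activation", "inactivation")) {
  curve_type <- match.arg(curve_type)
  gv <- gv[is.finite(gv$g) & is.finite(gv$vc), , drop = FALSE]
  if (nrow(gv) < 5L) stop("fit error: need at least 5 conductance points")
  if (diff(range(gv$g)) <= 1e-12 * max(abs(gv$g), 1))
    stop("fit error: degenerate data (all conductances equal)")
  g0 <- max(gv$g)
  v50_0 <- gv$vc[which.min(abs(gv$g - g0 / 2))]
  sgn <- if (curve_type == "activation") 1 else -1
  fit <- tryCatch(
    minpack.lm::nlsLM(
      g ~ gmax / (1 + exp(sgn * (v50 - vc) / h)),
      data = gv,
      start = list(gmax = g0, v50 = v50_0, h = 7),
      lower = c(gmax = 1e-12, v50 = -Inf, h = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 500, ptol = 1e-8)),
    error = function(e) stop("fit error: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  structure(list(gmax = unname(cf["gmax"]), v50 = unname(cf["v50"]),
                 h = unname(cf["h"]),
                 rss = sum(stats::residuals(fit)^2),
                 n_points = nrow(gv), curve_type = curve_type),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<boltzmann_fit> %s: Gmax = %.3g nS, V50 = %.2f mV, h = %.2f mV (rss %.3g, n %d)\n",
              x$curve_type, x$gmax, x$v50, x$h, x$rss, x$n_points))
  invisible(x)
}

#' Evaluate a fitted Boltzmann curve
#'
#' @param fit a `boltzmann_fit`.
#' @param v voltages in mV.
#' @param normalized divide by Gmax (steady-state occupancy) instead of
#'   returning conductance.
#' @return conductance in nS, or occupancy in \[0, 1\] when normalized.
#' @export
boltzmann_curve <- function(fit, v, normalized = FALSE) {
  sgn <- if (fit$curve_type == "activation") 1 else -1
  occ <- 1 / (1 + exp(sgn * (fit$v50 - v) / fit$h))
  if (normalized) occ else fit$gmax * occ
}

#' Availability-window analysis of paired activation/inactivation fits
#'
#' The availability window is the voltage range where the normalized
#' steady-state activation and inactivation curves overlap; their product
#' is the window curve, whose maximum indexes the sustained (window)
#' current. The crossing point solves act(v) = inact(v) by bisection to
#' 1e-6.
#'
#' @param act activation `boltzmann_fit`.
#' @param inact inactivation `boltzmann_fit`.
#' @param grid_step voltage grid step in mV.
#' @param v_range grid range in mV.
#' @return a list of class `availability_window`: `voltage_grid`,
#'   `window_curve` (product of normalized curves, in \[0, 1\]),
#'   `window_max`, `v_at_max` (mV), `crossing_v` (mV, NA with a warning if
#'   the curves never cross on the grid) and `va50_minus_vi50` (mV).
#' @export
availability_window <- function(act, inact, grid_step = 0.5,
                                v_range = c(-120, 80)) {
  if (act$curve_type != "activation" || inact$curve_type != "inactivation")
    stop("need one activation fit and one inactivation fit")
  v <- seq(v_range[1L], v_range[2L], by = grid_step)
  a <- boltzmann_curve(act, v, normalized = TRUE)
  i <- boltzmann_curve(inact, v, normalized = TRUE)
  wc <- a * i
  k <- which.max(wc)
  f <- function(x) boltzmann_curve(act, x, normalized = TRUE) -
    boltzmann_curve(inact, x, normalized = TRUE)
  crossing <- NA_real_
  if (f(v_range[1L]) * f(v_range[2L]) <= 0) {
    lo <- v_range[1L]; hi <- v_range[2L]
    repeat {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (abs(fm) < 1e-6 || (hi - lo) < 1e-9) break
      if (f(lo) * fm <= 0) hi <- mid else lo <- mid
    }
    crossing <- mid
  } else {
    warning("activation and inactivation curves do not cross on the grid")
  }
  structure(list(voltage_grid = v, window_curve = wc,
                 window_max = wc[k], v_at_max = v[k],
                 crossing_v = crossing,
                 va50_minus_vi50 = act$v50 - inact$v50),
            class = "availability_window")
}

#' @export
print.availability_window <- function(x, ...) {
  cat(sprintf(paste0("<availability_window> max %.4f at %.1f mV; crossing ",
                     "%.2f mV; Va50 - Vi50 = %.2f mV\n"),
              x$window_max, x$v_at_max, x$crossing_v, x$va50_minus_vi50))
  invisible(x)
}

#' Full gating analysis of a paired voltage-clamp recording
#'
#' Convenience pipeline: peak extraction, conductance transform and
#' Boltzmann fitting of the activation and inactivation protocols, plus the
#' availability-window analysis of the fitted pair.
#'
#' @param activation activation-protocol `sweep_set`.
#' @param inactivation inactivation-protocol `sweep_set` (test-potential
#'   level in `metadata$v_test`).
#' @param e_rev reversal potential of the inward current in mV.
#' @param grid_step availability-window grid step in mV.
#' @return a list with `iv` (activation I-V table), `act` and `inact`
#'   (`boltzmann_fit`s) and `window` (`availability_window`).
#' @export
fit_na_gating <- function(activation, inactivation, e_rev = 66.7,
                          grid_step = 0.5) {
  iv <- extract_peak_currents(activation)
  gv_act <- conductance_transform(iv, e_rev = e_rev, branch = "inward")
  act <- fit_boltzmann(gv_act, "activation")
  iv_in <- extract_peak_currents(inactivation)
  v_test <- inactivation$metadata$v_test
  if (is.null(v_test)) v_test <- 0
  gv_in <- conductance_transform(iv_in, e_rev = e_rev, branch = "inward",
                                 driving_v = v_test)
  inact <- fit_boltzmann(gv_in, "inactivation")
  list(iv = iv, act = act, inact = inact,
       window = availability_window(act, inact, grid_step = grid_step))
}
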