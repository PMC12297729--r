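---
title: "Quantifying neuronal functional maturation with neuromat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neuronal functional maturation with neuromat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuromat)
```

## Scope and data model

`neuromat` quantifies the functional maturation of cultured neurons (for
example, iPSC-derived neurons differentiated by forced Ngn2 expression)
from three recording modalities: current-clamp step families, voltage-clamp
step families, and per-cell calcium-indicator fluorescence traces. All
three are carried by a single container, the `sweep_set`: a family of
uniformly sampled traces plus per-sweep stimulus metadata (step onset,
duration, level and holding level), cell capacitance, and free-form
metadata. The native exchange format is a comma-delimited sweep table (one
`time` column, one column per sweep, full double precision) with a JSON
protocol sidecar, chosen because it is inspectable, language-neutral, and
round-trips bit-identically. Time is stored internally in seconds; files
may declare milliseconds and are converted on read — a single internal
convention prevents unit bugs at module boundaries.

Because no raw recordings are distributed with the package, a synthetic
generator produces all three modalities with known ground truth, and every
analysis stage is validated against it.

## Induced-activity classification

In current clamp, a neuron is held near −80 mV and probed with 1-s current
injections from −10 to +190 pA. Each sweep is coded by its depolarizing
excursions from the within-step baseline:

* **Quiet** — no significant excursions during the injection;
* **Attempting single** — excursions that never reach 0 mV;
* **Single** — exactly one excursion that overshoots 0 mV;
* **Attempting train** — several excursions, exactly one overshooting;
* **Train** — several excursions, at least two overshooting.

A "significant" excursion is one whose peak exceeds the within-step
baseline by at least `min_rise` (default 15 mV, configurable): the
threshold is a package choice, made large enough to ignore ordinary
membrane noise but far below any regenerative event. Detection uses
hysteresis — an excursion ends only when the trace returns below
baseline + `min_rise`/2 — so a spike with a noisy top is one event, not
several. The within-step baseline is the median of the first 10 ms of the
step response after a 1-ms settling blank. The 0-mV overshoot criterion is
absolute, not baseline-relative.

The neuron-level class is the maximum sweep class under the ordering
Quiet < Attempting single < Single < Attempting train < Train. A protocol
usually elicits the strongest behaviour near the top of the step family,
and the maximum is the only reduction that is monotone in stimulus
strength. Non-induced activity uses a separate two-level coding
(Quiet/Spontaneous): a neuron is Spontaneous when an overshooting
excursion occurs with no injected current.

```{r census}
cohort <- make_current_clamp_cohort(
  c(Quiet = 1, Single = 2, Train = 1), seed = 1)
cls <- vapply(cohort, function(n) as.character(classify_induced(n)),
              character(1))
tally(factor(cls, levels = induced_levels), "demo")
```

## Spike morphometry

Spike analysis runs on the first qualifying spike (overshooting, or within
10 mV of 0 mV). The threshold is operationalized as the voltage at the
peak of the third time-derivative of voltage during the upstroke — the
point of fastest acceleration onset. Derived measures: amplitude
(peak − threshold), overshoot (the peak voltage itself, i.e. the amount
above 0 mV), half-width (duration at threshold + amplitude/2), and the
maximal depolarization rate (max dV/dt between threshold and peak, V/s).

Numerical choices, in order of consequence:

* **Derivative estimation.** Raw third differences at 10 kHz are
  noise-dominated, so the trace is Savitzky–Golay smoothed (order 3,
  window `smooth_window`) and the first/third derivatives are taken as
  Savitzky–Golay derivative estimates (local cubic least squares) over the
  same window. The single-spike default window is 1 ms, which on clean
  data reproduces a dense-grid differentiation oracle to within 2 samples.
  The batch default in `cohort_feature_table()` is 3 ms: a least-squares
  derivative over 31 samples is dramatically more stable against realistic
  recording noise, at the cost of a small systematic threshold bias
  (≈ −4 mV on the default template) that is constant within a cohort and
  so cancels in group comparisons.
* **Upstroke definition.** The upstroke runs from the last local minimum
  before the peak to the peak. On noisy data a "local minimum" must hold
  over a ±window neighbourhood and sit in the lower quartile of the
  excursion range, which prevents noise dimples on the rising phase from
  truncating the upstroke.
* **Half-width crossings** are linearly interpolated between samples on
  both flanks of the peak; an excursion whose half-amplitude level is
  never re-crossed is a morphology error, not a silent NA.

## Voltage-clamp gating analysis

The activation protocol holds at −70 mV and steps for 80 ms from −120 to
+80 mV; the main text of typical protocols uses 10-mV increments and the
protocol descriptor carries the actual list, so 5-mV families are equally
valid inputs. Per step, the peak inward current is the minimum over the
first 10 ms (after 0.3 ms of capacitive blanking) and the sustained
outward current is the mean of the last 20% of the step — all three
windows are package defaults and configurable. No leak subtraction is
applied by default.

Conductance follows from the driving force, G = I/(Vc − Erev), with
Erev = +66.7 mV for the inward Na⁺ branch; the activation branch uses only
steps below reversal, where the branch is well defined. Normalized
conductance is fitted with a Boltzmann curve

$$G/G_{max} = \frac{1}{1 + \exp((V_{50} - V_c)/h)}$$

by Levenberg–Marquardt least squares (start values: Gmax = max G, V50 = the
voltage nearest half-max, h = 7 mV; relative parameter tolerance 1e-8, at
most 500 iterations). Inactivation uses the mirrored sign,
`1/(1 + exp((Vc − V50)/h))`, so the slope factor is reported positive for
both branches with direction carried by `curve_type`. For the inactivation
protocol (200-ms pre-pulses, test step to 0 mV) the driving force is fixed
at the test potential.

The availability window is the overlap of the normalized steady-state
activation and inactivation curves: their product on a 0.5-mV grid over
−120…+80 mV gives the window curve, its maximum indexes the sustained
(window) current, and the crossing point where the two curves are equal is
solved by bisection to 1e-6. The summary statistic Va50 − Vi50 is reported
alongside.

```{r gating}
rec <- make_voltage_clamp_recording(noise_sd = 0, seed = 1)
res <- fit_na_gating(rec$activation, rec$inactivation)
res$act
res$window
```

## Calcium dF/F and spectral analysis

Fluorescence traces (default 60 s at 5 Hz) are baseline-normalized as
ΔF/F = (F − F0)/F0. The default F0 estimator is the mean of the lowest
decile of the trace: calcium transients are positive-going, so the low
decile tracks the quiescent baseline robustly. For symmetric oscillations
this estimator deliberately reads the trough region; when a closed-form
amplitude is needed (as in the tests) the `"mean"` method recovers it
exactly.

The spectrum is a single tapered periodogram (Hann window) of the linearly
detrended, mean-subtracted trace: with 300-sample traces there is no room
for segment averaging, and resolution in the low-frequency band dominates.
Detrending matters because slow drift otherwise masquerades as
0–0.02 Hz power. The one-sided PSD is normalized so that its integral over
frequency equals the variance of the tapered, mean-subtracted signal
exactly (Parseval); the per-bin power spectrum is the PSD times the bin
width, so both conventions are available. Band statistics default to the
(0, 0.1] Hz band in which slow spontaneous calcium oscillations live; the
upper edge is inclusive. Event frequency counts local maxima with
topographic prominence of at least `prominence` (default 0.2 ΔF/F units)
and converts to events/min.

```{r calcium}
tr <- make_fluorescence_trace(
  calcium_ground_truth(osc_freq = 0.05, osc_amp = 0.3, noise_sd = 0.05),
  seed = 1)
sp <- compute_spectrum(delta_f_over_f(tr))
sp
```

## What the synthetic generator does and does not emulate

The generator exists to give every analysis stage a controllable,
verifiable input; it is not a biophysical simulator.

* **Current clamp.** Spikes are templated waveforms — a quintic-smoothstep
  depolarizing ramp into a logistic upstroke, with an infinitely
  differentiable soft-exponential repolarization — not solutions of a
  conductance-based membrane model. The template is constructed so the
  analytic third-derivative maximum sits exactly at the nominal threshold
  and the excursion peak exactly at the nominal peak, which is what makes
  oracle tests possible. Non-overshooting excursions default to −20 mV
  peaks and overshooting ones to +25 mV (both configurable), comfortably
  clear of the 0-mV rule boundary; the morphology of "attempting" events
  is a package choice, since no quantitative description exists to copy.
  Recording noise is white Gaussian at 0.5 mV s.d., a typical whole-cell
  figure; there are no line-frequency artifacts, no channel stochasticity,
  and no adaptation.
* **Voltage clamp.** Currents are products of Boltzmann steady states and
  exponential kinetics: the Na⁺-like conductance activates with a 0.5-ms
  time constant and inactivates with 5 ms; the K⁺-like conductance is
  non-inactivating with a fourth-power (delayed-rectifier-like) onset,
  whose sigmoidal delay keeps the early inward-peak window uncontaminated.
  Availability at the holding potential scales the whole activation family
  by the constant factor inact∞(−70 mV), so it rescales the apparent Gmax
  without displacing V50 or h. The noiseless peak current is available in
  closed form (`vc_peak_current()`), which is what round-trip tests fit
  against.
* **Calcium.** Traces are a baseline plus sinusoid plus linear drift plus
  white noise, clipped at zero. Real calcium transients are asymmetric
  spike-and-decay events; a sinusoid exercises the spectral pipeline with
  an unambiguous ground-truth frequency, which is the property under test.

Consequently, green tests demonstrate correctness of the analysis
pipeline's arithmetic, detection logic and fitting, under controlled
conditions — not robustness to the full pathology of real recordings
(electrode drift, seal instability, photobleaching, mechanical artifacts).

## Degenerate inputs and tie-breaks

Flat traces classify as Quiet, not as errors; truly empty inputs (no
sweeps, no stimulus-free segment, steps outside the trace) raise typed
errors naming the violated precondition. A conductance point at exactly
the reversal potential is excluded with a warning rather than producing an
infinite conductance. Boltzmann fitting refuses degenerate (constant)
conductance data. Percentages in tallies are rounded half-up to integers
for parity with how cohort compositions are conventionally printed, with
exact proportions always available; the report shows both.

## Problem sizes

The test suite and the acceptance script use cohorts of 33–37 neurons per
group (realistic patch-clamp cohort sizes), 10-kHz current-clamp sweeps
of 1.2 s, 21-step activation and 41-step inactivation voltage-clamp
families, 300-sample fluorescence traces, 100-seed Monte-Carlo loops for
spectral recovery, and 100 randomized templates for the threshold oracle.
These sizes keep the full validation run in the tens of seconds while
leaving every statistical check well-powered.

## Known limitations

* The third-derivative threshold is intrinsically noise-hungry; below
  roughly 0.2 mV r.m.s. noise the 1-ms window suffices, above it the
  wide-window estimate with its small bias is the practical choice.
  Cross-group threshold comparisons are unaffected; absolute thresholds
  carry the bias.
* The classifier's neuron-level reduction (maximum over sweeps) assumes a
  monotone protocol; pathological non-monotone protocols would need a
  different reduction.
* Input resistance assumes a passive, settled response in the last 20% of
  the step; strongly rectifying cells violate this.
* The availability-window maximum depends steeply on both slope factors;
  it is reported as computed from the fitted pair, and no attempt is made
  to reproduce published window maxima whose underlying fit parameters
  are not available.
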