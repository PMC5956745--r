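---
title: "Quantal analysis of mossy fiber-granule cell transmission: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantal analysis methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptiq)
library(dplyr)
```

synaptiq implements the measurement chain used to characterize synaptic
transmission at the cerebellar mossy fiber-granule cell relay: detection
and screening of miniature and quantal EPSCs, their kinetics, peak-scaled
non-stationary fluctuation analysis (ps-NSFA), rectification indices,
Sr²⁺-desynchronized quantal counting, short-term plasticity trains, and
vesicle morphometry of electron-microscopy annotations. Every analysis
stage is paired with a generator that produces the same class of data
with known ground truth, so the whole chain is validated by parameter
recovery rather than by eye.

Units are fixed package-wide: ms, pA, mV, nS/pS, nm and μm²; inward
current is negative. All stage outputs are tidy tables keyed by
(recording, sweep, event), so external statistics can be applied without
re-parsing.

## The stochastic gating model behind ps-NSFA

A quantal current is modeled as `N_p` independent channels, each passing
a unitary current `i` (pA). A deterministic rise envelope
(`1 - exp(-t/τ_rise)`, normalized to reach 1 at `5 τ_rise`) brings all
channels to the open state at the peak; from the peak onward each channel
closes after an i.i.d. exponential lifetime with mean `τ_decay`. The
observable current is `i` times the number of channels still open. Three
exact consequences make this the right generator for validating ps-NSFA:

* the peak current is exactly `i N_p`, with zero variance;
* the ensemble mean decay is `i N_p exp(-t/τ_decay)`;
* at any decay time the open count is binomial, so the variance against
  the mean current `Ī` is exactly the parabola

  σ²(Ī) = i·Ī − Ī²/N_p.

This is the minimal stochastic model whose peak-scaled variance is the
fitted relationship itself, giving an analytic oracle: no reference
implementation is needed to know what the right answer is. Reopenings,
multi-state receptor kinetics, temperature and dendritic filtering are
deliberately out of scope. The closing clocks start at the peak rather
than at onset because the parabola's vertex condition — zero excess
variance where `Ī = i N_p` — requires every channel to be open at the
peak deterministically.

Defaults follow the wild-type cultured-granule-cell estimates: `N_p` 20,
`i` −0.69 pA at −60 mV (chord conductance 11.5 pS with reversal at
0 mV), `τ_rise` 0.15 ms, `τ_decay` 1.3 ms.

## Detection and screening

Events are detected by amplitude threshold crossing on the
baseline-subtracted trace, with the threshold expressed as `k` baseline
noise SDs (default `k = 3`; the noise SD comes from the median absolute
deviation, so sparse events barely perturb it). Two practical details
matter:

* **Band-limiting.** The trace is boxcar-smoothed over 0.3 ms before
  thresholding (the acquisition bandwidth of a 2 kHz-filtered recording
  sampled at 20 kHz). Unfiltered white noise crosses a 3-SD threshold
  tens of times per second; band-limited noise essentially never does.
  Peak amplitudes are always read from the unsmoothed trace.
* **Refractory merging.** Threshold crossings closer than 1 ms (default)
  are one event. Merging interacts with thresholding: two overlapping
  events can merge at a low threshold and split at a high one, so the
  "detection count never increases with threshold" property is exact
  only for non-overlapping events; the tests scope it accordingly.

Onset is the last pre-peak crossing of baseline ± one noise SD, searched
backward from the threshold crossing; a risetime needs a defined onset,
and this convention is robust to slow baseline wander.

Screening mirrors the analysis-inclusion rules used with real
recordings: `monotonic_rise` requires the 3-sample-smoothed rise to have
no slope reversal between onset and peak, with a tolerance of two SDs of
the smoothed-slope noise (exactly zero for noiseless traces — a strict
zero tolerance would reject most genuine events at realistic SNR simply
because the slope vanishes near a rounded peak); `clean_decay` requires
no second threshold crossing within the decay window after the peak;
`post_stimulus_ok` marks events outside the post-stimulus exclusion
window. Alignment for averaging is at the point of steepest rise
(maximum |dI/dt| between onset and peak).

## Peak-scaled NSFA

The ensemble mean waveform is scaled to each event's peak, decay-phase
samples are assigned to 30 equal-amplitude bins of the scaled mean, and
the squared deviation of each event from its scaled mean is pooled
across events per bin. The binned variance-mean pairs are fitted by
least squares to

σ²_PS = i·Ī − Ī²/N_p + σ²_B,

which is linear in `(i, 1/N_p, σ²_B)` and therefore fitted by weighted
linear regression (weights proportional to bin occupancy; plain least
squares available). The chord conductance is `γ = |i| / |V − E_rev|`,
reported in pS at `E_rev = 0`.

Numerical choices, each config-exposed:

* Only the decay phase (ensemble peak onward) enters the bins:
  rise-phase latency jitter inflates variance for reasons unrelated to
  gating.
* Each event's peak is measured on its 3-sample-smoothed waveform *at*
  the ensemble peak sample (±1 ms search window informs the smoothed
  trace, but no noisy-extremum maximization is used for the scale
  factor itself) — taking a windowed maximum of a noisy trace inflates
  every scale factor and biases `i` upward by ~10% at SNR 14.
* Bins with fewer than 5 pooled samples are excluded; occupancy is
  reported per bin.
* `σ²_B` is a free parameter of the fit; the measured pre-event baseline
  variance is reported alongside for comparison.
* Fits with fewer than 10 screened events are refused (the parabola is
  unidentifiable); non-negative fitted curvature is flagged as a
  degenerate fit with `N_p` unbounded rather than silently reported.

## Kinetics

The 10-90% risetime interpolates the crossings of 10% and 90% of the
baseline-to-peak amplitude on the rising limb (last 10% and first 90%
crossing before the peak when noise makes crossings ambiguous). Decays
are fitted with `A_f exp(-t/τ_f) + A_s exp(-t/τ_s)` by
Levenberg-Marquardt least squares with multistart initialization (τ_f
from the first e-fold time, τ_s = 4 τ_f, fractions 0.7/0.3, five
jittered restarts); single- versus double-exponential selection is by
BIC, with a numerically-exact single fit accepted outright. The weighted
decay constant is τ_w = (A_f τ_f + A_s τ_s)/(A_f + A_s). The fit window
runs from the peak to the first return within one noise SD of baseline,
capped at 10 initial-τ estimates so late baseline drift cannot dominate.

## Rectification

`RI_slope` is the ratio of OLS slope conductances in the +20..+40 mV and
−40..−20 mV limbs of the I-V ramp (window edges inclusive). The
count-matched index `RI_CM` divides the mean peak conductance of all
events at +60 mV by that of an equal number of the largest-magnitude
events at −60 mV; "largest" is judged by amplitude magnitude, and ties
at the cutoff share the marginal slot fractionally (exact-k truncation
available). Removing the largest negative events can only shrink the
denominator, so `RI_CM` is non-decreasing under that operation — the
useful direction of the monotonicity property.

## Sr²⁺ quantal analysis and trains

With Ca²⁺ replaced by Sr²⁺, evoked release desynchronizes into
countable single quanta. Counting uses every detected event with a
distinct peak occurring more than 10 ms (default) after the stimulus —
the exclusion window avoids multiquantal contamination; amplitude
statistics use only monotonic-rise events (overlapping decays allowed);
a failure is a sweep with no detected response at all. Because the
source recordings measured the initial synchronous EPSC ambiguously
(all sweeps versus responding sweeps), both summaries are reported
(`initial_epsc_pa`, `initial_epsc_pa_all`).

Train analysis measures each pulse's amplitude as the mean over sweeps
of the baseline-subtracted peak in a post-stimulus window, after
subtracting the previous pulse's single-exponential decay extrapolated
from a log-linear fit of the late inter-pulse segment (the overlap
correction is not specified in the source methods; this choice is logged
per run and can be disabled). Amplitudes normalize to the mean
first-pulse response of a reference condition, and PPR₂/₁ is the
within-condition ratio. The depletion generator uses the standard
resource recursion `R₁ = 1`,
`Rₙ₊₁ = Rₙ(1−f) + (1 − Rₙ(1−f))(1 − exp(−Δt/τ_rec))` with amplitudes
proportional to `f Rₙ`, so slow recovery gives the textbook limit
PPR → 1 − f.

The Wilcoxon rank-sum test reports the Mann-Whitney count of
`x_i > y_j` pairs (half per tie) with an exact two-sided p-value from
the null permutation distribution whenever the samples are tie-free and
`n_x n_y ≤ 10,000`, and a mid-rank normal approximation with continuity
and tie corrections otherwise. Repeated-measures ANOVA and mixed-model
tests are deliberately not reimplemented: the tidy output tables are the
interface to off-the-shelf statistics.

## EM morphometry

Annotations are planar (single 70-80 nm sections; no stereological 3-D
correction): a terminal polygon, organelle polygons, active-zone
polylines, and vesicle centers with diameters, all in continuous nm
(stored as pixels plus a scale in the JSON interchange format).

* **Grid density** overlays 0.1 μm² squares; a square counts only if
  fully inside the terminal and intersecting no organelle (the manual
  counting rule of excluding border and organelle squares). Density is
  centers in valid squares over valid area. Squares are half-open so a
  center on a shared edge is counted once. Only terminal-border and
  organelle squares are excluded — squares touching an active zone
  remain valid, following the stated counting rule. For a homogeneous
  pattern the estimate is origin-invariant in expectation;
  `grid_density_origins()` reports the spread over four quarter-phase
  origins.
* **Proximity**: a vesicle is proximal if its center is within 100 nm of
  an AZ polyline, assigned to the nearest AZ only; counts normalize per
  50 nm of AZ length.
* **Membrane adjacency** approximates docked vesicles without claiming
  to identify docking: a vesicle whose edge-to-AZ gap is at most one
  radius, i.e. center distance ≤ one diameter. The geometric reading of
  "within one vesicle radius" (center versus edge reference) is
  ambiguous in the source; the edge-referenced convention treats the
  vesicle as an extended object and is the one implemented, with the
  convention config-switchable at the call site via the count tables.
* **Diameters** are summarized per terminal (mean, SD, n). The generator
  draws truncated-normal diameters with a hard 10 nm floor (no
  non-physical sizes); at the default mean 33.5 nm and SD 3 nm the
  truncation bias is negligible.

## What the generators do and do not emulate

The generators reproduce the statistical structure the analyses consume:
Poisson event timing on Gaussian baseline noise, binomial channel-count
fluctuations, piecewise-linear ramp conductances with a smooth ±20 mV
transition, exponentially decaying asynchronous release with Bernoulli
failures, deterministic depletion dynamics, and homogeneous planar point
patterns with optional AZ enrichment bands. They do not emulate: 1/f or
line noise, series-resistance and dendritic filtering, receptor
desensitization or reopenings, quantal-size variability between sites
(only a uniform per-event scaling enters one property test), vesicle
exclusion volumes, or section-thickness projection effects. Passing
recovery tests therefore demonstrates that the chain measures what the
model generates — unbiasedly and at the stated precision — not that real
recordings satisfy the model.

## Problem sizes and reproducibility

The validation suite uses desk-scale problems chosen to keep Monte-Carlo
error well inside the assertion tolerances: conductance recovery uses 20
independent recordings of ~500 events each (median reported); the
variance-parabola check uses 10,000 events; density recovery uses 20
ten-μm² terminals (~1,300 vesicles each); diameter recovery uses ~1,000
vesicles. All generators are deterministic given a seed, and the
pipeline writes byte-identical result tables under a fixed seed and
configuration.

A worked end-to-end example:

```{r example, eval = FALSE}
qm <- quantal_model(n_p = 20, i_pa = -0.69, tau_decay_ms = 1.3)
sim <- simulate_mepsc_recording(qm, n_sweeps = 5, sweep_ms = 25000,
                                rate_hz = 4, noise_sd_pa = 1, seed = 1)
noise <- estimate_baseline_noise(sim$recording)$sd_pa
events <- detect_events(sim$recording, k = 3, noise_sd_pa = noise) |>
  screen_events(sim$recording, noise_sd_pa = noise)
ens <- events |>
  dplyr::filter(monotonic_rise, clean_decay) |>
  align_and_average(sim$recording, pre_ms = 5, post_ms = 15)
fit <- peak_scaled_nsfa(ens, n_bins = 30, v_mv = -60)
glance(fit)
autoplot(fit)
```

## Known limitations

* Overlapping-event decomposition is out of scope; overlaps are
  screened out, which slightly undercounts dense asynchronous release
  (~10% at 10 events per 450 ms sweep).
* ps-NSFA inherits the classical peak-scaling caveats: `N_p` is
  identified only up to the open probability at the peak, and alignment
  jitter contributes a small Ī²-shaped variance term that the fit
  absorbs mostly into `N_p`, not `i`.
* The train overlap correction assumes a single-exponential previous
  decay; strongly biexponential evoked currents at very high rates
  would need the full fit.
* Grid density at 0.1 μm² squares is unbiased for homogeneous patterns
  but, like the manual procedure it mirrors, underweights vesicles near
  excluded border/organelle squares for inhomogeneous ones.
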