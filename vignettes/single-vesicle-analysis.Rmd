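---
title: "Measuring single-vesicle endocytosis kinetics from pHluorin traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring single-vesicle endocytosis kinetics from pHluorin traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesitrace)
library(dplyr)
```

## The measurement problem

pHluorin and pHTomato are pH-sensitive fluorescent proteins fused to
synaptic-vesicle membrane proteins. Inside an acidified vesicle they are
quenched; when a vesicle fuses with the plasma membrane the probe is exposed
to extracellular pH and fluorescence steps up by one quantal unit. After the
protein is retrieved and the vesicle re-acidifies, fluorescence decays back
towards baseline. A bouton imaged at 10 or 40 Hz under sparse (0.05 Hz)
single-action-potential stimulation therefore reports, for each stimulus:
whether a vesicle fused (a step), how long its protein stayed at the surface
(the *dwell time*: peak plateau until the fluorescence starts to decay), and
how much of the fused protein was recovered (the *fraction of retrieval*,
the retrieved amplitude relative to the fusion step).

Dwell times fall into three kinetic classes: *ultrafast* retrieval
(0--1 s, with a time constant of a few hundred milliseconds), *fast*
retrieval (1--20 s, several seconds), and *ultraslow* events that never
decay within the observation window (> 20 s, treated as right-censored).
The package implements the full chain from raw intensity traces to these
quantities, together with a synthetic-data generator that produces traces
with known ground truth for validation.

## The processing model, stage by stage

### Synthetic traces

`sim_config()` + `simulate_experiment()` generate per-bouton traces as

* a constant background plus an additive photobleaching trend
  `bleach_amplitude * exp(-t / bleach_tau_s)`;
* per stimulus, a Bernoulli fusion draw with probability `p_release`;
* fused events step up within one frame by a quantal amplitude
  (`quantal_amplitude`, CV `quantal_cv`; with probability
  `multivesicular_prob` the event carries two quanta — these exercise the
  quantal upper limit downstream);
* a plateau whose duration is drawn by kinetic class: ultrafast,
  `Exp(tau_ultrafast_s)` truncated to (0, 1] s; fast, `Exp(tau_fast_s)`
  truncated to (1, 20] s; ultraslow, no decay at all. Because the draws are
  conditioned on the class band, `mode_weights` *are* the true mode
  proportions, which keeps parameter-recovery studies well posed;
* a single-exponential re-acidification decay
  (`tau_reacidification_s`, default 4 s) towards
  `baseline + (1 - retrieval_fraction) * amplitude`; the retrieval fraction
  is drawn from a partial / quantal / excess mixture whose spread widens
  with dwell time (`dwell_dispersion_per_s`), emulating the observed growth
  of retrieval dispersion with dwell;
* additive Gaussian noise (`noise_sd`).

Defaults encode the sparse-stimulation study conditions: 20 stimuli at 20 s
intervals, 10 Hz sampling, `p_release = 0.15` (the low-calcium,
room-temperature regime; 0.45 reproduces the high-calcium one), mode
weights (0.2, 0.4, 0.4), `tau_ultrafast_s = 0.2`, `tau_fast_s = 8`. Two
generator constants are free choices stated here once: the signal-to-noise
ratio (quantal amplitude = 5 x noise SD) and the quantal CV of 0.15, a
realistic single-vesicle amplitude spread. The generator emulates the
statistical structure of bouton traces, not their optics: there is no point
spread, no shot-noise scaling with intensity, no focal drift, and fusion is
strictly stimulus-locked (no spontaneous events). Passing tests therefore
validate the estimators under the stated statistical model, not every
property of real recordings.

### Photobleaching and background correction

`correct_photobleaching()` fits `a * exp(-t / tau) + c` per bouton and
subtracts the fitted trend (re-anchored at the trace end, so corrected
traces keep their level). The additive, subtractive model — rather than
divisive normalisation — preserves amplitude units, which the 3x-SD
detection threshold and the quantal limit depend on.

Two practical points shaped this stage. First, an event-free mask of
[-0.5 s, +20 s] around each stimulus leaves zero samples under the 0.05 Hz
protocol itself (stimuli arrive every 20 s), so the pipeline fits each
ROI's full trace instead; `stimulus_mask()` remains available for sparser
protocols. Second, fusion events that are never retrieved permanently
elevate the trace, and a run of them forms a rising staircase that a plain
exponential fit either absorbs (inventing drift) or capitulates to
(leaving the true bleach uncorrected). When stimulus times are supplied the
model therefore adds a nonnegative persistent step at each stimulus; steps
only increase while bleach only decreases, so the two are identifiable.
The within-trace curvature that pins the bleach constants comes from
intervals with no apparent event; event-containing intervals contribute
their end-of-interval baseline block, and an asymmetric reweighting
discounts samples still elevated by unfinished decays. Among
near-equivalent fits the smallest total drift wins, so a pathological trace
with events at every stimulus does not acquire an invented trend.

### Chung-Kennedy de-noising

`ck_filter()` implements the forward-backward nonlinear filter: banks of
forward and backward moving-average predictors (windows of 2, 4, 8, 16
samples) whose outputs are combined with weights proportional to
`(error + epsilon)^(-p)`, where each predictor's error is the sum of its
M = 8 most recent squared one-sided residuals (past residuals for forward
predictors, future for backward). Around a step, predictors whose window
straddles the edge accumulate large errors and drop out, so the step
survives while stationary noise is averaged down (white-noise SD falls to
~0.27 of the input at the defaults). The exact window set, M and p are
design parameters tuned on simulated traces; all are exposed in
`denoise_config()`. The epsilon regulariser (1e-12) keeps weights defined
on noiseless plateaus where prediction errors vanish; it is invisible at
any realistic noise level. Boundary samples use truncated windows rather
than reflection padding, which would fabricate symmetric data around
segment edges. Per-predictor prior weights default to 1.

Two intrinsic resolution limits are worth knowing. A plateau shorter than
about M + 2 samples (0.25 s at 40 Hz, 1 s at 10 Hz) has no sample whose
error window is clean on either side, so its measured dwell is biased
short — events remain correctly classified as ultrafast, but sub-frame
accuracy claims only hold above that floor. And a rectangular pulse much
shorter than the comparison window is partially attenuated, unlike a step
into a sustained plateau, which is preserved essentially exactly.

`fft_lowpass()` is the comparator: zeroing all components above 2 Hz
attenuates plateaus in the ultrafast band by tens of percent (60% at
0.1 s, ~12% at 0.25 s), which is precisely why the time-domain filter is
used for this analysis. `noise_gaussianity()` (Lilliefors test) checks the
Gaussian-noise assumption the filter relies on.

### Event detection, dwell times, censoring

`detect_events()` scores each stimulus on the de-noised trace:

* baseline mean and SD from the 2 s window before the stimulus. The SD
  enters the threshold from the *corrected raw* trace by default: the 2 s
  window holds only ~20 strongly autocorrelated de-noised samples, whose
  SD estimate is so downward-biased that the false-positive rate on pure
  noise exceeds the design bound; the raw-trace SD is calibrated.
  `detect_config(baseline_sd_on = "denoised")` switches the convention.
* an event is called iff the trace clears
  `baseline + 3 * SD` within the 3-frame coincidence window — the crossing
  may register on the raw trace, which shows the one-frame step without
  the 1--3-frame rise smear the filter introduces — and the event's peak
  amplitude (peak of the de-noised trace in the rise window minus baseline)
  itself exceeds the threshold. At most one event is scored per stimulus.
* events whose amplitude exceeds the quantal upper limit are flagged
  multivesicular and excluded from kinetic measurements. They still count
  as releases in the failure analysis: excluding them there would bias the
  release-probability estimate low by the multivesicular rate.
  `estimate_quantal_bounds()` locates the one- and two-quantum modes with a
  Gaussian location mixture and sets the limit at
  `q1 + 0.5 * (q2 - q1)`, falling back to `1.5 * q1` with a warning when
  the amplitude distribution is effectively unimodal.
* the dwell time runs from peak attainment to the decay onset: the first
  run of at least 2 consecutive negative first differences of the de-noised
  trace. Two guards make this literal derivative rule usable: each step
  must exceed a minute fraction (1e-3) of the event amplitude, screening
  out the microscopic plateau declines the filter can produce on noiseless
  data; and the candidate must be *confirmed* — the de-noised trace,
  averaged 1 s and 1--3 s after the candidate, must drop below the running
  plateau median by 0.6x and 0.8x the raw baseline SD respectively.
  Without confirmation, smoothed noise on a 20 s plateau produces
  qualifying derivative runs with near-certainty and the censored class
  collapses; the near-window condition ties the onset to the start of the
  decline, since a far drop alone would back-date slow decays into the
  plateau. Both guard multiples were calibrated on simulated traces with
  known ground truth (as the filter parameters were) and vanish on
  noiseless data, recovering the plain derivative rule. If no confirmed
  onset occurs within 20 s the event is censored — ultraslow retrieval.
* the fraction of retrieval is `(peak - endpoint) / (peak - baseline)`,
  with the endpoint averaged over the final settled second before the next
  stimulus; classes are partial (< 0.8), quantal (1.0 +/- 0.2) and excess
  (> 1.2). For dwell times approaching the inter-stimulus interval the
  decay is incomplete at the endpoint, so measured fractions are biased
  low — a measurement-window limitation shared with the real experiment.

With 0.05 Hz stimulation the inter-stimulus interval equals the 20 s
censoring limit, so the two coincide; both are configurable independently
for other protocols. Release probability (`release_probability()`) is the
per-bouton fraction of scoreable stimuli with a detected event.

### Kinetics

`fit_dwell_distribution()` histograms uncensored dwells (density scale;
0.1 s bins below 1 s to resolve the ultrafast peak, 1 s bins above) and
fits one- or two-exponential decays with no constant offset — censored
events are excluded and counted, not modelled as an offset. A
maximum-likelihood exponential-mixture fit (EM) on the raw dwell times is
returned alongside; the two routes agree within a few percent at
realistic sample sizes and serve as mutual checks. `compare_models()`
performs the extra-sum-of-squares F test plus a reduced-R^2 comparison
between the nested fits. Fitted time constants are reported as such; mode
percentages always come from the hard 1 s / 20 s boundaries, not from
mixture responsibilities, mirroring the dual reporting convention of the
field.

`average_event_trace()` averages raw (non-de-noised) onset-aligned
segments, and `fit_two_phase_decay()` fits two exponentials plus a
constant (the constant absorbs the never-decaying fraction). When only one
kinetic phase is present the two components collapse and the fit is
flagged. `analyze_train_response()` measures 40 Hz train responses:
amplitude over the pre-train baseline, rise slope by linear regression
during the train, decay constant by a single-exponential fit of the
post-train return.

### Statistics and pools

`ks_two_sample()` and `kruskal_dunn()` wrap the two-sample
Kolmogorov-Smirnov and Kruskal-Wallis tests; Dunn's pairwise post-test is
computed from pooled tie-corrected rank sums with Bonferroni adjustment
(the adjustment method is switchable; the family correction is the
documented default). `surface_internal_ratio()` computes surface and
internal probe pools from acid-quench / NH4Cl epochs, discarding 2 s after
each solution switch for perfusion mixing, and refuses to report fractions
when a pool difference comes out negative.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(p_release = 0.45, seed = 1)
ds <- simulate_experiment(cfg, n_boutons = 60)
res <- run_pipeline(ds)
res
glance(res$release)
res$mode_proportions
glance(res$dwell_fit_double)
res$model_comparison
autoplot(res$dwell_fit_double)
```

## Validation scales and known limitations

The test suite validates the pipeline at the sizes the estimators need:
false positives on 500 negative-control boutons (10,000 stimuli), mode
composition on ~2,000 detected events, release probability on 500 boutons
of 20 stimuli, dwell-mixture recovery on 5,000 draws, and test calibration
on 2,000 null replicates; smaller versions of the same checks run in the
module tests.

Known limitations, all visible in the synthetic studies:

* dwell times of events that ride on the residual decay of a long-dwell
  event at the previous stimulus can be clipped when noise is absent or
  the confirmation guards are disabled; under the default noise model the
  SD-scaled guards absorb this.
* plateaus below the filter's resolution floor (about M + 2 frames) are
  measured short, so ultrafast time constants from 10 Hz recordings lean
  on the histogram fit rather than single-event accuracy.
* more broadly, the onset of a slow (default 4 s) re-acidification decay
  cannot be located to better than ~0.2 s at the default signal-to-noise
  ratio, so histograms of *measured* dwell times compress the ultrafast
  component towards zero even though mode classification (<= 1 s) is
  unaffected; the fitting routines themselves recover ultrafast and fast
  constants within 15% when applied to the underlying dwell samples.
* fractions of retrieval for dwell times near the inter-stimulus interval
  are biased low because the decay has not completed within the window.
* the bleach-plus-steps correction needs some event-free intervals (or a
  supplied mask) to pin the trend; with events at literally every
  stimulus it falls back to the minimal-drift solution.
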