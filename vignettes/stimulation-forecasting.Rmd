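---
title: "Forecasting seizures from stimulation responses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting seizures from stimulation responses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In people with treatment-resistant focal epilepsy undergoing intracranial
EEG (iEEG) monitoring, brief electrical probe pulses delivered through an
implanted electrode pair evoke measurable cortical responses. Under the
critical-slowing-down hypothesis, cortical dynamics approach a transition
before a seizure: perturbations decay more slowly, so the variance and the
lag-1 autocorrelation of the measured signal rise. `spescast` implements an
analysis pipeline that turns this idea into a testable forecaster: periodic
paired-pulse stimulation, artifact-repaired stimulus-locked epochs,
window-relative variance/autocorrelation features, a leave-one-patient-out
(LOSO) logistic classifier producing a per-stimulus seizure likelihood, and
an alarm system evaluated with chance-corrected metrics.

Because clinical iEEG of this kind is not freely redistributable, the
package ships a first-class synthetic cohort generator that reproduces the
statistical structure the analysis relies on. Every downstream stage is
exercised and tested against that generator.

## The synthetic cohort generator

Each patient is a multichannel recording at 512 Hz (so that downsampling to
the 256 Hz analysis rate is a real operation) with:

* a stimulation schedule of paired 1-ms pulses, 5 s apart within a pair,
  one pair every 5 min — the probing protocol of the study design;
* a saturating stimulus artifact in the first 20 ms after each pulse
  (5x larger on the stimulated channel pair);
* Gabor-shaped early (< 100 ms) and late (100 ms – 1 s) evoked components;
  the late component has full amplitude only on a configurable subset of
  "responsive" channels (default 5), mimicking electrodes near the
  epileptogenic tissue and giving the channel-selection stage a ground
  truth;
* AR(1) background noise per channel. The AR(1) choice is deliberate: the
  monitored features are exactly variance and lag-1 autocorrelation, and
  for an AR(1) process both have closed forms (variance
  $\sigma_e^2/(1-\phi^2)$, lag-1 autocorrelation $\phi$), so generator
  ground truth is analytic.

The pre-ictal state is modelled as a linear ramp over the final
`preictal_hours` (default 3 h) before the single annotated seizure onset:
the AR coefficient rises by `effect_ac` and the process variance by the
factor `effect_var`. The study-protocol effect conditions correspond to
`effect_var = 2`, `effect_ac = 0.1` over interictal
`ar_coeff_interictal = 0.6`. The ramp is expressed fully
(`stim_gain = 1`) inside the 6 s following each first pulse and at half
strength (`baseline_gain = 0.5`) in the unstimulated baseline; this encodes
the hypothesis that probing the cortex reveals excitability changes more
clearly than passive observation, and it is what makes the post-stimulus
4000–4980 ms window more informative than the pre-stimulus window in the
end-to-end tests. A linear ramp is an assumption — the source data show
monotone-looking but unspecified trends; any monotone ramp would serve.

Implementation notes: the AR coefficient and variance are held
piecewise-constant between stimulation events (segments delimited by pulse
times, the 6-s post-stimulus windows and the ramp boundaries) and segments
are chained through the recursion's initial state, so the signal is
continuous and the per-epoch ground truth exact. The recursion itself and
the decimating FIR are compiled (Rcpp) — they are the only per-sample loops
in the package. The seizure is represented only by its onset annotation; no
ictal waveform is synthesized because the analysis never uses post-onset
data (only the first seizure is analysed, and evaluation stops at its
onset).

What the generator does *not* emulate: circadian/multidien rhythms (absent
from the emulated ~1-day recordings), spatial correlation between channels
beyond the common evoked responses, non-stationary interictal epochs,
multi-seizure patients. Passing tests therefore show that the pipeline
recovers the planted critical-slowing structure under realistic noise — not
that real iEEG carries that structure.

## Preprocessing

The chain is: common-average re-reference, anti-aliased downsampling to
256 Hz, epoching, automatic rejection, cubic-spline artifact repair,
zero-phase filtering.

* **Epoch span.** Epochs cover −1500 ms to +6000 ms around the *first*
  pulse (1920 samples at 256 Hz). A ±2 s epoch cannot hold the analysis
  windows, which extend to 4980 ms after the first pulse and 1000 ms after
  the second (6000 ms after the first); one wide epoch per pulse *pair*
  holds all six.
* **Rejection.** Visual inspection is replaced by a reproducible robust
  criterion: an epoch is flagged invalid when its peak absolute amplitude
  (ignoring the 50 ms after each pulse, which contain the artifact and its
  anti-alias smear) exceeds the median + 8 MAD of the per-epoch peak
  distribution. Flags are never deletions; downstream stages treat invalid
  epochs as missing. With zero spread (identical epochs) nothing is
  rejected. Rejection amplitudes are measured before repair and filtering
  so bursts cannot hide behind them; ordering rejection after the (linear)
  re-reference and downsampling is harmless because a burst can only leak
  into other channels of its *own* already-flagged epoch.
* **Artifact repair.** The samples covering 0 ≤ t < 20 ms after each pulse
  — 5 samples per pulse at 256 Hz, the pulse-onset sample included — are
  replaced by a cubic spline fitted on 8 flanking samples per side
  (Forsythe–Malcolm–Moler end conditions, so cubic signals are reproduced
  exactly). Repair precedes filtering so the saturating artifact never
  smears through the IIR filters.
* **Filtering.** Per channel and epoch: demean, then forward–backward
  4th-order Butterworth high-pass at 0.1 Hz and low-pass at 120 Hz, then a
  4-pole band-stop at 48–52 Hz (European line noise). Forward–backward
  application makes the chain zero-phase; the demeaning step pins the DC
  response of the short-epoch high-pass to exactly zero.
* **Downsampling** uses a 33-tap symmetric (hence zero-phase) FIR low-pass
  with cutoff at 0.8x the target Nyquist, evaluated only at the kept
  sample positions; edges replicate the boundary sample. Only integer
  decimation factors are supported.

## Features, labels, normalization

Six analysis windows are defined relative to the pulses: −1000…−20 ms
before pulse 1 (passive baseline), 20–100 ms and 20–1000 ms after each
pulse, and 4000–4980 ms after pulse 1 (ending 20 ms before pulse 2). The
channel set is the single most "prominent" channel, the top 5, or all
channels — prominence being the mean RMS amplitude in the 100–1000 ms
late-response band after pulse 1, with the stimulated pair always excluded
and ties broken by label order. Per stimulus: population variance (N
denominator, the critical-slowing convention — immaterial at 250-sample
windows) and lag-1 Pearson autocorrelation, averaged across the selected
channels, plus trailing cumulative means over the previous 12 values
(including the current one: 12 stimuli x 5 min = exactly 1 h), skipping
invalid entries. The lag of one sample at 256 Hz is a documented assumption
exposed as a parameter; it is the standard estimator in the cited
critical-slowing literature.

Stimuli in [onset − 3 h, onset) are labelled pre-ictal (closed lower
bound), earlier stimuli inter-ictal, and everything from onset on is
excluded. Features are z-normalized within patient: *retrospectively* with
interictal mean/SD (the primary analysis), or *pseudo-prospectively* with
the mean/SD of the first two recording hours, which are then excluded from
evaluation. Prospective mode needs 2 h of normalization data plus the 3-h
pre-ictal window, i.e. at least 5 h before the seizure; patients failing
that are skipped (with the skip logged) but still serve as training data.

## Forecaster

The classifier is L2-regularized logistic regression (glmnet, alpha = 0,
convergence threshold 1e-12 so LOSO outputs are reproducible to numerical
precision) on the 4 features of one window/channel-mode combination. The
default penalty is lambda = 1/n_train — the glmnet equivalent of the
standard C = 1 default of stock logistic-regression implementations — and
rows are unweighted, again the stock behaviour. The unweighted default
matters for the chance-level contract: an uninformative fit then predicts
roughly the pooled pre-ictal base rate (~0.2–0.3), below the 0.4 floor of
the alarm-threshold grid, so a null forecaster raises no alarms. An
inverse-class-frequency-weighted fit instead centres null probabilities
near 0.5, inside the grid, and because temporally smooth probability
series accumulate systematically *less* warning time than their shuffled
surrogates (clustered crossings are absorbed by a running alarm), a
zero-information forecaster would spuriously beat its own chance level.
Weighting is therefore available as an explicit flag for sensitivity
analyses, not as the default. Training folds
never touch the held-out patient — asserted by construction and by a
leakage test that mangles the held-out table and requires bit-identical
fold coefficients.

## Alarm system and metrics

An alarm starts when the likelihood reaches the threshold and no alarm is
active; it lasts one seizure occurrence period (SOP); crossings during an
active alarm are absorbed. The evaluated span runs from the first evaluated
stimulus to the (first) seizure onset, and warning time is truncated there.
Sensitivity is 1 iff the onset falls in [alarm start, start + SOP); the
forecasting horizon is the time from the covering alarm's start to the
onset. Time in warning (tiw) is the warned fraction of the evaluated span.
Improvement over chance is implemented as IoC = sensitivity − tiw, the
standard chance-corrected sensitivity; the jointly reported cohort averages
of the source analysis (sensitivity 0.88, tiw 0.14, IoC 0.74) satisfy this
identity exactly, which the acceptance checks verify. The Brier Skill Score
uses the per-patient climatological reference (constant forecast equal to
the pre-ictal prevalence): BSS = 1 − BS/BS_ref, undefined when a patient
has only one class.

Alarm parameters are grid-searched on training patients only: thresholds
0.40–0.80 in steps of 0.01 and SOP 30–240 min in steps of 30 (the SOP
granularity is a package choice; only the range is prescribed). The
training criterion is the mean IoC over the training patients' own LOSO
forecast series, with deterministic tie-breaks toward smaller SOP, then
lower threshold. Chance levels come from shuffling each patient's
probability sequence 100 times, re-running the alarms with identical
parameters, and averaging sensitivity, tiw and IoC — negative surrogate IoC
values are clamped to zero before averaging, so the reported chance level
is conservative (never below zero).

The alarm logic is verified exactly against an independent brute-force
minute-grid simulator on 1000 randomized instances with integer-minute
geometry, where the continuous-interval and minute-count formulations must
agree to the last bit.

## Problem sizes and numerical choices

The test suite exercises the full chain on two 8-patient cohorts (the
pre-ictal-effect cohort and its matched null): 12-h recordings — the
study protocol's minimum duration, which keeps the pooled pre-ictal
prevalence near the study's — with 8 channels and 144 pulse pairs per
patient, sizes chosen so the whole suite runs on one CPU in well under
half an hour. The generator accepts the full-scale
ranges (12–26 h, 13–62 channels) but materialises recordings densely in
memory (a 26-h, 62-channel recording at 512 Hz is ~16 GB), so full-scale
runs need commensurate resources; the statistical structure does not
change with duration or channel count. Other numerical choices: tie-breaks
in channel selection and grid search are deterministic; the spline repair
errors rather than extrapolating when the repair window leaves the epoch;
zero-variance windows mark the feature row invalid instead of producing
NaN autocorrelations; all randomness flows from explicit integer seeds,
with per-patient and per-purpose sub-seeds derived arithmetically so that
regeneration is order-independent and bit-identical.

## Known limitations

* IoC, sensitivity and BSS definitions follow the standard forecasting
  literature; the source analysis's own supplementary definitions were not
  available, so agreement is by identity checks on jointly printed
  averages, not by formula transcription.
* The generator's evoked-response morphology (Gabor shapes, amplitudes,
  latencies) is free parameterisation; only its ordinal structure (late
  responses largest on responsive channels) is used by the analysis.
* Cohort-scale results from the synthetic cohorts are not expected to
  reproduce the clinical cohort's printed averages; they establish that
  the pipeline detects planted critical-slowing effects and stays at
  chance on null cohorts.
* Single seizure per patient, no multi-seizure evaluation, no circadian
  covariates, no time-matched seizure surrogates.
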