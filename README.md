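# spescast

Seizure forecasting from intracranial EEG (iEEG) responses to paired-pulse
electrical stimulation.

## The problem

In focal epilepsy, the hypothesis of *critical slowing down* predicts that
as cortical dynamics approach a seizure, perturbations decay more slowly:
signal variance and lag-1 autocorrelation rise. Actively probing the cortex
with periodic single-pulse electrical stimulation (SPES) — paired 1-ms
pulses 5 s apart, one pair every 5 min, through a fixed electrode pair —
and measuring features of the evoked iEEG response may expose this drift
more clearly than passive monitoring. `spescast` implements the full
analysis as a tested R package plus an `analysis/` workflow:

1. **Synthetic cohort** (`generate_cohort`): seeded multichannel recordings
   with the stimulation protocol, stimulus artifacts, early/late evoked
   responses, and AR(1) background whose variance (factor `effect_var`) and
   AR coefficient (`+effect_ac`) ramp linearly over a 3-h pre-ictal window
   ending at a single annotated seizure onset. Clinical data of this kind
   are not redistributable, so the generator is a first-class, tested
   module, not a fixture.
2. **Preprocessing** (`preprocess_patient`): common-average reference,
   anti-aliased downsampling to 256 Hz, epochs from −1.5 s to +6 s around
   each pulse pair, robust automatic rejection of corrupted epochs
   (median + 8·MAD on peak amplitude), cubic-spline repair of the 0–20 ms
   stimulus artifact, zero-phase 4th-order Butterworth band-pass
   (0.1–120 Hz) and 48–52 Hz band-stop.
3. **Features** (`featurize_patient`): per stimulus, in one of six windows
   relative to the pulses (e.g. 4000–4980 ms after pulse 1, or the passive
   −1000…−20 ms baseline), on the top-1/top-5/all channels ranked by
   late-response prominence: population variance, lag-1 autocorrelation,
   and their trailing 12-value (1-h) cumulative averages; pre-ictal labels
   (`[onset − 3 h, onset)`) and per-patient z-normalization (retrospective
   interictal, or pseudo-prospective first-2-h).
4. **Forecast** (`fit_loso`): leave-one-patient-out L2 logistic regression
   on the 4 features, yielding a seizure likelihood `p` per stimulus.
5. **Evaluation** (`evaluate_cohort`): an alarm starts when `p` crosses a
   threshold and lasts one seizure occurrence period (SOP); threshold
   (0.40–0.80, step 0.01) and SOP (30–240 min) are grid-searched on
   training patients only. Metrics per patient:
   - sensitivity ∈ {0, 1}: does an alarm interval cover the onset;
   - time in warning `tiw`: warned fraction of the evaluated span;
   - improvement over chance `IoC = sensitivity − tiw`;
   - Brier Skill Score `BSS = 1 − BS/BS_ref` against the patient's
     base-rate forecast;
   - forecasting horizon: minutes from the covering alarm's start to onset;
   - chance level: mean sensitivity/tiw/IoC over 100 shuffles of the
     probability sequence (negative surrogate IoC clamped to 0).

## Worked example

The `analysis/` scripts run the whole study on a 4-patient demo cohort
(6-h recordings, 10 channels, variance ×2 and autocorrelation +0.1
pre-ictal ramps, 2% corrupted stimuli):

```sh
Rscript analysis/run_all.R     # ~5 min; stages also runnable one by one
```

Stage 2 reports the automatic rejection recovering the planted corrupt
epochs:

```
P01: 72 epochs, 1 rejected (1 planted corrupt)
P02: 72 epochs, 1 rejected (1 planted corrupt)
P03: 72 epochs, 0 rejected (0 planted corrupt)
P04: 72 epochs, 1 rejected (1 planted corrupt)
```

Stage 3 shows the planted effect in the normalized features — the
post-stimulus window carries the stronger pre-ictal shift (the generator
couples the excitability change more strongly to the stimulated state):

```
post_first_4000_4980: mean z-var preictal 10.05 vs interictal 0.00
pre_first:            mean z-var preictal  5.31 vs interictal 0.00
```

Stage 5 evaluates the LOSO forecaster on the post-stimulus 4000–4980 ms
window (`results/report.json` holds the full report):

```
 patient_id p_threshold sop_min sensitivity   tiw   ioc   bss horizon_min
        P01        0.76      30           1 0.438 0.562 0.699      20.073
        P02        0.76      30           1 0.485 0.515 0.754       0.648
        P03        0.76      30           1 0.491 0.509 0.764       9.369
        P04        0.71      30           1 0.524 0.476 0.847      15.053
cohort: sens 1.00 | tiw 0.48 | IoC 0.52 | BSS 0.77 | horizon 11.3 min |
        surrogate IoC 0.14 | above chance 4/4
```

Every patient's seizure is caught (sensitivity 1) with IoC far above the
100-shuffle chance level (~0.14). The `tiw` values (~0.5) are a property
of the short 6-h demo records, where the 3-h pre-ictal period is half the
evaluated span; on longer records the warning load drops accordingly. On
a matched null cohort (`effect_var = 1`, `effect_ac = 0` — see the test
suite) the same pipeline stays at its chance level.

The same computation is available as one call:

```r
library(spescast)
cfg <- run_config(gen = generator_params(n_patients = 4,
                                         record_hours = c(6, 6),
                                         n_channels = c(10, 10),
                                         effect_var = 2, effect_ac = 0.1,
                                         seed = 1))
report <- run_pipeline(cfg)   # spes_eval_report, printable as above
```

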