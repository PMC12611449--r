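# Shared configuration of the analysis workflow.
#
# Desk-scale demo cohort: 4 synthetic patients, 6-h recordings, 10 channels,
# paired pulses every 5 min, 3-h pre-ictal window with a variance x2 /
# autocorrelation +0.1 ramp. Bulk intermediates (raw signals, epochs) go to
# scratch/ as RDS; compact tables and reports go to results/.
library(spescast)

ANALYSIS_SEED <- 1L
SCRATCH <- "scratch/analysis"
RESULTS <- "results"

demo_params <- function(effect = TRUE, seed = ANALYSIS_SEED) {
  generator_params(
    n_patients = 4, record_hours = c(6, 6), n_channels = c(10, 10),
    effect_var = if (effect) 2.0 else 1.0,
    effect_ac = if (effect) 0.1 else 0.0,
    corrupt_epoch_rate = 0.02,
    seed = seed)
}

dir.create(SCRATCH, recursive = TRUE, showWarnings = FALSE)
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)
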