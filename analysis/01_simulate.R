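#!/usr/bin/env Rscript
# Stage 1 — simulate the synthetic SPES cohort.
#
# Generates the demo cohort and stores each patient's continuous recording,
# stimulation schedule and seizure annotation. One patient is additionally
# written in the portable CSV + JSON-sidecar exchange format as a format
# round-trip example.
source("analysis/00_config.R")

params <- demo_params()
# one patient in memory at a time; a continuous recording is ~0.9 GB
for (i in seq_len(params$n_patients)) {
  p <- generate_patient(params, i)
  cat(sprintf("%s: %.1f h, %d channels, %d pulse pairs, seizure at %.2f h\n",
              p$patient_id, ncol(p$recording$signal) / p$recording$fs / 3600,
              nrow(p$recording$signal), nrow(p$schedule$pairs),
              p$seizure$onset_s / 3600))
  saveRDS(p, file.path(SCRATCH, paste0(p$patient_id, ".rds")))
  if (i == 1) write_patient(p, file.path(SCRATCH, "exchange_P01"))
  rm(p); gc(FALSE)
}
cat("cohort written to", SCRATCH, "\n")
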