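#!/usr/bin/env Rscript
# Stage 2 — preprocessing chain.
#
# Common-average re-reference, downsample 512 -> 256 Hz, epoch around each
# pulse pair (-1.5 s .. +6 s), flag corrupted epochs by the robust
# amplitude criterion, cubic-spline repair of the 0-20 ms stimulus
# artifact, zero-phase band-pass + notch filtering. Writes the per-patient
# epoch stores and a rejection log.
source("analysis/00_config.R")

files <- list.files(SCRATCH, pattern = "^P[0-9]+\\.rds$", full.names = TRUE)
log <- list()
for (f in files) {
  p <- readRDS(f)
  ep <- preprocess_patient(p$recording, p$schedule)
  saveRDS(list(patient_id = p$patient_id, epochs = ep,
               onset_s = p$seizure$onset_s),
          file.path(SCRATCH, paste0(p$patient_id, "_epochs.rds")))
  log[[p$patient_id]] <- data.frame(
    patient_id = p$patient_id, n_epochs = length(ep$valid),
    n_rejected = sum(!ep$valid), n_dropped = ep$n_dropped,
    planted_corrupt = length(p$corrupt_stimuli))
  cat(sprintf("%s: %d epochs, %d rejected (%d planted corrupt)\n",
              p$patient_id, length(ep$valid), sum(!ep$valid),
              length(p$corrupt_stimuli)))
  rm(p, ep); gc(FALSE)
}
log <- do.call(rbind, log)
write.csv(log, file.path(RESULTS, "rejection_log.csv"), row.names = FALSE)
cat("epoch stores written; rejection log in results/rejection_log.csv\n")
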