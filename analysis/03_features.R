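#!/usr/bin/env Rscript
# Stage 3 — feature extraction.
#
# For the post-stimulus 4000-4980 ms window and the passive pre-stimulus
# window (-1000 to -20 ms), on the top-5 late-response channels: variance,
# lag-1 autocorrelation, their trailing 1-h cumulative averages, pre-ictal
# labels and per-patient retrospective z-normalization.
source("analysis/00_config.R")

files <- list.files(SCRATCH, pattern = "_epochs\\.rds$", full.names = TRUE)
all_rows <- list()
for (f in files) {
  st <- readRDS(f)
  for (win in c("post_first_4000_4980", "pre_first")) {
    tbl <- featurize_patient(st$epochs, window = win,
                             channel_mode = "top5", onset_s = st$onset_s)
    z <- znormalize(tbl)$table
    z$patient_id <- st$patient_id
    z$window_id <- win
    z$onset_s <- st$onset_s
    all_rows[[paste(st$patient_id, win)]] <- z
  }
}
feat <- do.call(rbind, all_rows)
write.csv(feat, file.path(RESULTS, "features.csv"), row.names = FALSE)
pre <- subset(feat, label == "preictal" & valid)
inter <- subset(feat, label == "interictal" & valid)
for (win in unique(feat$window_id)) {
  cat(sprintf("%s: mean z-var preictal %.2f vs interictal %.2f\n", win,
              mean(pre$var[pre$window_id == win]),
              mean(inter$var[inter$window_id == win])))
}
cat("feature table written to results/features.csv\n")
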