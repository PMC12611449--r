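#!/usr/bin/env Rscript
# Stage 4 — leave-one-patient-out logistic forecasting.
#
# Per analysis window, trains the weighted L2 logistic model on the other
# patients' normalized features and predicts each held-out patient's
# seizure likelihood per stimulus.
source("analysis/00_config.R")

feat <- read.csv(file.path(RESULTS, "features.csv"))
probs <- list()
for (win in unique(feat$window_id)) {
  sub <- subset(feat, window_id == win)
  tabs <- split(sub, sub$patient_id)
  tabs <- lapply(tabs, function(tb) {
    attr(tb, "onset_s") <- tb$onset_s[1]
    tb
  })
  loso <- fit_loso(tabs)
  for (id in names(loso$series)) {
    s <- loso$series[[id]]
    s$window_id <- win
    probs[[paste(win, id)]] <- s
  }
  cat(sprintf("%s: fitted %d LOSO folds\n", win, length(loso$series)))
}
probs <- do.call(rbind, probs)
write.csv(probs, file.path(RESULTS, "probabilities.csv"),
          row.names = FALSE)
cat("seizure-likelihood series written to results/probabilities.csv\n")
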