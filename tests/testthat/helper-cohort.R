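# Desk-scale study cohorts shared across test files (memoised: generation +
# preprocessing of 16 patients is the dominant cost of the suite). 12-h
# records (the study's minimum duration), 8 channels, stimulation every
# 5 min as in the study protocol;
# the "effect" cohort carries the pre-ictal variance x2 / autocorrelation
# +0.1 ramp, the "null" cohort is its matched no-effect control. Seeds are
# fixed constants of the test design.
.spes_cache <- new.env(parent = emptyenv())

study_cohort_params <- function(kind = c("effect", "null")) {
  kind <- match.arg(kind)
  generator_params(
    n_patients = 8, record_hours = c(12, 12), n_channels = c(8, 8),
    effect_var = if (kind == "effect") 2.0 else 1.0,
    effect_ac = if (kind == "effect") 0.1 else 0.0,
    corrupt_epoch_rate = 0,
    seed = if (kind == "effect") 1L else 2L)
}

# returns list(epochs = list of spes_epochs, onsets, patients meta)
cached_study_epochs <- function(kind) {
  key <- paste0("epochs_", kind)
  if (!exists(key, envir = .spes_cache)) {
    params <- study_cohort_params(kind)
    epochs <- list(); onsets <- numeric(0); meta <- list()
    # one patient in memory at a time: a continuous multichannel recording
    # is large, the preprocessed epochs are small
    for (i in seq_len(params$n_patients)) {
      p <- generate_patient(params, i)
      epochs[[i]] <- preprocess_patient(p$recording, p$schedule)
      onsets[p$patient_id] <- p$seizure$onset_s
      meta[[i]] <- list(patient_id = p$patient_id,
                        responsive = p$responsive)
      rm(p); gc(FALSE)
    }
    assign(key, list(epochs = epochs, onsets = onsets, meta = meta),
           envir = .spes_cache)
  }
  get(key, envir = .spes_cache)
}

# normalized per-patient feature tables for a window/channel mode
study_feature_tables <- function(kind, window = "post_first_4000_4980",
                                 channel_mode = "top5") {
  co <- cached_study_epochs(kind)
  tabs <- list()
  for (i in seq_along(co$epochs)) {
    id <- names(co$onsets)[i]
    tbl <- featurize_patient(co$epochs[[i]], window = window,
                             channel_mode = channel_mode,
                             onset_s = co$onsets[[i]])
    tabs[[id]] <- znormalize(tbl)$table
  }
  list(tables = tabs, onsets = co$onsets)
}
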