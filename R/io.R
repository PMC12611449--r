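#' Write a synthetic patient to disk
#'
#' Plain-text on-disk format: `signal.csv` (channels as columns, one row per
#' sample) and `sidecar.json` holding the sampling rate, channel labels,
#' stimulation pairs (seconds), the stimulated channel pair and the seizure
#' onset. Event times round-trip exactly; signal values round-trip to full
#' double precision.
#'
#' @param patient a patient list from [generate_patient()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_patient <- function(patient, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sig <- t(patient$recording$signal)
  colnames(sig) <- patient$recording$channel_labels
  data.table::fwrite(data.table::as.data.table(sig),
                     file.path(dir, "signal.csv"))
  sidecar <- list(patient_id = patient$patient_id,
                  fs = patient$recording$fs,
                  t0 = patient$recording$t0,
                  channel_labels = patient$recording$channel_labels,
                  stim_pairs = patient$schedule$pairs,
                  stim_channel_pair = patient$schedule$stim_channel_pair,
                  seizure_onset_s = patient$seizure$onset_s)
  jsonlite::write_json(sidecar, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a patient (signal + sidecar) from disk
#'
#' Counterpart of [write_patient()]; also accepts user-supplied data in the
#' same layout. Errors descriptively when the sidecar is missing or its
#' stimulated channels are absent from the signal header.
#'
#' @param dir directory holding `signal.csv` and `sidecar.json`.
#' @return list with recording, schedule, seizure and patient_id.
#' @export
read_patient <- function(dir) {
  sig_path <- file.path(dir, "signal.csv")
  sc_path <- file.path(dir, "sidecar.json")
  if (!file.exists(sc_path))
    stop(sprintf("missing sidecar.json in %s", dir), call. = FALSE)
  if (!file.exists(sig_path))
    stop(sprintf("missing signal.csv in %s", dir), call. = FALSE)
  sidecar <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  sig <- data.table::fread(sig_path)
  labels <- names(sig)
  if (!all(sidecar$stim_channel_pair %in% labels))
    stop("sidecar stimulation channels not present in the signal header",
         call. = FALSE)
  if (!identical(labels, as.character(sidecar$channel_labels)))
    stop("sidecar channel labels do not match the signal header",
         call. = FALSE)
  rec <- new_recording(t(as.matrix(sig)), sidecar$fs, labels,
                       t0 = sidecar$t0)
  sched <- structure(list(pairs = as.data.frame(sidecar$stim_pairs),
                          stim_channel_pair = sidecar$stim_channel_pair),
                     class = "spes_schedule")
  list(patient_id = sidecar$patient_id, recording = rec, schedule = sched,
       seizure = list(onset_s = sidecar$seizure_onset_s))
}
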