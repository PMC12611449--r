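# Wrap a channels x samples matrix (one epoch) into a spes_epochs object
# with the standard geometry: 1920 samples at 256 Hz, pulses at offsets 0
# and +5 s relative to sample 385.
make_epochs <- function(..., fs = 256) {
  mats <- list(...)
  arr <- array(0, dim = c(nrow(mats[[1]]), ncol(mats[[1]]), length(mats)))
  for (j in seq_along(mats)) arr[, , j] <- mats[[j]]
  structure(list(signal = arr, fs = fs,
                 channel_labels = sprintf("CH%02d", seq_len(dim(arr)[1])),
                 stim_index = seq_along(mats),
                 t_first = 150 + (seq_along(mats) - 1) * 300,
                 pulse_offsets = c(0, round(5 * fs)),
                 zero_sample = round(1.5 * fs) + 1,
                 valid = rep(TRUE, length(mats)),
                 n_dropped = 0,
                 stim_channel_pair = character(0)),
            class = "spes_epochs")
}

epoch_time_ms <- function(fs = 256, n = 1920) {
  ((seq_len(n) - (round(1.5 * fs) + 1)) / fs) * 1000
}
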