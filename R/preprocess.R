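#' Preprocessing configuration
#'
#' Parameters of the stimulus-locked preprocessing chain: common-average
#' re-reference, anti-aliased downsampling to 256 Hz, epoching around each
#' pulse pair, robust automatic epoch rejection, cubic-spline repair of the
#' 0-20 ms stimulus artifact, and zero-phase Butterworth band-pass (0.1-120
#' Hz) plus band-stop (48-52 Hz) filtering.
#'
#' @param fs_target target rate in Hz (256).
#' @param artifact_repair_ms artifact-repair span after each pulse.
#' @param bandpass_hz length-2 band edges of the band-pass.
#' @param filter_order Butterworth order of high-/low-pass sections.
#' @param notch_hz length-2 edges of the band-stop (line noise).
#' @param rejection_zmax robust-z cutoff on per-epoch peak amplitude; epochs
#'   whose peak (outside the immediate post-pulse windows) exceeds
#'   median + zmax * MAD are flagged invalid.
#' @param rejection_exclude_ms span after each pulse ignored when measuring
#'   the peak (covers the artifact plus anti-alias filter smear).
#' @return list of class `spes_preprocess_config`.
#' @export
preprocess_config <- function(fs_target = 256,
                              artifact_repair_ms = 20,
                              bandpass_hz = c(0.1, 120),
                              filter_order = 4,
                              notch_hz = c(48, 52),
                              rejection_zmax = 8,
                              rejection_exclude_ms = 50) {
  stopifnot(bandpass_hz[1] < bandpass_hz[2],
            bandpass_hz[2] < fs_target / 2,
            artifact_repair_ms > 0)
  structure(list(fs_target = fs_target,
                 artifact_repair_ms = artifact_repair_ms,
                 bandpass_hz = bandpass_hz, filter_order = filter_order,
                 notch_hz = notch_hz, rejection_zmax = rejection_zmax,
                 rejection_exclude_ms = rejection_exclude_ms),
            class = "spes_preprocess_config")
}

#' Common-average re-reference
#'
#' Subtracts, at every sample, the mean across channels; afterwards the
#' channel mean at each time point is zero.
#'
#' @param rec a `spes_recording`.
#' @return re-referenced `spes_recording`.
#' @export
rereference_common_average <- function(rec) {
  if (nrow(rec$signal) < 2)
    stop("common-average reference is undefined for a single channel",
         call. = FALSE)
  mu <- colMeans(rec$signal)
  # blockwise so long recordings never hold several full-size temporaries
  nch <- nrow(rec$signal)
  n <- ncol(rec$signal)
  block <- 1e6L
  for (b in seq(1L, n, by = block)) {
    idx <- b:min(b + block - 1L, n)
    rec$signal[, idx] <- rec$signal[, idx] - rep(mu[idx], each = nch)
  }
  rec
}

#' Anti-aliased downsampling by an integer factor
#'
#' Applies a zero-phase (symmetric FIR) low-pass at 0.8 x the new Nyquist
#' before decimating. Edge samples where the symmetric filter is undefined
#' keep their unfiltered values.
#'
#' @param rec a `spes_recording`.
#' @param fs_target new rate in Hz; must divide `rec$fs`.
#' @return downsampled `spes_recording`.
#' @export
downsample <- function(rec, fs_target) {
  if (fs_target > rec$fs)
    stop("fs_target exceeds the recording rate", call. = FALSE)
  if (fs_target == rec$fs) return(rec)
  q <- rec$fs / fs_target
  if (abs(q - round(q)) > 1e-9)
    stop("fs_target must divide the recording rate", call. = FALSE)
  q <- round(q)
  h <- signal::fir1(32, 0.8 / q)
  n <- ncol(rec$signal)
  out <- matrix(0, nrow = nrow(rec$signal), ncol = length(seq(1, n, by = q)))
  for (ch in seq_len(nrow(rec$signal))) {
    out[ch, ] <- .fir_decimate(rec$signal[ch, ], h, q)
  }
  new_recording(out, fs_target, rec$channel_labels, rec$t0)
}

# Fused common-average reference + decimation, channel by channel: the
# arithmetic is bit-identical to rereference_common_average() followed by
# downsample() (both are linear and act per channel), but the full-rate
# re-referenced matrix is never materialised — this halves the peak memory
# on multi-hour recordings.
car_downsample <- function(rec, fs_target) {
  if (nrow(rec$signal) < 2)
    stop("common-average reference is undefined for a single channel",
         call. = FALSE)
  if (fs_target > rec$fs)
    stop("fs_target exceeds the recording rate", call. = FALSE)
  q <- rec$fs / fs_target
  if (abs(q - round(q)) > 1e-9)
    stop("fs_target must divide the recording rate", call. = FALSE)
  q <- round(q)
  mu <- colMeans(rec$signal)
  n <- ncol(rec$signal)
  if (q == 1) {
    return(rereference_common_average(rec))
  }
  h <- signal::fir1(32, 0.8 / q)
  out <- matrix(0, nrow = nrow(rec$signal),
                ncol = length(seq(1, n, by = q)))
  for (ch in seq_len(nrow(rec$signal))) {
    out[ch, ] <- .fir_decimate(rec$signal[ch, ] - mu, h, q)
  }
  new_recording(out, fs_target, rec$channel_labels, rec$t0)
}

# epoch geometry at 256 Hz: -1500 ms .. +6000 ms around the first pulse
EPOCH_PRE_S <- 1.5
EPOCH_POST_S <- 6.0

#' Cut stimulus-locked epochs
#'
#' One epoch per pulse pair, spanning -1500 ms to +6000 ms around the first
#' pulse (wide enough to hold every analysis window, including 20-1000 ms
#' after the second pulse). Pairs whose span exceeds the recording bounds are
#' dropped with a reported count.
#'
#' @param rec a `spes_recording` at the target rate.
#' @param sched a `spes_schedule`.
#' @return object of class `spes_epochs`: signal array channels x samples x
#'   epochs, pulse offsets, times, and a `valid` flag per epoch.
#' @export
epoch_stimuli <- function(rec, sched) {
  if (is.null(sched$pairs) || nrow(sched$pairs) == 0)
    stop("empty stimulation schedule", call. = FALSE)
  fs <- rec$fs
  pre <- round(EPOCH_PRE_S * fs)
  post <- round(EPOCH_POST_S * fs) - 1
  n_samp <- pre + post + 1              # 1920 at 256 Hz
  n <- ncol(rec$signal)
  i0 <- round((sched$pairs$t_first - rec$t0) * fs) + 1
  ok <- (i0 - pre >= 1) & (i0 + post <= n)
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(sprintf("epoch_stimuli: dropped %d out-of-bounds pulse pair(s)",
                    n_dropped))
  kept <- which(ok)
  arr <- array(0, dim = c(nrow(rec$signal), n_samp, length(kept)))
  for (j in seq_along(kept)) {
    arr[, , j] <- rec$signal[, (i0[kept[j]] - pre):(i0[kept[j]] + post)]
  }
  pulse2 <- round(mean(sched$pairs$t_second - sched$pairs$t_first) * fs)
  structure(list(signal = arr, fs = fs,
                 channel_labels = rec$channel_labels,
                 stim_index = kept,
                 t_first = sched$pairs$t_first[kept],
                 pulse_offsets = c(0, pulse2),   # samples after epoch zero
                 zero_sample = pre + 1,
                 valid = rep(TRUE, length(kept)),
                 n_dropped = n_dropped,
                 stim_channel_pair = sched$stim_channel_pair),
            class = "spes_epochs")
}

#' @export
#' @method print spes_epochs
print.spes_epochs <- function(x, ...) {
  cat(sprintf("<spes_epochs> %d epochs x %d channels x %d samples @ %g Hz (%d valid)\n",
              dim(x$signal)[3], dim(x$signal)[1], dim(x$signal)[2], x$fs,
              sum(x$valid)))
  invisible(x)
}

#' Automatic rejection of corrupted epochs
#'
#' Algorithmic stand-in for visual inspection: computes each epoch's peak
#' absolute amplitude outside the post-pulse exclusion windows and flags
#' epochs whose peak exceeds `median + rejection_zmax * MAD` of the peak
#' distribution. Flags only; epochs are never deleted, and downstream stages
#' treat invalid epochs as missing. With zero spread (all-identical epochs)
#' nothing is rejected.
#'
#' @param epochs a `spes_epochs` object.
#' @param cfg a `spes_preprocess_config`.
#' @return `epochs` with updated `valid` flags.
#' @export
reject_corrupted <- function(epochs, cfg = preprocess_config()) {
  excl <- integer(0)
  w <- round(cfg$rejection_exclude_ms / 1000 * epochs$fs)
  for (po in epochs$pulse_offsets) {
    excl <- c(excl, epochs$zero_sample + po + 0:(w - 1))
  }
  keep_samp <- setdiff(seq_len(dim(epochs$signal)[2]), excl)
  peaks <- apply(abs(epochs$signal[, keep_samp, , drop = FALSE]), 3, max)
  med <- stats::median(peaks)
  s <- stats::mad(peaks)
  if (s > 0) {
    bad <- peaks > med + cfg$rejection_zmax * s
    epochs$valid <- epochs$valid & !bad
  }
  epochs
}

#' Cubic-spline repair of the stimulus artifact
#'
#' Replaces the samples covering 0 <= t < `artifact_repair_ms` after each
#' pulse (5 samples per pulse at 256 Hz with the 20 ms default, pulse-onset
#' sample included) by a cubic spline fitted on the flanking samples. All
#' other samples are untouched.
#'
#' @param epochs a `spes_epochs` object.
#' @param artifact_repair_ms repair span in milliseconds.
#' @param n_flank flanking samples used on each side of the gap.
#' @return repaired `spes_epochs`.
#' @export
repair_stim_artifact <- function(epochs, artifact_repair_ms = 20,
                                 n_flank = 8) {
  n_rep <- round(artifact_repair_ms / 1000 * epochs$fs)
  n_samp <- dim(epochs$signal)[2]
  for (po in epochs$pulse_offsets) {
    gap <- epochs$zero_sample + po + 0:(n_rep - 1)
    flank <- c(gap[1] - n_flank:1, gap[n_rep] + 1:n_flank)
    if (any(c(gap, flank) < 1) || any(c(gap, flank) > n_samp))
      stop("artifact-repair window exceeds epoch bounds", call. = FALSE)
    for (j in seq_len(dim(epochs$signal)[3])) {
      for (ch in seq_len(dim(epochs$signal)[1])) {
        sf <- stats::splinefun(flank, epochs$signal[ch, flank, j],
                               method = "fmm")
        epochs$signal[ch, gap, j] <- sf(gap)
      }
    }
  }
  epochs
}

butter_filters <- function(cfg, fs) {
  ny <- fs / 2
  list(hp = signal::butter(cfg$filter_order, cfg$bandpass_hz[1] / ny,
                           type = "high"),
       lp = signal::butter(cfg$filter_order, cfg$bandpass_hz[2] / ny,
                           type = "low"),
       notch = signal::butter(cfg$filter_order / 2, cfg$notch_hz / ny,
                              type = "stop"))
}

#' Zero-phase band-pass and notch filtering of epochs
#'
#' Per channel and epoch: remove the epoch mean, then apply forward-backward
#' (zero-phase) 4th-order Butterworth high-pass at 0.1 Hz, low-pass at 120
#' Hz, and a 4-pole band-stop at 48-52 Hz.
#'
#' @param epochs a `spes_epochs` object at 256 Hz.
#' @param cfg a `spes_preprocess_config`.
#' @return filtered `spes_epochs`.
#' @export
filter_epoch <- function(epochs, cfg = preprocess_config()) {
  if (!all(is.finite(epochs$signal)))
    stop("non-finite samples in epochs", call. = FALSE)
  flt <- butter_filters(cfg, epochs$fs)
  for (j in seq_len(dim(epochs$signal)[3])) {
    for (ch in seq_len(dim(epochs$signal)[1])) {
      x <- epochs$signal[ch, , j]
      x <- x - mean(x)
      x <- signal::filtfilt(flt$hp, x)
      x <- signal::filtfilt(flt$lp, x)
      x <- signal::filtfilt(flt$notch, x)
      epochs$signal[ch, , j] <- x
    }
  }
  epochs
}

#' Full preprocessing chain for one patient
#'
#' Common-average re-reference, downsample to the target rate, epoch around
#' each pulse pair, flag corrupted epochs, repair the stimulus artifact, and
#' filter. Rejection flags are set from the pre-repair amplitudes so gross
#' bursts cannot hide behind the spline repair or the filters.
#'
#' @param rec a `spes_recording`.
#' @param sched a `spes_schedule`.
#' @param cfg a `spes_preprocess_config`.
#' @return a `spes_epochs` object ready for feature extraction.
#' @export
preprocess_patient <- function(rec, sched, cfg = preprocess_config()) {
  rec <- car_downsample(rec, cfg$fs_target)
  gc(FALSE)
  epochs <- epoch_stimuli(rec, sched)
  epochs <- reject_corrupted(epochs, cfg)
  epochs <- repair_stim_artifact(epochs, cfg$artifact_repair_ms)
  epochs <- filter_epoch(epochs, cfg)
  epochs
}
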