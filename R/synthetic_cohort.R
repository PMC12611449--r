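#' Generator configuration for a synthetic SPES cohort
#'
#' Builds the parameter set for the synthetic intracranial-EEG cohort
#' generator. Each synthetic patient is a multichannel recording with paired
#' 1-ms stimulation pulses delivered on a fixed schedule, stimulus artifacts,
#' early (<100 ms) and late (100 ms - 1 s) evoked responses on a subset of
#' "responsive" channels, and AR(1) background noise whose variance and lag-1
#' autocorrelation ramp upward over a pre-ictal period ending at a single
#' annotated seizure onset.
#'
#' The background process on every channel is AR(1): the two monitored
#' features (variance, lag-1 autocorrelation) then have closed-form ground
#' truth. During the pre-ictal window the AR coefficient ramps linearly from
#' `ar_coeff_interictal` to `ar_coeff_interictal + effect_ac` and the process
#' variance ramps linearly by factor `effect_var`. The ramp is applied more
#' strongly inside the 6 s following each first pulse (gain `stim_gain`) than
#' in the unstimulated baseline (gain `baseline_gain`), emulating a cortical
#' excitability change that is most visible in the post-stimulus response.
#'
#' @param n_patients number of patients in the cohort (LOSO needs >= 2).
#' @param record_hours length-2 range (hours) from which each patient's
#'   recording duration is drawn uniformly.
#' @param fs_raw generated sampling rate in Hz; the preprocessing chain
#'   downsamples to 256 Hz, so the default 512 makes that a real operation.
#' @param n_channels length-2 integer range of channels per patient.
#' @param stim_period_s seconds between successive pulse pairs.
#' @param pair_gap_s seconds between the first and second pulse of a pair.
#' @param pulse_width_ms width of each pulse in milliseconds.
#' @param artifact_ms duration of the saturating stimulus artifact.
#' @param early_resp,late_resp lists (amp, latency_ms, sigma_ms, freq_hz)
#'   describing the Gabor-shaped early and late evoked components.
#' @param baseline_sigma interictal SD of the background process.
#' @param ar_coeff_interictal lag-1 AR coefficient of interictal background.
#' @param preictal_hours duration of the pre-seizure feature ramp.
#' @param effect_var multiplicative variance ramp reached at seizure onset
#'   (1 = null effect).
#' @param effect_ac additive AR-coefficient ramp reached at onset (0 = null).
#' @param stim_gain,baseline_gain fraction of the pre-ictal effect expressed
#'   inside the 6 s post-stimulus window / in the unstimulated baseline.
#' @param n_responsive_channels channels carrying full-amplitude evoked
#'   responses (others receive strongly attenuated copies).
#' @param corrupt_epoch_rate fraction of stimuli corrupted by a gross
#'   high-amplitude broadband burst (for the automatic-rejection stage).
#' @param onset_range_h optional length-2 range (hours) for the seizure onset
#'   draw; by default the onset leaves `preictal_hours` + 2 h of data before
#'   it and 30 min after it.
#' @param seed integer seed; together with the patient index it fixes every
#'   random draw, so regeneration is bit-identical.
#' @return a validated list of class `spes_gen_params`.
#' @export
generator_params <- function(n_patients = 8,
                             record_hours = c(12, 26),
                             fs_raw = 512,
                             n_channels = c(13, 62),
                             stim_period_s = 300,
                             pair_gap_s = 5,
                             pulse_width_ms = 1,
                             artifact_ms = 20,
                             early_resp = list(amp = 40, latency_ms = 30,
                                               sigma_ms = 12, freq_hz = 18),
                             late_resp = list(amp = 60, latency_ms = 250,
                                              sigma_ms = 120, freq_hz = 3),
                             baseline_sigma = 20,
                             ar_coeff_interictal = 0.6,
                             preictal_hours = 3,
                             effect_var = 1.0,
                             effect_ac = 0.0,
                             stim_gain = 1.0,
                             baseline_gain = 0.5,
                             n_responsive_channels = 5,
                             corrupt_epoch_rate = 0,
                             onset_range_h = NULL,
                             seed = 1L) {
  p <- list(n_patients = n_patients, record_hours = record_hours,
            fs_raw = fs_raw, n_channels = n_channels,
            stim_period_s = stim_period_s, pair_gap_s = pair_gap_s,
            pulse_width_ms = pulse_width_ms, artifact_ms = artifact_ms,
            early_resp = early_resp, late_resp = late_resp,
            baseline_sigma = baseline_sigma,
            ar_coeff_interictal = ar_coeff_interictal,
            preictal_hours = preictal_hours,
            effect_var = effect_var, effect_ac = effect_ac,
            stim_gain = stim_gain, baseline_gain = baseline_gain,
            n_responsive_channels = n_responsive_channels,
            corrupt_epoch_rate = corrupt_epoch_rate,
            onset_range_h = onset_range_h, seed = as.integer(seed))
  class(p) <- "spes_gen_params"
  validate_generator_params(p)
  p
}

validate_generator_params <- function(p) {
  fail <- function(field, why) {
    stop(sprintf("invalid generator configuration: `%s` %s", field, why),
         call. = FALSE)
  }
  if (length(p$record_hours) == 1) p$record_hours <- rep(p$record_hours, 2)
  if (length(p$n_channels) == 1) p$n_channels <- rep(p$n_channels, 2)
  if (p$pair_gap_s >= p$stim_period_s)
    fail("pair_gap_s", "must be smaller than stim_period_s")
  if (p$artifact_ms < 0) fail("artifact_ms", "must be >= 0")
  if (p$ar_coeff_interictal < 0)
    fail("ar_coeff_interictal", "must be >= 0")
  if (p$ar_coeff_interictal + max(p$effect_ac * c(p$stim_gain, p$baseline_gain),
                                  p$effect_ac) >= 1)
    fail("effect_ac", "drives the AR coefficient to >= 1")
  if (p$preictal_hours >= min(p$record_hours))
    fail("preictal_hours", "must be smaller than record_hours")
  if (p$effect_var <= 0) fail("effect_var", "must be > 0")
  if (p$fs_raw <= 0) fail("fs_raw", "must be > 0")
  if (p$n_channels[1] < 4)
    fail("n_channels", "must allow at least 4 channels")
  if (!is.null(p$onset_range_h)) {
    if (any(p$onset_range_h <= 0) || any(p$onset_range_h >= min(p$record_hours)))
      fail("onset_range_h", "must lie strictly inside the recording")
  } else if (p$preictal_hours + 2.6 >= min(p$record_hours)) {
    fail("record_hours",
         "must leave preictal_hours + 2 h of data before the seizure onset")
  }
  invisible(p)
}

#' Draw the layout (sizes, schedule, onset) of one synthetic patient
#'
#' Separates the cheap, size-determining draws from signal synthesis so that
#' cohort-level properties (channel counts, schedule arithmetic, onset
#' placement) can be checked without materialising any signal.
#'
#' @param params a `spes_gen_params` object.
#' @param patient_index 1-based index of the patient within the cohort.
#' @return list with duration_s, n_channels, channel_labels, stim_pair,
#'   responsive channels, onset_s and the pulse-pair schedule.
#' @export
draw_patient_layout <- function(params, patient_index) {
  validate_generator_params(params)
  set.seed(patient_seed(params$seed, patient_index, 0L))
  rh <- params$record_hours
  if (length(rh) == 1) rh <- rep(rh, 2)
  nc <- params$n_channels
  if (length(nc) == 1) nc <- rep(nc, 2)
  duration_s <- round(stats::runif(1, rh[1], rh[2]) * 3600)
  n_channels <- if (nc[1] == nc[2]) nc[1] else
    sample(seq(nc[1], nc[2]), 1)
  labels <- sprintf("CH%02d", seq_len(n_channels))
  stim_pair <- sort(sample(n_channels, 2))
  pool <- setdiff(seq_len(n_channels), stim_pair)
  n_resp <- min(params$n_responsive_channels, length(pool))
  responsive <- sort(sample(pool, n_resp))
  orh <- params$onset_range_h
  if (is.null(orh)) {
    orh <- c(params$preictal_hours + 2 + 1 / 6, duration_s / 3600 - 0.5)
  }
  onset_s <- stats::runif(1, orh[1] * 3600, min(orh[2] * 3600, duration_s - 60))
  # first pulse mid-interval so every epoch (-1.5 s .. +6 s) is in-bounds;
  # pair count is floor(duration / period)
  k <- floor(duration_s / params$stim_period_s)
  t_first <- (seq_len(k) - 1) * params$stim_period_s + params$stim_period_s / 2
  t_second <- t_first + params$pair_gap_s
  list(patient_id = sprintf("P%02d", patient_index),
       duration_s = duration_s, n_channels = n_channels,
       channel_labels = labels,
       stim_pair = labels[stim_pair], responsive = labels[responsive],
       onset_s = onset_s,
       schedule = list(pairs = data.frame(t_first = t_first,
                                          t_second = t_second),
                       stim_channel_pair = labels[stim_pair]))
}

# deterministic sub-seed per (cohort seed, patient, stream), kept < 2^31
patient_seed <- function(seed, patient_index, stream) {
  (as.numeric(seed) * 7919 + patient_index * 104729 + stream * 7) %%
    2147483647
}

# pre-ictal modulation in [0, 1]: 0 interictal, linear ramp over the
# pre-ictal window, held at 1 from onset on (post-onset data are never
# analysed)
preictal_ramp <- function(t, onset_s, preictal_s) {
  pmin(1, pmax(0, (t - (onset_s - preictal_s)) / preictal_s))
}

# Gabor-shaped evoked component sampled at fs, offsets in samples from pulse
evoked_template <- function(resp, fs, span_ms) {
  t_ms <- seq(0, span_ms, by = 1000 / fs)
  resp$amp * exp(-((t_ms - resp$latency_ms)^2) / (2 * resp$sigma_ms^2)) *
    sin(2 * pi * resp$freq_hz * (t_ms - resp$latency_ms) / 1000)
}

#' Generate one synthetic patient
#'
#' Synthesises the continuous multichannel recording, the stimulation
#' schedule and the seizure annotation for one patient. The background of
#' each channel is a piecewise-stationary AR(1) process: within each segment
#' (delimited by stimulation times, the 6 s post-stimulus windows and the
#' pre-ictal ramp) the AR coefficient and stationary variance are constant at
#' the ramp value of the segment midpoint, and segments are chained through
#' the recursion's initial condition so the signal is continuous. Pulse
#' artifacts, evoked components and (optionally) gross corruption bursts are
#' then added at the scheduled times.
#'
#' @param params a `spes_gen_params` object.
#' @param patient_index 1-based patient index.
#' @return list with elements `recording` (class `spes_recording`),
#'   `schedule` (class `spes_schedule`), `seizure` (list with `onset_s`),
#'   and the ground-truth layout (responsive channels, corrupt stimuli).
#' @export
generate_patient <- function(params, patient_index) {
  lay <- draw_patient_layout(params, patient_index)
  fs <- params$fs_raw
  n <- lay$duration_s * fs
  nch <- lay$n_channels
  preictal_s <- params$preictal_hours * 3600

  # segment table: constant AR coefficient / variance per segment
  t1 <- lay$schedule$pairs$t_first
  brk <- sort(unique(c(0, t1, pmin(t1 + 6, lay$duration_s),
                       lay$onset_s - preictal_s, lay$onset_s,
                       lay$duration_s)))
  brk <- brk[brk >= 0 & brk <= lay$duration_s]
  seg_start <- brk[-length(brk)]
  seg_end <- brk[-1]
  keep <- seg_end > seg_start
  seg_start <- seg_start[keep]; seg_end <- seg_end[keep]
  mid <- (seg_start + seg_end) / 2
  in_stim <- vapply(mid, function(m) any(m >= t1 & m < t1 + 6), logical(1))
  gain <- ifelse(in_stim, params$stim_gain, params$baseline_gain)
  m <- preictal_ramp(mid, lay$onset_s, preictal_s) * gain
  phi <- params$ar_coeff_interictal + params$effect_ac * m
  v <- params$baseline_sigma^2 * (1 + (params$effect_var - 1) * m)
  sd_innov <- sqrt(v * (1 - phi^2))
  i0 <- round(seg_start * fs) + 1
  i1 <- round(seg_end * fs)
  i1[length(i1)] <- n

  set.seed(patient_seed(params$seed, patient_index, 1L))
  corrupt <- which(stats::runif(nrow(lay$schedule$pairs)) <
                     params$corrupt_epoch_rate)

  early <- evoked_template(params$early_resp, fs, 100)
  late <- evoked_template(params$late_resp, fs, 1000)
  art_n <- round(params$artifact_ms / 1000 * fs)
  artifact <- if (art_n > 0) {
    # saturating shape: plateau over the first half, then exponential decay
    a <- numeric(art_n)
    half <- ceiling(art_n / 2)
    a[seq_len(half)] <- 1
    a[(half + 1):art_n] <- exp(-(seq_len(art_n - half)) / (art_n / 4))
    a
  } else numeric(0)

  stim_idx <- match(lay$stim_pair, lay$channel_labels)
  resp_idx <- match(lay$responsive, lay$channel_labels)
  pulse_samples <- round(c(t1, lay$schedule$pairs$t_second) * fs) + 1

  signal <- matrix(0, nrow = nch, ncol = n)
  for (ch in seq_len(nch)) {
    e <- stats::rnorm(n)
    x <- .ar1_piecewise(e, as.integer(i1), phi, sd_innov)
    g_early <- if (ch %in% stim_idx) 0 else if (ch %in% resp_idx) 1 else 0.3
    g_late <- if (ch %in% stim_idx) 0 else if (ch %in% resp_idx) 1 else 0.05
    g_art <- if (ch %in% stim_idx) 5 else 1
    for (ps in pulse_samples) {
      if (art_n > 0 && ps + art_n - 1 <= n)
        x[ps:(ps + art_n - 1)] <- x[ps:(ps + art_n - 1)] + 400 * g_art * artifact
      if (g_early > 0 && ps + length(early) - 1 <= n) {
        ii <- ps:(ps + length(early) - 1)
        x[ii] <- x[ii] + g_early * early
      }
      if (g_late > 0 && ps + length(late) - 1 <= n) {
        ii <- ps:(ps + length(late) - 1)
        x[ii] <- x[ii] + g_late * late
      }
    }
    signal[ch, ] <- x
  }

  # gross corruption bursts 2.5-3.0 s after the first pulse of chosen pairs
  if (length(corrupt) > 0) {
    set.seed(patient_seed(params$seed, patient_index, 2L))
    for (k in corrupt) {
      ii <- (round((t1[k] + 2.5) * fs) + 1):(round((t1[k] + 3.0) * fs))
      ii <- ii[ii <= n]
      # independent per channel so a common-average reference cannot cancel it
      burst <- matrix(50 * params$baseline_sigma *
                        stats::runif(nch * length(ii), -1, 1),
                      nrow = nch)
      signal[, ii] <- signal[, ii, drop = FALSE] + burst
    }
  }

  rec <- new_recording(signal, fs, lay$channel_labels, t0 = 0)
  sched <- structure(lay$schedule, class = "spes_schedule")
  list(patient_id = lay$patient_id,
       recording = rec, schedule = sched,
       seizure = list(onset_s = lay$onset_s),
       responsive = lay$responsive,
       corrupt_stimuli = corrupt)
}

#' Generate a synthetic cohort
#'
#' @param params a `spes_gen_params` object with `n_patients >= 2`.
#' @return list of patients as returned by [generate_patient()].
#' @export
generate_cohort <- function(params) {
  validate_generator_params(params)
  if (params$n_patients < 2)
    stop("a cohort needs at least 2 patients (leave-one-patient-out)",
         call. = FALSE)
  lapply(seq_len(params$n_patients),
         function(i) generate_patient(params, i))
}

#' Recording container
#'
#' @param signal channels x samples numeric matrix.
#' @param fs sampling rate in Hz.
#' @param channel_labels unique labels, one per row of `signal`.
#' @param t0 epoch-zero time in seconds.
#' @return object of class `spes_recording`.
#' @export
new_recording <- function(signal, fs, channel_labels, t0 = 0) {
  stopifnot(is.matrix(signal), fs > 0,
            length(channel_labels) == nrow(signal),
            !anyDuplicated(channel_labels))
  if (!all(is.finite(signal)))
    stop("recording contains non-finite samples", call. = FALSE)
  structure(list(signal = signal, fs = fs,
                 channel_labels = channel_labels, t0 = t0),
            class = "spes_recording")
}

#' @export
#' @method print spes_recording
print.spes_recording <- function(x, ...) {
  cat(sprintf("<spes_recording> %d channels x %d samples @ %g Hz (%.2f h)\n",
              nrow(x$signal), ncol(x$signal), x$fs,
              ncol(x$signal) / x$fs / 3600))
  invisible(x)
}
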