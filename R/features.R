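#' The six analysis windows
#'
#' Window presets relative to the stimulation pulses: one pre-stimulus
#' baseline window (-1000 to -20 ms before the first pulse), short (20-100
#' ms) and long (20-1000 ms) post-stimulus windows after each pulse, and the
#' late 4000-4980 ms window after the first pulse (stopping 20 ms before the
#' second pulse).
#'
#' @return data.frame with columns id, anchor, start_ms, end_ms.
#' @export
window_presets <- function() {
  data.frame(
    id = c("pre_first", "post_first_20_100", "post_second_20_100",
           "post_first_20_1000", "post_second_20_1000",
           "post_first_4000_4980"),
    anchor = c("pre_first", "post_first", "post_second",
               "post_first", "post_second", "post_first"),
    start_ms = c(-1000, 20, 20, 20, 20, 4000),
    end_ms = c(-20, 100, 100, 1000, 1000, 4980),
    stringsAsFactors = FALSE)
}

get_window <- function(window) {
  if (is.character(window)) {
    w <- window_presets()
    row <- w[w$id == window, ]
    if (nrow(row) != 1)
      stop(sprintf("unknown window id '%s'", window), call. = FALSE)
    return(row)
  }
  stopifnot(is.data.frame(window), window$start_ms < window$end_ms)
  window
}

window_sample_idx <- function(epochs, window) {
  w <- get_window(window)
  anchor_off <- if (w$anchor %in% c("pre_first", "post_first"))
    epochs$pulse_offsets[1] else epochs$pulse_offsets[2]
  offs_ms <- ((seq_len(dim(epochs$signal)[2]) - epochs$zero_sample) -
                anchor_off) / epochs$fs * 1000
  which(offs_ms >= w$start_ms & offs_ms < w$end_ms)
}

#' Extract one analysis window from epochs
#'
#' @param epochs a `spes_epochs` object.
#' @param window a preset id from [window_presets()] or a one-row data.frame
#'   (anchor, start_ms, end_ms).
#' @param channels channel labels to keep (default all).
#' @param epoch_idx epochs to keep (default all).
#' @return numeric array channels x samples x epochs.
#' @export
extract_window <- function(epochs, window, channels = NULL,
                           epoch_idx = NULL) {
  w <- get_window(window)
  idx <- window_sample_idx(epochs, window)
  # the window must fit inside the epoch: all but at most one boundary
  # sample of the nominal span must be present
  n_req <- round((w$end_ms - w$start_ms) / 1000 * epochs$fs)
  if (length(idx) < n_req - 1)
    stop("analysis window lies outside the epoch span", call. = FALSE)
  ch <- if (is.null(channels)) seq_len(dim(epochs$signal)[1]) else
    match(channels, epochs$channel_labels)
  if (anyNA(ch)) stop("unknown channel label", call. = FALSE)
  ep <- if (is.null(epoch_idx)) seq_len(dim(epochs$signal)[3]) else epoch_idx
  epochs$signal[ch, idx, ep, drop = FALSE]
}

#' Score channel prominence of the late evoked response
#'
#' Operationalises "most prominent response": the mean over valid epochs of
#' the RMS amplitude in the 100-1000 ms window after the first pulse (the
#' late-response band). The stimulated channel pair scores -Inf so it can
#' never be selected.
#'
#' @param epochs a `spes_epochs` object.
#' @return named numeric vector of per-channel scores.
#' @export
score_channel_prominence <- function(epochs) {
  if (!any(epochs$valid)) stop("no valid epochs to score", call. = FALSE)
  w <- data.frame(id = "late_band", anchor = "post_first",
                  start_ms = 100, end_ms = 1000)
  x <- extract_window(epochs, w, epoch_idx = which(epochs$valid))
  rms <- sqrt(apply(x^2, c(1, 3), mean))     # channels x epochs
  score <- rowMeans(rms)
  names(score) <- epochs$channel_labels
  score[epochs$channel_labels %in% epochs$stim_channel_pair] <- -Inf
  score
}

#' Select the analysed channel set
#'
#' @param scores named vector from [score_channel_prominence()].
#' @param mode "top1", "top5" or "all"; "all" keeps every channel except the
#'   stimulated pair. Ties break deterministically by label order.
#' @return character vector of selected channel labels.
#' @export
select_channels <- function(scores, mode = c("top5", "top1", "all")) {
  mode <- match.arg(mode)
  eligible <- names(scores)[is.finite(scores)]
  if (mode == "all") return(eligible)
  k <- if (mode == "top1") 1 else 5
  ord <- order(-scores[eligible], seq_along(eligible))
  eligible[ord][seq_len(min(k, length(eligible)))]
}

#' Population variance
#'
#' Variance with the N denominator, the convention of the critical-slowing
#' estimator literature.
#'
#' @param x numeric vector with at least 2 samples.
#' @return nonnegative scalar.
#' @export
signal_variance <- function(x) {
  if (length(x) < 2) stop("variance needs at least 2 samples", call. = FALSE)
  mean((x - mean(x))^2)
}

#' Lag-1 autocorrelation
#'
#' Pearson correlation between the series and its one-sample lag, clipped to
#' [-1, 1].
#'
#' @param x numeric vector with at least 3 samples and nonzero variance.
#' @param lag lag in samples (default 1).
#' @return scalar in [-1, 1].
#' @export
lag1_autocorrelation <- function(x, lag = 1) {
  n <- length(x)
  if (n < lag + 2)
    stop("autocorrelation needs at least lag + 2 samples", call. = FALSE)
  a <- x[seq_len(n - lag)]
  b <- x[(lag + 1):n]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("autocorrelation undefined for zero-variance input", call. = FALSE)
  max(-1, min(1, stats::cor(a, b)))
}

#' Average features across the analysed channels
#'
#' @param x numeric vector of per-channel feature values.
#' @return unweighted mean.
#' @export
average_across_channels <- function(x) {
  if (length(x) < 1) stop("no channels to average", call. = FALSE)
  mean(x)
}

#' Trailing cumulative average
#'
#' Element i is the mean of the valid values at indices max(1, i-history+1)
#' .. i; with the default history of 12 values at one stimulus per 5 min the
#' window spans exactly 1 h. NA entries are skipped; if no valid value falls
#' in the window the result is NA.
#'
#' @param x numeric series (may contain NA).
#' @param history trailing window length including the current value.
#' @return numeric series of the same length.
#' @export
cumulative_average <- function(x, history = 12) {
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    w <- x[max(1, i - history + 1):i]
    w <- w[!is.na(w)]
    if (length(w) > 0) out[i] <- mean(w)
  }
  out
}

#' Label stimuli relative to the first seizure
#'
#' Stimuli within the pre-ictal window [onset - preictal_h, onset) are
#' "preictal" (closed lower bound), stimuli earlier than that are
#' "interictal", and stimuli at or after the onset are "excluded" (only the
#' first seizure is analysed).
#'
#' @param times stimulus times in seconds.
#' @param onset_s seizure onset in seconds.
#' @param preictal_h pre-ictal window length in hours.
#' @return character vector of labels.
#' @export
label_stimuli <- function(times, onset_s, preictal_h = 3) {
  if (!any(times < onset_s))
    stop("no stimuli before the seizure onset", call. = FALSE)
  lab <- rep("excluded", length(times))
  lab[times < onset_s] <- "preictal"
  lab[times < onset_s - preictal_h * 3600] <- "interictal"
  lab
}

FEATURE_COLS <- c("var", "ac", "cum_var", "cum_ac")

#' Per-patient feature table
#'
#' For every epoch: population variance and lag-1 autocorrelation of the
#' chosen window, computed per channel and averaged over the selected
#' channel set, plus their trailing 12-value cumulative averages, the
#' pre-ictal/inter-ictal label, and the valid flag. Invalid epochs yield NA
#' features and are skipped by the cumulative averages.
#'
#' @param epochs a `spes_epochs` object.
#' @param window window preset id.
#' @param channel_mode "top1", "top5" or "all".
#' @param onset_s seizure onset in seconds.
#' @param preictal_h pre-ictal window in hours.
#' @param history cumulative-average window length.
#' @param ac_lag autocorrelation lag in samples.
#' @return data.frame (FeatureTable) with one row per epoch.
#' @export
featurize_patient <- function(epochs, window = "post_first_4000_4980",
                              channel_mode = "top5", onset_s,
                              preictal_h = 3, history = 12, ac_lag = 1) {
  scores <- score_channel_prominence(epochs)
  sel <- select_channels(scores, channel_mode)
  x <- extract_window(epochs, window, channels = sel)
  n_ep <- dim(x)[3]
  v <- rep(NA_real_, n_ep)
  a <- rep(NA_real_, n_ep)
  valid <- epochs$valid
  for (j in seq_len(n_ep)) {
    if (!valid[j]) next
    vc <- numeric(length(sel)); ac <- numeric(length(sel))
    ok <- TRUE
    for (ch in seq_along(sel)) {
      s <- x[ch, , j]
      if (signal_variance(s) == 0) { ok <- FALSE; break }
      vc[ch] <- signal_variance(s)
      ac[ch] <- lag1_autocorrelation(s, ac_lag)
    }
    if (!ok) { valid[j] <- FALSE; next }
    v[j] <- average_across_channels(vc)
    a[j] <- average_across_channels(ac)
  }
  tbl <- data.frame(stim_index = epochs$stim_index,
                    t_s = epochs$t_first,
                    var = v, ac = a,
                    cum_var = cumulative_average(v, history),
                    cum_ac = cumulative_average(a, history),
                    label = label_stimuli(epochs$t_first, onset_s,
                                          preictal_h),
                    valid = valid,
                    stringsAsFactors = FALSE)
  attr(tbl, "window") <- window
  attr(tbl, "channel_mode") <- channel_mode
  attr(tbl, "channels") <- sel
  attr(tbl, "onset_s") <- onset_s
  tbl
}

#' Per-patient z-normalization of the features
#'
#' Retrospective mode uses the mean/SD of each feature over all valid
#' interictal rows (the retrospective analysis); pseudo-prospective mode uses
#' only the rows from the first two hours of the recording, then marks those
#' rows "excluded" so evaluation never sees them. Prospective normalization
#' requires at least `min_preseizure_h` hours of data before the seizure
#' (2 h for normalization + the 3 h pre-ictal window); patients failing it
#' raise a `spescast_skip` condition that the pipeline logs and skips.
#'
#' @param tbl a FeatureTable from [featurize_patient()].
#' @param mode "retrospective_interictal" or "prospective_first2h".
#' @param min_preseizure_h minimum pre-seizure data for prospective mode.
#' @return list with `table` (normalized) and `stats` (per-feature mean/SD,
#'   plus the mode).
#' @export
znormalize <- function(tbl, mode = c("retrospective_interictal",
                                     "prospective_first2h"),
                       min_preseizure_h = 5) {
  mode <- match.arg(mode)
  onset_s <- attr(tbl, "onset_s")
  if (mode == "retrospective_interictal") {
    ref <- tbl$valid & tbl$label == "interictal"
  } else {
    if (!is.null(onset_s) && onset_s < min_preseizure_h * 3600) {
      cond <- structure(
        class = c("spescast_skip", "error", "condition"),
        list(message = sprintf(
          "patient skipped: %.2f h of pre-seizure data (< %g h needed for prospective normalization)",
          onset_s / 3600, min_preseizure_h), call = NULL))
      stop(cond)
    }
    ref <- tbl$valid & tbl$t_s < 2 * 3600
  }
  if (sum(ref) < 2)
    stop("fewer than 2 valid reference rows for normalization",
         call. = FALSE)
  mu <- vapply(FEATURE_COLS, function(f) mean(tbl[[f]][ref]), numeric(1))
  sd_ <- vapply(FEATURE_COLS, function(f) stats::sd(tbl[[f]][ref]),
                numeric(1))
  if (any(sd_ == 0))
    stop("zero SD in the normalization reference set", call. = FALSE)
  for (f in FEATURE_COLS) tbl[[f]] <- (tbl[[f]] - mu[f]) / sd_[f]
  if (mode == "prospective_first2h")
    tbl$label[tbl$t_s < 2 * 3600] <- "excluded"
  list(table = tbl,
       stats = list(mean = mu, sd = sd_, mode = mode))
}
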