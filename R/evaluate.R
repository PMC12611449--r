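#' Alarm parameter grid
#'
#' Probability thresholds 0.4 to 0.8 in steps of 0.01 and seizure occurrence
#' periods (SOP) from 30 to 240 min. The SOP step is configurable (the range
#' is fixed, its granularity is not).
#'
#' @param thresholds numeric vector of probability thresholds.
#' @param sop_min numeric vector of SOP values in minutes.
#' @return list of class `spes_alarm_grid`.
#' @export
alarm_grid <- function(thresholds = seq(0.4, 0.8, by = 0.01),
                       sop_min = seq(30, 240, by = 30)) {
  structure(list(thresholds = thresholds, sop_min = sop_min),
            class = "spes_alarm_grid")
}

#' Run the alarm system over a forecast series
#'
#' Scans the stimuli in time order over the evaluated span (first evaluated
#' stimulus to seizure onset): whenever the seizure likelihood reaches the
#' threshold and no alarm is active, an alarm is raised that lasts `sop_min`
#' minutes; crossings during an active alarm are absorbed; once the SOP has
#' passed a new alarm can start. Warning time is the union of alarm
#' intervals truncated at the seizure onset.
#'
#' @param series ForecastSeries data.frame (columns t_s, p).
#' @param p_threshold alarm threshold on the seizure likelihood.
#' @param sop_min seizure occurrence period in minutes.
#' @param onset_s seizure onset in seconds (end of the evaluated span).
#' @return list of class `spes_alarm_trace`: alarm start times (s), sop_s,
#'   span = c(start_s, end_s).
#' @export
run_alarms <- function(series, p_threshold, sop_min, onset_s) {
  keep <- series$t_s < onset_s
  if (!any(keep)) stop("no stimuli in the evaluated span", call. = FALSE)
  t_s <- series$t_s[keep]; p <- series$p[keep]
  ord <- order(t_s)
  t_s <- t_s[ord]; p <- p[ord]
  sop_s <- sop_min * 60
  starts <- numeric(0)
  alarm_end <- -Inf
  for (i in seq_along(t_s)) {
    if (p[i] >= p_threshold && t_s[i] >= alarm_end) {
      starts <- c(starts, t_s[i])
      alarm_end <- t_s[i] + sop_s
    }
  }
  structure(list(starts_s = starts, sop_s = sop_s,
                 span = c(t_s[1], onset_s)),
            class = "spes_alarm_trace")
}

#' Seizure sensitivity of an alarm trace
#'
#' 1 if the seizure onset falls inside an active alarm interval
#' [start, start + SOP), else 0.
#'
#' @param trace a `spes_alarm_trace`.
#' @param onset_s seizure onset in seconds.
#' @return 0 or 1.
#' @export
alarm_sensitivity <- function(trace, onset_s) {
  as.integer(any(trace$starts_s <= onset_s &
                   onset_s < trace$starts_s + trace$sop_s))
}

#' Fraction of evaluated time spent in warning
#'
#' @param trace a `spes_alarm_trace`.
#' @return tiw in [0, 1].
#' @export
time_in_warning <- function(trace) {
  if (length(trace$starts_s) == 0) return(0)
  ends <- pmin(trace$starts_s + trace$sop_s, trace$span[2])
  starts <- pmax(trace$starts_s, trace$span[1])
  keep <- ends > starts
  sum(ends[keep] - starts[keep]) / diff(trace$span)
}

#' Improvement over chance
#'
#' IoC = sensitivity - time in warning: a random forecaster with the same
#' warning load scores 0, a perfect forecaster scores 1.
#'
#' @param sens sensitivity (0/1 per patient, or a cohort average).
#' @param tiw time in warning on the same footing.
#' @return sens - tiw.
#' @export
ioc <- function(sens, tiw) sens - tiw

#' Brier Skill Score against the per-patient base-rate forecast
#'
#' BS is the mean squared error of the probabilities against the binary
#' pre-ictal outcome; the reference BS uses the constant climatological
#' forecast equal to the patient's pre-ictal prevalence. BSS = 1 - BS/BS_ref
#' (1 = perfect, 0 = no better than the base rate). Undefined (NA) when the
#' patient has no pre-ictal or no inter-ictal rows.
#'
#' @param p forecast probabilities for the evaluated stimuli.
#' @param labels matching labels ("preictal"/"interictal").
#' @return BSS scalar or NA.
#' @export
brier_skill_score <- function(p, labels) {
  o <- as.numeric(labels == "preictal")
  prev <- mean(o)
  if (prev == 0 || prev == 1) return(NA_real_)
  bs <- mean((p - o)^2)
  bs_ref <- mean((prev - o)^2)
  1 - bs / bs_ref
}

#' Forecasting horizon
#'
#' Minutes between the start of the alarm interval containing the seizure
#' onset and the onset itself; NA when no alarm covers the onset.
#'
#' @param trace a `spes_alarm_trace`.
#' @param onset_s seizure onset in seconds.
#' @return minutes, or NA.
#' @export
forecasting_horizon <- function(trace, onset_s) {
  cover <- trace$starts_s[trace$starts_s <= onset_s &
                            onset_s < trace$starts_s + trace$sop_s]
  if (length(cover) == 0) return(NA_real_)
  (onset_s - max(cover)) / 60
}

patient_metrics <- function(series, p_threshold, sop_min, onset_s) {
  trace <- run_alarms(series, p_threshold, sop_min, onset_s)
  sens <- alarm_sensitivity(trace, onset_s)
  tiw <- time_in_warning(trace)
  list(sensitivity = sens, tiw = tiw, ioc = ioc(sens, tiw),
       horizon_min = forecasting_horizon(trace, onset_s))
}

#' Grid search of alarm parameters on training patients only
#'
#' Exhaustive scan of the threshold x SOP grid; returns the combination
#' maximizing the mean IoC across the training patients. Ties break
#' deterministically toward the smaller SOP, then the lower threshold.
#'
#' @param series_list list of training ForecastSeries.
#' @param onsets matching vector of training-patient seizure onsets (s).
#' @param grid a `spes_alarm_grid`.
#' @return list(p_threshold, sop_min, mean_ioc).
#' @export
grid_search <- function(series_list, onsets, grid = alarm_grid()) {
  stopifnot(length(series_list) >= 1,
            length(onsets) == length(series_list))
  best <- list(p_threshold = NA_real_, sop_min = NA_real_,
               mean_ioc = -Inf)
  for (sop in sort(grid$sop_min)) {
    for (thr in sort(grid$thresholds)) {
      vals <- vapply(seq_along(series_list), function(i) {
        m <- patient_metrics(series_list[[i]], thr, sop, onsets[i])
        m$ioc
      }, numeric(1))
      mi <- mean(vals)
      if (mi > best$mean_ioc + 1e-12) {
        best <- list(p_threshold = thr, sop_min = sop, mean_ioc = mi)
      }
    }
  }
  best
}

#' Shuffled-forecast chance level
#'
#' Permutes the probability sequence uniformly `n` times (times fixed),
#' reruns the alarm system with identical parameters, and averages
#' sensitivity, tiw and IoC across the shuffles. Negative IoC values are set
#' to zero before averaging. Seeded and reproducible; the caller's RNG state
#' is restored on exit.
#'
#' @param series ForecastSeries for one patient.
#' @param p_threshold,sop_min alarm parameters.
#' @param onset_s seizure onset (s).
#' @param n number of shuffles.
#' @param seed integer seed.
#' @return list with mean_sens, mean_tiw, mean_ioc and their SEs.
#' @export
surrogate_chance <- function(series, p_threshold, sop_min, onset_s,
                             n = 100, seed = 1L) {
  if (nrow(series) < 2)
    stop("surrogates need a series of length >= 2", call. = FALSE)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  sens <- tiw <- iocs <- numeric(n)
  sh <- series
  for (k in seq_len(n)) {
    sh$p <- series$p[sample.int(nrow(series))]
    m <- patient_metrics(sh, p_threshold, sop_min, onset_s)
    sens[k] <- m$sensitivity
    tiw[k] <- m$tiw
    iocs[k] <- max(0, m$ioc)
  }
  list(mean_sens = mean(sens), mean_tiw = mean(tiw),
       mean_ioc = mean(iocs),
       se_sens = stats::sd(sens) / sqrt(n),
       se_tiw = stats::sd(tiw) / sqrt(n),
       se_ioc = stats::sd(iocs) / sqrt(n))
}

#' Alarm-based evaluation of a LOSO forecast
#'
#' For each held-out patient: grid-searches the alarm parameters on the
#' *training* patients' forecast series only, applies them to the held-out
#' series, and reports sensitivity, time in warning, IoC, BSS, forecasting
#' horizon and the 100-shuffle surrogate chance level.
#'
#' @param loso result of [fit_loso()].
#' @param onsets named vector of seizure onsets (s) per patient.
#' @param grid a `spes_alarm_grid`.
#' @param n_surrogates shuffles per patient.
#' @param seed base seed for the surrogates.
#' @return list of class `spes_eval_report`: per-patient data.frame and
#'   cohort averages.
#' @export
evaluate_cohort <- function(loso, onsets, grid = alarm_grid(),
                            n_surrogates = 100, seed = 1L) {
  ids <- names(loso$series)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    train_ids <- setdiff(ids, id)
    pars <- grid_search(loso$series[train_ids], onsets[train_ids], grid)
    m <- patient_metrics(loso$series[[id]], pars$p_threshold,
                         pars$sop_min, onsets[id])
    ev <- loso$series[[id]]
    ev <- ev[ev$t_s < onsets[id], ]
    bss <- brier_skill_score(ev$p, ev$label)
    surr <- surrogate_chance(loso$series[[id]], pars$p_threshold,
                             pars$sop_min, onsets[id], n = n_surrogates,
                             seed = patient_seed(seed, i, 3L))
    rows[[i]] <- data.frame(
      patient_id = id, p_threshold = pars$p_threshold,
      sop_min = pars$sop_min, sensitivity = m$sensitivity,
      tiw = m$tiw, ioc = m$ioc, bss = bss,
      horizon_min = m$horizon_min,
      surr_sens = surr$mean_sens, surr_tiw = surr$mean_tiw,
      surr_ioc = surr$mean_ioc, surr_ioc_se = surr$se_ioc,
      stringsAsFactors = FALSE)
  }
  patients <- do.call(rbind, rows)
  cohort <- list(
    sensitivity = mean(patients$sensitivity),
    tiw = mean(patients$tiw),
    ioc = mean(patients$ioc),
    bss = mean(patients$bss, na.rm = TRUE),
    horizon_min = mean(patients$horizon_min, na.rm = TRUE),
    surr_ioc = mean(patients$surr_ioc),
    n_above_chance = sum(patients$ioc > patients$surr_ioc))
  structure(list(patients = patients, cohort = cohort,
                 n_surrogates = n_surrogates),
            class = "spes_eval_report")
}

#' @export
#' @method print spes_eval_report
print.spes_eval_report <- function(x, ...) {
  cat(sprintf("<spes_eval_report> %d patients\n", nrow(x$patients)))
  print(x$patients, digits = 3, row.names = FALSE)
  with(x$cohort, cat(sprintf(
    "cohort: sens %.2f | tiw %.2f | IoC %.2f | BSS %.2f | horizon %.1f min | surrogate IoC %.2f | above chance %d/%d\n",
    sensitivity, tiw, ioc, bss, horizon_min, surr_ioc, n_above_chance,
    nrow(x$patients))))
  invisible(x)
}
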