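# Independent brute-force alarm simulator on a 1-minute grid. All times in
# whole minutes so that the continuous-interval implementation and the
# minute-count implementation must agree exactly.
oracle_alarms <- function(t_min, p, thr, sop_min, onset_min) {
  span <- seq(t_min[1], onset_min - 1)       # unit bins [m, m+1)
  warn <- logical(length(span))
  alarm_end <- -Inf
  starts <- numeric(0)
  for (k in seq_along(span)) {
    m <- span[k]
    i <- match(m, t_min)
    if (!is.na(i) && m >= alarm_end && p[i] >= thr) {
      starts <- c(starts, m)
      alarm_end <- m + sop_min
    }
    if (m < alarm_end) warn[k] <- TRUE
  }
  covering <- starts[starts <= onset_min & onset_min < starts + sop_min]
  sens <- as.integer(length(covering) > 0)
  list(sens = sens,
       tiw = mean(warn),
       horizon = if (sens == 1) onset_min - max(covering) else NA_real_)
}
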