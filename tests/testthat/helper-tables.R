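# Synthetic normalized feature tables (no signal synthesis): n stimuli at
# 5-min spacing, seizure onset just after the last stimulus, pre-ictal rows
# shifted by `shift` SD on all four features.
make_feature_table <- function(seed, shift = 3, n = 70) {
  set.seed(seed)
  t_s <- (seq_len(n) - 1) * 300 + 150
  onset <- t_s[n] + 100
  lab <- label_stimuli(t_s, onset)
  X <- matrix(rnorm(n * 4), n, 4)
  X[lab == "preictal", ] <- X[lab == "preictal", ] + shift
  tbl <- data.frame(stim_index = seq_len(n), t_s = t_s,
                    var = X[, 1], ac = X[, 2],
                    cum_var = X[, 3], cum_ac = X[, 4],
                    label = lab, valid = TRUE, stringsAsFactors = FALSE)
  attr(tbl, "onset_s") <- onset
  tbl
}

rank_auc <- function(p, y) {
  r <- rank(p)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
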