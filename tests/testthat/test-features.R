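test_that("the six window presets have the stated spans and anchors", {
  w <- window_presets()
  expect_identical(nrow(w), 6L)
  ep <- make_epochs(matrix(seq_len(1920), nrow = 1))
  t_ms <- epoch_time_ms()
  # 4000-4980 ms after pulse 1: ~251 samples, 20 ms short of pulse 2
  x <- extract_window(ep, "post_first_4000_4980")
  expect_equal(dim(x)[2], 251, tolerance = 1)
  expect_true(all(t_ms[ep$signal[1, , 1] %in% x[1, , 1]] < 5000 - 19))
  # pre-stimulus window lies strictly before pulse 1
  xp <- extract_window(ep, "pre_first")
  expect_true(max(ep$signal[1, , 1][ep$signal[1, , 1] %in% xp[1, , 1]]) <
                ep$zero_sample)
  # second-pulse windows are anchored 5 s after the first pulse
  xs <- extract_window(ep, "post_second_20_100")
  first_idx <- xs[1, 1, 1]                 # signal is the sample index
  expect_equal(first_idx - (ep$zero_sample + ep$pulse_offsets[2]),
               round(0.020 * 256), tolerance = 1)
  expect_equal(dim(extract_window(ep, "post_first_20_100"))[2], 20,
               tolerance = 1)
  expect_error(extract_window(ep, data.frame(anchor = "post_first",
                                             start_ms = 5000,
                                             end_ms = 9000)), "outside")
})

test_that("channel prominence recovers planted responsive channels", {
  p <- generator_params(n_patients = 2, record_hours = c(1, 1),
                        n_channels = c(12, 12), preictal_hours = 0.25,
                        onset_range_h = c(0.8, 0.9),
                        n_responsive_channels = 5, seed = 21)
  pat <- generate_patient(p, 1)
  ep <- preprocess_patient(pat$recording, pat$schedule)
  sc <- score_channel_prominence(ep)
  top5 <- select_channels(sc, "top5")
  expect_gte(length(intersect(top5, pat$responsive)), 4)
  # the stimulated pair is never selected at any k
  for (mode in c("top1", "top5", "all")) {
    expect_length(intersect(select_channels(sc, mode),
                            pat$schedule$stim_channel_pair), 0)
  }
  expect_setequal(select_channels(sc, "all"),
                  setdiff(ep$channel_labels,
                          pat$schedule$stim_channel_pair))
})

test_that("channel selection tie-break is deterministic by label order", {
  sc <- stats::setNames(rep(1, 6), sprintf("CH%02d", 1:6))
  expect_identical(select_channels(sc, "top1"), "CH01")
  expect_identical(select_channels(sc, "top5"), sprintf("CH%02d", 1:5))
})

test_that("variance is the population variance with AR(1) ground truth", {
  expect_identical(signal_variance(rep(3, 10)), 0)
  expect_identical(signal_variance(c(1, 2, 3, 4)), 1.25)
  expect_error(signal_variance(1), "2 samples")
  set.seed(31)
  x <- as.numeric(stats::arima.sim(list(ar = 0.5), n = 2e5))
  expect_equal(signal_variance(x), 1 / (1 - 0.5^2), tolerance = 0.05)
})

test_that("lag-1 autocorrelation matches analytic cases", {
  expect_equal(lag1_autocorrelation(rep(c(1, -1), 10)), -1,
               tolerance = 1e-12)
  set.seed(32)
  expect_lt(abs(lag1_autocorrelation(rnorm(1e4))), 3 / sqrt(1e4))
  x <- as.numeric(stats::arima.sim(list(ar = 0.8), n = 2e5))
  expect_equal(lag1_autocorrelation(x), 0.8, tolerance = 0.02)
  expect_error(lag1_autocorrelation(rep(1, 10)), "zero-variance")
  expect_error(lag1_autocorrelation(c(1, 2)), "samples")
})

test_that("channel averaging is an unweighted symmetric mean", {
  expect_identical(average_across_channels(7), 7)
  expect_identical(average_across_channels(c(1, 3)), 2)
  set.seed(33)
  v <- rnorm(9)
  expect_identical(average_across_channels(v),
                   average_across_channels(rev(v)))
})

test_that("cumulative average uses a trailing 12-value window, NA-tolerant", {
  expect_equal(cumulative_average(rep(4, 30)), rep(4, 30))
  expect_equal(cumulative_average(1:12)[12], 6.5)
  expect_equal(cumulative_average(seq(3, 60, by = 3))[3], 6)
  # linearity
  set.seed(34)
  x <- rnorm(40)
  expect_equal(cumulative_average(5 * x), 5 * cumulative_average(x))
  # invalid entries are skipped, not propagated
  y <- c(1, NA, 3)
  expect_equal(cumulative_average(y), c(1, 1, 2))
})

test_that("stimulus labels follow the 3-h pre-ictal rule with closed bound", {
  onset <- 10 * 3600
  expect_identical(label_stimuli(8 * 3600, onset), "preictal")
  expect_identical(label_stimuli(6 * 3600 + 59 * 60, onset), "interictal")
  expect_identical(label_stimuli(7 * 3600, onset), "preictal")
  expect_identical(label_stimuli(c(5, 10.5) * 3600, onset)[2], "excluded")
  expect_error(label_stimuli(11 * 3600, onset), "before the seizure")
})

test_that("retrospective z-normalization standardises the interictal rows", {
  tbl <- make_feature_table(41, shift = 2)
  tbl$var <- tbl$var * 50 + 100                  # arbitrary scale
  z <- znormalize(tbl, "retrospective_interictal")
  ii <- z$table$label == "interictal"
  for (f in c("var", "ac", "cum_var", "cum_ac")) {
    expect_lt(abs(mean(z$table[[f]][ii])), 1e-9)
    expect_equal(stats::sd(z$table[[f]][ii]), 1, tolerance = 1e-9)
  }
  tbl0 <- tbl
  tbl0$var <- 1
  expect_error(znormalize(tbl0), "zero SD")
})

test_that("prospective normalization excludes its 2-h reference and enforces the 5-h rule", {
  tbl <- make_feature_table(42, n = 80)          # onset ~6.6 h
  z <- znormalize(tbl, "prospective_first2h")
  first2 <- z$table$t_s < 2 * 3600
  expect_true(all(z$table$label[first2] == "excluded"))
  # stats computed from the first two hours only
  ref <- tbl$t_s < 2 * 3600
  expect_equal(unname(z$stats$mean["var"]), mean(tbl$var[ref]))
  # a patient with < 5 h of pre-seizure data is skipped
  short <- make_feature_table(43, n = 50)
  attr(short, "onset_s") <- 4 * 3600
  expect_condition(znormalize(short, "prospective_first2h"),
                   class = "spescast_skip")
})

test_that("null cohort features are distributionally label-blind", {
  ft <- study_feature_tables("null")
  pooled_p <- vapply(ft$tables, function(tbl) {
    rows <- tbl$valid & tbl$label != "excluded"
    suppressWarnings(stats::ks.test(
      tbl$var[rows & tbl$label == "preictal"],
      tbl$var[rows & tbl$label == "interictal"])$p.value)
  }, numeric(1))
  expect_lte(sum(pooled_p < 0.01), 2)
})

test_that("the pre-ictal effect couples more strongly to the post-stimulus window", {
  post <- study_feature_tables("effect", window = "post_first_4000_4980")
  pre <- study_feature_tables("effect", window = "pre_first")
  shift <- function(ft) mean(vapply(ft$tables, function(tb)
    mean(tb$var[tb$label == "preictal"], na.rm = TRUE), numeric(1)))
  expect_gt(shift(post), shift(pre))
})
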