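test_that("common-average reference removes exactly the common mode", {
  set.seed(1)
  x <- matrix(rnorm(4 * 1000), nrow = 4)
  rec <- new_recording(x, 256, sprintf("C%d", 1:4))
  out <- rereference_common_average(rec)
  expect_lt(max(abs(colMeans(out$signal))), 1e-9)
  # antisymmetric pair is untouched
  rec2 <- new_recording(rbind(x[1, ], -x[1, ]), 256, c("a", "b"))
  expect_equal(rereference_common_average(rec2)$signal, rec2$signal)
  # invariance to a common offset
  rec3 <- rec
  rec3$signal <- rec3$signal + 42
  expect_equal(rereference_common_average(rec3)$signal, out$signal)
  expect_error(rereference_common_average(
    new_recording(x[1, , drop = FALSE], 256, "a")), "single channel")
})

test_that("downsampling preserves pass band, kills aliases, keeps duration", {
  fs <- 512
  tt <- (0:(fs * 20 - 1)) / fs
  rec <- new_recording(rbind(sin(2 * pi * 10 * tt),
                             sin(2 * pi * 200 * tt)), fs, c("lo", "hi"))
  d <- downsample(rec, 256)
  expect_equal(d$fs, 256)
  mid <- 100:5000
  rms <- function(v) sqrt(mean(v^2))
  expect_equal(rms(d$signal[1, mid]) / sqrt(0.5), 1, tolerance = 0.01)
  expect_lt(rms(d$signal[2, mid]) / sqrt(0.5), 0.05)
  expect_lte(abs(ncol(d$signal) / d$fs - ncol(rec$signal) / rec$fs),
             1 / d$fs)
  expect_identical(downsample(rec, 512), rec)
  expect_error(downsample(rec, 1024), "exceeds")
  expect_error(downsample(rec, 300), "divide")
})

test_that("epoching yields one epoch per in-bounds pair, sample-aligned", {
  fs <- 256
  set.seed(2)
  n <- fs * 1000
  rec <- new_recording(matrix(rnorm(2 * n), nrow = 2), fs, c("a", "b"))
  sched <- structure(list(pairs = data.frame(
    t_first = c(150, 450, 997), t_second = c(155, 455, 1002)),
    stim_channel_pair = c("a", "b")), class = "spes_schedule")
  expect_message(ep <- epoch_stimuli(rec, sched), "dropped 1")
  expect_equal(dim(ep$signal)[3], 2)            # last pair 3 s before end
  expect_equal(dim(ep$signal)[2], round(7.5 * 256))
  # offset-0 sample equals the recording sample nearest t_first
  i0 <- round(150 * fs) + 1
  expect_identical(ep$signal[1, ep$zero_sample, 1], rec$signal[1, i0])
  expect_error(epoch_stimuli(rec, structure(
    list(pairs = data.frame()[0, ]), class = "spes_schedule")), "empty")
})

test_that("robust amplitude rejection flags planted bursts only", {
  set.seed(3)
  clean <- replicate(40, matrix(rnorm(2 * 1920), nrow = 2),
                     simplify = FALSE)
  ep <- do.call(make_epochs, clean)
  expect_true(all(reject_corrupted(ep)$valid))
  # corrupt 2 epochs with 50x bursts away from the pulses
  bad <- clean
  for (j in c(5, 20)) bad[[j]][, 900:1000] <- bad[[j]][, 900:1000] + 50
  epb <- do.call(make_epochs, bad)
  out <- reject_corrupted(epb)
  expect_false(any(out$valid[c(5, 20)]))
  expect_true(all(out$valid[-c(5, 20)]))
  # degenerate zero-spread input: nothing rejected
  same <- replicate(10, matrix(1, nrow = 2, ncol = 1920), simplify = FALSE)
  expect_true(all(reject_corrupted(do.call(make_epochs, same))$valid))
})

test_that("rejection on a generated cohort recovers planted corrupt epochs", {
  p <- generator_params(n_patients = 2, record_hours = c(1.5, 1.5),
                        n_channels = c(6, 6), preictal_hours = 0.25,
                        onset_range_h = c(1.2, 1.3),
                        corrupt_epoch_rate = 0.25, seed = 9)
  pat <- generate_patient(p, 1)
  rec <- downsample(rereference_common_average(pat$recording), 256)
  ep <- reject_corrupted(epoch_stimuli(rec, pat$schedule))
  planted <- pat$corrupt_stimuli
  expect_gt(length(planted), 0)
  flagged <- ep$stim_index[!ep$valid]
  expect_gte(mean(planted %in% flagged), 0.9)
  # clean patient: no rejections
  p0 <- generator_params(n_patients = 2, record_hours = c(1.5, 1.5),
                         n_channels = c(6, 6), preictal_hours = 0.25,
                         onset_range_h = c(1.2, 1.3),
                         corrupt_epoch_rate = 0, seed = 9)
  pat0 <- generate_patient(p0, 1)
  rec0 <- downsample(rereference_common_average(pat0$recording), 256)
  ep0 <- reject_corrupted(epoch_stimuli(rec0, pat0$schedule))
  expect_true(all(ep0$valid))
})

test_that("spline repair reproduces cubic signals and touches 2 x 5 samples", {
  t_ms <- epoch_time_ms()
  cubic <- 1e-6 * t_ms^3 - 2e-4 * t_ms^2 + 0.05 * t_ms + 3
  ep <- make_epochs(rbind(cubic, 2 * cubic))
  rep_ <- repair_stim_artifact(ep)
  expect_equal(rep_$signal[1, , 1], cubic, tolerance = 1e-9)
  # exactly 5 samples per pulse replaced, everything else bit-identical
  set.seed(4)
  noise <- matrix(rnorm(2 * 1920), nrow = 2)
  epn <- make_epochs(noise)
  repn <- repair_stim_artifact(epn)
  changed <- which(repn$signal[1, , 1] != noise[1, ])
  expect_identical(length(changed), 10L)
  expect_equal(changed,
               c(epn$zero_sample + 0:4,
                 epn$zero_sample + epn$pulse_offsets[2] + 0:4))
})

test_that("spline repair removes a step artifact without creating jumps", {
  t_ms <- epoch_time_ms()
  base <- sin(2 * pi * 5 * t_ms / 1000)
  art <- base
  for (po in c(0, 5 * 256)) {
    idx <- (385 + po) + 0:4                       # 0 <= t < 20 ms
    art[idx] <- art[idx] + 100
  }
  ep <- make_epochs(rbind(art, art))
  out <- repair_stim_artifact(ep)$signal[1, , 1]
  max_jump_clean <- max(abs(diff(base)))
  expect_lt(max(abs(diff(out))), 2 * max_jump_clean)
})

test_that("repair window exceeding the epoch errors out", {
  ep <- make_epochs(matrix(0, nrow = 1, ncol = 1920))
  expect_error(repair_stim_artifact(ep, artifact_repair_ms = 3000),
               "bounds")
})

test_that("filtering is zero-phase, band-selective and DC-free", {
  fs <- 256
  t_s <- (seq_len(1920) - 385) / fs
  rms <- function(v) sqrt(mean(v^2))
  s10 <- sin(2 * pi * 10 * t_s)
  s50 <- sin(2 * pi * 50 * t_s)
  ep <- make_epochs(rbind(s10, s50, rep(1, 1920)))
  out <- filter_epoch(ep)
  expect_equal(rms(out$signal[1, , 1]) / rms(s10), 1, tolerance = 0.05)
  expect_lt(rms(out$signal[2, , 1]) / rms(s50), 0.05)
  expect_lt(max(abs(out$signal[3, , 1])), 1e-6)
  # zero phase: cross-correlation of the 10 Hz sine peaks at lag 0
  mid <- 300:1600
  lags <- -20:20
  cc <- vapply(lags, function(L)
    sum(out$signal[1, mid, 1] * s10[mid + L]), numeric(1))
  expect_identical(lags[which.max(cc)], 0L)
  # filtering twice changes pass-band RMS by < 5%
  out2 <- filter_epoch(out)
  expect_equal(rms(out2$signal[1, , 1]) / rms(out$signal[1, , 1]), 1,
               tolerance = 0.05)
  ep_bad <- make_epochs(matrix(c(NA, rep(0, 1919)), nrow = 1))
  expect_error(filter_epoch(ep_bad), "non-finite")
})

test_that("the fused preprocessing path equals re-reference then downsample", {
  set.seed(6)
  fs <- 512
  rec <- new_recording(matrix(rnorm(4 * fs * 30), nrow = 4), fs,
                       sprintf("C%d", 1:4))
  sched <- structure(list(pairs = data.frame(t_first = 10, t_second = 15),
                          stim_channel_pair = c("C1", "C2")),
                     class = "spes_schedule")
  a <- preprocess_patient(rec, sched)
  b <- filter_epoch(repair_stim_artifact(reject_corrupted(epoch_stimuli(
    downsample(rereference_common_average(rec), 256), sched))))
  expect_identical(a$signal, b$signal)
  expect_identical(a$valid, b$valid)
})
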