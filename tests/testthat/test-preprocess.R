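make_rec <- function(x, rate, modality = "EEG", events = NULL) {
  recording(matrix(x, nrow = 1), rate, modality = modality, events = events)
}

test_that("EEG band-pass rejects DC, passes 10 Hz, attenuates 60 Hz", {
  rate <- 2048
  n <- 4096
  rec <- recording(rbind(rep(5, n), rep(-3, n)), rate)
  out <- filter_eeg(rec)
  core <- 500:3500
  expect_lt(max(abs(out$data[, core])), 5e-6 * 5)

  t <- seq_len(n) / rate
  rms <- function(x) sqrt(mean(x^2))
  s60 <- filter_eeg(make_rec(sin(2 * pi * 60 * t), rate))
  expect_lt(rms(s60$data[1, core]), 0.1 * rms(sin(2 * pi * 60 * t)))
  s10 <- filter_eeg(make_rec(sin(2 * pi * 10 * t), rate))
  expect_lt(abs(rms(s10$data[1, core]) / rms(sin(2 * pi * 10 * t)) - 1), 0.1)

  expect_error(filter_eeg(make_rec(rnorm(100), 64)), "rate too low")
})

test_that("resampling rescales sample counts, events and spectra", {
  rec <- recording(matrix(rnorm(2 * 2048), 2), 2048,
                   events = data.frame(sample = 1024L, label = "movement_onset"))
  out <- resample_recording(rec, 128)
  expect_equal(ncol(out$data), 128L)
  expect_equal(out$events$sample, 64)
  expect_error(resample_recording(out, 256), "upsampling")

  # a sub-40 Hz tone keeps its spectral peak
  t <- seq_len(8192) / 2048
  tone <- make_rec(sin(2 * pi * 12 * t), 2048)
  res <- resample_recording(tone, 128)
  sp <- Mod(stats::fft(res$data[1, ]))[1:256]
  f <- (seq_len(256) - 1) * 128 / ncol(res$data)
  expect_equal(f[which.max(sp[-1]) + 1], 12, tolerance = 0.5)
})

test_that("average reference zeroes channel means and is idempotent", {
  rec <- recording(matrix(rnorm(8 * 100), 8), 128)
  out <- rereference_average(rec)
  expect_lt(max(abs(colMeans(out$data))), 1e-10)
  expect_equal(rereference_average(out)$data, out$data, tolerance = 1e-12)
  two <- rereference_average(recording(matrix(c(3, 1), 2, 1), 128))
  expect_equal(as.vector(two$data), c(1, -1))
})

test_that("epoching spans the documented intervals and logs discards", {
  rate <- 128
  n <- rate * 30
  ev <- data.frame(sample = c(10 * rate + 1, 11 * rate + 1,
                              20 * rate + 1, 21 * rate + 1),
                   label = c("movement_onset", "holding_onset",
                             "movement_onset", "holding_onset"))
  rec <- recording(matrix(rnorm(2 * n), 2), rate, events = ev)
  mv <- epoch_movement(rec)
  expect_length(mv$epochs, 2L)
  expect_equal(ncol(mv$epochs[[1]]), 384L)     # 256 pre + 128 movement
  hd <- epoch_holding(rec)
  expect_equal(ncol(hd$epochs[[1]]), 256L)

  # missing holding onset: trial discarded with a logged reason
  ev2 <- ev[-2, ]
  rec2 <- recording(matrix(rnorm(2 * n), 2), rate, events = ev2)
  mv2 <- epoch_movement(rec2)
  expect_length(mv2$epochs, 1L)
  expect_false(all(mv2$kept))
  expect_match(mv2$discarded$reason, "missing event", all = FALSE)
  expect_error(epoch_movement(recording(matrix(0, 2, 10), rate)),
               "no valid trials")
})

test_that("epoch-length equalization interpolates to the mean length", {
  eps <- epoch_set(list(matrix(rnorm(100), 1), matrix(rnorm(120), 1)), 128)
  eq <- equalize_epoch_lengths(eps)
  expect_equal(vapply(eq$epochs, ncol, 1L), c(110L, 110L))

  one <- equalize_epoch_lengths(epoch_set(list(matrix(1:50, 1)), 128))
  expect_equal(as.vector(one$epochs[[1]]), 1:50)

  # cubic splines are exact on a linear ramp and preserve endpoints
  ramp <- matrix(seq(0, 1, length.out = 90), 1)
  eq2 <- equalize_epoch_lengths(epoch_set(list(ramp, matrix(rnorm(110), 1)), 128))
  got <- eq2$epochs[[1]][1, ]
  expect_lt(max(abs(got - seq(0, 1, length.out = 100))), 1e-9)
  expect_equal(got[1], 0); expect_equal(got[100], 1)
})

test_that("epoch averaging is the element-wise mean with landmark average", {
  e <- matrix(rnorm(3 * 50), 3)
  eps <- epoch_set(list(e, e, e), 128,
                   landmarks = data.frame(onset = c(10L, 12L, 14L),
                                          hold = c(30L, 30L, 30L)))
  avg <- average_epochs(eps)
  expect_equal(avg$data, e, tolerance = 1e-12)
  expect_equal(attr(avg, "landmarks")$onset, 12)
  opp <- average_epochs(epoch_set(list(e, -e), 128))
  expect_equal(max(abs(opp$data)), 0)
})

test_that("linear stages commute with averaging on equal-length epochs", {
  rate <- 512
  epochs <- lapply(1:3, function(i) matrix(rnorm(2 * rate), 2))
  favg <- filter_eeg(recording(Reduce(`+`, epochs) / 3, rate))$data
  avgf <- Reduce(`+`, lapply(epochs, function(e)
    filter_eeg(recording(e, rate))$data)) / 3
  expect_lt(max(abs(favg - avgf)), 1e-8)
})

test_that("EMG conditioning yields a nonnegative MVC-scaled envelope", {
  rate <- 2000
  const <- process_emg(recording(matrix(1, 1, 4000), rate, modality = "EMG"),
                       mvc = 1)
  expect_lt(max(abs(const$data[, 500:3500])), 1e-6)

  # amplitude-modulated 150 Hz carrier: envelope must track the modulator
  t <- seq_len(3 * rate) / rate
  mod <- 1 + 0.8 * sin(2 * pi * 1.5 * t)
  raw <- mod * sin(2 * pi * 150 * t)
  env <- process_emg(recording(matrix(raw, 1), rate, modality = "EMG"), mvc = 2)
  core <- 1000:5000
  expect_gt(stats::cor(env$data[1, core], mod[core]), 0.95)
  expect_true(all(env$data >= 0))
  expect_error(process_emg(recording(matrix(raw, 1), rate, modality = "EMG"),
                           mvc = 0), "positive")
})
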