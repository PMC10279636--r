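make_recording <- function(n_ch = 4, n_sa = 2048, fs = 512, events = NULL,
                           gen = function(t) sin(2 * pi * 10 * t)) {
  t <- (seq_len(n_sa) - 1) / fs
  data <- t(vapply(seq_len(n_ch), function(i) gen(t), numeric(n_sa)))
  eeg_recording(data, fs_hz = fs, events = events)
}

test_that("resampling halves the sample count and preserves the sine peak", {
  rec <- make_recording(n_ch = 2, n_sa = 1024, fs = 512)
  out <- resample_recording(rec, 256)
  expect_equal(ncol(out$data), 512, tolerance = 0, ignore_attr = TRUE)
  expect_equal(out$fs_hz, 256)

  # 10 Hz periodogram peak preserved
  x <- out$data[1, ]
  pw <- Mod(fft(x - mean(x)))^2
  freqs <- (seq_along(x) - 1) * 256 / length(x)
  half <- freqs > 0 & freqs <= 128
  expect_lt(abs(freqs[half][which.max(pw[half])] - 10), 1)

  expect_identical(resample_recording(rec, 512), rec)
  expect_error(resample_recording(rec, -1), "positive")

  ev <- data.frame(sample = c(100L, 800L), code = c("a", "b"))
  rec2 <- make_recording(n_ch = 2, n_sa = 1024, fs = 512, events = ev)
  out2 <- resample_recording(rec2, 256)
  expect_equal(out2$events$sample, c(51L, 401L), tolerance = 1)
})

test_that("average reference zeroes the per-sample channel mean", {
  rec <- make_recording(n_ch = 2, n_sa = 100, fs = 100)
  rec$data <- rbind(rep(5, 100), rep(-5, 100))
  out <- average_reference(rec)
  expect_equal(out$data, rec$data)

  rec$data <- matrix(10, 3, 100)
  expect_true(all(average_reference(rec)$data == 0))

  set.seed(5)
  rec$data <- matrix(rnorm(300), 3, 100)
  out <- average_reference(rec)
  expect_lt(max(abs(colMeans(out$data))), 1e-10)

  rec$data <- rec$data[1, , drop = FALSE]
  expect_error(average_reference(rec), "two channels")
})

test_that("the alpha band-pass passes 10 Hz, rejects 40 Hz and removes DC", {
  fs <- 256
  t <- (0:(fs * 4 - 1)) / fs
  rec <- eeg_recording(rbind(sin(2 * pi * 10 * t), sin(2 * pi * 40 * t)),
                       fs_hz = fs)
  out <- bandpass(rec, 8, 12)
  mid <- seq(fs, 3 * fs)   # avoid transients at the borders
  amp <- function(x) sqrt(mean(x^2)) * sqrt(2)
  expect_gte(amp(out$data[1, mid]) / amp(rec$data[1, mid]), 0.9)
  expect_lte(amp(out$data[2, mid]) / amp(rec$data[2, mid]), 0.1)

  rec$data <- matrix(7, 2, length(t))   # pure DC
  out <- bandpass(rec, 8, 12)
  expect_lt(max(abs(rowMeans(out$data))), 0.05)   # > 99% attenuation

  expect_error(bandpass(rec, 8, 200), "fs/2")

  resp <- filter_response(fs, 8, 12, freqs_hz = c(4, 10, 24))
  expect_gte(resp$gain[resp$freq_hz == 10], 0.9)
  expect_lte(resp$gain[resp$freq_hz == 4], 0.1)
  expect_lte(resp$gain[resp$freq_hz == 24], 0.1)
})

test_that("epoching uses the stated sample convention and drops edge events", {
  fs <- 256
  ev <- data.frame(sample = c(1L, 400L, 700L), code = "stim")
  rec <- make_recording(n_ch = 3, n_sa = 1100, fs = fs, events = ev)
  expect_warning(ep <- epoch_recording(rec, -0.5, 0.8), "dropped")
  # event at sample 1 cannot supply the pre-stimulus baseline; event at 700
  # runs past the end (700 + 204 > 1100 - ... actually fits); check count
  expect_equal(dim(ep$data)[3], 333)
  expect_equal(ep$t0_s, -0.5)

  ev2 <- data.frame(sample = c(300L, 600L), code = "stim")
  rec2 <- make_recording(n_ch = 2, n_sa = 1100, fs = fs, events = ev2)
  ep2 <- epoch_recording(rec2, -0.5, 0.8)
  expect_equal(dim(ep2$data)[1], 2)
  expect_equal(epoch_times(ep2)[1], -0.5)
  # both epochs share one time axis and carry the right slice of data
  s0 <- 300 - 128
  expect_equal(ep2$data[1, 1, ], rec2$data[1, s0:(s0 + 332)])
})

test_that("moving-window rejection flags spikes but tolerates slow drifts", {
  fs <- 256
  n_sa <- 333
  flat <- array(0, dim = c(1, 2, n_sa))
  spike <- flat
  spike[1, 2, 150] <- 250
  ramp <- flat
  ramp[1, 1, ] <- seq(0, 150, length.out = n_sa)
  ep <- epoch_array(abind_epochs(list(flat, spike, ramp)), fs_hz = fs, t0_s = -0.5)

  rep_ <- reject_peak_to_peak(ep, threshold_uv = 100)
  expect_identical(rep_$kept_mask, c(TRUE, FALSE, TRUE))
  expect_identical(rep_$offending_channel[2], "node_2")
  expect_equal(rep_$retained_fraction, mean(rep_$kept_mask))

  kept <- apply_rejection(ep, rep_)
  expect_equal(dim(kept$data)[1], 2)

  # monotone in the threshold: a higher threshold never rejects more
  set.seed(11)
  noisy <- epoch_array(array(rnorm(20 * 3 * n_sa, sd = 40), c(20, 3, n_sa)),
                       fs_hz = fs, t0_s = -0.5)
  th <- c(50, 100, 150, 200)
  kept_n <- vapply(th, function(x) sum(reject_peak_to_peak(noisy, x)$kept_mask),
                   numeric(1))
  expect_true(all(diff(kept_n) >= 0))
})

test_that("bad channels are flagged by decorrelation or line noise", {
  fs <- 256
  t <- (0:(fs * 4 - 1)) / fs
  common <- sin(2 * pi * 10 * t) + 0.5 * sin(2 * pi * 6 * t)
  set.seed(21)
  data <- rbind(common + rnorm(length(t), sd = 0.1),
                common + rnorm(length(t), sd = 0.1),
                common + rnorm(length(t), sd = 0.1),
                rnorm(length(t)))                     # independent channel
  rec <- eeg_recording(data, fs_hz = fs,
                       channel_labels = c("c1", "c2", "c3", "loose"))
  expect_identical(detect_bad_channels(rec), "loose")

  rec$data <- rbind(common, common, common)
  rec$channel_labels <- c("a", "b", "c")
  expect_length(detect_bad_channels(rec), 0)

  hum <- rbind(common + rnorm(length(t), sd = 0.1),
               common + rnorm(length(t), sd = 0.1),
               common + rnorm(length(t), sd = 0.1),
               common + rnorm(length(t), sd = 0.1) + 3 * sin(2 * pi * 60 * t))
  rec <- eeg_recording(hum, fs_hz = fs,
                       channel_labels = c("c1", "c2", "c3", "mains"))
  expect_true("mains" %in% detect_bad_channels(rec))

  expect_error(detect_bad_channels(eeg_recording(hum[1:2, ], fs_hz = fs)),
               "three channels")
})

test_that("filtering and epoching commute away from the epoch borders", {
  fs <- 256
  set.seed(31)
  n_sa <- fs * 6
  # stationary in-band signal: alpha-range sinusoids with random phases,
  # plus weak broadband noise
  tt <- (seq_len(n_sa) - 1) / fs
  mk <- function() {
    rowSums(vapply(c(9, 10.2, 11.5), function(f)
      sin(2 * pi * f * tt + runif(1, 0, 2 * pi)), numeric(n_sa))) +
      rnorm(n_sa, sd = 0.1)
  }
  data <- rbind(mk(), mk())
  ev <- data.frame(sample = c(600L, 900L), code = "s")
  rec <- eeg_recording(data, fs_hz = fs, events = ev)

  # a window long enough that the filter's ring-down (time constant
  # ~1/(pi * bandwidth) ~ 0.08 s) has died away inside the central half
  a <- epoch_recording(bandpass(rec, 8, 12), -1.5, 1.5)
  b <- bandpass(epoch_recording(rec, -1.5, 1.5), 8, 12)
  n <- dim(a$data)[3]
  mid <- seq(round(n * 0.25), round(n * 0.75))
  rms <- function(x) sqrt(mean(x^2))
  rel <- rms(a$data[, , mid] - b$data[, , mid]) / rms(a$data[, , mid])
  expect_lt(rel, 0.01)
})
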