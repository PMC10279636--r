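#' Construct a continuous multichannel recording
#'
#' @param data Numeric matrix, channels x samples (microvolts for sensor
#'   data).
#' @param fs_hz Sampling rate in Hz.
#' @param channel_labels Channel labels; default `ch_1 ...`.
#' @param events Data frame with columns `sample` (1-based indices,
#'   strictly increasing, within bounds) and `code`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs_hz, channel_labels = NULL, events = NULL) {
  stopifnot(is.matrix(data), fs_hz > 0)
  if (is.null(channel_labels)) channel_labels <- sprintf("ch_%d", seq_len(nrow(data)))
  stopifnot(length(channel_labels) == nrow(data))
  if (is.null(events)) events <- data.frame(sample = integer(0), code = character(0))
  stopifnot(all(c("sample", "code") %in% names(events)))
  if (nrow(events)) {
    if (is.unsorted(events$sample, strictly = TRUE)) {
      stop("event latencies must be strictly increasing", call. = FALSE)
    }
    if (min(events$sample) < 1 || max(events$sample) > ncol(data)) {
      stop("event latencies outside the recording", call. = FALSE)
    }
  }
  structure(list(data = data, fs_hz = fs_hz,
                 channel_labels = as.character(channel_labels),
                 events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$fs_hz, nrow(x$events)))
  invisible(x)
}

#' Resample a recording to a new rate
#'
#' Polyphase resampling (via the `signal` package) applied per channel;
#' event latencies are remapped proportionally.  Upsampling is permitted
#' but flagged with a message.
#'
#' @param rec An [eeg_recording()].
#' @param target_fs Target sampling rate in Hz (> 0).
#' @return The resampled recording.
#' @export
resample_recording <- function(rec, target_fs) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.numeric(target_fs) || target_fs <= 0) {
    stop("`target_fs` must be positive", call. = FALSE)
  }
  if (target_fs == rec$fs_hz) return(rec)
  if (target_fs > rec$fs_hz) message("upsampling from ", rec$fs_hz, " to ", target_fs, " Hz")
  # rational approximation of the rate ratio
  scale <- 1000
  p <- round(target_fs * scale); q <- round(rec$fs_hz * scale)
  g <- gcd_int(p, q); p <- p / g; q <- q / g
  out <- t(apply(rec$data, 1L, function(x) signal::resample(x, p, q)))
  ev <- rec$events
  if (nrow(ev)) {
    ev$sample <- pmax(1L, pmin(ncol(out), round((ev$sample - 1L) * p / q) + 1L))
  }
  eeg_recording(out, fs_hz = target_fs, channel_labels = rec$channel_labels,
                events = ev)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Re-reference a recording to the channel average
#'
#' Subtracts the across-channel mean from every sample, so the per-sample
#' mean of the output is zero.
#'
#' @param rec An [eeg_recording()] with at least two channels.
#' @return The re-referenced recording.
#' @export
average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2L) {
    stop("average reference needs at least two channels", call. = FALSE)
  }
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data))
  rec
}

#' Zero-phase Butterworth band-pass filter
#'
#' Order-4 Butterworth design applied forward and backward
#' (`signal::filtfilt`), so the net response is zero-phase with squared
#' magnitude -- a requirement when the filtered signal feeds phase
#' estimates.  Works on a recording (per channel) or an epoch array (per
#' epoch and node).
#'
#' @param x An [eeg_recording()] or [epoch_array()].
#' @param low_hz,high_hz Band edges, `0 < low < high < fs/2`.
#' @param order Butterworth design order (default 4).
#' @return Same type as the input.
#' @export
bandpass <- function(x, low_hz, high_hz, order = 4L) {
  UseMethod("bandpass")
}

bandpass_check <- function(low_hz, high_hz, fs) {
  if (!(low_hz > 0 && high_hz > low_hz && high_hz < fs / 2)) {
    stop("band must satisfy 0 < low < high < fs/2", call. = FALSE)
  }
}

#' @export
bandpass.eeg_recording <- function(x, low_hz, high_hz, order = 4L) {
  bandpass_check(low_hz, high_hz, x$fs_hz)
  flt <- signal::butter(order, c(low_hz, high_hz) / (x$fs_hz / 2), type = "pass")
  x$data <- t(apply(x$data, 1L, function(ch) signal::filtfilt(flt, ch)))
  x
}

#' @export
bandpass.epoch_array <- function(x, low_hz, high_hz, order = 4L) {
  bandpass_check(low_hz, high_hz, x$fs_hz)
  flt <- signal::butter(order, c(low_hz, high_hz) / (x$fs_hz / 2), type = "pass")
  d <- x$data
  for (e in seq_len(dim(d)[1L])) {
    for (i in seq_len(dim(d)[2L])) {
      d[e, i, ] <- signal::filtfilt(flt, d[e, i, ])
    }
  }
  x$data <- d
  x
}

#' Realized band-pass transfer function
#'
#' Squared Butterworth magnitude response (forward-backward application),
#' for reporting the filter actually applied by [bandpass()].
#'
#' @param fs_hz Sampling rate.
#' @param low_hz,high_hz Band edges.
#' @param freqs_hz Frequencies at which to evaluate the gain.
#' @param order Design order (default 4, as in [bandpass()]).
#' @return Data frame with columns `freq_hz` and `gain`.
#' @export
filter_response <- function(fs_hz, low_hz, high_hz,
                            freqs_hz = seq(0.5, fs_hz / 2 - 0.5, by = 0.5),
                            order = 4L) {
  bandpass_check(low_hz, high_hz, fs_hz)
  flt <- signal::butter(order, c(low_hz, high_hz) / (fs_hz / 2), type = "pass")
  w <- freqs_hz * 2 * pi / fs_hz
  z <- exp(-1i * w)
  h <- vapply(z, function(zi) {
    sum(flt$b * zi^(seq_along(flt$b) - 1)) /
      sum(flt$a * zi^(seq_along(flt$a) - 1))
  }, complex(1))
  data.frame(freq_hz = freqs_hz, gain = Mod(h)^2)
}

#' Segment a continuous recording into stimulus-locked epochs
#'
#' Epochs start `tmin_s` before each event and hold
#' `floor((tmax - tmin) * fs) + 1` samples (truncation convention; 333 at
#' 256 Hz for the default -0.5 to 0.8 s window, with the last sample on
#' the largest grid point not beyond `tmax_s`).  Events too close to the
#' record edges are dropped with a warning.
#'
#' @param rec An [eeg_recording()] with events.
#' @param tmin_s,tmax_s Epoch limits in seconds relative to the event.
#' @return An [epoch_array()] with `t0_s = tmin_s`.
#' @export
epoch_recording <- function(rec, tmin_s = -0.5, tmax_s = 0.8) {
  stopifnot(inherits(rec, "eeg_recording"), tmax_s > tmin_s)
  if (!nrow(rec$events)) stop("recording has no events to epoch around", call. = FALSE)
  n_samp <- n_epoch_samples(tmin_s, tmax_s, rec$fs_hz)
  off0 <- as.integer(round_half_up(tmin_s * rec$fs_hz))
  starts <- rec$events$sample + off0
  ok <- starts >= 1L & (starts + n_samp - 1L) <= ncol(rec$data)
  if (any(!ok)) {
    warning(sum(!ok), " event(s) too close to the record edge; epoch(s) dropped")
  }
  starts <- starts[ok]
  if (!length(starts)) stop("no epochs fit within the recording", call. = FALSE)
  out <- array(0, dim = c(length(starts), nrow(rec$data), n_samp))
  for (e in seq_along(starts)) {
    out[e, , ] <- rec$data[, starts[e]:(starts[e] + n_samp - 1L)]
  }
  epoch_array(out, fs_hz = rec$fs_hz, t0_s = tmin_s,
              labels = rec$channel_labels)
}

#' Moving-window peak-to-peak artifact rejection
#'
#' An epoch is rejected when any channel's peak-to-peak amplitude exceeds
#' `threshold_uv` within at least one window position; windows of
#' `win_ms` advance by `step_ms` and the last partial window is included.
#'
#' @param epochs An [epoch_array()] (sensor units, microvolts).
#' @param threshold_uv Peak-to-peak threshold (default 100).
#' @param win_ms Window length in ms (default 200).
#' @param step_ms Step between window onsets in ms (default 20).
#' @return A `rejection_report`: list with `kept_mask`,
#'   `offending_channel` (NA for kept epochs) and `retained_fraction`.
#' @export
reject_peak_to_peak <- function(epochs, threshold_uv = 100, win_ms = 200,
                                step_ms = 20) {
  stopifnot(inherits(epochs, "epoch_array"), threshold_uv > 0)
  d <- epochs$data
  n_ep <- dim(d)[1L]; n_ch <- dim(d)[2L]; n_sa <- dim(d)[3L]
  win <- max(2L, round_half_up(win_ms / 1000 * epochs$fs_hz))
  step <- max(1L, round_half_up(step_ms / 1000 * epochs$fs_hz))
  if (win > n_sa) stop("window longer than the epoch", call. = FALSE)
  starts <- unique(pmin(seq(1L, n_sa, by = step), n_sa - win + 1L))
  kept <- rep(TRUE, n_ep)
  offender <- rep(NA_character_, n_ep)
  for (e in seq_len(n_ep)) {
    for (ch in seq_len(n_ch)) {
      x <- d[e, ch, ]
      for (s in starts) {
        seg <- x[s:(s + win - 1L)]
        if (max(seg) - min(seg) > threshold_uv) {
          kept[e] <- FALSE
          offender[e] <- epochs$labels[ch]
          break
        }
      }
      if (!kept[e]) break
    }
  }
  structure(list(kept_mask = kept, offending_channel = offender,
                 retained_fraction = mean(kept)),
            class = "rejection_report")
}

#' Keep only the epochs retained by a rejection report
#' @param epochs An [epoch_array()].
#' @param report A `rejection_report` from [reject_peak_to_peak()].
#' @return The filtered [epoch_array()].
#' @export
apply_rejection <- function(epochs, report) {
  stopifnot(inherits(epochs, "epoch_array"), inherits(report, "rejection_report"))
  epochs$data <- epochs$data[report$kept_mask, , , drop = FALSE]
  epochs
}

#' Flag bad channels by neighbourhood correlation and line noise
#'
#' A channel is flagged when its maximal absolute correlation with any
#' other channel falls below `corr_threshold`, or when its line-noise
#' ratio (spectral power above `line_freq_hz` over power below) exceeds
#' the across-channel mean by more than `line_noise_sd` standard
#' deviations.  With no montage available the "neighbourhood" is all other
#' channels.
#'
#' @param rec An [eeg_recording()] with at least three channels.
#' @param corr_threshold Correlation criterion (default 0.85).
#' @param line_noise_sd Robustness multiplier for the noise criterion
#'   (default 4).
#' @param line_freq_hz Boundary between "signal" and "line noise" bands
#'   (default 45 Hz).
#' @return Character vector of flagged channel labels (possibly empty).
#' @export
detect_bad_channels <- function(rec, corr_threshold = 0.85,
                                line_noise_sd = 4, line_freq_hz = 45) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_ch <- nrow(rec$data)
  if (n_ch < 3L) stop("need at least three channels", call. = FALSE)
  cc <- abs(stats::cor(t(rec$data)))
  diag(cc) <- 0
  max_corr <- apply(cc, 1L, max)
  low_corr <- max_corr < corr_threshold

  n <- ncol(rec$data)
  freqs <- (seq_len(n) - 1L) * rec$fs_hz / n
  half <- freqs <= rec$fs_hz / 2
  pow <- t(apply(rec$data, 1L, function(x) Mod(stats::fft(x - mean(x)))^2))
  hi_band <- half & freqs > line_freq_hz
  lo_band <- half & freqs > 0 & freqs <= line_freq_hz
  ratio <- rowSums(pow[, hi_band, drop = FALSE]) /
    pmax(rowSums(pow[, lo_band, drop = FALSE]), .Machine$double.eps)
  noisy <- ratio > mean(ratio) + line_noise_sd * stats::sd(ratio)

  rec$channel_labels[low_corr | noisy]
}
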