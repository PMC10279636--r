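#' Construct a connectivity matrix
#'
#' @param plv Symmetric numeric matrix with unit diagonal, entries in
#'   `[0, 1]`.
#' @param labels Node (parcel) labels.
#' @param cell Optional named list identifying the design cell (subject,
#'   condition, emotion).
#' @return An object of class `connectivity_matrix` (a plain matrix with
#'   attributes, so matrix algebra keeps working).
#' @export
connectivity_matrix <- function(plv, labels = NULL, cell = NULL) {
  check_symmetric_unit_diag(plv, "plv")
  if (is.null(labels)) labels <- sprintf("node_%d", seq_len(nrow(plv)))
  stopifnot(length(labels) == nrow(plv))
  dimnames(plv) <- list(labels, labels)
  structure(plv, class = c("connectivity_matrix", "matrix", "array"),
            cell = cell)
}

#' Instantaneous phase via the analytic signal
#'
#' Computes the Hilbert analytic signal of every epoch x node trace with
#' the frequency-domain method and returns its argument, wrapped to
#' `(-pi, pi]`.  Inputs should already be band-limited to the analysis
#' band (see [bandpass()]).
#'
#' @param epochs An [epoch_array()].
#' @return A `phase_array`: same shape and metadata as the input, values
#'   in radians.
#' @export
instantaneous_phase <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_array"))
  d <- epochs$data
  n_ep <- dim(d)[1L]; n_no <- dim(d)[2L]; n_sa <- dim(d)[3L]
  # columns = one trace each; mvfft does all epochs x nodes in one pass
  m <- matrix(aperm(d, c(3L, 1L, 2L)), nrow = n_sa)
  if (any(apply(m, 2L, function(x) all(x == 0)))) {
    stop("degenerate input: all-zero signal has undefined phase", call. = FALSE)
  }
  h <- numeric(n_sa)
  if (n_sa %% 2L == 0L) {
    h[c(1L, n_sa / 2L + 1L)] <- 1
    h[2L:(n_sa / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n_sa + 1L) / 2L)] <- 2
  }
  analytic <- stats::mvfft(stats::mvfft(m) * h, inverse = TRUE) / n_sa
  ph <- Arg(analytic)                      # already in (-pi, pi]
  out <- aperm(array(ph, dim = c(n_sa, n_ep, n_no)), c(2L, 3L, 1L))
  structure(list(data = out, fs_hz = epochs$fs_hz, t0_s = epochs$t0_s,
                 labels = epochs$labels),
            class = "phase_array")
}

#' @export
print.phase_array <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<phase_array> %d epochs x %d nodes x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$fs_hz))
  invisible(x)
}

#' Phase-locking value of two phase series
#'
#' The modulus of the mean unit phasor of the phase differences,
#' `|mean(exp(i * (phi_i - phi_j)))|`.  The series may index time samples
#' (within-epoch PLV) or trials at a fixed latency (cross-trial PLV); the
#' statistic is the same.
#'
#' @param phases_i,phases_j Equal-length numeric vectors of phases in
#'   radians (at least 2 samples).
#' @return A value in `[0, 1]`.
#' @export
plv <- function(phases_i, phases_j) {
  if (length(phases_i) != length(phases_j)) {
    stop("phase series must have equal length", call. = FALSE)
  }
  stopifnot(length(phases_i) >= 2L)
  Mod(mean(exp(1i * (phases_i - phases_j))))
}

#' Pairwise PLV matrix of a phase array
#'
#' Two averaging schemes are provided.  The default, `"trials"`, is the
#' classical cross-trial PLV: at every time sample the unit phasors of the
#' phase differences are averaged across epochs, the modulus is taken, and
#' the resulting time course is averaged over the analysis window.  The
#' alternative, `"time"`, averages phasors over time within each epoch and
#' then takes the arithmetic mean of the per-epoch moduli across epochs.
#' With narrow-band signals whose phase offsets are stable within a trial,
#' only the cross-trial scheme is sensitive to trial-to-trial phase
#' consistency; see the package vignette for the rationale.
#'
#' @param phases A `phase_array` from [instantaneous_phase()].
#' @param window Length-2 numeric, analysis window in seconds relative to
#'   stimulus onset.  `NULL` (default) uses the post-stimulus interval with
#'   `edge_trim_s` removed from the epoch end, to suppress Hilbert edge
#'   artifacts.
#' @param average `"trials"` (default) or `"time"`.
#' @param edge_trim_s Border trim applied when `window` is `NULL`
#'   (default 0.1 s).
#' @return A [connectivity_matrix()].
#' @export
plv_matrix <- function(phases, window = NULL,
                       average = c("trials", "time"), edge_trim_s = 0.1) {
  stopifnot(inherits(phases, "phase_array"))
  average <- match.arg(average)
  d <- phases$data
  tt <- phases$t0_s + (seq_len(dim(d)[3L]) - 1L) / phases$fs_hz
  if (is.null(window)) {
    window <- c(max(0, tt[1L] + edge_trim_s), tt[length(tt)] - edge_trim_s)
  }
  keep <- which(tt >= window[1L] & tt <= window[2L])
  if (length(keep) < 2L) stop("empty analysis window", call. = FALSE)
  n_ep <- dim(d)[1L]; n_no <- dim(d)[2L]
  acc <- matrix(0, n_no, n_no)
  if (average == "trials") {
    if (n_ep < 2L) stop("cross-trial PLV needs at least two epochs", call. = FALSE)
    for (s in keep) {
      z <- exp(1i * d[, , s, drop = TRUE])       # epochs x nodes
      if (n_no == 1L) z <- matrix(z, ncol = 1L)
      acc <- acc + Mod(crossprod(Conj(z), z)) / n_ep
    }
    p <- acc / length(keep)
  } else {
    for (e in seq_len(n_ep)) {
      z <- exp(1i * t(d[e, , keep, drop = TRUE]))  # time x nodes
      if (n_no == 1L) z <- matrix(z, ncol = 1L)
      acc <- acc + Mod(crossprod(Conj(z), z)) / length(keep)
    }
    p <- acc / n_ep
  }
  p <- (p + t(p)) / 2
  diag(p) <- 1
  connectivity_matrix(pmin(p, 1), labels = phases$labels)
}
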