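# internal helpers shared across modules

# Run code with a private RNG state so seeded package functions do not
# perturb (or depend on) the caller's random stream.
with_local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed for a (subject, cell) unit, kept inside 32-bit range.
derive_seed <- function(seed, i, j = 0L) {
  as.integer((as.numeric(seed) * 2654435761 + i * 40503 + j * 9973) %%
               .Machine$integer.max)
}

check_symmetric_unit_diag <- function(m, name = "target_plv") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(sprintf("`%s` must be a square matrix", name), call. = FALSE)
  }
  if (any(!is.finite(m))) stop(sprintf("`%s` has non-finite entries", name), call. = FALSE)
  if (max(abs(m - t(m))) > 1e-12) {
    stop(sprintf("`%s` must be symmetric", name), call. = FALSE)
  }
  if (any(m < 0) || any(m > 1)) {
    stop(sprintf("`%s` entries must lie in [0, 1]", name), call. = FALSE)
  }
  if (max(abs(diag(m) - 1)) > 1e-12) {
    stop(sprintf("`%s` must have a unit diagonal", name), call. = FALSE)
  }
  invisible(TRUE)
}

upper_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

# round-half-up (base round() is half-to-even)
round_half_up <- function(x) floor(x + 0.5)

# samples in [tmin, tmax] at rate fs, first sample at tmin, last sample the
# largest grid point not beyond tmax (truncation convention: floor(span*fs)+1,
# e.g. 333 samples for -0.5..0.8 s at 256 Hz, 205 for a 0.8 s window)
n_epoch_samples <- function(tmin_s, tmax_s, fs_hz) {
  as.integer(floor((tmax_s - tmin_s) * fs_hz + 1e-9)) + 1L
}
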