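#' Describe a two-condition by four-emotion within-subject design
#'
#' The default design mirrors an overt/covert emotional-face experiment:
#' every subject sees every condition x emotion cell, with 100 trials per
#' cell (400 stimuli per task split over four expressions).
#'
#' @param n_subjects Number of subjects (default 52).
#' @param conditions Character vector of condition labels.
#' @param emotions Character vector of emotion labels.
#' @param trials_per_cell Trials (epochs) per subject x condition x emotion
#'   cell.
#' @param seed Integer seed associated with the design.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(n_subjects = 52,
                              conditions = c("overt", "covert"),
                              emotions = c("fear", "sad", "happy", "neutral"),
                              trials_per_cell = 100,
                              seed = 1L) {
  stopifnot(n_subjects >= 1, trials_per_cell >= 1)
  if (anyDuplicated(conditions) || anyDuplicated(emotions)) {
    stop("condition and emotion labels must be unique", call. = FALSE)
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         conditions = as.character(conditions),
         emotions = as.character(emotions),
         trials_per_cell = as.integer(trials_per_cell),
         seed = as.integer(seed)),
    class = "experiment_design"
  )
}

#' Mean resultant length of a von Mises distribution
#'
#' `kappa_to_plv()` maps a concentration parameter to the expected phase
#' locking it induces, `A(kappa) = I1(kappa) / I0(kappa)`;
#' `plv_to_kappa()` inverts that map numerically.  Two oscillators whose
#' phase offsets are independent von Mises jitters around a shared
#' reference attain a pairwise PLV equal to the product of their individual
#' resultant lengths, which is how [coupling_spec()] calibrates node
#' concentrations.
#'
#' @param kappa Non-negative concentration (may be `Inf`).
#' @return Mean resultant length in `[0, 1]`.
#' @export
kappa_to_plv <- function(kappa) {
  stopifnot(all(kappa >= 0))
  out <- numeric(length(kappa))
  mid <- is.finite(kappa) & kappa > 0 & kappa <= 5000
  big <- is.finite(kappa) & kappa > 5000
  out[mid] <- besselI(kappa[mid], 1, expon.scaled = TRUE) /
    besselI(kappa[mid], 0, expon.scaled = TRUE)
  # large-argument expansion of I1/I0 (besselI loses accuracy out here)
  kb <- kappa[big]
  out[big] <- 1 - 1 / (2 * kb) - 1 / (8 * kb^2) - 1 / (8 * kb^3)
  out[!is.finite(kappa)] <- 1
  out
}

#' @rdname kappa_to_plv
#' @param target_plv Desired mean resultant length, in `[0, 1)`.
#' @param tol Convergence tolerance on the Bessel ratio.
#' @return Concentration `kappa >= 0` with
#'   `|kappa_to_plv(kappa) - target_plv| <= tol`.
#' @export
plv_to_kappa <- function(target_plv, tol = 1e-9) {
  stopifnot(length(target_plv) == 1L, is.finite(target_plv))
  if (target_plv < 0 || target_plv >= 1) {
    stop("`target_plv` must lie in [0, 1): kappa diverges as PLV -> 1",
         call. = FALSE)
  }
  if (target_plv == 0) return(0)
  r <- target_plv
  # piecewise starting value (Fisher's A1 inverse), then Newton steps on
  # A(kappa) - r using A'(kappa) = 1 - A^2 - A/kappa
  k <- if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
  for (it in 1:50) {
    a <- kappa_to_plv(k)
    if (abs(a - r) <= tol) break
    deriv <- 1 - a^2 - a / k
    k <- max(k - (a - r) / deriv, k / 2)
  }
  k
}

# von Mises sampler (Best & Fisher rejection scheme), mean 0.
rvonmises <- function(n, kappa) {
  if (n == 0L) return(numeric(0))
  if (!is.finite(kappa)) return(rep(0, n))
  if (kappa < 1e-10) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    z <- cos(pi * stats::runif(m))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    nk <- sum(keep)
    if (nk > 0L) {
      theta <- sign(stats::runif(nk) - 0.5) * acos(pmin(1, pmax(-1, f[keep])))
      out[(got + 1L):(got + nk)] <- theta
      got <- got + nk
    }
  }
  out
}

#' Specify pairwise phase coupling for a set of oscillating nodes
#'
#' A `coupling_spec` fixes the statistical structure the generator imposes
#' on parcel-level oscillations: an n x n matrix of target phase-locking
#' values, a carrier frequency, an amplitude and an additive Gaussian noise
#' level.  When `membership` groups nodes into modules, the generator uses
#' a two-level phase hierarchy (a von Mises module offset around a shared
#' epoch phase, plus node jitter around the module offset) that reproduces
#' block-structured targets exactly in expectation; without a membership an
#' arbitrary matrix is approximated by its best rank-one factorisation on
#' the log scale.
#'
#' @param target_plv Symmetric matrix with unit diagonal and entries in
#'   `[0, 1]`.
#' @param carrier_freq_hz Oscillation frequency in Hz (default 10, i.e. the
#'   centre of the alpha band).
#' @param amplitude Carrier amplitude (arbitrary source units).
#' @param noise_sd Standard deviation of additive Gaussian sample noise.
#' @param membership Optional character/factor vector (length n) mapping
#'   nodes to modules (e.g. `"core"`, `"extended"`, `"other"`).
#' @param labels Optional node labels; defaults to `node_1 ...`.
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(target_plv, carrier_freq_hz = 10, amplitude = 1,
                          noise_sd = 1, membership = NULL, labels = NULL) {
  check_symmetric_unit_diag(target_plv)
  n <- nrow(target_plv)
  stopifnot(carrier_freq_hz > 0, amplitude >= 0, noise_sd >= 0)
  if (!is.null(membership)) {
    membership <- as.character(membership)
    stopifnot(length(membership) == n)
  }
  if (is.null(labels)) labels <- sprintf("node_%d", seq_len(n))
  stopifnot(length(labels) == n)
  structure(
    list(n_nodes = n, target_plv = unname(target_plv),
         carrier_freq_hz = carrier_freq_hz, amplitude = amplitude,
         noise_sd = noise_sd, membership = membership,
         labels = as.character(labels)),
    class = "coupling_spec"
  )
}

#' Build a block-structured coupling specification with planted communities
#'
#' Same-module node pairs receive `within_plv`, cross-module pairs
#' `between_plv`; the membership is retained so the generator can realise
#' the block structure exactly in expectation.
#'
#' @param membership Character/factor vector mapping each node to a module.
#' @param within_plv Target PLV for same-module pairs; must exceed
#'   `between_plv`.
#' @param between_plv Target PLV for cross-module pairs (>= 0).
#' @inheritParams coupling_spec
#' @return A [coupling_spec()].
#' @export
plant_communities <- function(membership, within_plv, between_plv,
                              carrier_freq_hz = 10, amplitude = 1,
                              noise_sd = 1, labels = NULL) {
  membership <- as.character(membership)
  n <- length(membership)
  stopifnot(n >= 2)
  if (!(within_plv > between_plv && between_plv >= 0 && within_plv <= 1)) {
    stop("need within_plv > between_plv >= 0 (equal blocks are unidentifiable)",
         call. = FALSE)
  }
  same <- outer(membership, membership, "==")
  target <- ifelse(same, within_plv, between_plv)
  diag(target) <- 1
  coupling_spec(target, carrier_freq_hz = carrier_freq_hz,
                amplitude = amplitude, noise_sd = noise_sd,
                membership = membership, labels = labels)
}

# Calibrate per-node (and per-module) von Mises concentrations so the
# generated phases attain the spec's pairwise PLV targets.
# Returns list(a = node resultants, g = module resultants or NULL).
calibrate_coupling <- function(spec) {
  target <- spec$target_plv
  n <- spec$n_nodes
  if (is.null(spec$membership)) {
    a <- rank_one_resultants(target)
    return(list(a = a, g = NULL, modules = NULL, module_of = NULL))
  }
  memb <- spec$membership
  modules <- unique(memb)
  a <- numeric(n)
  wbar <- stats::setNames(numeric(length(modules)), modules)
  for (m in modules) {
    idx <- which(memb == m)
    if (length(idx) >= 2L) {
      block <- target[idx, idx, drop = FALSE]
      w <- mean(block[upper.tri(block)])
      wbar[m] <- w
      a[idx] <- sqrt(w)
    } else {
      wbar[m] <- 1
      a[idx] <- 1
    }
  }
  g <- stats::setNames(rep(1, length(modules)), modules)
  if (length(modules) >= 2L) {
    # module-pair targets relative to the node-level attenuation
    k <- length(modules)
    cross <- matrix(1, k, k, dimnames = list(modules, modules))
    for (p in seq_len(k - 1L)) {
      for (q in seq(p + 1L, k)) {
        ip <- which(memb == modules[p]); iq <- which(memb == modules[q])
        b <- mean(target[ip, iq])
        denom <- mean(a[ip]) * mean(a[iq])
        cross[p, q] <- cross[q, p] <- if (denom > 0) min(1, b / denom) else 0
      }
    }
    g <- rank_one_resultants(cross)
    names(g) <- modules
  }
  list(a = a, g = g, modules = modules, module_of = match(memb, modules))
}

# Best rank-one factorisation of a symmetric affinity matrix on the log
# scale: find a_i in [0, 1] with a_i * a_j ~= T_ij (least squares over the
# positive off-diagonal entries).  Exact when T is rank one (e.g. uniform).
rank_one_resultants <- function(target) {
  n <- nrow(target)
  if (n == 1L) return(1)
  pairs <- upper_pairs(n)
  w <- target[pairs]
  pos <- w > 0
  a <- rep(0, n)
  involved <- unique(c(pairs[pos, 1L], pairs[pos, 2L]))
  if (!length(involved)) return(a)
  if (all(w[pos] == w[pos][1L])) {
    a[involved] <- sqrt(w[pos][1L])
    return(pmin(a, 1))
  }
  ip <- pairs[pos, , drop = FALSE]
  y <- log(w[pos])
  x <- solve_log_ls(ip, y, n)
  a[seq_len(n)] <- exp(pmin(0, x))
  a[!(seq_len(n) %in% involved)] <- 0
  a
}

# Solve min sum (x_i + x_j - y_ij)^2 by normal equations.
solve_log_ls <- function(pairs, y, n) {
  A <- matrix(0, n, n)
  b <- numeric(n)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    A[i, i] <- A[i, i] + 1; A[j, j] <- A[j, j] + 1
    A[i, j] <- A[i, j] + 1; A[j, i] <- A[j, i] + 1
    b[i] <- b[i] + y[r]; b[j] <- b[j] + y[r]
  }
  keep <- diag(A) > 0
  x <- rep(-Inf, n)
  x[keep] <- solve(A[keep, keep, drop = FALSE] +
                     diag(1e-10, sum(keep)), b[keep])
  x
}

resultant_to_kappa <- function(a) {
  vapply(a, function(ai) {
    if (ai >= 1) Inf else if (ai <= 0) 0 else plv_to_kappa(ai)
  }, numeric(1))
}

# Draw per-epoch phase offsets (epochs x nodes) under the hierarchy:
# shared epoch phase -> module offset (von Mises) -> node jitter (von Mises).
draw_phase_offsets <- function(spec, n_epochs) {
  cal <- calibrate_coupling(spec)
  n <- spec$n_nodes
  theta <- stats::runif(n_epochs, -pi, pi)
  phi <- matrix(theta, n_epochs, n)
  if (!is.null(cal$g)) {
    kmod <- resultant_to_kappa(cal$g)
    eta <- vapply(kmod, function(k) rvonmises(n_epochs, k),
                  numeric(n_epochs))
    if (n_epochs == 1L) eta <- matrix(eta, 1L)
    phi <- phi + eta[, cal$module_of, drop = FALSE]
  }
  knode <- resultant_to_kappa(cal$a)
  for (i in seq_len(n)) phi[, i] <- phi[, i] + rvonmises(n_epochs, knode[i])
  phi
}

#' Cross-trial PLV matrix implied by a coupling spec, at the phase level
#'
#' Draws per-epoch phase offsets from the generator's von Mises hierarchy
#' and computes the empirical cross-trial phase-locking matrix directly
#' from the offsets, skipping time-domain signal synthesis.  This is the
#' quantity the full route (epochs -> analytic phase -> [plv_matrix()])
#' converges to as sample noise vanishes, and is the workhorse for
#' operating-characteristic simulations where many replicates are needed.
#'
#' @param spec A [coupling_spec()].
#' @param n_epochs Number of epochs (trials) to draw.
#' @param seed Integer seed; identical seeds give identical matrices.
#' @return A `connectivity_matrix` (symmetric, unit diagonal, entries in
#'   `[0, 1]`).
#' @export
simulate_plv_matrix <- function(spec, n_epochs, seed = 1L) {
  stopifnot(inherits(spec, "coupling_spec"), n_epochs >= 2)
  phi <- with_local_seed(seed, draw_phase_offsets(spec, n_epochs))
  z <- exp(1i * phi)                      # epochs x nodes
  p <- Mod(crossprod(Conj(z), z)) / n_epochs
  p <- (p + t(p)) / 2
  diag(p) <- 1
  connectivity_matrix(p, labels = spec$labels)
}

#' Generate epoched oscillatory node signals with planted phase coupling
#'
#' Every node carries `amplitude * cos(2*pi*f*t + phi)` plus Gaussian
#' noise; the per-epoch phase offsets `phi` follow the spec's von Mises
#' coupling hierarchy so that the expected cross-trial PLV of node pair
#' (i, j) equals `target_plv[i, j]` (exactly for block-structured targets,
#' to a rank-one approximation otherwise).
#'
#' @param spec A [coupling_spec()].
#' @param n_epochs Number of epochs to generate.
#' @param seed Integer seed; identical `(spec, n_epochs, seed)` give
#'   bit-identical output.
#' @param fs_hz Sampling rate (default 256 Hz).
#' @param tmin_s,tmax_s Epoch limits relative to stimulus onset (defaults
#'   -0.5 and 0.8 s); the epoch holds `floor((tmax - tmin) * fs) + 1`
#'   samples starting at `tmin_s` (333 for the defaults).
#' @return An `epoch_array`: list with `data` (epochs x nodes x samples),
#'   `fs_hz`, `t0_s` and `labels`.
#' @export
generate_epochs <- function(spec, n_epochs, seed = 1L, fs_hz = 256,
                            tmin_s = -0.5, tmax_s = 0.8) {
  stopifnot(inherits(spec, "coupling_spec"), n_epochs >= 1, fs_hz > 0,
            tmax_s > tmin_s)
  n_samp <- n_epoch_samples(tmin_s, tmax_s, fs_hz)
  tt <- tmin_s + (seq_len(n_samp) - 1L) / fs_hz
  with_local_seed(seed, {
    phi <- draw_phase_offsets(spec, n_epochs)          # epochs x nodes
    ang <- outer(phi, 2 * pi * spec$carrier_freq_hz * tt, "+")
    x <- spec$amplitude * cos(ang)
    if (spec$noise_sd > 0) {
      x <- x + array(stats::rnorm(length(x), sd = spec$noise_sd), dim = dim(x))
    }
    epoch_array(x, fs_hz = fs_hz, t0_s = tmin_s, labels = spec$labels)
  })
}

#' Construct an epoch array
#'
#' @param data Numeric array, epochs x nodes(channels) x samples.
#' @param fs_hz Sampling rate in Hz.
#' @param t0_s Time of the first sample relative to stimulus onset.
#' @param labels Node/channel labels.
#' @return An object of class `epoch_array`.
#' @export
epoch_array <- function(data, fs_hz, t0_s, labels = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L, fs_hz > 0)
  if (anyNA(data)) stop("epoch data must not contain missing values", call. = FALSE)
  dimnames(data) <- NULL
  if (is.null(labels)) labels <- sprintf("node_%d", seq_len(dim(data)[2L]))
  stopifnot(length(labels) == dim(data)[2L])
  structure(list(data = data, fs_hz = fs_hz, t0_s = t0_s,
                 labels = as.character(labels)),
            class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_array> %d epochs x %d nodes x %d samples @ %g Hz, t0 = %g s\n",
              d[1L], d[2L], d[3L], x$fs_hz, x$t0_s))
  invisible(x)
}

#' Time axis of an epoch array
#' @param x An `epoch_array`.
#' @return Numeric vector of sample times in seconds.
#' @export
epoch_times <- function(x) {
  stopifnot(inherits(x, "epoch_array"))
  x$t0_s + (seq_len(dim(x$data)[3L]) - 1L) / x$fs_hz
}

#' Plant a condition-by-emotion coupling effect with subject random intercepts
#'
#' Builds a lazy collection of per-subject, per-cell coupling specs from a
#' base spec.  Each named `effects` entry (`"condition.emotion"`) declares
#' a coupling increment for that cell, with two components: a
#' cross-subsystem component added to every core-extended pair of the base
#' membership (emulating improved cross-communication within the
#' face-processing network) and an optional global component added to all
#' off-diagonal pairs (emulating a whole-brain shift towards integration).
#' Each subject additionally receives a Gaussian random intercept (sd
#' `subject_sd`) added to all off-diagonal couplings; results are clipped
#' to `[0, 1)`.  Cells without a declared effect therefore equal the base
#' spec in expectation.
#'
#' @param design An [experiment_design()].
#' @param base_spec A [coupling_spec()]; must carry a membership including
#'   modules `"core"` and `"extended"` when `effects` is non-empty.
#' @param effects Named list of coupling increments, names of the form
#'   `"condition.emotion"`.  Each element is either a single number (a
#'   cross-subsystem increment, e.g. `list(overt.fear = 0.15)`) or a named
#'   vector with components `cross` and/or `global`, e.g.
#'   `list(overt.fear = c(cross = 0.15, global = 0.08))`.
#' @param subject_sd SD of the subject random intercept on the coupling
#'   scale.
#' @param seed Integer seed for the subject intercept draws.
#' @return An object of class `study_spec`; use [cell_spec()] to realise
#'   the coupling spec of one subject x condition x emotion cell.
#' @export
plant_effect <- function(design, base_spec, effects = list(),
                         subject_sd = 0, seed = 1L) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(base_spec, "coupling_spec"), subject_sd >= 0)
  effects <- normalize_effects(effects)
  if (length(effects)) {
    cells <- as.vector(outer(design$conditions, design$emotions, paste, sep = "."))
    bad <- setdiff(names(effects), cells)
    if (length(bad)) {
      stop("unknown effect cell(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    if (is.null(base_spec$membership) ||
        !all(c("core", "extended") %in% base_spec$membership)) {
      stop("effects target core-extended pairs: base_spec needs a membership ",
           "containing modules 'core' and 'extended'", call. = FALSE)
    }
    cross <- outer(base_spec$membership == "core",
                   base_spec$membership == "extended", "&")
    cross <- cross | t(cross)
    off <- row(cross) != col(cross)
    mx_cross <- max(base_spec$target_plv[cross])
    mx_off <- max(base_spec$target_plv[off])
    for (e in effects) {
      if (mx_cross + e[["cross"]] + e[["global"]] >= 1 ||
          mx_off + e[["global"]] >= 1) {
        stop("effect increment pushes a target coupling to 1 or beyond",
             call. = FALSE)
      }
    }
  }
  intercepts <- with_local_seed(seed,
                                stats::rnorm(design$n_subjects, 0, subject_sd))
  structure(
    list(design = design, base_spec = base_spec, effects = effects,
         subject_sd = subject_sd, subject_intercepts = intercepts,
         seed = as.integer(seed)),
    class = "study_spec"
  )
}

# canonical form: named list of c(cross = ., global = .)
normalize_effects <- function(effects) {
  if (!length(effects)) return(list())
  if (is.null(names(effects)) || any(!nzchar(names(effects)))) {
    stop("effects must be a named list (\"condition.emotion\")", call. = FALSE)
  }
  lapply(effects, function(e) {
    if (length(e) == 1L && is.null(names(e))) {
      c(cross = as.numeric(e), global = 0)
    } else {
      ok <- names(e) %in% c("cross", "global")
      if (!all(ok)) {
        stop("effect components must be named 'cross' and/or 'global'",
             call. = FALSE)
      }
      c(cross = if ("cross" %in% names(e)) as.numeric(e[["cross"]]) else 0,
        global = if ("global" %in% names(e)) as.numeric(e[["global"]]) else 0)
    }
  })
}

#' Realise the coupling spec of one design cell
#'
#' @param study A `study_spec` from [plant_effect()].
#' @param subject Subject index in `1:n_subjects`.
#' @param condition,emotion Cell labels.
#' @return A [coupling_spec()] with the subject intercept and any declared
#'   cell effect applied (couplings clipped to `[0, 1)`).
#' @export
cell_spec <- function(study, subject, condition, emotion) {
  stopifnot(inherits(study, "study_spec"))
  d <- study$design
  stopifnot(subject >= 1, subject <= d$n_subjects,
            condition %in% d$conditions, emotion %in% d$emotions)
  base <- study$base_spec
  target <- base$target_plv
  off <- row(target) != col(target)
  target[off] <- target[off] + study$subject_intercepts[subject]
  key <- paste(condition, emotion, sep = ".")
  if (key %in% names(study$effects)) {
    e <- study$effects[[key]]
    cross <- outer(base$membership == "core",
                   base$membership == "extended", "&")
    cross <- cross | t(cross)
    target[cross] <- target[cross] + e[["cross"]]
    target[off] <- target[off] + e[["global"]]
  }
  target[off] <- pmin(pmax(target[off], 0), 1 - 1e-9)
  coupling_spec(target, carrier_freq_hz = base$carrier_freq_hz,
                amplitude = base$amplitude, noise_sd = base$noise_sd,
                membership = base$membership, labels = base$labels)
}
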