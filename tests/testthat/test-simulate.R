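test_that("concentration calibration inverts the Bessel ratio", {
  expect_identical(plv_to_kappa(0), 0)
  for (r in c(0.1, 0.5, 0.9, 0.999)) {
    k <- plv_to_kappa(r)
    expect_lte(abs(kappa_to_plv(k) - r), 1e-6)
  }
  # Monte-Carlo oracle: mean resultant length of von Mises draws
  set.seed(101)
  for (r in c(0.5, 0.9)) {
    draws <- alphanet:::rvonmises(50000, plv_to_kappa(r))
    expect_lt(abs(Mod(mean(exp(1i * draws))) - r), 0.02)
  }
  expect_error(plv_to_kappa(1), "diverges")
  expect_error(plv_to_kappa(1.2), "diverges")
})

test_that("generation is deterministic given the seed, through serialization", {
  spec <- plant_communities(rep(c("a", "b"), each = 3), 0.7, 0.2)
  e1 <- generate_epochs(spec, 5, seed = 7)
  e2 <- generate_epochs(spec, 5, seed = 7)
  expect_identical(serialize(e1, NULL), serialize(e2, NULL))
  e3 <- generate_epochs(spec, 5, seed = 8)
  expect_false(identical(e1$data, e3$data))
  p1 <- simulate_plv_matrix(spec, 50, seed = 3)
  p2 <- simulate_plv_matrix(spec, 50, seed = 3)
  expect_identical(p1, p2)
})

test_that("perfect coupling yields PLV one and zero coupling stays near zero", {
  t1 <- matrix(1, 4, 4)
  spec <- coupling_spec(t1, noise_sd = 0)
  p <- simulate_plv_matrix(spec, 100, seed = 1)
  expect_true(all(abs(p[upper.tri(p)] - 1) <= 0.01))
  # full signal route on noiseless locked oscillators
  ep <- generate_epochs(spec, 30, seed = 2)
  pm <- plv_matrix(instantaneous_phase(ep))
  expect_true(all(pm[upper.tri(pm)] > 0.99))

  t0 <- diag(4)
  diag(t0) <- 1
  p0 <- simulate_plv_matrix(coupling_spec(t0 + 0, labels = letters[1:4]), 500, seed = 1)
  expect_lt(mean(p0[upper.tri(p0)]), 0.1)
})

test_that("a 0.6 coupling target is recovered within sampling error", {
  target <- matrix(0.6, 5, 5)
  diag(target) <- 1
  spec <- coupling_spec(target)
  est <- vapply(1:20, function(s) {
    p <- simulate_plv_matrix(spec, 200, seed = s)
    mean(p[upper.tri(p)])
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.6), 0.05)
})

test_that("the noiseless carrier has unit amplitude and the stated epoch grid", {
  spec <- coupling_spec(diag(3) * 0 + diag(3), noise_sd = 0, amplitude = 1)
  ep <- generate_epochs(spec, 4, seed = 1)
  expect_equal(dim(ep$data), c(4, 3, 333))
  expect_lte(max(abs(ep$data)), 1 + 1e-12)
  expect_gte(max(abs(ep$data)), 0.99)
  tt <- epoch_times(ep)
  expect_equal(tt[1], -0.5)
  expect_lte(tt[length(tt)], 0.8)
})

test_that("the dominant spectral peak sits at the carrier frequency", {
  target <- matrix(0.5, 3, 3)
  diag(target) <- 1
  spec <- coupling_spec(target, carrier_freq_hz = 10, noise_sd = 0.4)
  ep <- generate_epochs(spec, 10, seed = 9)
  x <- ep$data[1, 1, ]
  n <- length(x)
  pw <- Mod(fft(x - mean(x)))^2
  freqs <- (seq_len(n) - 1) * ep$fs_hz / n
  half <- freqs > 0 & freqs <= ep$fs_hz / 2
  peak <- freqs[half][which.max(pw[half])]
  expect_lt(abs(peak - 10), 1)
})

test_that("plant_communities builds the block target and rejects flat structure", {
  memb <- rep(c("m1", "m2"), each = 3)
  spec <- plant_communities(memb, 0.8, 0.1)
  tg <- spec$target_plv
  same <- outer(memb, memb, "==")
  expect_true(all(tg[same & upper.tri(tg)] == 0.8))
  expect_true(all(tg[!same] == 0.1))
  expect_identical(sum(tg[same & upper.tri(tg)] == 0.8), 6L)
  expect_error(plant_communities(memb, 0.5, 0.5), "unidentifiable")

  # 148-node atlas-based membership: block means equal the requested levels
  atlas <- destrieux_face_systems()
  spec148 <- plant_communities(atlas$system, 0.7, 0.2, labels = atlas$parcel_label)
  tg <- spec148$target_plv
  core <- atlas$system == "core"
  ext <- atlas$system == "extended"
  w <- tg[core, core]
  expect_equal(mean(w[upper.tri(w)]), 0.7)
  expect_equal(mean(tg[core, ext]), 0.2)
})

test_that("plant_effect applies increments and intercepts on the coupling scale", {
  design <- experiment_design(n_subjects = 3, trials_per_cell = 10)
  memb <- rep(c("core", "extended", "other"), times = c(3, 3, 2))
  base <- plant_communities(memb, 0.5, 0.15)

  null_study <- plant_effect(design, base, effects = list(), subject_sd = 0)
  sp <- cell_spec(null_study, 1, "overt", "fear")
  expect_equal(sp$target_plv, base$target_plv)

  study <- plant_effect(design, base, effects = list(overt.fear = 0.2),
                        subject_sd = 0)
  sp <- cell_spec(study, 2, "overt", "fear")
  cross <- outer(memb == "core", memb == "extended") |
    outer(memb == "extended", memb == "core")
  expect_equal(mean(sp$target_plv[cross]) - mean(base$target_plv[cross]), 0.2)
  other <- cell_spec(study, 2, "covert", "fear")
  expect_equal(other$target_plv, base$target_plv)

  expect_error(plant_effect(design, base, effects = list(overt.fear = 0.9)),
               "pushes a target coupling")
  expect_error(plant_effect(design, base, effects = list(overt.bored = 0.1)),
               "unknown effect cell")
})

test_that("epoch arrays survive the TSV + sidecar round trip", {
  spec <- plant_communities(rep(c("a", "b"), each = 2), 0.6, 0.2)
  ep <- generate_epochs(spec, 3, seed = 4)
  prefix <- file.path(tempdir(), "ep_roundtrip")
  write_epochs(ep, prefix)
  back <- read_epochs(prefix)
  expect_equal(back$data, ep$data, tolerance = 1e-10)
  expect_equal(back$fs_hz, ep$fs_hz)
  expect_equal(back$t0_s, ep$t0_s)
  expect_identical(back$labels, ep$labels)
})
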