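#' Default study configuration
#'
#' One list holding every stage parameter, with defaults matching the
#' analysis conventions throughout the package: 20% proportional
#' threshold, 8-12 Hz alpha band, -0.5 to 0.8 s epochs at 256 Hz, 100 uV
#' peak-to-peak rejection.  The default problem size (10 subjects, 20
#' nodes, 40 epochs per cell) is the scaled-down study used for the
#' package's simulation experiments; pass `n_subjects = 52`,
#' `n_nodes = 148`, `epochs_per_cell = 100` for the full-scale design.
#'
#' @param n_subjects,epochs_per_cell Design size.
#' @param module_sizes Named integer vector of module sizes; must include
#'   `core` and `extended` (plus optionally `other`); defines both the
#'   planted community structure and the face-network subsystems.
#' @param within_plv,between_plv Planted block coupling.
#' @param effects Named coupling increments (see [plant_effect()]).
#' @param subject_sd Subject random-intercept SD on the coupling scale.
#' @param carrier_freq_hz,amplitude,noise_sd Signal parameters.
#' @param fs_hz,tmin_s,tmax_s Epoch axis.
#' @param band_hz Alpha band edges for the signal route.
#' @param p2p_uv Peak-to-peak artifact threshold.
#' @param density Proportional threshold density.
#' @param gamma,n_restarts Modularity parameters.
#' @param route `"phase"` (fast phase-level PLV) or `"signal"` (full
#'   time-domain synthesis, analytic phase and [plv_matrix()]).
#' @param metrics Which graph metrics to compute.
#' @param seed Master seed.
#' @return A named list of class `study_config`.
#' @export
study_config <- function(n_subjects = 10, epochs_per_cell = 40,
                         module_sizes = c(core = 6, extended = 7, other = 7),
                         within_plv = 0.45, between_plv = 0.2,
                         effects = list(), subject_sd = 0.05,
                         carrier_freq_hz = 10, amplitude = 1, noise_sd = 1,
                         fs_hz = 256, tmin_s = -0.5, tmax_s = 0.8,
                         band_hz = c(8, 12), p2p_uv = 100,
                         density = 0.2, gamma = 1, n_restarts = 20,
                         route = c("phase", "signal"),
                         metrics = c("modularity", "global_efficiency",
                                     "routing_efficiency"),
                         seed = 1L) {
  stopifnot(all(c("core", "extended") %in% names(module_sizes)))
  route <- match.arg(route)
  cfg <- mget(names(formals(study_config)))
  structure(cfg, class = "study_config")
}

config_membership <- function(config) {
  rep(names(config$module_sizes), times = config$module_sizes)
}

config_study <- function(config) {
  memb <- config_membership(config)
  base <- plant_communities(memb, config$within_plv, config$between_plv,
                            carrier_freq_hz = config$carrier_freq_hz,
                            amplitude = config$amplitude,
                            noise_sd = config$noise_sd)
  design <- experiment_design(n_subjects = config$n_subjects,
                              trials_per_cell = config$epochs_per_cell,
                              seed = config$seed)
  plant_effect(design, base, effects = config$effects,
               subject_sd = config$subject_sd,
               seed = derive_seed(config$seed, 1L))
}

#' Simulate one study and compute its graph-metric table
#'
#' For every subject x condition x emotion cell, realises the cell's
#' coupling spec, obtains a PLV connectivity matrix (phase-level by
#' default, or the full signal route with analytic-phase extraction),
#' applies the proportional threshold and computes the requested metrics.
#'
#' @param config A [study_config()].
#' @return A long metric table (see [metric_table()]) with one row per
#'   subject x condition x emotion x metric.
#' @export
simulate_study_metrics <- function(config) {
  stopifnot(inherits(config, "study_config"))
  study <- config_study(config)
  d <- study$design
  memb <- config_membership(config)
  labels <- study$base_spec$labels
  sets <- list(core = labels[memb == "core"],
               extended = labels[memb == "extended"])
  rows <- list()
  cell_idx <- 0L
  for (s in seq_len(d$n_subjects)) {
    for (cond in d$conditions) {
      for (emo in d$emotions) {
        cell_idx <- cell_idx + 1L
        spec <- cell_spec(study, s, cond, emo)
        cseed <- derive_seed(config$seed, s, cell_idx)
        p <- if (config$route == "phase") {
          simulate_plv_matrix(spec, d$trials_per_cell, seed = cseed)
        } else {
          ep <- generate_epochs(spec, d$trials_per_cell, seed = cseed,
                                fs_hz = config$fs_hz, tmin_s = config$tmin_s,
                                tmax_s = config$tmax_s)
          ep <- bandpass(ep, config$band_hz[1L], config$band_hz[2L])
          plv_matrix(instantaneous_phase(ep))
        }
        g <- proportional_threshold(p, density = config$density)
        vals <- c()
        if ("global_efficiency" %in% config$metrics) {
          vals["global_efficiency"] <- global_efficiency(g)
        }
        if ("routing_efficiency" %in% config$metrics) {
          vals["routing_efficiency"] <- routing_efficiency(routing_matrix(g), sets)
        }
        if ("modularity" %in% config$metrics) {
          vals["modularity"] <- graph_modularity(g, gamma = config$gamma,
                                                 n_restarts = config$n_restarts,
                                                 seed = cseed)$q
        }
        rows[[length(rows) + 1L]] <-
          data.frame(subject = sprintf("s%02d", s), condition = cond,
                     emotion = emo, metric = names(vals),
                     value = unname(vals))
      }
    }
  }
  out <- do.call(rbind, rows)
  metric_table(out$subject, out$condition, out$emotion, out$metric, out$value)
}

#' Mixed-model inference for every metric in a table
#'
#' @param table A metric table.
#' @return List with data frames `f_tests` and `contrasts` (each with a
#'   `metric` column) and the underlying `fits`.
#' @export
analyze_metrics <- function(table) {
  metrics <- unique(table$metric)
  fts <- list(); cts <- list(); fits <- list()
  for (m in metrics) {
    fit <- fit_lmm(table, m)
    ft <- f_tests(fit); ft$metric <- m
    ct <- pairwise_contrasts(fit); ct$metric <- m
    fts[[m]] <- ft; cts[[m]] <- ct; fits[[m]] <- fit
  }
  list(f_tests = do.call(rbind, c(fts, make.row.names = FALSE)),
       contrasts = do.call(rbind, c(cts, make.row.names = FALSE)),
       fits = fits)
}

#' Run the full study pipeline and write its outputs
#'
#' Simulation, connectivity, graph metrics and statistics from one
#' configuration, with a JSON run manifest.  Re-running with the same
#' configuration reproduces all numeric outputs exactly.
#'
#' @param config A [study_config()].
#' @param out_dir Output directory (created if needed).
#' @param write_matrices Also write per-cell connectivity matrices for the
#'   first subject (TSV; illustration only, default `FALSE`).
#' @return Invisibly, a list with `metrics`, `f_tests`, `contrasts` and
#'   the paths written.
#' @export
run_study <- function(config = study_config(), out_dir, write_matrices = FALSE) {
  stopifnot(inherits(config, "study_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- simulate_study_metrics(config)
  res <- analyze_metrics(tab)
  paths <- c(metrics = file.path(out_dir, "metric_table.csv"),
             f_tests = file.path(out_dir, "f_tests.csv"),
             contrasts = file.path(out_dir, "contrasts.csv"),
             manifest = file.path(out_dir, "manifest.json"))
  utils::write.csv(tab, paths["metrics"], row.names = FALSE)
  utils::write.csv(res$f_tests, paths["f_tests"], row.names = FALSE)
  utils::write.csv(res$contrasts, paths["contrasts"], row.names = FALSE)
  cfg <- unclass(config)
  cfg$effects <- as.list(unlist(cfg$effects))
  manifest <- list(
    package = "alphanet",
    package_version = as.character(utils::packageVersion("alphanet")),
    r_version = R.version.string,
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = config$seed,
    config = cfg,
    config_hash = config_hash(config),
    fdr_family = "12 within-condition emotion contrasts per metric, BH"
  )
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (write_matrices) {
    study <- config_study(config)
    cell_idx <- 0L
    for (cond in study$design$conditions) {
      for (emo in study$design$emotions) {
        cell_idx <- cell_idx + 1L
        p <- simulate_plv_matrix(cell_spec(study, 1L, cond, emo),
                                 study$design$trials_per_cell,
                                 seed = derive_seed(config$seed, 1L, cell_idx))
        write_matrix_tsv(p, file.path(out_dir,
                                      sprintf("plv_s01_%s_%s.tsv", cond, emo)))
      }
    }
  }
  invisible(list(metrics = tab, f_tests = res$f_tests,
                 contrasts = res$contrasts, paths = paths))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$effects <- as.list(unlist(cfg$effects))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Type-I-error simulation for the interaction term
#'
#' Repeatedly simulates the null study (no planted condition x emotion
#' effect), runs the graph-metric and mixed-model stages and records the
#' interaction-term p-value per metric.
#'
#' @param config A null [study_config()] (its `effects` must be empty).
#' @param n_reps Number of replicates.
#' @param alpha Nominal level (default 0.05).
#' @param metrics Metrics to track (default global and routing
#'   efficiency; modularity is excluded from the default replicate loop
#'   for speed).
#' @param seed Master seed for the replicate stream.
#' @return List with `rejection_rate` (named per metric), `p_values`
#'   (replicates x metrics matrix), `n_reps` and `alpha`.
#' @export
type1_error_sim <- function(config = study_config(), n_reps = 500,
                            alpha = 0.05,
                            metrics = c("global_efficiency",
                                        "routing_efficiency"),
                            seed = 1L) {
  stopifnot(length(config$effects) == 0L)
  config$metrics <- metrics
  pm <- matrix(NA_real_, n_reps, length(metrics),
               dimnames = list(NULL, metrics))
  for (r in seq_len(n_reps)) {
    config$seed <- derive_seed(seed, r)
    tab <- simulate_study_metrics(config)
    for (m in metrics) {
      pm[r, m] <- tryCatch({
        ft <- f_tests(fit_lmm(tab, m))
        ft$p[ft$term == "condition:emotion"]
      }, error = function(e) NA_real_)   # rare degenerate fits are dropped
    }
  }
  list(rejection_rate = colMeans(pm < alpha, na.rm = TRUE), p_values = pm,
       n_failed = colSums(is.na(pm)), n_reps = n_reps, alpha = alpha)
}

#' Power and directional-pattern simulation for a planted interaction
#'
#' Replicates the study with a planted coupling effect (by default +0.15
#' on core-extended pairs in the overt-fear and overt-sad cells), and
#' records per metric (a) the interaction-term rejection rate, (b) how
#' often the within-overt contrasts reproduce the negative-emotions >
#' happy/neutral direction (all four oriented contrast estimates
#' positive), and (c) how often that direction is also significant after
#' BH adjustment.
#'
#' @param config A [study_config()]; defaults to the reference planted
#'   effect of [planted_study_effect()].
#' @inheritParams type1_error_sim
#' @param negative,positive Emotion labels defining the oriented contrast
#'   family.
#' @return List with `power`, `directional_rate` (named per metric),
#'   `both_directional_rate`, `p_values` and the per-replicate contrast
#'   results.
#' @export
power_sim <- function(config = study_config(effects = planted_study_effect()),
                      n_reps = 100, alpha = 0.05,
                      metrics = c("global_efficiency", "routing_efficiency"),
                      negative = c("fear", "sad"),
                      positive = c("happy", "neutral"),
                      seed = 1L) {
  stopifnot(length(config$effects) > 0L)
  config$metrics <- metrics
  pm <- matrix(NA_real_, n_reps, length(metrics),
               dimnames = list(NULL, metrics))
  dir_ok <- sig_ok <- matrix(NA, n_reps, length(metrics),
                             dimnames = list(NULL, metrics))
  for (r in seq_len(n_reps)) {
    config$seed <- derive_seed(seed, r)
    tab <- simulate_study_metrics(config)
    for (m in metrics) {
      res <- tryCatch({
        fit <- fit_lmm(tab, m)
        ft <- f_tests(fit)
        ct <- pairwise_contrasts(fit)
        or <- oriented_contrasts(ct, condition = "overt",
                                 negative = negative, positive = positive)
        list(p = ft$p[ft$term == "condition:emotion"],
             dir = all(or$estimate > 0),
             sig = all(or$estimate > 0 & or$p_adj < alpha))
      }, error = function(e) list(p = NA_real_, dir = NA, sig = NA))
      pm[r, m] <- res$p
      dir_ok[r, m] <- res$dir
      sig_ok[r, m] <- res$sig
    }
  }
  list(power = colMeans(pm < alpha, na.rm = TRUE),
       directional_rate = colMeans(dir_ok, na.rm = TRUE),
       significant_directional_rate = colMeans(sig_ok, na.rm = TRUE),
       both_directional_rate = mean(apply(dir_ok, 1L, all), na.rm = TRUE),
       p_values = pm, directional = dir_ok,
       n_failed = colSums(is.na(pm)), n_reps = n_reps, alpha = alpha)
}

#' The package's reference planted effect for power studies
#'
#' The documented effect used by [power_sim()] and the acceptance
#' experiments, emulating the full condition-by-emotion pattern of
#' integration changes: under overt attention the two negative
#' expressions (fear, sad), and under covert attention only neutral
#' faces, receive a core-extended coupling increment of `cross` (driving
#' routing efficiency) together with a whole-brain increment of `global`
#' (driving global efficiency).
#'
#' @param cross Cross-subsystem coupling increment (default 0.15).
#' @param global Whole-brain coupling increment (default 0.13).
#' @return A named effects list for [plant_effect()] / [study_config()].
#' @export
planted_study_effect <- function(cross = 0.15, global = 0.13) {
  eff <- c(cross = cross, global = global)
  list(overt.fear = eff, overt.sad = eff, covert.neutral = eff)
}

#' Orient pairwise contrasts as negative-emotion minus positive-emotion
#'
#' Extracts, within one condition, the contrasts pairing each `negative`
#' emotion with each `positive` emotion, flipping signs where necessary so
#' a positive estimate always means negative-emotion > positive-emotion.
#'
#' @param contrasts Output of [pairwise_contrasts()].
#' @param condition Condition level to restrict to.
#' @param negative,positive Emotion label sets.
#' @return Data frame with `contrast`, `estimate`, `t`, `p`, `p_adj`.
#' @export
oriented_contrasts <- function(contrasts, condition = "overt",
                               negative = c("fear", "sad"),
                               positive = c("happy", "neutral")) {
  cc <- contrasts[contrasts$condition == condition, , drop = FALSE]
  out <- list()
  for (ne in negative) {
    for (po in positive) {
      fwd <- cc$contrast == paste(ne, "-", po)
      rev <- cc$contrast == paste(po, "-", ne)
      if (any(fwd)) {
        row <- cc[fwd, , drop = FALSE]
      } else if (any(rev)) {
        row <- cc[rev, , drop = FALSE]
        row$estimate <- -row$estimate
        row$t <- -row$t
      } else {
        stop("contrast ", ne, " vs ", po, " not found", call. = FALSE)
      }
      out[[paste(ne, po, sep = "_vs_")]] <-
        data.frame(contrast = paste(ne, "-", po), estimate = row$estimate,
                   t = row$t, p = row$p, p_adj = row$p_adj)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
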