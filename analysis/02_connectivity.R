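#!/usr/bin/env Rscript
# Stage 2: alpha-band PLV connectivity for one demo subject.
# Full signal route: synthesis -> 8-12 Hz zero-phase band-pass -> analytic
# phase -> cross-trial PLV matrix, one matrix per condition x emotion cell.

suppressPackageStartupMessages(library(alphanet))
dir.create("results", showWarnings = FALSE)
seed <- 1L

cfg <- study_config(effects = planted_study_effect(), seed = seed)
study <- alphanet:::config_study(cfg)
rows <- list()
idx <- 0L
for (cond in study$design$conditions) {
  for (emo in study$design$emotions) {
    idx <- idx + 1L
    spec <- cell_spec(study, 1, cond, emo)
    ep <- generate_epochs(spec, cfg$epochs_per_cell,
                          seed = alphanet:::derive_seed(seed, 1L, idx))
    ep <- bandpass(ep, cfg$band_hz[1], cfg$band_hz[2])
    p <- plv_matrix(instantaneous_phase(ep))
    write_matrix_tsv(p, sprintf("results/plv_s01_%s_%s.tsv", cond, emo))
    ut <- p[upper.tri(p)]
    rows[[idx]] <- data.frame(condition = cond, emotion = emo,
                              mean_plv = mean(ut), max_plv = max(ut))
  }
}
summ <- do.call(rbind, rows)
write.csv(summ, "results/connectivity_summary.csv", row.names = FALSE)
cat("Mean alpha-band PLV per cell (subject 1):\n")
print(summ, row.names = FALSE, digits = 3)
cat("Cells carrying the planted integration effect (overt fear/sad,",
    "covert neutral) show the elevated means.\n")
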