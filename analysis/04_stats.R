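#!/usr/bin/env Rscript
# Stage 4: mixed-model inference.
# For each metric: REML fit of value ~ condition * emotion + (1 | subject),
# Satterthwaite F tests, and BH-corrected pairwise emotion contrasts
# within each condition.

suppressPackageStartupMessages(library(alphanet))
seed <- 1L
tab <- read.csv("results/metric_table.csv")
res <- analyze_metrics(tab)
write.csv(res$f_tests, "results/f_tests.csv", row.names = FALSE)
write.csv(res$contrasts, "results/contrasts.csv", row.names = FALSE)

cat("F tests (Satterthwaite df):\n")
print(res$f_tests, row.names = FALSE, digits = 3)

for (m in c("global_efficiency", "routing_efficiency")) {
  cat("\nOriented within-overt contrasts,", m, "(negative - positive):\n")
  or <- oriented_contrasts(res$contrasts[res$contrasts$metric == m, ])
  print(or, row.names = FALSE, digits = 3)
}
cat("\nA positive estimate means fear/sad exceeded happy/neutral under\n",
    "overt attention, the planted direction.\n")
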