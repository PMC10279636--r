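#' Assemble a long-format metric table
#'
#' @param subject,condition,emotion,metric,value Equal-length vectors.
#' @return A data.frame with factor-coded design columns, one row per
#'   subject x condition x emotion x metric observation.
#' @export
metric_table <- function(subject, condition, emotion, metric, value) {
  df <- data.frame(subject = factor(subject), condition = factor(condition),
                   emotion = factor(emotion), metric = as.character(metric),
                   value = as.numeric(value))
  dup <- duplicated(df[c("subject", "condition", "emotion", "metric")])
  if (any(dup)) stop("duplicate design cells in metric table", call. = FALSE)
  df
}

#' Fit the study's linear mixed-effects model to one metric
#'
#' REML fit of `value ~ condition * emotion + (1 | subject)`: fixed
#' effects for condition, emotion and their interaction, and a random
#' intercept per subject to absorb the repeated-measures dependence.
#'
#' @param table A metric table (see [metric_table()]); extra metrics are
#'   filtered out.
#' @param metric Name of the metric to model (may be omitted when the
#'   table holds a single metric).
#' @return A `lmerModLmerTest` fit.
#' @export
fit_lmm <- function(table, metric = NULL) {
  stopifnot(is.data.frame(table),
            all(c("subject", "condition", "emotion", "value") %in% names(table)))
  if (!is.null(metric)) {
    stopifnot("metric" %in% names(table))
    table <- table[table$metric == metric, , drop = FALSE]
    if (!nrow(table)) stop("no rows for metric '", metric, "'", call. = FALSE)
  }
  table <- droplevels(table)
  if (nlevels(factor(table$subject)) < 2L) {
    stop("need at least two subjects", call. = FALSE)
  }
  if (nlevels(factor(table$condition)) < 2L ||
      nlevels(factor(table$emotion)) < 2L) {
    stop("both factors need at least two levels", call. = FALSE)
  }
  ctrl <- lme4::lmerControl(
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))
  fit <- tryCatch(
    suppressMessages(
      lmerTest::lmer(value ~ condition * emotion + (1 | subject),
                     data = table, REML = TRUE, control = ctrl)),
    error = function(e) stop("mixed-model fit failed: ", conditionMessage(e),
                             call. = FALSE)
  )
  fit
}

#' Satterthwaite F tests for the fixed-effect terms
#'
#' Type III F tests with Satterthwaite denominator degrees of freedom, one
#' row per fixed-effect term (condition, emotion, interaction).
#'
#' @param fit A fit from [fit_lmm()].
#' @return Data frame with columns `term`, `f`, `df1`, `df2`, `p`.
#' @export
f_tests <- function(fit) {
  stopifnot(inherits(fit, "lmerModLmerTest"))
  a <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
  data.frame(term = rownames(a), f = a[["F value"]],
             df1 = a[["NumDF"]], df2 = a[["DenDF"]],
             p = a[["Pr(>F)"]], row.names = NULL)
}

#' Pairwise emotion contrasts within each condition
#'
#' Contrasts of estimated marginal means between every emotion pair,
#' separately within each condition level (6 pairs x 2 conditions for the
#' default design), with Satterthwaite degrees of freedom.  Raw p-values
#' are adjusted together across the whole family with [bh_adjust()].
#'
#' @param fit A fit from [fit_lmm()].
#' @return Data frame with columns `condition`, `contrast`, `estimate`,
#'   `se`, `df`, `t`, `p`, `p_adj`.
#' @export
pairwise_contrasts <- function(fit) {
  stopifnot(inherits(fit, "lmerModLmerTest"))
  emm <- emmeans::emmeans(fit, ~ emotion | condition,
                          lmer.df = "satterthwaite")
  prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "none"))
  out <- data.frame(condition = prs$condition,
                    contrast = as.character(prs$contrast),
                    estimate = prs$estimate, se = prs$SE, df = prs$df,
                    t = prs$t.ratio, p = prs$p.value)
  out$p_adj <- bh_adjust(out$p)
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment `p_(i) * m / i` with cumulative-minimum enforcement
#' from the largest rank down; output order matches input order.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}
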