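#' Analytic sensitivity and specificity under the Gaussian score model
#'
#' When de novo scores are Gaussian given the true class, the sensitivity
#' and specificity at threshold `c` are available in closed form:
#' `w1 = P(score > c | de novo) = 1 - pnorm((c - dn_mean) / sqrt(dn_var))`
#' and `w2 = P(score <= c | inherited) = pnorm((c - inh_mean) /
#' sqrt(inh_var))`. Under the default model (means 0.6 and 0.2, variance
#' 0.1), `c = 0.7` gives `(w1, w2) = (0.376, 0.943)` to three decimals.
#'
#' @param c score threshold (vectorized).
#' @param model a [score_model()].
#' @return a `data.frame` with columns `threshold_c`, `w1`, `w2`.
#' @export
analytic_w1_w2 <- function(c, model = score_model()) {
  data.frame(
    threshold_c = c,
    w1 = 1 - stats::pnorm((c - model$dn_mean) / sqrt(model$dn_var)),
    w2 = stats::pnorm((c - model$inh_mean) / sqrt(model$inh_var))
  )
}

#' Simulation study configuration
#'
#' @param thresholds score thresholds to study.
#' @param n_reps replicate datasets per threshold (default 100).
#' @param score_model a [score_model()].
#' @param dn_fraction_risk de novo fraction of case variants in risk genes
#'   (default 0.603, the fraction observed in family-based data for genes
#'   with q-value < 0.05).
#' @param dn_fraction_nonrisk same for non-risk genes (default 0.026).
#' @param dn_fraction_null de novo fraction used for every gene in the null
#'   study, independent of risk status (default 0.026, sibling-like).
#' @param pi1 prior risk-gene proportion (default 0.06).
#' @param q_cut FDR cutoff (default 0.05).
#' @param seed base integer seed; replicate r at threshold index t uses seed
#'   `seed + 1000 * t + r`.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(thresholds = c(0.3, 0.5, 0.7, 0.9),
                              n_reps = 100,
                              score_model = tadard::score_model(),
                              dn_fraction_risk = 0.603,
                              dn_fraction_nonrisk = 0.026,
                              dn_fraction_null = 0.026,
                              pi1 = 0.06, q_cut = 0.05, seed = 1L) {
  assert_fraction(thresholds, "thresholds")
  assert_fraction(c(dn_fraction_risk, dn_fraction_nonrisk, dn_fraction_null),
                  "dn fractions")
  structure(list(thresholds = thresholds, n_reps = n_reps,
                 score_model = score_model,
                 dn_fraction_risk = dn_fraction_risk,
                 dn_fraction_nonrisk = dn_fraction_nonrisk,
                 dn_fraction_null = dn_fraction_null,
                 pi1 = pi1, q_cut = q_cut, seed = as.integer(seed)),
            class = "simulation_config")
}

# Shared machinery: given per-gene de novo fractions, simulate inheritance
# labels and Gaussian scores for every case variant, classify at c, and
# return per-gene (x_d, x_h) aligned with `genes`.
simulate_gene_counts <- function(genes, dn_fraction, cfg, c, seed) {
  n_var <- genes$case_variant_count
  if (any(is.na(n_var))) stop_tadard("`case_variant_count` required for simulation")
  n_dn <- pmax(0, round_half_up(dn_fraction * n_var))
  n_inh <- n_var - n_dn
  labels <- rep(rep(c("de_novo", "inherited"), nrow(genes)),
                times = as.vector(rbind(n_dn, n_inh)))
  gene_of <- rep(rep(genes$gene_id, 2L)[rep(seq_len(nrow(genes)), each = 2L)],
                 times = as.vector(rbind(n_dn, n_inh)))
  scores <- draw_scores(labels, cfg$score_model, seed = seed)
  called_dn <- classify_scores(scores, c) == "likely_de_novo"
  gi <- factor(gene_of, levels = genes$gene_id)
  data.frame(
    gene_id = genes$gene_id,
    x_d = as.integer(tapply(called_dn, gi, sum, default = 0L)),
    x_h = as.integer(tapply(!called_dn, gi, sum, default = 0L)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

rd_selection <- function(counts, genes, cfg, c) {
  perf <- analytic_w1_w2(c, cfg$score_model)
  rd <- rd_bayes_factor(counts, perf$w1, perf$w2,
                        rd_priors("point", p1 = cfg$dn_fraction_risk,
                                  p0 = cfg$dn_fraction_nonrisk))
  select_genes(rd, genes, pi1 = cfg$pi1, q_cut = cfg$q_cut)
}

family_only_selection <- function(genes, cfg) {
  rd1 <- data.frame(gene_id = genes$gene_id, bf_rd = 1)
  select_genes(rd1, genes, pi1 = cfg$pi1, q_cut = cfg$q_cut)
}

#' One power-simulation replicate
#'
#' Simulates case variants for every gene: the number of truly de novo
#' variants is the de novo fraction (risk or non-risk, by `risk_label`)
#' times the gene's case variant count, rounded half away from zero and
#' bounded below by zero; the rest are inherited. Gaussian scores are drawn,
#' classified at threshold `c`, converted to Random Draw Bayes factors using
#' the analytic (w1, w2), floored and combined with the family Bayes
#' factors, and genes with q-value below the cutoff are counted.
#'
#' @param genes gene `data.frame` with `case_variant_count`, `risk_label`,
#'   `family_bf`.
#' @param cfg a [simulation_config()].
#' @param c score threshold.
#' @param seed integer seed for this replicate.
#' @return number of discoveries (genes with `q_value < q_cut`).
#' @export
simulate_power_rep <- function(genes, cfg, c, seed) {
  frac <- ifelse(!is.na(genes$risk_label) & genes$risk_label,
                 cfg$dn_fraction_risk, cfg$dn_fraction_nonrisk)
  counts <- simulate_gene_counts(genes, frac, cfg, c, seed)
  sum(rd_selection(counts, genes, cfg, c)$selected_fdr)
}

#' Power study: mean discoveries per threshold
#'
#' Repeats [simulate_power_rep()] `n_reps` times per threshold and reports
#' the mean number of discoveries, alongside the family-only baseline (the
#' deterministic number of genes discovered from family Bayes factors
#' alone).
#'
#' @param genes gene `data.frame` (see [simulate_power_rep()]).
#' @param cfg a [simulation_config()].
#' @return a list: `report` (`data.frame` of `threshold_c`, `w1`, `w2`,
#'   `mean_discoveries`) and `family_only_discoveries`.
#' @export
run_power_study <- function(genes, cfg = simulation_config()) {
  baseline <- sum(family_only_selection(genes, cfg)$selected_fdr)
  rows <- lapply(seq_along(cfg$thresholds), function(t) {
    c <- cfg$thresholds[t]
    disc <- vapply(seq_len(cfg$n_reps), function(r) {
      simulate_power_rep(genes, cfg, c, seed = cfg$seed + 1000L * t + r)
    }, numeric(1))
    perf <- analytic_w1_w2(c, cfg$score_model)
    data.frame(threshold_c = c, w1 = perf$w1, w2 = perf$w2,
               mean_discoveries = mean(disc))
  })
  list(report = do.call(rbind, rows), family_only_discoveries = baseline)
}

#' One null-simulation replicate
#'
#' Simulates case data carrying no association signal: every gene, risk or
#' not, receives the same null de novo fraction, so the Random Draw Bayes
#' factors are pure noise. These are combined with the (signal-bearing)
#' family Bayes factors, genes are selected under both the FDR and the
#' Bonferroni rule, and false selections — the per-family error rate (PFER)
#' — are counted against the benchmark-positive set.
#'
#' @param genes gene `data.frame`.
#' @param cfg a [simulation_config()].
#' @param c score threshold.
#' @param seed integer seed.
#' @param benchmark_positive character vector of benchmark-positive gene ids
#'   (defaults to the true risk genes).
#' @param force_rd_one if `TRUE`, Random Draw Bayes factors are forced to 1,
#'   recovering the family-only analysis exactly.
#' @return a one-row `data.frame`: `pfer_bonferroni`, `pfer_qvalue`,
#'   `n_selected_fdr`, `n_selected_bonferroni`.
#' @export
simulate_null_rep <- function(genes, cfg, c, seed,
                              benchmark_positive = genes$gene_id[
                                !is.na(genes$risk_label) & genes$risk_label],
                              force_rd_one = FALSE) {
  res <- if (force_rd_one) {
    family_only_selection(genes, cfg)
  } else {
    counts <- simulate_gene_counts(genes, cfg$dn_fraction_null, cfg, c, seed)
    rd_selection(counts, genes, cfg, c)
  }
  sel_fdr <- res$gene_id[res$selected_fdr]
  sel_bon <- res$gene_id[res$selected_bonferroni]
  data.frame(
    pfer_bonferroni = count_false_selections(sel_bon, benchmark_positive),
    pfer_qvalue = count_false_selections(sel_fdr, benchmark_positive),
    n_selected_fdr = length(sel_fdr),
    n_selected_bonferroni = length(sel_bon)
  )
}

#' Null study: mean PFER per threshold
#'
#' Repeats [simulate_null_rep()] `n_reps` times per threshold and reports
#' mean per-family error rates under both selection rules, alongside the
#' family-only benchmark PFERs.
#'
#' @param genes gene `data.frame`.
#' @param cfg a [simulation_config()].
#' @param benchmark_positive benchmark-positive gene ids (default: the true
#'   risk genes).
#' @return a list: `report` (`data.frame` of `threshold_c`, `w1`, `w2`,
#'   `mean_pfer_bonferroni`, `mean_pfer_qvalue`) and `family_only`
#'   (one-row `data.frame` of the benchmark PFERs).
#' @export
run_null_study <- function(genes, cfg = simulation_config(),
                           benchmark_positive = genes$gene_id[
                             !is.na(genes$risk_label) & genes$risk_label]) {
  family_only <- simulate_null_rep(genes, cfg, c = 0, seed = cfg$seed,
                                   benchmark_positive = benchmark_positive,
                                   force_rd_one = TRUE)
  rows <- lapply(seq_along(cfg$thresholds), function(t) {
    c <- cfg$thresholds[t]
    reps <- do.call(rbind, lapply(seq_len(cfg$n_reps), function(r) {
      simulate_null_rep(genes, cfg, c, seed = cfg$seed + 1000L * t + r,
                        benchmark_positive = benchmark_positive)
    }))
    perf <- analytic_w1_w2(c, cfg$score_model)
    data.frame(threshold_c = c, w1 = perf$w1, w2 = perf$w2,
               mean_pfer_bonferroni = mean(reps$pfer_bonferroni),
               mean_pfer_qvalue = mean(reps$pfer_qvalue))
  })
  list(report = do.call(rbind, rows), family_only = family_only)
}
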