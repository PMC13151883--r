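#' Combine Random Draw and family-based Bayes factors
#'
#' Each Bayes factor is floored at 1 before multiplication, so that weak
#' evidence from one data source never down-weights strong evidence from the
#' other: `max(1, bf_rd) * max(1, bf_family)`.
#'
#' @param bf_rd,bf_family positive Bayes factors (vectorized).
#' @return combined Bayes factor, always >= 1.
#' @export
combine_bfs <- function(bf_rd, bf_family) {
  if (any(bf_rd <= 0, na.rm = TRUE) || any(bf_family <= 0, na.rm = TRUE)) {
    stop_tadard("Bayes factors must be positive")
  }
  pmax(1, bf_rd) * pmax(1, bf_family)
}

#' Bayesian FDR q-values from Bayes factors
#'
#' With prior risk-gene proportion `pi1`, the posterior probability that a
#' gene is null is `(1 - pi1) / ((1 - pi1) + pi1 * BF)`. Genes are ranked by
#' Bayes factor (descending; ties broken stably by input position) and the
#' q-value at rank k is the mean posterior null probability of the top k
#' genes — the Bayesian FDR incurred by selecting them. Tied Bayes factors
#' share the q-value of the last tied rank.
#'
#' @param bfs positive Bayes factors, one per gene.
#' @param pi1 prior proportion of risk genes, in (0, 1); default 0.06.
#' @return a list with `posterior_null` and `q_value`, both aligned with the
#'   input order.
#' @export
bayesian_fdr <- function(bfs, pi1 = 0.06) {
  if (length(bfs) == 0) stop_tadard("`bfs` must be nonempty")
  if (pi1 <= 0 || pi1 >= 1) stop_tadard("`pi1` must lie in (0, 1)")
  if (any(bfs <= 0)) stop_tadard("Bayes factors must be positive")
  post_null <- (1 - pi1) / ((1 - pi1) + pi1 * bfs)
  ord <- order(-bfs)  # stable: ties keep input order
  q_sorted <- cumsum(post_null[ord]) / seq_along(ord)
  # tied BFs share the q-value of the last tied rank
  bf_sorted <- bfs[ord]
  grp <- cumsum(!duplicated(bf_sorted))
  q_sorted <- stats::ave(q_sorted, grp, FUN = max)
  q <- numeric(length(bfs))
  q[ord] <- q_sorted
  list(posterior_null = post_null, q_value = q)
}

#' Convert q-values to p-values by inverting the step-up map
#'
#' The Bonferroni rule needs per-gene p-values, while the Bayesian ranking
#' yields q-values. The step-up (Benjamini–Hochberg) map from p-values to
#' q-values is `q_(k) = min_{j >= k} p_(j) m / j`; its inverse used here is
#' `p_(k) = q_(k) k / m` on the Bayes-factor ranking, with monotonicity
#' enforced and values capped at 1. This conversion is isolated so it can be
#' swapped for another convention.
#'
#' @param q_values q-values aligned with `bfs`.
#' @param bfs the Bayes factors defining the ranking.
#' @return p-values aligned with the input order.
#' @export
qvalue_to_pvalue <- function(q_values, bfs) {
  if (length(q_values) != length(bfs)) {
    stop_tadard("`q_values` and `bfs` must have equal length")
  }
  m <- length(bfs)
  ord <- order(-bfs)
  p_sorted <- q_values[ord] * seq_len(m) / m
  p_sorted <- pmin(1, cummax(p_sorted))
  p <- numeric(m)
  p[ord] <- p_sorted
  p
}

#' Assemble per-gene results and apply selection rules
#'
#' Builds the final gene-level table: floored combined Bayes factor,
#' posterior null probability, q-value, p-value (via [qvalue_to_pvalue()])
#' and the two selection flags — `selected_fdr` for `q_value < q_cut` and
#' `selected_bonferroni` for `p_value < bonferroni_alpha / n_genes`.
#'
#' @param rd `data.frame` from [rd_bayes_factor()] (needs `gene_id`,
#'   `bf_rd`).
#' @param genes gene `data.frame` with `gene_id` and `family_bf` (missing
#'   family BFs are treated as 1, i.e. no family evidence).
#' @param pi1 prior proportion of risk genes.
#' @param q_cut FDR cutoff (default 0.05).
#' @param bonferroni_alpha family-wise alpha (default 0.05).
#' @return a `data.frame` with columns `gene_id`, `bf_rd`, `bf_family`,
#'   `bf_final`, `posterior_null`, `q_value`, `p_value`, `selected_fdr`,
#'   `selected_bonferroni`, sorted by decreasing `bf_final` (ties by
#'   `gene_id` for reproducibility).
#' @export
select_genes <- function(rd, genes, pi1 = 0.06, q_cut = 0.05,
                         bonferroni_alpha = 0.05) {
  idx <- match(rd$gene_id, genes$gene_id)
  if (any(is.na(idx))) {
    stop_tadard("gene '%s' absent from the gene table",
                rd$gene_id[which(is.na(idx))[1]])
  }
  bf_family <- genes$family_bf[idx]
  bf_family[is.na(bf_family)] <- 1
  out <- data.frame(
    gene_id = rd$gene_id,
    bf_rd = rd$bf_rd,
    bf_family = bf_family,
    bf_final = combine_bfs(rd$bf_rd, bf_family),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$bf_final, out$gene_id), , drop = FALSE]
  fdr <- bayesian_fdr(out$bf_final, pi1)
  out$posterior_null <- fdr$posterior_null
  out$q_value <- fdr$q_value
  out$p_value <- qvalue_to_pvalue(out$q_value, out$bf_final)
  out$selected_fdr <- out$q_value < q_cut
  out$selected_bonferroni <- out$p_value < bonferroni_alpha / nrow(out)
  rownames(out) <- NULL
  out
}

#' Count false selections against a benchmark-positive set
#'
#' The per-family error rate (PFER) of a selection is the number of selected
#' genes outside the benchmark-positive set (in simulations, the known risk
#' genes).
#'
#' @param selected character vector of selected gene ids.
#' @param benchmark_positive character vector of benchmark-positive gene ids.
#' @return the number of selected genes not in the benchmark set.
#' @export
count_false_selections <- function(selected, benchmark_positive) {
  length(setdiff(unique(selected), benchmark_positive))
}
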