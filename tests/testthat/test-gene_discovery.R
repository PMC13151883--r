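test_that("Bayes factor combination floors each factor at 1", {
  expect_equal(combine_bfs(0.5, 10), 10)
  expect_equal(combine_bfs(1, 1), 1)
  expect_equal(combine_bfs(2, 3), 6)
  expect_error(combine_bfs(0, 2), "positive")
  # flooring dominance
  expect_true(all(combine_bfs(c(2, 5), c(3, 0.1)) >=
                    pmax(c(2, 5), c(3, 0.1), 1)))
})

test_that("Bayesian FDR q-values match the cumulative-mean oracle", {
  # all BF = 1 at pi1 = 0.06: posterior null and q are 0.94 everywhere
  flat <- bayesian_fdr(rep(1, 7), pi1 = 0.06)
  expect_equal(flat$posterior_null, rep(0.94, 7))
  expect_equal(flat$q_value, rep(0.94, 7))

  # a single overwhelming gene drives its q toward 0
  one <- bayesian_fdr(c(1, 1e12, 1), pi1 = 0.06)
  expect_lt(one$q_value[2], 1e-9)

  # worked 5-gene case and random vectors against the oracle
  exact <- bayesian_fdr(c(100, 50, 2, 1, 1), pi1 = 0.06)
  want <- oracle_bayesian_fdr(c(100, 50, 2, 1, 1), 0.06)
  expect_equal(exact$q_value, want$q_value, tolerance = 1e-12)

  withr::with_seed(21, {
    for (i in 1:20) {
      bfs <- exp(rnorm(50, 0, 3))
      if (i %% 3 == 0) bfs[1:10] <- bfs[11:20]  # force ties
      got <- bayesian_fdr(bfs, pi1 = 0.06)
      want <- oracle_bayesian_fdr(bfs, 0.06)
      expect_equal(got$q_value, want$q_value, tolerance = 1e-12)
      expect_equal(got$posterior_null, want$posterior_null, tolerance = 1e-14)
      # ranked by BF descending, q-values never decrease
      expect_true(all(diff(got$q_value[order(-bfs)]) >= -1e-14))
    }
  })
  expect_error(bayesian_fdr(numeric(0), 0.06), "nonempty")
  expect_error(bayesian_fdr(c(1, 2), 1.5), "pi1")
})

test_that("selection rules apply the q cutoff and the inverted-step-up Bonferroni", {
  genes <- data.frame(gene_id = c("a", "b", "c"), mu = 1e-6,
                      family_bf = c(500, 80, 2))
  rd <- data.frame(gene_id = c("a", "b", "c"), bf_rd = 1)
  res <- select_genes(rd, genes, pi1 = 0.06, q_cut = 0.05)
  expect_equal(res$gene_id, c("a", "b", "c"))  # sorted by bf_final
  expect_equal(res$selected_fdr, res$q_value < 0.05)
  # p-values: inverse step-up on the ranked list, monotone, capped at 1
  expect_equal(res$p_value, pmin(1, cummax(res$q_value * seq_len(3) / 3)))

  # nothing selected when every gene is flat
  flat_genes <- data.frame(gene_id = letters[1:4], mu = 1e-6, family_bf = 1)
  flat_rd <- data.frame(gene_id = letters[1:4], bf_rd = 1)
  flat <- select_genes(flat_rd, flat_genes)
  expect_false(any(flat$selected_fdr))
  expect_false(any(flat$selected_bonferroni))

  # Bonferroni is never more liberal than FDR, over random BF vectors
  withr::with_seed(22, {
    for (i in 1:20) {
      n <- 30
      g <- data.frame(gene_id = sprintf("g%02d", 1:n), mu = 1e-6,
                      family_bf = exp(rnorm(n, 1, 3)))
      r <- data.frame(gene_id = g$gene_id, bf_rd = exp(rnorm(n, 0, 2)))
      sel <- select_genes(r, g)
      expect_true(all(!sel$selected_bonferroni | sel$selected_fdr))
    }
  })
})

test_that("false-selection counts are set differences against the benchmark", {
  expect_equal(count_false_selections(c("a", "b"), c("a", "b", "c")), 0)
  expect_equal(count_false_selections(c("a", "b"), "a"), 1)
  withr::with_seed(23, {
    for (i in 1:10) {
      sel <- sample(letters, sample(0:20, 1))
      bench <- sample(letters, sample(0:20, 1))
      expect_equal(count_false_selections(sel, bench),
                   length(setdiff(sel, bench)))
    }
  })
})

test_that("Random Draw ranking is consistent with a mutation-rate de novo-count Bayes factor", {
  # fully labeled family-style data, perfect classifier (w1 = w2 = 1):
  # the Random Draw ranking should track a standard Poisson de novo-count
  # Bayes factor among genes with at least one de novo event
  genes <- generate_gene_table(300, 0.1, mean_case_variants = 4, seed = 12)
  frac <- ifelse(genes$risk_label, 0.603, 0.026)
  x_d <- pmax(0, round_half_up(frac * genes$case_variant_count))
  counts <- data.frame(gene_id = genes$gene_id, x_d = x_d,
                       x_h = genes$case_variant_count - x_d)
  rd <- rd_bayes_factor(counts, 1, 1, rd_priors("point", 0.603, 0.026))
  exposure <- 2 / mean(genes$mu) * 1e-2
  pois_log_bf <- dpois(counts$x_d, 20 * genes$mu * exposure, log = TRUE) -
    dpois(counts$x_d, genes$mu * exposure, log = TRUE)
  keep <- counts$x_d >= 1
  expect_gt(cor(rd$log_bf_rd[keep], pois_log_bf[keep], method = "spearman"), 0.9)
})
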