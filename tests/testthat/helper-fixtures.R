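# Shared fixtures, all generated in code.

fixture_genes <- function(n = 50, risk_fraction = 0.2, seed = 11, ...) {
  generate_gene_table(n, risk_fraction, seed = seed, ...)
}

# Covariate model with essentially disjoint class supports: any reasonable
# learner should separate the classes almost perfectly.
separable_model <- function() {
  covariate_model(
    de_novo = list(
      af = list(zero_prob = 1, log10_min = -6, log10_max = -5),
      loeuf = list(mean = 0.2, sd = 0.05),
      ccr = list(zero_prob = 0),
      fdr_tada_dd = list(shape1 = 1, shape2 = 9),
      obs_lof = list(lambda = 1),
      exp_lof = list(shape = 20, rate = 1)
    ),
    inherited = list(
      af = list(zero_prob = 0, log10_min = -4, log10_max = -3.1),
      loeuf = list(mean = 1.5, sd = 0.05),
      ccr = list(zero_prob = 1),
      fdr_tada_dd = list(shape1 = 9, shape2 = 1),
      obs_lof = list(lambda = 15),
      exp_lof = list(shape = 2, rate = 1)
    )
  )
}

# Small labeled cohort written to a temp file, for I/O round trips.
write_fixture_variant_table <- function(variants, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "variants.tsv")
  write_variant_table(variants, path)
  path
}

# End-to-end fixture set: labeled train/test cohorts, an unlabeled case
# cohort whose hidden truth concentrates de novo variants in risk genes, and
# a gene table with family Bayes factors. Returns the written paths.
make_pipeline_fixture <- function(dir, seed = 101) {
  genes <- generate_gene_table(120, risk_fraction = 0.1, mean_case_variants = 3,
                               seed = seed)
  model <- separable_model()
  train <- generate_family_variants(80, 1000, model, genes, seed = seed + 1)
  test <- generate_family_variants(60, 800, model, genes, seed = seed + 2)
  case <- generate_case_only_variants(400, 0.15, model, genes,
                                      seed = seed + 3)$variants
  paths <- list(
    train = file.path(dir, "train.tsv"), test = file.path(dir, "test.tsv"),
    case = file.path(dir, "case.tsv"), genes = file.path(dir, "genes.tsv")
  )
  write_variant_table(train, paths$train)
  write_variant_table(test, paths$test)
  write_variant_table(case, paths$case)
  write_gene_table(genes, paths$genes)
  paths
}

# Brute-force Random Draw Bayes factor: explicit pmf ratio, no log tricks.
oracle_rd_bf <- function(x_d, x_h, p1, p0, w1, w2) {
  q1 <- w1 * p1 + (1 - w2) * (1 - p1)
  q0 <- w1 * p0 + (1 - w2) * (1 - p0)
  (q1^x_d * (1 - q1)^x_h) / (q0^x_d * (1 - q0)^x_h)
}

# Brute-force Bayesian FDR: posterior nulls, sort by BF descending,
# cumulative mean, ties share the last tied rank, restore order.
oracle_bayesian_fdr <- function(bfs, pi1) {
  post <- (1 - pi1) / ((1 - pi1) + pi1 * bfs)
  ord <- order(-bfs)
  cm <- cumsum(post[ord]) / seq_along(ord)
  for (b in unique(bfs[ord])) {
    at <- which(bfs[ord] == b)
    cm[at] <- cm[max(at)]
  }
  q <- numeric(length(bfs))
  q[ord] <- cm
  list(posterior_null = post, q_value = q)
}
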