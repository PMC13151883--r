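#' Class-conditional covariate model for synthetic variants
#'
#' Describes, separately for de novo and inherited variants, the distribution
#' of each of the six classifier covariates. Defaults emulate the qualitative
#' separation seen in family-based proband data: de novo variants have lower
#' allele frequency, lower LOEUF, higher CCR, lower FDR_TADA_DD, lower obs_lof
#' and higher exp_lof than inherited variants. Distribution families are
#' chosen for support-correctness (AF: point mass at 0 plus log-uniform;
#' LOEUF: normal truncated to \[0, 2\]; CCR: point mass at 0 plus uniform on
#' (0, 100\]; FDR_TADA_DD: Beta; obs_lof: Poisson; exp_lof: gamma); only the
#' direction of separation is treated as fixed.
#'
#' @param de_novo,inherited named lists of per-covariate parameters; see the
#'   defaults for the expected structure.
#' @return an object of class `covariate_model`.
#' @export
covariate_model <- function(
  de_novo = list(
    af = list(zero_prob = 0.8, log10_min = -6, log10_max = -4),
    loeuf = list(mean = 0.35, sd = 0.30),
    ccr = list(zero_prob = 0.3),
    fdr_tada_dd = list(shape1 = 0.4, shape2 = 1.6),
    obs_lof = list(lambda = 3),
    exp_lof = list(shape = 6, rate = 0.25)
  ),
  inherited = list(
    af = list(zero_prob = 0.2, log10_min = -5, log10_max = -3),
    loeuf = list(mean = 1.0, sd = 0.45),
    ccr = list(zero_prob = 0.7),
    fdr_tada_dd = list(shape1 = 1.5, shape2 = 1.0),
    obs_lof = list(lambda = 12),
    exp_lof = list(shape = 6, rate = 0.6)
  )
) {
  model <- list(de_novo = de_novo, inherited = inherited)
  for (cls in names(model)) {
    miss <- setdiff(covariate_names(), names(model[[cls]]))
    if (length(miss)) {
      stop_tadard("covariate model for class '%s' lacks: %s",
                  cls, paste(miss, collapse = ", "))
    }
  }
  structure(model, class = "covariate_model")
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

draw_covariates <- function(n, params) {
  af <- ifelse(stats::runif(n) < params$af$zero_prob, 0,
               10^stats::runif(n, params$af$log10_min, params$af$log10_max))
  loeuf <- rtrunc_norm(n, params$loeuf$mean, params$loeuf$sd, 0, 2)
  ccr <- ifelse(stats::runif(n) < params$ccr$zero_prob, 0,
                stats::runif(n, 0, 100))
  data.frame(
    af = af, loeuf = loeuf, ccr = ccr,
    fdr_tada_dd = stats::rbeta(n, params$fdr_tada_dd$shape1, params$fdr_tada_dd$shape2),
    obs_lof = as.numeric(stats::rpois(n, params$obs_lof$lambda)),
    exp_lof = stats::rgamma(n, params$exp_lof$shape, params$exp_lof$rate)
  )
}

new_variant_frame <- function(ids, gene_id, cov, label) {
  n <- length(ids)
  cbind(
    data.frame(variant_id = ids, gene_id = gene_id, stringsAsFactors = FALSE),
    cov,
    data.frame(inheritance_label = rep(label, n),
               de_novo_score = rep(NA_real_, n),
               predicted_class = rep("unset", n), stringsAsFactors = FALSE)
  )
}

#' Generate a labeled family-based variant table
#'
#' Emulates a family-based cohort in which the inheritance class of every
#' offspring variant is known from parental genotypes. De novo variants are
#' assigned to genes with probability proportional to the baseline mutation
#' rate `mu`; inherited variants uniformly (or by `inherited_weights`).
#'
#' @param n_de_novo,n_inherited number of variants per class. A realistic
#'   proband carries roughly thirty times more ultra-rare inherited than
#'   de novo exonic variants, so e.g. `n_de_novo = 100, n_inherited = 3000`.
#' @param model a [covariate_model()].
#' @param genes gene `data.frame` (needs `gene_id` and `mu`).
#' @param seed integer seed; the output is deterministic given the seed.
#' @param inherited_weights optional per-gene weights for inherited variants.
#' @return a variant `data.frame` with `inheritance_label` filled in.
#' @export
generate_family_variants <- function(n_de_novo, n_inherited, model, genes,
                                     seed, inherited_weights = NULL) {
  if (nrow(genes) == 0) stop_tadard("`genes` must be nonempty")
  stopifnot(n_de_novo >= 0, n_inherited >= 0)
  with_seed(seed, {
    dn_genes <- if (n_de_novo > 0) {
      sample(genes$gene_id, n_de_novo, replace = TRUE, prob = genes$mu)
    } else character(0)
    inh_genes <- if (n_inherited > 0) {
      sample(genes$gene_id, n_inherited, replace = TRUE, prob = inherited_weights)
    } else character(0)
    dn <- new_variant_frame(
      sprintf("dn%06d", seq_len(n_de_novo)), dn_genes,
      draw_covariates(n_de_novo, model$de_novo), "de_novo")
    inh <- new_variant_frame(
      sprintf("inh%06d", seq_len(n_inherited)), inh_genes,
      draw_covariates(n_inherited, model$inherited), "inherited")
    out <- rbind(dn, inh)
    rownames(out) <- NULL
    validate_variants(out)
  })
}

#' Generate an unlabeled case-only variant table with hidden truth
#'
#' Emulates case variants whose inheritance class is hidden (no parental
#' genotypes). Exactly `round_half_up(n_variants * de_novo_fraction)` variants
#' are truly de novo; the emitted table carries `inheritance_label = unknown`
#' and the truth is returned alongside for evaluation. When `genes` carries
#' `risk_label`, de novo variants are assigned to risk genes with mutation
#' rate inflated by `gamma`, mimicking ascertainment of affected cases.
#'
#' @param n_variants total number of variants.
#' @param de_novo_fraction fraction of truly de novo variants, in \[0, 1\].
#' @param model a [covariate_model()].
#' @param genes gene `data.frame`.
#' @param seed integer seed.
#' @param gamma relative-risk multiplier applied to `mu` of risk genes when
#'   placing de novo variants (ignored if `risk_label` is absent).
#' @return a list with `variants` (labels hidden) and `hidden_labels`
#'   (character vector of the true classes, aligned with `variants`).
#' @export
generate_case_only_variants <- function(n_variants, de_novo_fraction, model,
                                        genes, seed, gamma = 20) {
  if (nrow(genes) == 0) stop_tadard("`genes` must be nonempty")
  assert_fraction(de_novo_fraction, "de_novo_fraction")
  n_dn <- as.integer(round_half_up(n_variants * de_novo_fraction))
  n_inh <- n_variants - n_dn
  dn_weight <- genes$mu
  if (!is.null(genes$risk_label) && !all(is.na(genes$risk_label))) {
    dn_weight <- genes$mu * ifelse(!is.na(genes$risk_label) & genes$risk_label,
                                   gamma, 1)
  }
  with_seed(seed, {
    dn_genes <- if (n_dn > 0) {
      sample(genes$gene_id, n_dn, replace = TRUE, prob = dn_weight)
    } else character(0)
    inh_genes <- if (n_inh > 0) {
      sample(genes$gene_id, n_inh, replace = TRUE)
    } else character(0)
    dn <- new_variant_frame(character(n_dn), dn_genes,
                            draw_covariates(n_dn, model$de_novo), "de_novo")
    inh <- new_variant_frame(character(n_inh), inh_genes,
                             draw_covariates(n_inh, model$inherited), "inherited")
    out <- rbind(dn, inh)
    if (nrow(out)) {
      perm <- sample.int(nrow(out))
      out <- out[perm, , drop = FALSE]
      out$variant_id <- sprintf("case%06d", seq_len(nrow(out)))
      rownames(out) <- NULL
    }
    truth <- out$inheritance_label
    out$inheritance_label <- rep("unknown", nrow(out))
    list(variants = validate_variants(out), hidden_labels = truth)
  })
}

#' Gaussian de novo score model
#'
#' The simulation studies model the classifier's de novo score as Gaussian
#' given the true inheritance class: mean 0.6, variance 0.1 for de novo
#' variants and mean 0.2, variance 0.1 for inherited variants. Raw draws are
#' kept unclamped; only the classification step compares them to a threshold.
#'
#' @param dn_mean,dn_var mean and variance of the de novo score distribution.
#' @param inh_mean,inh_var mean and variance for inherited variants.
#' @return an object of class `score_model`.
#' @export
score_model <- function(dn_mean = 0.6, dn_var = 0.1,
                        inh_mean = 0.2, inh_var = 0.1) {
  if (dn_var <= 0 || inh_var <= 0) stop_tadard("score variances must be positive")
  if (dn_mean <= inh_mean) {
    stop_tadard("de novo score mean must exceed the inherited mean")
  }
  structure(list(dn_mean = dn_mean, dn_var = dn_var,
                 inh_mean = inh_mean, inh_var = inh_var),
            class = "score_model")
}

#' Draw de novo scores from the Gaussian score model
#'
#' @param labels character vector of true classes (`de_novo` / `inherited`).
#' @param model a [score_model()].
#' @param seed integer seed.
#' @return numeric vector of raw (unclamped) scores, aligned with `labels`.
#' @export
draw_scores <- function(labels, model = score_model(), seed) {
  bad <- !labels %in% c("de_novo", "inherited")
  if (any(bad)) stop_tadard("unknown label '%s'", labels[which(bad)[1]])
  with_seed(seed, {
    n <- length(labels)
    dn <- labels == "de_novo"
    scores <- numeric(n)
    scores[dn] <- stats::rnorm(sum(dn), model$dn_mean, sqrt(model$dn_var))
    scores[!dn] <- stats::rnorm(sum(!dn), model$inh_mean, sqrt(model$inh_var))
    scores
  })
}

#' Generate a synthetic gene table
#'
#' Builds a genome-scale gene table with baseline mutation rates, risk
#' labels, family-based Bayes factors and case variant counts, sized so that
#' every downstream module can run without external data. Defaults: 6% of
#' genes are risk genes; mutation rates are log-normal; risk genes receive
#' much larger family BF draws than non-risk genes; case variant counts are
#' Poisson with mean `mean_case_variants`, proportional to `mu` and enriched
#' by `risk_case_multiplier` in risk genes.
#'
#' @param n_genes number of genes.
#' @param risk_fraction fraction flagged as risk genes (default 0.06, the
#'   prior proportion of risk genes used throughout).
#' @param mu_meanlog,mu_sdlog log-normal parameters of the mutation rate.
#' @param bf_risk_meanlog,bf_risk_sdlog log-normal family-BF parameters for
#'   risk genes.
#' @param bf_null_meanlog,bf_null_sdlog log-normal family-BF parameters for
#'   non-risk genes.
#' @param mean_case_variants expected case variants per gene.
#' @param risk_case_multiplier case-variant enrichment of risk genes.
#' @param seed integer seed.
#' @return a gene `data.frame` with columns `gene_id`, `mu`, `family_bf`,
#'   `risk_label`, `case_variant_count`.
#' @export
generate_gene_table <- function(n_genes, risk_fraction = 0.06,
                                mu_meanlog = log(2e-6), mu_sdlog = 1,
                                bf_risk_meanlog = log(10), bf_risk_sdlog = 2,
                                bf_null_meanlog = 0, bf_null_sdlog = 1.5,
                                mean_case_variants = 0.75,
                                risk_case_multiplier = 2,
                                seed = 1L) {
  assert_fraction(risk_fraction, "risk_fraction")
  n_risk <- as.integer(round_half_up(n_genes * risk_fraction))
  with_seed(seed, {
    mu <- stats::rlnorm(n_genes, mu_meanlog, mu_sdlog)
    risk <- rep(FALSE, n_genes)
    if (n_risk > 0) risk[sample.int(n_genes, n_risk)] <- TRUE
    family_bf <- ifelse(
      risk,
      stats::rlnorm(n_genes, bf_risk_meanlog, bf_risk_sdlog),
      stats::rlnorm(n_genes, bf_null_meanlog, bf_null_sdlog)
    )
    lambda <- mu / mean(mu) * mean_case_variants *
      ifelse(risk, risk_case_multiplier, 1)
    data.frame(
      gene_id = sprintf("g%05d", seq_len(n_genes)),
      mu = mu,
      family_bf = family_bf,
      risk_label = risk,
      case_variant_count = as.numeric(stats::rpois(n_genes, lambda)),
      stringsAsFactors = FALSE
    )
  })
}
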