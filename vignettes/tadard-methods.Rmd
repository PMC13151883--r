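---
title: "Methods: inferring de novo status and the Random Draw model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring de novo status and the Random Draw model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadard)
```

## The inference problem

In family-based sequencing designs the de novo or inherited status of an
offspring variant is read directly off the parental genotypes. In case-only
cohorts it is hidden, yet it carries most of the gene-level association
signal for developmental disorders: de novo protein-truncating variants
(PTVs) are rare (one to two per exome) but highly enriched in risk genes,
while ultra-rare inherited PTVs are roughly thirty times more numerous and
carry far less signal. `tadard` recovers part of the hidden information in
two stages: a classifier that scores each case variant's probability of
being de novo, and a gene-level Bayes factor that uses the score-derived
calls while explicitly modeling their error rates.

## Stage 1: ClassDn

Six covariates separate the two inheritance classes: population allele
frequency (de novo variants are rarer or absent from references), the gene
constraint score LOEUF and its components obs_lof and exp_lof (constrained
genes tolerate few loss-of-function variants, so PTVs observed there are
more often de novo), the regional constraint percentile CCR, and
FDR_TADA_DD, a prior developmental-disorder association score of the gene.

Because the classes are heavily imbalanced, ClassDn uses ensembles built on
random undersampling of the majority (inherited) class:

* **RUSBoost**: AdaBoost.M1 in which each boosting round draws all minority
  records plus a weighted undersample of majority records (size =
  `sampling_ratio` × minority size), fits a shallow classification tree with
  the current boosting weights, and updates the weights on the *full*
  training set. The de novo score is the alpha-weighted mean of the trees'
  class-probability estimates. Rounds whose weighted error reaches 0.5 are
  discarded and the weight distribution is reset, which keeps the score a
  convex combination in [0, 1].
* **Underbagging**: bagging of trees each fitted on an independent balanced
  undersample; the score is the fraction of trees voting de novo.

Defaults — 100 trees of depth 3, balanced undersamples — are conventional
choices for undersampling ensembles; all are exposed as arguments. Missing
allele frequency is interpreted as absence from the reference (af = 0);
other missing covariates are imputed with training-set medians stored in the
model, so scoring never re-learns from test data. A variant is called
*likely de novo* when its score strictly exceeds the threshold `c` (ties go
to the majority class, a conservative reading of "exceeds"). Performance at
`c` is summarized by the sensitivity `w1` and specificity `w2`, estimated on
a labeled cohort disjoint from training; the train/test split is
caller-controlled.

The default threshold `c = 0.7` is deliberately conservative: at that point
specificity has essentially plateaued while sensitivity is still falling,
and the downstream Bayes factor benefits more from clean likely-de-novo
calls than from complete ones.

## Stage 2: the Random Draw model

For a gene, condition on the total number `n = x_d + x_h` of its classified
case variants and treat each as a draw from a pool mixing de novo and
inherited variants. Let `D` indicate the risk status of the gene and `p1 >
p0` the probabilities that a drawn variant is truly de novo under `D = 1`
and `D = 0`. Conditioning on the total builds in the observed negative
correlation between de novo and inherited evidence — at fixed `n`, a larger
`x_d` forces a smaller `x_h`.

The classifier's calls are noisy proxies of the truth, so the binomial
parameter is the call probability, not the truth probability:

$$q_D = w_1\,p_D + (1 - w_2)(1 - p_D).$$

The Bayes factor contrasting the scenarios is the binomial likelihood ratio
(the binomial coefficients cancel):

$$\mathrm{BF}_{RD} =
\frac{q_1^{x_d}(1-q_1)^{x_h}}{q_0^{x_d}(1-q_0)^{x_h}}.$$

Useful identities, all verified against a brute-force probability-mass
oracle in the test suite: `BF = 1` when `p1 = p0`, when `x_d = x_h = 0`, or
when `w1 + w2 = 1` (uninformative classifier); with a perfect classifier the
model reduces to the plain binomial Bayes factor in the true counts; when
`w1 + w2 > 1` the Bayes factor is strictly increasing in `x_d` at fixed
total, and when `w1 + w2 < 1` the direction flips and the package warns.

### Choosing p1 and p0

Three routes are supported, because the estimation of gene-specific prior
distributions for the de novo-draw probability is upstream of this package:

1. **Point values** (default `p1 = 0.603`, `p0 = 0.026`): the de novo
   fractions observed among family-based variants in risk and non-risk
   genes. These are the values used throughout the simulation studies.
2. **Beta priors** on `p_D`, marginalized exactly. Because `q_D` is affine
   in `p_D`, the integrand is a degree-`n` polynomial in `p`, and the
   marginal is computed by exact Beta moments for `n ≤ 60`; larger totals
   use adaptive quadrature (`stats::integrate`, relative tolerance 1e-12)
   on a max-rescaled integrand, and the perfect-classifier case uses the
   closed-form beta-binomial. The 60-count switch point keeps the explicit
   alternating-sign expansion well inside double precision.
3. **A competing-rates map from the mutation rate**: with de novo arrivals
   proportional to `mu` (non-risk) or `gamma * mu` (risk, `gamma > 1`) and
   inherited arrivals at rate `nu`, the draw probabilities are
   `p0 = mu / (mu + nu)` and `p1 = gamma mu / (gamma mu + nu)`. This
   guarantees `p1 > p0`, is continuous in `gamma` down to the `p1 = p0`
   limit, and is invariant to joint rescaling of `mu` and `nu`.

Genes with no classified variants carry no draw information and receive
`BF = 1`. Degenerate call probabilities (0 or 1) incompatible with the
observed counts yield an explicit 0 or infinite Bayes factor with a
warning rather than an error, since they can arise from legitimate corner
configurations of `(w1, w2, p)`.

## Stage 3: integration and selection

Each gene's `BF_RD` is floored at 1, multiplied by its family-based Bayes
factor (also floored), and the products are converted to Bayesian FDR
q-values: posterior null probability `(1 - π1)/((1 - π1) + π1 BF)` with
`π1 = 0.06` (the prior fraction of risk genes), ranked by Bayes factor
descending, q at rank k = mean posterior null of the top k. Ties share the
q-value of the last tied rank, and ranking ties are broken by gene id so
results are reproducible. Selection is `q < 0.05` (FDR rule) or
`p < 0.05 / m` (Bonferroni), where p-values are obtained from q-values by
inverting the step-up map, `p_(k) = q_(k) · k / m` with monotonicity
enforced. The inversion convention is not canonical; it is isolated in
`qvalue_to_pvalue()` so it can be swapped. Under this convention the
Bonferroni rule is never more liberal than the FDR rule at the same
nominal level, a property the tests check on random Bayes-factor vectors.

## What the synthetic data emulate — and what they do not

The generators reproduce the *statistical structure* the method relies on,
not the sequencing process:

* Class-conditional covariate distributions with the observed directions of
  separation (de novo: lower AF, lower LOEUF, higher CCR, lower
  FDR_TADA_DD, lower obs_lof, higher exp_lof). The parametric families
  (log-uniform AF with a point mass at zero, truncated-normal LOEUF,
  zero-inflated uniform CCR, Beta, Poisson, gamma) are support-correct
  design choices; real densities are not available in parametric form.
  Covariates are drawn independently within class, so the LOEUF ≈
  obs/exp relationship and gene-level covariate sharing across variants of
  the same gene are *not* emulated — passing tests show the pipeline's
  statistics are correct, not that real-data classifier performance is
  attained.
* The Gaussian score model: scores ~ N(0.6, 0.1) for de novo and
  N(0.2, 0.1) for inherited variants. Raw draws are kept unclamped and the
  classification step compares them to `c` directly, so the analytic
  operating points `w1 = 1 - Φ((c - 0.6)/√0.1)`, `w2 = Φ((c - 0.2)/√0.1)`
  are exact for the simulation.
* Gene tables at genome scale: 18,000 genes, 6% risk (matching `π1`),
  log-normal mutation rates (median 2e-6, log-sd 1), case variant counts
  Poisson with mean 0.75 per gene — about 13,500 case variants, the scale
  of a large case-only PTV dataset — with 2× enrichment in risk genes.
  Family Bayes factors are log-normal: log-mean log(10), log-sd 2 for risk
  genes, log-mean 0 with a deliberately heavy log-sd 1.5 tail for non-risk
  genes so that a handful of null genes sit near the FDR boundary, as a
  realistic benchmark requires. These values were fixed once as the study
  conditions; they are arguments, not tuned constants.
* Expected de novo counts use round-half-away-from-zero with a floor at
  zero (`round_half_up()`), fixing a convention the half-case otherwise
  leaves ambiguous.

## The simulation studies

**Null study** (`run_null_study()`): every gene — risk or not — receives
the same sibling-like de novo fraction (0.026), so the Random Draw Bayes
factors are pure noise; they are combined with the signal-bearing family
Bayes factors and the per-family error rate (PFER: selected genes outside
the benchmark-positive set) is averaged over 100 replicates per threshold.
In simulations the benchmark-positive set is the known risk-gene truth.
Forcing all RD Bayes factors to 1 must (and does, exactly) recover the
family-only analysis. **Power study** (`run_power_study()`): risk genes
receive de novo fraction 0.603 and non-risk 0.026, scores are drawn from
the Gaussian model, and the mean number of `q < 0.05` discoveries is
compared with the family-only baseline on paired seeds.

Replicate r at threshold index t uses seed `seed + 1000 t + r`, so studies
are reproducible and pairwise comparable across configurations. Problem
sizes (18,000 genes, 100 replicates, ~13,500 variants per replicate) are
the package's standard study conditions and run in seconds because every
replicate is vectorized across genes.

One internal consistency check mirrors validation practice: with a perfect
classifier on fully labeled family-style data, the Random Draw ranking is
compared against a standard mutation-rate-based Poisson de novo-count Bayes
factor. The rank correlation is computed among genes with at least one de
novo event: among zero-event genes both models report near-flat evidence
and their orderings are driven by nuisance quantities (mutation rate versus
inherited count), so including them measures tie noise, not disagreement.

## Numerical and design notes

* All Bayes factors are computed and stored in natural-log space and
  reported on the linear scale; counts in the thousands are exercised in
  the tests against exact log-pmf arithmetic.
* TSV writers emit 17 significant digits so that a write/read round trip
  reproduces doubles bit-identically; pipeline artifacts are therefore
  byte-identical across reruns with the same config and seed, which the
  manifest (config hash, seed, package version) makes checkable.
* `rd_priors()` accepts `p0 = p1` (a degenerate prior with Bayes factor 1);
  only `p0 > p1` is rejected. The identity `BF ≡ 1` at `p0 = p1` is part of
  the model's contract and is tested.
* Variants mapping to multiple genes or transcripts must be resolved to a
  single `gene_id` upstream; the I/O layer treats gene assignment as given.

## Known limitations

* `p1`/`p0` defaults derive from genes with prior evidence of association,
  so they inherit that ascertainment bias; the Beta-prior and
  mutation-rate routes are provided precisely because the point values are
  not settled.
* The synthetic covariate model cannot certify real-data classifier
  accuracy: operating points on real cohorts can only be estimated on the
  restricted family-based data themselves, and real classifiers at strict
  thresholds are typically far more conservative (much lower sensitivity at
  near-perfect specificity) than on clean synthetic covariates.
* `gamma` (the risk relative-rate multiplier) is a user input, not
  estimated; only PTVs are modeled — extending to missense classes would
  require per-class classifiers and priors.
* The family-based Bayes factor is consumed as an input column; the
  package does not re-derive it from trio counts.
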