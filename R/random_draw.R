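#' Misclassification-adjusted draw probability
#'
#' If a variant is truly de novo with probability `p`, and the classifier
#' calls de novo with sensitivity `w1` and calls inherited with specificity
#' `w2`, then the probability that the variant is *called* de novo is
#' `w1 * p + (1 - w2) * (1 - p)`. With a perfect classifier this reduces to
#' `p`; with `w1 + w2 = 1` the classifier is uninformative and the result is
#' `1 - w2` regardless of `p`.
#'
#' @param p true de novo-draw probability, in \[0, 1\].
#' @param w1 sensitivity in \[0, 1\].
#' @param w2 specificity in \[0, 1\].
#' @return the probability of a likely-de-novo call, in \[0, 1\].
#' @export
misclassified_param <- function(p, w1, w2) {
  assert_fraction(p, "p"); assert_fraction(w1, "w1"); assert_fraction(w2, "w2")
  w1 * p + (1 - w2) * (1 - p)
}

#' Random Draw binomial likelihood
#'
#' Probability of observing `x_d` likely-de-novo and `x_h` likely-inherited
#' variants in a gene when each of the `x_d + x_h` draws is called de novo
#' independently with probability `q`: the binomial pmf
#' `C(x_d + x_h, x_d) q^x_d (1 - q)^x_h`.
#'
#' @param x_d,x_h nonnegative counts (vectorized).
#' @param q likely-de-novo call probability, in \[0, 1\].
#' @param log if `TRUE`, return the log likelihood.
#' @return likelihood (or log likelihood), vectorized over counts.
#' @export
rd_likelihood <- function(x_d, x_h, q, log = FALSE) {
  assert_fraction(q, "q")
  stats::dbinom(x_d, x_d + x_h, q, log = log)
}

#' Priors for the de novo-draw probabilities
#'
#' The Random Draw model contrasts two scenarios for a gene: risk (`D = 1`),
#' where the probability that a drawn variant is de novo is `p1`, and
#' non-risk (`D = 0`), with probability `p0 < p1`. Either point values or
#' Beta priors (hyperparameters `a1, b1` and `a0, b0`) may be supplied.
#'
#' @param kind `"point"` or `"beta"`.
#' @param p1,p0 point de novo-draw probabilities (kind `"point"`), with
#'   `p0 <= p1` (equality gives a degenerate prior with Bayes factor 1);
#'   defaults are the de novo fractions observed in family-based data for
#'   risk and non-risk genes (0.603 and 0.026).
#' @param a1,b1,a0,b0 Beta hyperparameters (kind `"beta"`), all positive.
#' @return an object of class `rd_priors`.
#' @export
rd_priors <- function(kind = c("point", "beta"), p1 = 0.603, p0 = 0.026,
                      a1 = NULL, b1 = NULL, a0 = NULL, b0 = NULL) {
  kind <- match.arg(kind)
  if (kind == "point") {
    assert_fraction(p1, "p1"); assert_fraction(p0, "p0")
    if (p0 > p1) stop_tadard("point priors require p0 <= p1")
    structure(list(kind = "point", p1 = p1, p0 = p0), class = "rd_priors")
  } else {
    hp <- c(a1 = a1, b1 = b1, a0 = a0, b0 = b0)
    if (length(hp) != 4 || any(hp <= 0)) {
      stop_tadard("beta priors require positive a1, b1, a0, b0")
    }
    if (a1 / (a1 + b1) <= a0 / (a0 + b0)) {
      stop_tadard("beta priors require prior mean of p1 to exceed that of p0")
    }
    structure(list(kind = "beta", a1 = a1, b1 = b1, a0 = a0, b0 = b0),
              class = "rd_priors")
  }
}

#' Point priors derived from the gene mutation rate
#'
#' Competing-rates mapping from the baseline de novo mutation rate `mu` to
#' the de novo-draw probabilities: expected de novo draws are proportional to
#' `mu` under non-risk and to `gamma * mu` under risk (the relative-risk
#' multiplier `gamma > 1`), while inherited draws arrive at a per-gene rate
#' `nu`. The probability that a drawn variant is de novo is then
#' `p0 = mu / (mu + nu)` and `p1 = gamma * mu / (gamma * mu + nu)`, which
#' guarantees `p1 > p0` and is invariant to common rescaling of `mu` and
#' `nu`.
#'
#' @param gene one-row gene `data.frame` (or list) with positive `mu`.
#' @param gamma relative-risk multiplier, > 1.
#' @param nu per-gene inherited-variant rate, > 0.
#' @return an `rd_priors` object of kind `"point"`.
#' @export
priors_from_mutation_rate <- function(gene, gamma, nu) {
  mu <- gene$mu
  if (is.null(mu) || mu <= 0) stop_tadard("`mu` must be positive")
  if (nu <= 0) stop_tadard("`nu` must be positive")
  if (gamma <= 1) stop_tadard("`gamma` must exceed 1")
  rd_priors("point", p1 = gamma * mu / (gamma * mu + nu), p0 = mu / (mu + nu))
}

# log L(x_d, x_h | q) without the binomial coefficient (it cancels in the BF)
log_kernel <- function(x_d, x_h, q) {
  out <- numeric(length(x_d))
  with_d <- x_d > 0
  with_h <- x_h > 0
  out[with_d & q == 0] <- -Inf
  out[with_h & q == 1] <- -Inf
  ok_d <- with_d & q > 0
  ok_h <- with_h & q < 1
  out[ok_d] <- out[ok_d] + x_d[ok_d] * log(q)
  out[ok_h] <- out[ok_h] + x_h[ok_h] * log1p(-q)
  out
}

# Marginal likelihood kernel under a Beta(a, b) prior on p, where the call
# probability is q(p) = w1 p + (1 - w2)(1 - p) — affine in p. The integrand
# q^x_d (1 - q)^x_h is a polynomial of degree x_d + x_h in p, so the Beta
# moment expansion is exact; large totals fall back to adaptive quadrature,
# and the perfect-classifier case is the closed-form beta-binomial.
log_marginal_beta_one <- function(x_d, x_h, a, b, w1, w2) {
  if (x_d + x_h == 0) return(0)
  if (w1 == 1 && w2 == 1) {
    return(lbeta(a + x_d, b + x_h) - lbeta(a, b))
  }
  off <- 1 - w2              # q(0)
  slope <- w1 + w2 - 1       # q(1) - q(0)
  n <- x_d + x_h
  if (n <= 60) {
    j <- 0:x_d
    k <- 0:x_h
    # coefficients of (off + slope p)^x_d and (1 - off - slope p)^x_h
    cj <- choose(x_d, j) * off^(x_d - j) * slope^j
    ck <- choose(x_h, k) * (1 - off)^(x_h - k) * (-slope)^k
    # E[p^m] under Beta(a, b)
    m <- 0:n
    mom <- exp(lbeta(a + m, b) - lbeta(a, b))
    tot <- 0
    for (jj in seq_along(j)) {
      tot <- tot + cj[jj] * sum(ck * mom[j[jj] + k + 1L])
    }
    if (tot <= 0) tot <- .Machine$double.xmin
    log(tot)
  } else {
    # rescale the integrand by its maximum to keep integrate() stable
    f_log <- function(p) {
      q <- pmin(1, pmax(0, off + slope * p))
      x_d * log(q) + x_h * log1p(-q) +
        stats::dbeta(p, a, b, log = TRUE)
    }
    grid <- seq(1e-9, 1 - 1e-9, length.out = 2001)
    m <- max(f_log(grid))
    val <- stats::integrate(function(p) exp(f_log(p) - m), 0, 1,
                            rel.tol = 1e-12, abs.tol = 0)$value
    m + log(val)
  }
}

#' Marginal Random Draw likelihood under a Beta prior
#'
#' Integrates the binomial likelihood [rd_likelihood()] over a Beta(`a`, `b`)
#' prior on the true de novo-draw probability `p`, with the call probability
#' given by [misclassified_param()]: the marginal of `x_d` likely-de-novo
#' calls out of `x_d + x_h` draws. With a perfect classifier this is the
#' beta-binomial pmf. The affine map from `p` to the call probability makes
#' the integrand a polynomial in `p`, evaluated by exact Beta moments for
#' small totals and adaptive quadrature otherwise.
#'
#' @param x_d,x_h nonnegative counts (vectorized).
#' @param a,b positive Beta hyperparameters.
#' @param w1,w2 classifier sensitivity and specificity (default perfect).
#' @param log if `TRUE`, return the log marginal likelihood.
#' @return marginal likelihood, vectorized over counts.
#' @export
rd_marginal_likelihood <- function(x_d, x_h, a, b, w1 = 1, w2 = 1, log = FALSE) {
  if (a <= 0 || b <= 0) stop_tadard("Beta hyperparameters must be positive")
  assert_fraction(w1, "w1"); assert_fraction(w2, "w2")
  out <- vapply(seq_along(x_d), function(i) {
    lchoose(x_d[i] + x_h[i], x_d[i]) +
      log_marginal_beta_one(x_d[i], x_h[i], a, b, w1, w2)
  }, numeric(1))
  if (log) out else exp(out)
}

#' Random Draw Bayes factor per gene
#'
#' For each gene with `x_d` likely-de-novo and `x_h` likely-inherited calls,
#' computes the Bayes factor contrasting the risk scenario (`D = 1`, draw
#' probability `p1`) against non-risk (`D = 0`, `p0`), with the binomial
#' parameters corrected for classifier error:
#' `q1 = w1 p1 + (1 - w2)(1 - p1)` and `q0 = w1 p0 + (1 - w2)(1 - p0)`.
#' The binomial coefficients cancel and all work is done in log space, so
#' counts in the thousands are handled without overflow. Under Beta priors
#' the likelihoods are marginalized over the prior on `p`.
#'
#' Genes with `x_d = x_h = 0` carry no draw information and receive
#' `bf_rd = 1`. A classifier with `w1 + w2 < 1` is anti-informative (the
#' Bayes factor decreases in `x_d`); a warning is emitted. Degenerate call
#' probabilities (`q0` or `q1` equal to 0 or 1) incompatible with the counts
#' yield an infinite or zero Bayes factor with a warning, never an error.
#'
#' @param counts `data.frame` with `gene_id`, `x_d`, `x_h` (see
#'   [aggregate_gene_counts()]).
#' @param w1,w2 classifier sensitivity and specificity, in \[0, 1\].
#' @param priors an [rd_priors()] object.
#' @return a `data.frame`: `gene_id`, `x_d`, `x_h`, `q1`, `q0` (point kind;
#'   `NA` under Beta priors), `log_bf_rd`, `bf_rd`.
#' @export
rd_bayes_factor <- function(counts, w1, w2, priors = rd_priors()) {
  assert_fraction(w1, "w1"); assert_fraction(w2, "w2")
  if (!inherits(priors, "rd_priors")) stop_tadard("`priors` must be an rd_priors object")
  x_d <- as.numeric(counts$x_d)
  x_h <- as.numeric(counts$x_h)
  if (any(x_d < 0 | x_h < 0 | x_d != floor(x_d) | x_h != floor(x_h))) {
    stop_tadard("counts must be nonnegative integers")
  }
  if (w1 + w2 < 1) {
    warning("w1 + w2 < 1: the classifier is anti-informative and the ",
            "Random Draw Bayes factor decreases in x_d", call. = FALSE)
  }
  if (priors$kind == "point") {
    q1 <- misclassified_param(priors$p1, w1, w2)
    q0 <- misclassified_param(priors$p0, w1, w2)
    log_bf <- log_kernel(x_d, x_h, q1) - log_kernel(x_d, x_h, q0)
    # 0/0 (both scenarios impossible) has no evidence either way
    log_bf[is.nan(log_bf)] <- 0
  } else {
    q1 <- NA_real_; q0 <- NA_real_
    log_bf <- vapply(seq_along(x_d), function(i) {
      log_marginal_beta_one(x_d[i], x_h[i], priors$a1, priors$b1, w1, w2) -
        log_marginal_beta_one(x_d[i], x_h[i], priors$a0, priors$b0, w1, w2)
    }, numeric(1))
  }
  log_bf[x_d + x_h == 0] <- 0
  if (any(is.infinite(log_bf))) {
    warning("degenerate call probability: some Bayes factors are 0 or Inf",
            call. = FALSE)
  }
  data.frame(gene_id = counts$gene_id, x_d = as.integer(x_d),
             x_h = as.integer(x_h), q1 = q1, q0 = q0,
             log_bf_rd = log_bf, bf_rd = exp(log_bf),
             stringsAsFactors = FALSE)
}
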