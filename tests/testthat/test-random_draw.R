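test_that("misclassification-adjusted parameter reduces correctly at the corners", {
  expect_equal(misclassified_param(0.5, 1, 1), 0.5)
  # uninformative classifier: result is 1 - w2 regardless of p
  for (p in c(0, 0.2, 0.9)) {
    expect_equal(misclassified_param(p, 0.3, 0.7), 0.3)
  }
  expect_equal(misclassified_param(0.026, 0.376, 0.943), 0.065294)
  expect_error(misclassified_param(1.2, 0.5, 0.5), "p")
})

test_that("Random Draw likelihood is the binomial pmf", {
  expect_equal(rd_likelihood(0, 0, 0.3), 1)
  expect_equal(rd_likelihood(1, 1, 0.5), 0.5)
  expect_equal(rd_likelihood(2, 3, 0.25), choose(5, 2) * 0.25^2 * 0.75^3)
})

test_that("Random Draw Bayes factor identities hold against the brute-force oracle", {
  grid <- expand.grid(x_d = 0:20, x_h = 0:20)
  grid <- grid[grid$x_d + grid$x_h <= 20, ]
  counts <- data.frame(gene_id = sprintf("g%03d", seq_len(nrow(grid))),
                       x_d = grid$x_d, x_h = grid$x_h)

  # p1 = p0: identical scenarios, BF = 1 everywhere
  same <- rd_bayes_factor(counts, 0.8, 0.9, rd_priors("point", p1 = 0.3, p0 = 0.3))
  expect_equal(same$bf_rd, rep(1, nrow(counts)))

  # w1 + w2 = 1: classifier carries no information, BF = 1 everywhere
  flat <- rd_bayes_factor(counts, 0.3, 0.7, rd_priors("point", 0.603, 0.026))
  expect_equal(flat$bf_rd, rep(1, nrow(counts)))

  # general point case matches the explicit pmf ratio
  res <- rd_bayes_factor(counts, 0.376, 0.943, rd_priors("point", 0.603, 0.026))
  expect_equal(res$bf_rd,
               oracle_rd_bf(counts$x_d, counts$x_h, 0.603, 0.026, 0.376, 0.943),
               tolerance = 1e-12)
  expect_equal(res$bf_rd[counts$x_d == 2 & counts$x_h == 3], 7.554,
               tolerance = 1e-3)

  # perfect classifier reduces to the pure binomial Bayes factor
  pure <- rd_bayes_factor(counts, 1, 1, rd_priors("point", 0.603, 0.026))
  expect_equal(pure$bf_rd,
               dbinom(counts$x_d, counts$x_d + counts$x_h, 0.603) /
                 dbinom(counts$x_d, counts$x_d + counts$x_h, 0.026),
               tolerance = 1e-12)

  # informative regime: BF strictly increasing in x_d at fixed total
  for (n in c(1, 5, 20)) {
    sub <- res[res$x_d + res$x_h == n, ]
    sub <- sub[order(sub$x_d), ]
    expect_true(all(diff(log(sub$bf_rd)) > 0))
  }

  # anti-informative regime flips the direction and warns
  expect_warning(
    anti <- rd_bayes_factor(counts, 0.2, 0.7, rd_priors("point", 0.603, 0.026)),
    "anti-informative"
  )
  sub <- anti[anti$x_d + anti$x_h == 10, ]
  sub <- sub[order(sub$x_d), ]
  expect_true(all(diff(log(sub$bf_rd)) < 0))
})

test_that("no-variant genes carry no evidence and log-space handles huge counts", {
  counts <- data.frame(gene_id = c("a", "b"), x_d = c(0, 5000), x_h = c(0, 5000))
  res <- rd_bayes_factor(counts, 0.376, 0.943, rd_priors("point", 0.603, 0.026))
  expect_equal(res$bf_rd[1], 1)
  expect_true(is.finite(res$log_bf_rd[2]))
  # exact log-pmf arithmetic at scale
  q1 <- misclassified_param(0.603, 0.376, 0.943)
  q0 <- misclassified_param(0.026, 0.376, 0.943)
  expect_equal(res$log_bf_rd[2],
               dbinom(5000, 10000, q1, log = TRUE) -
                 dbinom(5000, 10000, q0, log = TRUE),
               tolerance = 1e-9)
  # degenerate call probability: w1 = 1, w2 = 1, p0 = 0 makes x_d impossible
  # under the null scenario
  expect_warning(
    deg <- rd_bayes_factor(data.frame(gene_id = "a", x_d = 2, x_h = 1),
                           1, 1, rd_priors("point", p1 = 0.5, p0 = 0)),
    "degenerate"
  )
  expect_equal(deg$bf_rd, Inf)
})

test_that("Beta-prior marginal likelihood agrees with independent quadrature", {
  grid <- expand.grid(x_d = 0:10, x_h = 0:10)
  cases <- list(c(a = 2, b = 5, w1 = 1, w2 = 1),
                c(a = 0.8, b = 3, w1 = 0.376, w2 = 0.943),
                c(a = 5, b = 1.5, w1 = 0.829, w2 = 0.624))
  for (cs in cases) {
    got <- rd_marginal_likelihood(grid$x_d, grid$x_h, cs["a"], cs["b"],
                                  cs["w1"], cs["w2"])
    want <- mapply(function(xd, xh) {
      stats::integrate(function(p) {
        rd_likelihood(xd, xh, misclassified_param(p, cs["w1"], cs["w2"])) *
          dbeta(p, cs["a"], cs["b"])
      }, 0, 1, rel.tol = 1e-13, abs.tol = 0)$value
    }, grid$x_d, grid$x_h)
    expect_lt(max(abs(got - want) / pmax(want, .Machine$double.xmin)), 1e-10)
  }
  # Bayes factors under Beta priors combine the two marginals
  counts <- data.frame(gene_id = "g", x_d = 3, x_h = 7)
  bf <- rd_bayes_factor(counts, 0.376, 0.943,
                        rd_priors("beta", a1 = 3, b1 = 2, a0 = 0.5, b0 = 18))
  num <- rd_marginal_likelihood(3, 7, 3, 2, 0.376, 0.943)
  den <- rd_marginal_likelihood(3, 7, 0.5, 18, 0.376, 0.943)
  expect_equal(bf$bf_rd, num / den, tolerance = 1e-10)
})

test_that("mutation-rate priors follow the competing-rates model", {
  pr <- priors_from_mutation_rate(list(mu = 1e-5), gamma = 20, nu = 3e-4)
  expect_equal(pr$p0, 1 / 31)
  expect_equal(pr$p1, 0.4)
  # continuity: gamma -> 1+ collapses p1 onto p0
  near <- priors_from_mutation_rate(list(mu = 1e-5), gamma = 1 + 1e-9, nu = 3e-4)
  expect_equal(near$p1, near$p0, tolerance = 1e-8)
  # scale invariance of the ratio
  doubled <- priors_from_mutation_rate(list(mu = 2e-5), gamma = 20, nu = 6e-4)
  expect_equal(doubled$p0, pr$p0)
  expect_equal(doubled$p1, pr$p1)
  expect_error(priors_from_mutation_rate(list(mu = 1e-5), 20, nu = 0), "nu")
  expect_error(priors_from_mutation_rate(list(mu = 1e-5), 0.5, nu = 1e-4), "gamma")
})

test_that("prior constructors reject invalid hyperparameters", {
  expect_error(rd_priors("point", p1 = 0.2, p0 = 0.5), "p0 <= p1")
  expect_error(rd_priors("beta", a1 = 1, b1 = -1, a0 = 1, b0 = 1), "positive")
  expect_error(rd_priors("beta", a1 = 1, b1 = 9, a0 = 9, b0 = 1), "prior mean")
})
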