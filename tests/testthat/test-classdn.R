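test_that("both ensembles separate disjoint-support classes nearly perfectly", {
  genes <- fixture_genes()
  model <- separable_model()
  train <- generate_family_variants(100, 1500, model, genes, seed = 1)
  test <- generate_family_variants(80, 1200, model, genes, seed = 2)
  for (alg in c("rusboost", "underbagging")) {
    fit <- classdn_train(train, alg, n_estimators = 25, seed = 3)
    scored <- classdn_score(fit, test)
    perf <- evaluate_classifier(classify_scores(scored$de_novo_score, 0.5),
                                test$inheritance_label, 0.5)
    expect_gte(perf$w1, 0.95)
    expect_gte(perf$w2, 0.95)
  }
})

test_that("training is deterministic under a fixed seed and scores are pure", {
  genes <- fixture_genes()
  train <- generate_family_variants(60, 600, covariate_model(), genes, seed = 4)
  probe <- generate_family_variants(20, 200, covariate_model(), genes, seed = 5)
  for (alg in c("rusboost", "underbagging")) {
    s1 <- classdn_score(classdn_train(train, alg, n_estimators = 15, seed = 6), probe)
    s2 <- classdn_score(classdn_train(train, alg, n_estimators = 15, seed = 6), probe)
    expect_identical(s1$de_novo_score, s2$de_novo_score)
    expect_true(all(s1$de_novo_score >= 0 & s1$de_novo_score <= 1))
    # duplicated record gets an identical score
    dup <- probe[c(1, 1), ]
    sd <- classdn_score(classdn_train(train, alg, n_estimators = 15, seed = 6), dup)
    expect_equal(sd$de_novo_score[1], sd$de_novo_score[2])
  }
  expect_error(classdn_train(train[train$inheritance_label == "inherited", ],
                             "rusboost"), "both classes")
  expect_error(classdn_train(train[0, ], "rusboost"), "empty")
  expect_error(classdn_score(structure(list(), class = "lm"), probe), "fitted")
})

test_that("label-shuffled training yields an uninformative classifier", {
  genes <- fixture_genes()
  train <- generate_family_variants(150, 1500, covariate_model(), genes, seed = 4)
  train$inheritance_label <- withr::with_seed(5, sample(train$inheritance_label))
  test <- generate_family_variants(150, 1500, covariate_model(), genes, seed = 6)
  test$inheritance_label <- withr::with_seed(7, sample(test$inheritance_label))
  fit <- classdn_train(train, "underbagging", n_estimators = 25, seed = 8)
  scored <- classdn_score(fit, test)
  perf <- evaluate_classifier(classify_scores(scored$de_novo_score, 0.5),
                              test$inheritance_label)
  expect_lt(abs(perf$w1 - (1 - perf$w2)), 0.15)
})

test_that("classification uses a strict threshold", {
  expect_equal(classify_scores(0.71, 0.7), "likely_de_novo")
  expect_equal(classify_scores(0.7, 0.7), "likely_inherited")
  expect_true(all(classify_scores(runif(20), 1.0) == "likely_inherited"))
})

test_that("evaluation tallies sensitivity and specificity, NA for empty classes", {
  truth <- c(rep("de_novo", 10), rep("inherited", 90))
  pred <- c(rep("likely_de_novo", 3), rep("likely_inherited", 7),
            rep("likely_de_novo", 9), rep("likely_inherited", 81))
  perf <- evaluate_classifier(pred, truth)
  expect_equal(perf$w1, 0.3)
  expect_equal(perf$w2, 0.9)
  expect_equal(perf$n_de_novo_eval, 10)

  all_right <- ifelse(truth == "de_novo", "likely_de_novo", "likely_inherited")
  expect_equal(evaluate_classifier(all_right, truth)$w1, 1)
  expect_equal(evaluate_classifier(all_right, truth)$w2, 1)

  no_dn <- evaluate_classifier(rep("likely_inherited", 3), rep("inherited", 3))
  expect_true(is.na(no_dn$w1))
  expect_error(evaluate_classifier("likely_de_novo", c("de_novo", "inherited")),
               "equal length")
})

test_that("threshold sweeps trade sensitivity for specificity monotonically", {
  scores <- draw_scores(rep(c("de_novo", "inherited"), c(500, 5000)),
                        score_model(), seed = 9)
  truth <- rep(c("de_novo", "inherited"), c(500, 5000))
  sweep <- perf_sweep(scores, truth, grid = seq(0, 1, by = 0.05))
  expect_true(all(diff(sweep$w1) <= 0))
  expect_true(all(diff(sweep$w2) >= 0))
  # raw scores are unclamped, so a few legitimately fall outside [0, 1];
  # at a threshold at or above the maximum score everything is inherited
  expect_gt(sweep$w2[sweep$threshold_c == 1], 0.98)
  expect_gt(sweep$w1[sweep$threshold_c == 0], 0.95)

  # same monotonicity through the model-facing interface
  genes <- fixture_genes()
  train <- generate_family_variants(60, 600, covariate_model(), genes, seed = 10)
  test <- generate_family_variants(40, 400, covariate_model(), genes, seed = 11)
  fit <- classdn_train(train, "underbagging", n_estimators = 15, seed = 12)
  ms <- threshold_sweep(fit, test, grid = seq(0.1, 0.9, by = 0.2))
  expect_true(all(diff(ms$w1) <= 0))
  expect_true(all(diff(ms$w2) >= 0))
})

test_that("imbalance-aware ensemble beats an unresampled tree on the minority class", {
  genes <- fixture_genes()
  # 30:1 imbalance with overlapping covariates
  train <- generate_family_variants(60, 1800, covariate_model(), genes, seed = 9)
  test <- generate_family_variants(200, 6000, covariate_model(), genes, seed = 10)
  fit <- classdn_train(train, "underbagging", n_estimators = 50, seed = 11)
  scored <- classdn_score(fit, test)
  ens <- evaluate_classifier(classify_scores(scored$de_novo_score, 0.5),
                             test$inheritance_label)

  x <- train[c("af", "loeuf", "ccr", "fdr_tada_dd", "obs_lof", "exp_lof")]
  x$af[is.na(x$af)] <- 0
  x$.label <- factor(train$inheritance_label, levels = c("inherited", "de_novo"))
  plain <- rpart::rpart(.label ~ ., x, method = "class",
                        control = rpart::rpart.control(maxdepth = 3, cp = 0, xval = 0))
  xt <- test[c("af", "loeuf", "ccr", "fdr_tada_dd", "obs_lof", "exp_lof")]
  xt$af[is.na(xt$af)] <- 0
  plain_scores <- predict(plain, xt, type = "prob")[, "de_novo"]
  sw <- perf_sweep(plain_scores, test$inheritance_label, seq(0.01, 0.99, by = 0.01))
  # compare at the plain-tree threshold whose specificity matches the ensemble's
  j <- which.min(abs(sw$w2 - ens$w2))
  expect_gt(ens$w1, sw$w1[j])
})
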