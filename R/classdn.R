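#' Train an imbalanced-data ensemble for de novo classification
#'
#' De novo variants are vastly outnumbered by rare inherited variants
#' (roughly 30:1 per proband), so a naive classifier neglects the minority
#' class. Two resampling ensembles over shallow classification trees are
#' provided:
#'
#' * `rusboost` — AdaBoost.M1 boosting where each round randomly
#'   undersamples the majority (inherited) class to `sampling_ratio` times
#'   the minority size before fitting the tree; boosting weights are updated
#'   on the full training set.
#' * `underbagging` — bagging of trees each fitted on an independent
#'   balanced undersample (all minority records plus a random majority
#'   undersample).
#'
#' Features are the six covariates: `af`, `loeuf`, `ccr`, `fdr_tada_dd`,
#' `obs_lof`, `exp_lof`. Missing allele frequency is treated as 0 (absence
#' from the population reference); other missing covariates are imputed with
#' training-set medians, stored in the model and re-applied at scoring time.
#'
#' @param variants labeled variant `data.frame`; `inheritance_label` must be
#'   `de_novo` or `inherited` for every row and both classes must be present.
#' @param algorithm `"rusboost"` or `"underbagging"`.
#' @param n_estimators ensemble size (default 100).
#' @param max_depth maximum depth of each tree (default 3).
#' @param sampling_ratio majority:minority size ratio after undersampling
#'   (default 1, a balanced sample).
#' @param seed integer seed; training is deterministic given the seed.
#' @return an object of class `classdn_model`.
#' @export
classdn_train <- function(variants, algorithm = c("rusboost", "underbagging"),
                          n_estimators = 100, max_depth = 3,
                          sampling_ratio = 1, seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (n_estimators < 1) stop_tadard("`n_estimators` must be >= 1")
  if (nrow(variants) == 0) stop_tadard("empty training set")
  labels <- variants$inheritance_label
  if (!all(labels %in% c("de_novo", "inherited"))) {
    stop_tadard("training labels must be 'de_novo' or 'inherited'")
  }
  if (length(unique(labels)) < 2) {
    stop_tadard("training set must contain both classes")
  }
  feats <- impute_fit(variants)
  x <- feats$data
  x$.label <- factor(labels, levels = c("inherited", "de_novo"))
  model <- with_seed(seed, {
    if (algorithm == "rusboost") {
      fit_rusboost(x, n_estimators, max_depth, sampling_ratio)
    } else {
      fit_underbagging(x, n_estimators, max_depth, sampling_ratio)
    }
  })
  structure(list(algorithm = algorithm, n_estimators = n_estimators,
                 max_depth = max_depth, sampling_ratio = sampling_ratio,
                 imputation_values = feats$medians, seed = seed,
                 fitted_state = model, version = 1L),
            class = "classdn_model")
}

impute_fit <- function(variants) {
  x <- variants[covariate_names()]
  x$af[is.na(x$af)] <- 0
  medians <- vapply(x, function(col) stats::median(col, na.rm = TRUE), numeric(1))
  medians["af"] <- 0
  list(data = impute_apply(x, medians), medians = medians)
}

impute_apply <- function(x, medians) {
  for (cov in names(x)) {
    x[[cov]][is.na(x[[cov]])] <- medians[[cov]]
  }
  x
}

tree_control <- function(max_depth) {
  rpart::rpart.control(maxdepth = max_depth, cp = 0, minsplit = 10,
                       minbucket = 5, xval = 0)
}

undersample_majority <- function(x, ratio, prob = NULL) {
  idx_min <- which(x$.label == "de_novo")
  idx_maj <- which(x$.label == "inherited")
  take <- min(length(idx_maj), max(1L, as.integer(round_half_up(length(idx_min) * ratio))))
  p <- if (is.null(prob)) NULL else prob[idx_maj]
  c(idx_min, sample(idx_maj, take, replace = FALSE, prob = p))
}

fit_rusboost <- function(x, n_estimators, max_depth, ratio) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  trees <- vector("list", n_estimators)
  alphas <- numeric(n_estimators)
  ctrl <- tree_control(max_depth)
  for (t in seq_len(n_estimators)) {
    idx <- undersample_majority(x, ratio, prob = w)
    sub <- x[idx, , drop = FALSE]
    sw <- w[idx]
    fit <- rpart::rpart(.label ~ ., data = sub, weights = sw / mean(sw),
                        method = "class", control = ctrl)
    p_dn <- stats::predict(fit, x, type = "prob")[, "de_novo"]
    miss <- (p_dn > 0.5) != (x$.label == "de_novo")
    err <- sum(w * miss)
    err <- min(max(err, 1e-10), 1 - 1e-10)
    if (err >= 0.5) {
      # uninformative round: drop it and reset the weight distribution
      alphas[t] <- 0
      w <- rep(1 / n, n)
    } else {
      alphas[t] <- log((1 - err) / err)
      w <- w * exp(alphas[t] * miss)
      w <- w / sum(w)
    }
    trees[[t]] <- fit
  }
  list(trees = trees, alphas = alphas)
}

fit_underbagging <- function(x, n_estimators, max_depth, ratio) {
  ctrl <- tree_control(max_depth)
  trees <- lapply(seq_len(n_estimators), function(t) {
    idx <- undersample_majority(x, ratio)
    rpart::rpart(.label ~ ., data = x[idx, , drop = FALSE],
                 method = "class", control = ctrl)
  })
  list(trees = trees, alphas = rep(1, n_estimators))
}

#' Score variants with a fitted ClassDn model
#'
#' Produces the de novo score — the ensemble's estimate of the likelihood
#' that a variant is de novo — in \[0, 1\] for each record. For underbagging
#' the score is the fraction of base learners voting de novo; for RUSBoost it
#' is the alpha-weighted mean of the trees' de novo class probabilities.
#'
#' @param model a fitted `classdn_model`.
#' @param variants variant `data.frame`.
#' @return `variants` with `de_novo_score` populated.
#' @export
classdn_score <- function(model, variants) {
  if (!inherits(model, "classdn_model") || is.null(model$fitted_state)) {
    stop_tadard("`model` is not a fitted classdn model")
  }
  x <- variants[covariate_names()]
  x$af[is.na(x$af)] <- 0
  x <- impute_apply(x, model$imputation_values)
  st <- model$fitted_state
  keep <- st$alphas > 0 | model$algorithm == "underbagging"
  if (!any(keep)) keep <- rep(TRUE, length(st$alphas))
  votes <- vapply(which(keep), function(t) {
    p_dn <- stats::predict(st$trees[[t]], x, type = "prob")[, "de_novo"]
    if (model$algorithm == "underbagging") as.numeric(p_dn > 0.5) else p_dn
  }, numeric(nrow(x)))
  votes <- matrix(votes, nrow = nrow(x))
  a <- if (model$algorithm == "underbagging") rep(1, sum(keep)) else st$alphas[keep]
  scores <- as.numeric(votes %*% a / sum(a))
  variants$de_novo_score <- pmin(1, pmax(0, scores))
  variants
}

#' Classify de novo scores at a threshold
#'
#' A variant is called `likely_de_novo` if and only if its score strictly
#' exceeds the threshold; scores equal to the threshold are
#' `likely_inherited`.
#'
#' @param scores numeric vector of de novo scores (raw scores permitted).
#' @param threshold_c threshold in \[0, 1\].
#' @return character vector of `likely_de_novo` / `likely_inherited`.
#' @export
classify_scores <- function(scores, threshold_c) {
  assert_fraction(threshold_c, "threshold_c")
  ifelse(scores > threshold_c, "likely_de_novo", "likely_inherited")
}

#' Sensitivity and specificity of predicted classes
#'
#' Computes `w1` (sensitivity: fraction of true de novo variants called
#' `likely_de_novo`) and `w2` (specificity: fraction of true inherited
#' variants called `likely_inherited`). A class absent from the truth leaves
#' the corresponding parameter `NA` (undefined), never 0.
#'
#' @param predicted character vector of predicted classes.
#' @param truth character vector of true classes (`de_novo` / `inherited`).
#' @param threshold_c optional threshold to record alongside the estimates.
#' @return a one-row `data.frame`: `threshold_c`, `w1`, `w2`,
#'   `n_de_novo_eval`, `n_inherited_eval`.
#' @export
evaluate_classifier <- function(predicted, truth, threshold_c = NA_real_) {
  if (length(predicted) != length(truth)) {
    stop_tadard("`predicted` and `truth` must have equal length")
  }
  dn <- truth == "de_novo"
  inh <- truth == "inherited"
  w1 <- if (any(dn)) mean(predicted[dn] == "likely_de_novo") else NA_real_
  w2 <- if (any(inh)) mean(predicted[inh] == "likely_inherited") else NA_real_
  data.frame(threshold_c = threshold_c, w1 = w1, w2 = w2,
             n_de_novo_eval = sum(dn), n_inherited_eval = sum(inh))
}

#' Sensitivity/specificity sweep over score thresholds
#'
#' @param scores numeric de novo scores.
#' @param truth true classes aligned with `scores`.
#' @param grid thresholds in \[0, 1\]; as the threshold rises, `w1` is
#'   nonincreasing and `w2` nondecreasing.
#' @return a `data.frame` with one row per threshold.
#' @export
perf_sweep <- function(scores, truth, grid = seq(0.05, 0.95, by = 0.05)) {
  assert_fraction(grid, "grid")
  do.call(rbind, lapply(grid, function(cc) {
    evaluate_classifier(classify_scores(scores, cc), truth, threshold_c = cc)
  }))
}

#' Threshold sweep for a fitted model on a labeled test set
#'
#' Scores the held-out labeled records with the model, then evaluates
#' sensitivity and specificity at each threshold. The train/test split
#' mirrors practice: train on one family-based cohort, learn (w1, w2) on a
#' disjoint one.
#'
#' @param model a fitted `classdn_model`.
#' @param variants labeled variant `data.frame`.
#' @param grid thresholds in \[0, 1\].
#' @return a `data.frame` with one row per threshold.
#' @export
threshold_sweep <- function(model, variants, grid = seq(0.05, 0.95, by = 0.05)) {
  scored <- classdn_score(model, variants)
  perf_sweep(scored$de_novo_score, variants$inheritance_label, grid)
}
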