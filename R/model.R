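# Preprocessing, feature selection, classification, and stratified nested
# cross-validation over the 72-feature patient table. The positive class is
# "PTC" throughout; decision scores are oriented so larger = more PTC-like.

CLASS_LEVELS <- c("nonPTC", "PTC")

#' Default classifier hyperparameter grids
#'
#' Representative grids for the six classifiers; every entry can be
#' overridden through [pipeline_config()]. Grid rows are enumerated with the
#' first parameter varying fastest; ties in inner-CV score are broken by that
#' enumeration order.
#'
#' @return Named list of per-classifier parameter grids.
#' @export
default_hyper_grids <- function() {
  list(
    svc = list(cost = c(0.1, 1, 10, 100), kernel = c("radial", "linear"),
               gamma = c("scale", "0.01", "0.001")),
    knn = list(k = c(3, 5, 7, 11), weights = c("uniform", "distance")),
    gnb = list(),
    dt = list(max_depth = c(3, 5, 10, 30)),
    logreg = list(C = c(0.01, 0.1, 1, 10)),
    rf = list(num_trees = c(100, 300), max_depth = c(5, 0))
  )
}

#' Pipeline configuration for nested cross-validation
#'
#' Fixes the preprocessing switches, the feature-selection method, the
#' classifier, and the fold layout. These choices are deliberately *not*
#' tuned inside the nested CV; only the classifier's hyperparameters are
#' optimized in the inner loop.
#'
#' @param quantile_transform Map each feature through its training-fold
#'   empirical CDF to a uniform target before scaling.
#' @param standard_scale Center/scale with training-fold statistics.
#' @param selector `"none"`, `"chi2"` (univariate filter) or `"sfs"`
#'   (greedy sequential forward selection).
#' @param k_features Number of features to keep (1..25 in the study design;
#'   ignored for `selector = "none"`).
#' @param classifier One of `"svc"`, `"knn"`, `"gnb"`, `"dt"`, `"logreg"`,
#'   `"rf"`.
#' @param hyper_grid Parameter grid for the classifier; defaults to the
#'   matching entry of [default_hyper_grids()]. A grid with a single row
#'   disables optimization.
#' @param outer_folds,inner_folds Stratified fold counts (5 outer / 4 inner).
#' @param seed Top-level seed; all fold and model seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(quantile_transform = TRUE, standard_scale = TRUE,
                            selector = c("none", "chi2", "sfs"),
                            k_features = 22,
                            classifier = c("svc", "knn", "gnb", "dt",
                                           "logreg", "rf"),
                            hyper_grid = NULL,
                            outer_folds = 5, inner_folds = 4, seed = 1) {
  selector <- match.arg(selector)
  classifier <- match.arg(classifier)
  if (selector != "none" && (k_features < 1 || k_features > 72)) {
    abort("k_features must be in [1, 72]")
  }
  if (is.null(hyper_grid)) hyper_grid <- default_hyper_grids()[[classifier]]
  structure(list(
    quantile_transform = quantile_transform, standard_scale = standard_scale,
    selector = selector, k_features = as.integer(k_features),
    classifier = classifier, hyper_grid = hyper_grid,
    outer_folds = as.integer(outer_folds),
    inner_folds = as.integer(inner_folds), seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Baseline configuration (hyperparameter optimization disabled)
#'
#' SVC with library-default hyperparameters (single-row grid, so the inner
#' loop degenerates to a plain fit), standard scaling on, quantile transform
#' off, no feature selection. Under the same seed its outer test folds are
#' identical to a tuned run's, so the two are directly comparable.
#'
#' @param seed Top-level seed.
#' @return A `pipeline_config`.
#' @export
baseline_config <- function(seed = 1) {
  pipeline_config(
    quantile_transform = FALSE, standard_scale = TRUE, selector = "none",
    classifier = "svc",
    hyper_grid = list(cost = 1, kernel = "radial", gamma = "scale"),
    seed = seed
  )
}

# ---------------------------------------------------------------------------
# Preprocessing

#' Fit preprocessing transforms on a training fold
#'
#' Quantile transform (empirical CDF of the training fold mapped to a uniform
#' target, at most 1000 quantiles) followed by standard scaling, each
#' individually switchable. Statistics come from the training fold only.
#'
#' @param train Numeric matrix or data frame (rows = patients).
#' @param cfg A [pipeline_config()].
#' @return A `preprocessor` object for [apply_preprocessors()].
#' @export
fit_preprocessors <- function(train, cfg) {
  X <- as.matrix(train)
  if (nrow(X) == 0) abort("training data is empty")
  qt <- NULL
  if (cfg$quantile_transform) {
    probs <- seq(0, 1, length.out = min(1000, nrow(X)))
    qt <- lapply(seq_len(ncol(X)), function(j) {
      quantile(X[, j], probs = probs, type = 7, names = FALSE)
    })
    X <- quantile_apply(X, qt, probs)
  }
  sc <- NULL
  if (cfg$standard_scale) {
    mu <- colMeans(X)
    sdv <- apply(X, 2, sd)
    sdv[sdv == 0 | is.na(sdv)] <- 1  # constant feature: center only
    sc <- list(mu = mu, sd = sdv)
  }
  structure(list(qt = qt, probs = if (is.null(qt)) NULL else probs, sc = sc,
                 cols = colnames(train)),
            class = "preprocessor")
}

quantile_apply <- function(X, qt, probs) {
  out <- X
  for (j in seq_len(ncol(X))) {
    q <- qt[[j]]
    if (max(q) == min(q)) { out[, j] <- 0.5; next }
    out[, j] <- approx(q, probs, xout = X[, j], rule = 2, ties = "ordered")$y
  }
  out
}

#' Apply fitted preprocessors
#'
#' @param prep A `preprocessor` from [fit_preprocessors()].
#' @param newdata Matrix/data frame with the training columns.
#' @return Transformed numeric matrix.
#' @export
apply_preprocessors <- function(prep, newdata) {
  X <- as.matrix(newdata)
  if (!is.null(prep$cols)) X <- X[, prep$cols, drop = FALSE]
  if (!is.null(prep$qt)) X <- quantile_apply(X, prep$qt, prep$probs)
  if (!is.null(prep$sc)) {
    X <- sweep(sweep(X, 2, prep$sc$mu, "-"), 2, prep$sc$sd, "/")
  }
  X
}

# ---------------------------------------------------------------------------
# Feature selection

#' Univariate chi-squared feature scores
#'
#' The sklearn-style statistic for non-negative features: per class, observed
#' mass is the class-wise feature sum and expected mass follows the class
#' priors; the score sums `(observed - expected)^2 / expected` over classes.
#'
#' @param X Non-negative numeric matrix.
#' @param y Binary factor of class labels.
#' @return Named numeric vector of scores.
#' @export
chi2_scores <- function(X, y) {
  X <- as.matrix(X)
  if (any(X < 0)) {
    abort(paste0("chi-squared scoring needs non-negative features; ",
                 "map them to [0, 1] first (see select_chi2)"))
  }
  y <- factor(y)
  Y <- stats::model.matrix(~ y - 1)
  observed <- t(Y) %*% X
  expected <- outer(colMeans(Y), colSums(X))
  contrib <- (observed - expected)^2 / expected
  contrib[expected == 0] <- 0
  setNames(colSums(contrib), colnames(X))
}

#' Chi-squared feature selection
#'
#' Keeps the `k` features with the largest chi-squared statistic between
#' feature and class. When `X` contains negative values (e.g. after standard
#' scaling) and `rescale = TRUE`, features are min-max mapped to \[0, 1\]
#' for scoring only.
#'
#' @param X Numeric matrix of features.
#' @param y Binary factor.
#' @param k Number of features to keep.
#' @param rescale Min-max map features to \[0, 1\] before scoring.
#' @return Character vector of `k` selected feature names (ties broken by
#'   canonical column order).
#' @export
select_chi2 <- function(X, y, k, rescale = TRUE) {
  X <- as.matrix(X)
  if (k < 1 || k > ncol(X)) abort("k out of range")
  Xs <- X
  if (rescale && any(X < 0)) {
    rng <- apply(X, 2, range)
    span <- rng[2, ] - rng[1, ]
    span[span == 0] <- 1
    Xs <- sweep(sweep(X, 2, rng[1, ], "-"), 2, span, "/")
  }
  sc <- chi2_scores(Xs, y)
  colnames(X)[order(-sc)[seq_len(k)]]  # stable order: ties keep column order
}

#' Sequential forward feature selection
#'
#' Greedy wrapper selection: starting from the empty set, repeatedly add the
#' feature that maximizes the cross-validated accuracy of the base
#' classifier; ties are broken by canonical column order. Selections are
#' nested by construction (the set at `k` extends the set at `k - 1`).
#'
#' @param X Numeric matrix (already preprocessed).
#' @param y Binary factor.
#' @param k Number of features to select.
#' @param classifier Base classifier name (default parameters).
#' @param folds Scoring fold count.
#' @param seed Seed for the scoring folds.
#' @return Character vector of `k` selected feature names, in selection
#'   order.
#' @export
select_sfs <- function(X, y, k, classifier = "svc", folds = 4, seed = 1) {
  X <- as.matrix(X)
  if (k < 1 || k > ncol(X)) abort("k out of range")
  params <- lapply(default_hyper_grids()[[classifier]], function(v) v[1])
  fold_id <- stratified_folds(y, folds, seed)
  selected <- character(0)
  remaining <- colnames(X)
  for (step in seq_len(k)) {
    scores <- vapply(remaining, function(f) {
      cv_accuracy(X[, c(selected, f), drop = FALSE], y, classifier, params,
                  fold_id, seed)
    }, numeric(1))
    best <- remaining[which.max(scores)]  # which.max: first max = canonical
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  selected
}

# ---------------------------------------------------------------------------
# Folds and classifiers

#' Stratified fold assignment
#'
#' Shuffles each class separately and deals patients to folds cyclically, so
#' every fold's class counts are within one patient of perfect proportion.
#'
#' @param y Factor of class labels.
#' @param k Number of folds.
#' @param seed Seed for the shuffle.
#' @return Integer vector of fold ids (1..k) aligned with `y`.
#' @export
stratified_folds <- function(y, k, seed) {
  y <- factor(y)
  if (min(table(y)) < k) {
    abort("each class needs at least as many members as folds; reduce folds")
  }
  fold <- integer(length(y))
  set.seed(derive_seed(seed, 101))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Fit one classifier; returns an object predict_classifier() understands.
# y must be a factor with levels CLASS_LEVELS.
fit_classifier <- function(name, params, X, y, seed = 1) {
  X <- as.matrix(X)
  y <- factor(y, levels = CLASS_LEVELS)
  if (name == "svc") {
    gamma <- params$gamma %||% "scale"
    gnum <- if (identical(gamma, "scale")) {
      v <- var(as.vector(X)); if (is.na(v) || v == 0) 1 else 1 / (ncol(X) * v)
    } else as.numeric(gamma)
    m <- e1071::svm(x = X, y = y, kernel = params$kernel %||% "radial",
                    cost = params$cost %||% 1, gamma = gnum, scale = FALSE)
    list(kind = "svc", model = m)
  } else if (name == "knn") {
    list(kind = "knn", X = X, y = y, k = params$k %||% 5,
         weights = params$weights %||% "uniform")
  } else if (name == "gnb") {
    m <- e1071::naiveBayes(x = as.data.frame(X), y = y)
    # guard zero within-class variance (constant feature in a small fold)
    m$tables <- lapply(m$tables, function(tb) {
      tb[, 2][tb[, 2] < 1e-9 | is.na(tb[, 2])] <- 1e-9
      tb
    })
    list(kind = "gnb", model = m, cols = colnames(X))
  } else if (name == "dt") {
    df <- data.frame(X, check.names = FALSE)
    df$.y <- y
    depth <- params$max_depth %||% 30
    if (depth == 0) depth <- 30
    m <- rpart::rpart(.y ~ ., data = df, method = "class",
                      control = rpart::rpart.control(maxdepth = depth,
                                                     xval = 0, cp = 0.001))
    list(kind = "dt", model = m, cols = colnames(X))
  } else if (name == "logreg") {
    C <- params$C %||% 1
    Xg <- X
    if (ncol(Xg) < 2) Xg <- cbind(Xg, `.dummy` = 0)  # glmnet needs >= 2 cols
    m <- glmnet::glmnet(Xg, y, family = "binomial", alpha = 0,
                        lambda = 1 / (C * nrow(Xg)), standardize = FALSE)
    list(kind = "logreg", model = m, p = ncol(X))
  } else if (name == "rf") {
    df <- data.frame(X, check.names = FALSE)
    df$.y <- y
    m <- ranger::ranger(
      dependent.variable.name = ".y", data = df, probability = TRUE,
      num.trees = params$num_trees %||% 300,
      max.depth = params$max_depth %||% 0,
      seed = derive_seed(seed, 77), num.threads = 1
    )
    list(kind = "rf", model = m, cols = colnames(X))
  } else {
    abort(paste0("unknown classifier: ", name))
  }
}

# Predict class + PTC-oriented decision score.
predict_classifier <- function(fit, X) {
  X <- as.matrix(X)
  if (fit$kind == "svc") {
    pr <- predict(fit$model, X, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # e1071 orients the decision value toward the first class in "A/B"
    score <- if (startsWith(colnames(dv)[1], "PTC")) dv[, 1] else -dv[, 1]
    list(class = factor(as.character(pr), levels = CLASS_LEVELS),
         score = as.numeric(score))
  } else if (fit$kind == "knn") {
    dmat <- as.matrix(pracma::distmat(X, fit$X))
    score <- apply(dmat, 1, function(dr) {
      nb <- order(dr)[seq_len(min(fit$k, length(dr)))]
      w <- if (fit$weights == "distance") 1 / pmax(dr[nb], 1e-9) else rep(1, length(nb))
      sum(w[fit$y[nb] == "PTC"]) / sum(w)
    })
    cls <- factor(ifelse(score > 0.5, "PTC", "nonPTC"), levels = CLASS_LEVELS)
    list(class = cls, score = score)
  } else if (fit$kind == "gnb") {
    nd <- as.data.frame(X)[, fit$cols, drop = FALSE]
    pr <- predict(fit$model, nd, type = "raw")
    score <- pr[, "PTC"]
    cls <- factor(ifelse(score > 0.5, "PTC", "nonPTC"), levels = CLASS_LEVELS)
    list(class = cls, score = as.numeric(score))
  } else if (fit$kind == "dt") {
    nd <- data.frame(X, check.names = FALSE)[, fit$cols, drop = FALSE]
    pr <- predict(fit$model, nd, type = "prob")
    score <- pr[, "PTC"]
    cls <- factor(ifelse(score > 0.5, "PTC", "nonPTC"), levels = CLASS_LEVELS)
    list(class = cls, score = as.numeric(score))
  } else if (fit$kind == "logreg") {
    Xg <- X
    if (fit$p < 2) Xg <- cbind(Xg, `.dummy` = 0)
    score <- as.numeric(predict(fit$model, Xg, type = "response"))
    # glmnet models P(second level) = P(PTC)
    cls <- factor(ifelse(score > 0.5, "PTC", "nonPTC"), levels = CLASS_LEVELS)
    list(class = cls, score = score)
  } else if (fit$kind == "rf") {
    nd <- data.frame(X, check.names = FALSE)[, fit$cols, drop = FALSE]
    pr <- predict(fit$model, data = nd)$predictions
    score <- pr[, "PTC"]
    cls <- factor(ifelse(score > 0.5, "PTC", "nonPTC"), levels = CLASS_LEVELS)
    list(class = cls, score = as.numeric(score))
  }
}

# Mean accuracy of `classifier(params)` over pre-assigned CV folds.
cv_accuracy <- function(X, y, classifier, params, fold_id, seed) {
  accs <- vapply(sort(unique(fold_id)), function(f) {
    tr <- fold_id != f
    fit <- fit_classifier(classifier, params, X[tr, , drop = FALSE], y[tr],
                          seed = seed)
    pred <- predict_classifier(fit, X[!tr, , drop = FALSE])
    mean(pred$class == y[!tr])
  }, numeric(1))
  mean(accs)
}

expand_grid_rows <- function(grid) {
  if (length(grid) == 0) return(list(list()))
  df <- expand.grid(grid, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

# ---------------------------------------------------------------------------
# Metrics

#' Classification metrics: accuracy, Cohen's kappa, confusion, ROC, AUC
#'
#' Kappa is `(p_o - p_e) / (1 - p_e)`; the ROC sweeps the decision score
#' (larger = more PTC-like) and the AUC is the trapezoid area under it. With
#' a single observed class, kappa and AUC are `NA`.
#'
#' @param y_true,y_pred Factors (or characters) over `nonPTC`/`PTC`.
#' @param scores Decision scores oriented toward PTC; optional.
#' @return List: `accuracy`, `kappa`, `confusion` (2x2, rows = truth),
#'   `roc_points` (tibble fpr/tpr), `auc`.
#' @export
compute_metrics <- function(y_true, y_pred, scores = NULL) {
  y_true <- factor(y_true, levels = CLASS_LEVELS)
  y_pred <- factor(y_pred, levels = CLASS_LEVELS)
  stopifnot(length(y_true) == length(y_pred))
  confusion <- table(truth = y_true, predicted = y_pred)
  accuracy <- mean(y_true == y_pred)
  n <- length(y_true)
  p_o <- accuracy
  p_e <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  kappa <- if (length(unique(y_true)) < 2 || p_e == 1) NA_real_ else {
    (p_o - p_e) / (1 - p_e)
  }
  roc <- NULL; auc <- NA_real_
  if (!is.null(scores) && length(unique(y_true)) == 2) {
    roc <- roc_curve(y_true, scores)
    auc <- trapezoid_auc(roc$fpr, roc$tpr)
  }
  list(accuracy = accuracy, kappa = kappa, confusion = confusion,
       roc_points = roc, auc = auc)
}

# ROC points over unique score thresholds (descending), PTC = positive.
roc_curve <- function(y_true, scores) {
  pos <- y_true == "PTC"
  ord <- order(-scores)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  # collapse ties: keep the last point of each distinct score
  keep <- c(diff(scores[ord]) != 0, TRUE)
  tibble::tibble(
    fpr = c(0, fp[keep] / max(1, sum(!pos))),
    tpr = c(0, tp[keep] / max(1, sum(pos)))
  )
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

#' Majority vote over per-image predictions (pessimistic ties)
#'
#' Returns the majority class of the per-image predictions for one case; an
#' exact 50-50 tie returns the class opposite to the true class, so a
#' tie never counts in the classifier's favour.
#'
#' @param predictions Character/factor vector of per-image classes.
#' @param true_class The case's true class.
#' @return Single class label (character).
#' @export
majority_vote <- function(predictions, true_class) {
  predictions <- as.character(predictions)
  true_class <- as.character(true_class)
  if (length(predictions) == 0) abort("need at least one prediction")
  n_ptc <- sum(predictions == "PTC")
  n_non <- sum(predictions == "nonPTC")
  if (n_ptc > n_non) return("PTC")
  if (n_non > n_ptc) return("nonPTC")
  setdiff(CLASS_LEVELS, true_class)[1]  # tie: the wrong class
}

# ---------------------------------------------------------------------------
# Nested cross-validation

#' Stratified nested cross-validation over the patient feature table
#'
#' Outer folds estimate generalization; inner folds tune only the
#' classifier's hyperparameters. For each outer fold the preprocessors and
#' the feature selector are fitted on the outer-training portion alone, the
#' hyper grid is scored by stratified inner CV accuracy on that portion
#' (ties broken by grid order), the winner is refitted on the full
#' outer-training portion and evaluated once on the held-out fold. The
#' preprocessing switches, selector, and classifier are fixed by `cfg`.
#'
#' @param patients Tibble from [aggregate_patients()]: `patient_id`,
#'   `class_label`, and the 72 feature columns.
#' @param cfg A [pipeline_config()].
#' @return A `nucleo_cv` object; see [tidy.nucleo_cv()], [glance.nucleo_cv()]
#'   and [autoplot.nucleo_cv()].
#' @export
nested_cv <- function(patients, cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  feats <- intersect(patient_feature_names(), names(patients))
  if (length(feats) == 0) abort("patients table has no recognized feature columns")
  if (any(!complete.cases(patients[feats]))) {
    abort("feature table contains NA; impute or drop before nested_cv")
  }
  y <- factor(patients$class_label, levels = c("nonPTC", "PTC"),
              labels = CLASS_LEVELS)
  if (any(is.na(y))) abort("class_label must be PTC/nonPTC for every patient")
  X <- as.matrix(patients[feats])
  rownames(X) <- patients$patient_id
  outer_id <- stratified_folds(y, cfg$outer_folds, cfg$seed)
  grid_rows <- expand_grid_rows(cfg$hyper_grid)
  folds <- vector("list", cfg$outer_folds)
  pooled <- list()
  for (f in seq_len(cfg$outer_folds)) {
    tr <- outer_id != f
    prep <- fit_preprocessors(X[tr, , drop = FALSE], cfg)
    Xtr <- apply_preprocessors(prep, X[tr, , drop = FALSE])
    Xte <- apply_preprocessors(prep, X[!tr, , drop = FALSE])
    sel <- colnames(Xtr)
    if (cfg$selector == "chi2") {
      # score on a non-negative view of the training fold: the quantile
      # transform output if enabled, else a min-max map (scoring only)
      Xscore <- if (cfg$quantile_transform) {
        quantile_apply(X[tr, , drop = FALSE], prep$qt, prep$probs)
      } else X[tr, , drop = FALSE]
      sel <- select_chi2(Xscore, y[tr], min(cfg$k_features, ncol(Xtr)))
    } else if (cfg$selector == "sfs") {
      sel <- select_sfs(Xtr, y[tr], min(cfg$k_features, ncol(Xtr)),
                        classifier = cfg$classifier,
                        folds = cfg$inner_folds,
                        seed = derive_seed(cfg$seed, 300 + f))
    }
    Xtr_s <- Xtr[, sel, drop = FALSE]
    Xte_s <- Xte[, sel, drop = FALSE]
    inner_seed <- derive_seed(cfg$seed, 200 + f)
    if (length(grid_rows) > 1) {
      inner_id <- stratified_folds(y[tr], cfg$inner_folds, inner_seed)
      inner_scores <- vapply(grid_rows, function(par) {
        cv_accuracy(Xtr_s, y[tr], cfg$classifier, par, inner_id, inner_seed)
      }, numeric(1))
      best <- which.max(inner_scores)  # first best = canonical grid order
      val_acc <- inner_scores[best]
    } else {
      best <- 1L
      val_acc <- NA_real_
    }
    fit <- fit_classifier(cfg$classifier, grid_rows[[best]], Xtr_s, y[tr],
                          seed = inner_seed)
    pred_tr <- predict_classifier(fit, Xtr_s)
    pred_te <- predict_classifier(fit, Xte_s)
    met <- compute_metrics(y[!tr], pred_te$class, pred_te$score)
    folds[[f]] <- list(
      fold_index = f,
      test_patient_ids = patients$patient_id[!tr],
      chosen_hyperparams = grid_rows[[best]],
      chosen_features = sel,
      validation_accuracy = val_acc,
      training_accuracy = mean(pred_tr$class == y[tr]),
      accuracy = met$accuracy, kappa = met$kappa,
      confusion = met$confusion, roc_points = met$roc_points, auc = met$auc
    )
    pooled[[f]] <- tibble::tibble(
      fold = f, patient_id = patients$patient_id[!tr],
      truth = as.character(y[!tr]),
      predicted = as.character(pred_te$class),
      score = pred_te$score
    )
  }
  pooled <- dplyr::bind_rows(pooled)
  pm <- compute_metrics(pooled$truth, pooled$predicted, pooled$score)
  aucs <- vapply(folds, function(fl) fl$auc, numeric(1))
  structure(list(
    folds = folds,
    predictions = pooled,
    pooled_accuracy = pm$accuracy,
    pooled_kappa = pm$kappa,
    pooled_confusion = pm$confusion,
    auc_mean = mean(aucs, na.rm = TRUE),
    auc_sd = sd(aucs, na.rm = TRUE),
    validation_accuracy = mean(vapply(folds, function(fl) fl$validation_accuracy,
                                      numeric(1)), na.rm = TRUE),
    training_accuracy = mean(vapply(folds, function(fl) fl$training_accuracy,
                                    numeric(1))),
    hyperparameter_optimization = length(grid_rows) > 1,
    outer_fold_count = cfg$outer_folds,
    inner_fold_count = cfg$inner_folds,
    config = cfg
  ), class = "nucleo_cv")
}

#' @export
print.nucleo_cv <- function(x, ...) {
  cat("<nucleo_cv> ", x$outer_fold_count, "-fold outer / ",
      x$inner_fold_count, "-fold inner nested CV (", x$config$classifier,
      ", selector=", x$config$selector, ")\n", sep = "")
  cat(sprintf("  pooled test accuracy %.3f, kappa %.3f, AUC %.3f +/- %.3f\n",
              x$pooled_accuracy, x$pooled_kappa, x$auc_mean, x$auc_sd))
  invisible(x)
}

#' Per-fold summary of a nested CV run
#'
#' @param x A `nucleo_cv` object.
#' @param ... Unused.
#' @return Tibble with one row per outer fold: accuracy, kappa, AUC,
#'   validation and training accuracy, chosen hyperparameters (list column),
#'   number of selected features.
#' @exportS3Method generics::tidy
tidy.nucleo_cv <- function(x, ...) {
  tibble::tibble(
    fold = vapply(x$folds, function(f) f$fold_index, integer(1)),
    n_test = vapply(x$folds, function(f) length(f$test_patient_ids), integer(1)),
    accuracy = vapply(x$folds, function(f) f$accuracy, numeric(1)),
    kappa = vapply(x$folds, function(f) f$kappa, numeric(1)),
    auc = vapply(x$folds, function(f) f$auc, numeric(1)),
    validation_accuracy = vapply(x$folds, function(f) f$validation_accuracy,
                                 numeric(1)),
    training_accuracy = vapply(x$folds, function(f) f$training_accuracy,
                               numeric(1)),
    n_features = vapply(x$folds, function(f) length(f$chosen_features),
                        integer(1)),
    hyperparams = lapply(x$folds, function(f) f$chosen_hyperparams)
  )
}

#' One-row summary of a nested CV run
#'
#' @param x A `nucleo_cv` object.
#' @param ... Unused.
#' @return One-row tibble: pooled test accuracy and kappa, mean and sd of the
#'   per-fold AUC, validation accuracy, training accuracy, and whether
#'   hyperparameter optimization was active.
#' @exportS3Method generics::glance
glance.nucleo_cv <- function(x, ...) {
  tibble::tibble(
    accuracy = x$pooled_accuracy,
    kappa = x$pooled_kappa,
    auc_mean = x$auc_mean,
    auc_sd = x$auc_sd,
    validation_accuracy = x$validation_accuracy,
    training_accuracy = x$training_accuracy,
    outer_folds = x$outer_fold_count,
    inner_folds = x$inner_fold_count,
    hyperparameter_optimization = x$hyperparameter_optimization
  )
}
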