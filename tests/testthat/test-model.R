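test_that("preprocessors: identity, scaling moments, quantile rank preservation", {
  set.seed(5)
  X <- matrix(rnorm(40 * 6, mean = 3, sd = 2), 40, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  off <- pipeline_config(quantile_transform = FALSE, standard_scale = FALSE)
  expect_equal(apply_preprocessors(fit_preprocessors(X, off), X), X)

  sc <- pipeline_config(quantile_transform = FALSE, standard_scale = TRUE)
  Xs <- apply_preprocessors(fit_preprocessors(X, sc), X)
  expect_equal(unname(colMeans(Xs)), rep(0, 6), tolerance = 1e-9)
  expect_equal(unname(apply(Xs, 2, sd)), rep(1, 6), tolerance = 1e-9)

  # constant feature: centered only, no division blow-up
  Xc <- cbind(X, const = 5)
  Xcs <- apply_preprocessors(fit_preprocessors(Xc, sc), Xc)
  expect_true(all(is.finite(Xcs)))
  expect_equal(unname(Xcs[, "const"]), rep(0, 40))

  qt <- pipeline_config(quantile_transform = TRUE, standard_scale = FALSE)
  Xq <- apply_preprocessors(fit_preprocessors(X, qt), X)
  expect_true(all(Xq >= 0 & Xq <= 1))
  for (j in 1:6) {
    expect_equal(cor(Xq[, j], X[, j], method = "spearman"), 1)
  }
})

test_that("chi-squared scoring matches the hand computation and selects top-k", {
  X <- cbind(A = c(2, 2, 0, 0), B = c(1, 1, 1, 1))
  y <- factor(c("PTC", "PTC", "nonPTC", "nonPTC"))
  sc <- chi2_scores(X, y)
  expect_equal(unname(sc), c(4, 0))  # hand: (0-2)^2/2 + (4-2)^2/2 = 4
  expect_equal(select_chi2(X, y, 1), "A")
  expect_setequal(select_chi2(X, y, 2), c("A", "B"))
  expect_error(chi2_scores(cbind(A = c(-1, 1)), factor(c("a", "b"))),
               "non-negative")

  # k = 22 on a 72-feature table returns exactly 22 names
  pat <- gaussian_patients(10, delta = 0.5, seed = 3)
  Xp <- abs(as.matrix(pat[patient_feature_names()]))
  sel <- select_chi2(Xp, factor(pat$class_label), 22)
  expect_length(sel, 22)
  expect_true(all(sel %in% patient_feature_names()))
})

test_that("sequential forward selection finds dominant features, nested sets", {
  set.seed(9)
  n <- 40
  y <- factor(rep(c("nonPTC", "PTC"), each = n / 2), levels = c("nonPTC", "PTC"))
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  X[, "f4"] <- ifelse(y == "PTC", 3, -3) + rnorm(n, 0, 0.1)  # only informative one
  expect_equal(select_sfs(X, y, 1, classifier = "svc", seed = 2), "f4")

  s4 <- select_sfs(X, y, 4, classifier = "svc", seed = 2)
  s5 <- select_sfs(X, y, 5, classifier = "svc", seed = 2)
  expect_equal(s5[1:4], s4)  # greedy nesting under identical folds/seed
  expect_length(s5, 5)
})

test_that("stratified folds balance class proportions within one patient", {
  y <- factor(c(rep("PTC", 13), rep("nonPTC", 22)))
  fold <- stratified_folds(y, 5, seed = 4)
  for (f in 1:5) {
    tab <- table(y[fold == f])
    expect_lte(abs(tab[["PTC"]] - 13 / 5), 1)
    expect_lte(abs(tab[["nonPTC"]] - 22 / 5), 1)
  }
  expect_error(stratified_folds(factor(c("PTC", rep("nonPTC", 9))), 5, 1),
               "reduce folds")
})

test_that("metrics: accuracy, kappa, confusion, and AUC against oracles", {
  y <- factor(rep(c("PTC", "nonPTC"), each = 5), levels = c("nonPTC", "PTC"))
  perfect <- compute_metrics(y, y, scores = c(rep(1, 5), rep(0, 5)))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$auc, 1)
  expect_equal(sum(perfect$confusion), 10)

  # all-one-class predictions on balanced truth: chance agreement, kappa 0
  allp <- compute_metrics(y, factor(rep("PTC", 10), levels = levels(y)))
  expect_equal(allp$kappa, 0)
  expect_equal(allp$accuracy, 0.5)

  # AUC equals the Mann-Whitney pair-counting oracle on random scores
  set.seed(77)
  yt <- factor(sample(c("PTC", "nonPTC"), 30, replace = TRUE),
               levels = c("nonPTC", "PTC"))
  sc <- rnorm(30)
  m <- compute_metrics(yt, yt, scores = sc)
  pos <- sc[yt == "PTC"]; neg <- sc[yt == "nonPTC"]
  pairs <- 0
  for (p in pos) for (q in neg) {
    pairs <- pairs + (p > q) + 0.5 * (p == q)
  }
  expect_equal(m$auc, pairs / (length(pos) * length(neg)), tolerance = 1e-12)
  # and agrees with an established ROC implementation
  expect_equal(m$auc,
               as.numeric(pROC::auc(pROC::roc(yt, sc, levels = c("nonPTC", "PTC"),
                                              direction = "<", quiet = TRUE))),
               tolerance = 1e-12)

  # single observed class: kappa and AUC undefined
  one <- compute_metrics(factor(rep("PTC", 4), levels = levels(y)),
                         factor(rep("PTC", 4), levels = levels(y)),
                         scores = 1:4)
  expect_true(is.na(one$kappa))
  expect_true(is.na(one$auc))

  # ROC is monotone non-decreasing in both axes
  expect_true(all(diff(m$roc_points$fpr) >= 0))
  expect_true(all(diff(m$roc_points$tpr) >= 0))
})

test_that("majority vote is pessimistic on exact ties", {
  expect_equal(majority_vote(c("PTC", "PTC", "nonPTC"), "nonPTC"), "PTC")
  expect_equal(majority_vote(c("PTC", "nonPTC"), "PTC"), "nonPTC")  # tie: wrong
  expect_equal(majority_vote(c("nonPTC", "PTC"), "nonPTC"), "PTC")
  expect_equal(majority_vote(rep("nonPTC", 4), "nonPTC"), "nonPTC")
})

test_that("nested CV separates well-separated classes and records its layout", {
  pat <- gaussian_patients(15, delta = 3, seed = 6)
  cfg <- pipeline_config(selector = "none", classifier = "svc", seed = 6,
                         hyper_grid = list(cost = c(0.1, 1), kernel = "linear",
                                           gamma = "0.01"))
  cv <- nested_cv(pat, cfg)
  expect_gte(cv$pooled_accuracy, 0.95)
  expect_equal(cv$outer_fold_count, 5)
  expect_equal(cv$inner_fold_count, 4)
  expect_equal(nrow(cv$predictions), nrow(pat))
  expect_true(cv$hyperparameter_optimization)

  td <- tidy(cv)
  expect_equal(nrow(td), 5)
  expect_equal(sum(td$n_test), nrow(pat))
  gl <- glance(cv)
  expect_equal(gl$accuracy, cv$pooled_accuracy)

  # determinism: identical seed, identical pooled metrics and predictions
  cv2 <- nested_cv(pat, cfg)
  expect_equal(cv$predictions, cv2$predictions)
  expect_equal(glance(cv), glance(cv2))
})

test_that("all six classifiers train and predict within the nested CV", {
  pat <- gaussian_patients(14, delta = 3, seed = 13)
  small_grids <- list(
    svc = list(cost = 1, kernel = "linear", gamma = "0.01"),
    knn = list(k = c(3, 5), weights = c("uniform", "distance")),
    gnb = list(),
    dt = list(max_depth = c(3, 10)),
    logreg = list(C = c(0.1, 1)),
    rf = list(num_trees = 100, max_depth = c(0, 5))
  )
  for (clf in names(small_grids)) {
    cfg <- pipeline_config(selector = "none", classifier = clf, seed = 3,
                           hyper_grid = small_grids[[clf]])
    cv <- nested_cv(pat, cfg)
    expect_gte(cv$pooled_accuracy, 0.8)
    expect_true(all(is.finite(cv$predictions$score)))
  }
})

test_that("baseline config disables optimization but keeps the outer splits", {
  pat <- gaussian_patients(12, delta = 1, seed = 10)
  base <- nested_cv(pat, baseline_config(seed = 42))
  tuned <- nested_cv(pat, pipeline_config(
    selector = "none", classifier = "svc", seed = 42,
    hyper_grid = list(cost = c(0.5, 2), kernel = "radial", gamma = "scale")
  ))
  expect_false(base$hyperparameter_optimization)
  expect_true(tuned$hyperparameter_optimization)
  for (f in 1:5) {
    expect_setequal(base$folds[[f]]$test_patient_ids,
                    tuned$folds[[f]]$test_patient_ids)
  }
  # grid of size 1: inner loop degenerates, no validation score
  expect_true(is.na(base$validation_accuracy))
})

test_that("fold-indicator canary cannot leak into the selection", {
  pat <- gaussian_patients(15, delta = 1.2, seed = 20)
  cfg <- pipeline_config(selector = "chi2", k_features = 10,
                         classifier = "svc", seed = 20,
                         hyper_grid = list(cost = 1, kernel = "linear",
                                           gamma = "0.01"))
  clean <- nested_cv(pat, cfg)

  # canary feature: label-valued on the patients of outer test fold 1, pure
  # noise everywhere else. A leak-free pipeline fits preprocessing/selection
  # on outer-training data only, where the canary is noise, so it gains
  # nothing; a pipeline that peeks at the full table could select it and
  # inflate fold-1 accuracy.
  y <- factor(pat$class_label, levels = c("nonPTC", "PTC"))
  fold <- stratified_folds(y, cfg$outer_folds, cfg$seed)
  set.seed(1)
  canary <- rnorm(nrow(pat))
  canary[fold == 1] <- ifelse(y[fold == 1] == "PTC", 10, -10)
  pat_canary <- pat
  pat_canary$std_nn_distance <- canary
  leaky <- nested_cv(pat_canary, cfg)
  expect_lte(leaky$pooled_accuracy, clean$pooled_accuracy + 0.1)
})
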