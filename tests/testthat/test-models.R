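test_that("compute_f1 matches hand-computed and degenerate cases", {
  y <- rep(c("a", "b", "c"), each = 4)
  expect_equal(compute_f1(y, y), 1.0)
  # disjoint predictions: no class ever correct
  yp <- rep(c("b", "c", "a"), each = 4)
  expect_equal(compute_f1(y, yp), 0.0)
  # stated confusion: A 8/10, B 5/10, C 9/10 with fixed off-diagonals
  yt <- rep(c("A", "B", "C"), each = 10)
  yp <- c(rep("A", 8), "B", "C",
          rep("B", 5), rep("A", 3), rep("C", 2),
          rep("C", 9), "B")
  # oracle from precision/recall definitions
  expect_equal(compute_f1(yt, yp), oracle_f1(yt, yp), tolerance = 1e-12)
  expect_equal(compute_f1(yt, yp, "macro"), oracle_f1(yt, yp, "macro"),
               tolerance = 1e-12)
  expect_error(compute_f1(y, y[-1]), "lengths differ")
})

test_that("compute_f1 agrees with the oracle on random label vectors", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    yt <- sample(c("a", "b", "c"), n, TRUE)
    yp <- sample(c("a", "b", "c"), n, TRUE)
    expect_equal(compute_f1(yt, yp), oracle_f1(yt, yp),
                 tolerance = 1e-12)
    expect_equal(compute_f1(yt, yp, "macro"), oracle_f1(yt, yp, "macro"),
                 tolerance = 1e-12)
  }
})

test_that("stratified folds keep every class in every fold", {
  y <- factor(rep(c("a", "b", "c"), times = c(30, 20, 10)))
  fold <- stratified_folds(y, 5, seed = 2)
  for (k in 1:5)
    expect_setequal(as.character(unique(y[fold == k])), c("a", "b", "c"))
  expect_identical(fold, stratified_folds(y, 5, seed = 2))
  expect_error(stratified_folds(factor(rep(c("a", "b", "c"),
                                           times = c(30, 20, 3))), 5),
               "stratification error.*'c'")
  expect_error(stratified_folds(rep("a", 30), 5), "single-class")
})

test_that("a perfectly separable label is learned to F1 = 1 by trees", {
  set.seed(7)
  n <- 120
  # three value bands separated by clear margins
  band <- sample(1:3, n, TRUE)
  x1 <- c(0, 0.35, 0.7)[band] + runif(n, 0, 0.3)
  y <- factor(c("minor", "moderate", "major")[band],
              levels = c("minor", "moderate", "major"))
  X <- cbind(signal = x1, noise = rnorm(n))
  fm <- structure(list(X = X, feature_names = colnames(X), y = y,
                       feature_set = "clinical_only",
                       case_ids = as.character(1:n), encoding = list()),
                  class = "feature_matrix")
  g <- model_grid(families = "decision_tree", seed = 1)
  rep <- run_competition(fm, g)
  expect_equal(rep$winner$cv_f1, 1.0)
  expect_identical(rep$winner$family, "decision_tree")
})

test_that("the competition is reproducible and ranks by F1 with tie-breaks", {
  cs <- tiny_cases(seed = 43)
  fm <- encode_features(cs, "clinical_only")
  g <- model_grid(families = c("decision_tree", "logistic", "knn"),
                  seed = 5)
  r1 <- run_competition(fm, g)
  r2 <- run_competition(fm, g)
  expect_identical(r1$per_family, r2$per_family)
  expect_identical(r1$winner$family, r2$winner$family)
  expect_equal(r1$winner$cv_f1, max(r1$per_family$cv_f1))
  expect_error(run_competition(fm, model_grid(families = "knn",
                                              cv_folds = 2)), NA)
})

test_that("competition preconditions are enforced", {
  cs <- tiny_cases(seed = 43)
  fm <- encode_features(cs, "clinical_only")
  g <- model_grid(families = "decision_tree", seed = 1)
  small <- fm
  small$X <- fm$X[1:20, ]; small$y <- fm$y[1:20]
  small$case_ids <- fm$case_ids[1:20]
  expect_error(run_competition(small, g), "at least")
  onecls <- fm
  onecls$y <- factor(rep("minor", nrow(fm$X)),
                     levels = levels(fm$y))
  expect_error(run_competition(onecls, g), "single-class")
})

test_that("exact tree SHAP satisfies local accuracy and ranks the signal", {
  set.seed(9)
  n <- 150
  strong <- rnorm(n)
  X <- cbind(strong = strong, weak = rnorm(n), flat = rep(1, n))
  y <- factor(ifelse(strong < -0.4, "minor",
                     ifelse(strong < 0.4, "moderate", "major")),
              levels = c("minor", "moderate", "major"))
  fm <- structure(list(X = X, feature_names = colnames(X), y = y,
                       feature_set = "clinical_only",
                       case_ids = as.character(1:n), encoding = list()),
                  class = "feature_matrix")
  g <- model_grid(families = "xgboost", seed = 3)
  rep <- run_competition(fm, g)
  # local accuracy: contributions + bias reproduce the margin output
  contrib <- predict(rep$winner$model$model, xgboost::xgb.DMatrix(X),
                     predcontrib = TRUE)
  marg <- predict(rep$winner$model$model, xgboost::xgb.DMatrix(X),
                  outputmargin = TRUE)
  expect_lt(max(abs(apply(contrib, c(1, 2), sum) - marg)), 1e-4)
  rk <- rank_shap(rep, seed = 1)
  expect_identical(attr(rk, "method"), "treeshap")
  for (cl in names(rk)) {
    expect_identical(rk[[cl]]$feature[1], "strong")
    expect_equal(rk[[cl]]$mean_abs_shap[rk[[cl]]$feature == "flat"], 0)
  }
})

test_that("sampling SHAP recovers a planted signal for non-tree winners", {
  set.seed(15)
  n <- 120
  strong <- rnorm(n)
  X <- cbind(strong = strong, w1 = rnorm(n), w2 = rnorm(n))
  y <- factor(ifelse(strong < 0, "minor", "major"),
              levels = c("minor", "major"))
  fm <- structure(list(X = X, feature_names = colnames(X), y = y,
                       feature_set = "clinical_only",
                       case_ids = as.character(1:n), encoding = list()),
                  class = "feature_matrix")
  g <- model_grid(families = "logistic", seed = 3)
  rep <- run_competition(fm, g)
  expect_message(rk <- rank_shap(rep, nsim = 15, seed = 2), "sampling")
  expect_identical(rk[[1]]$feature[1], "strong")
})

test_that("subset comparison runs per subset and rejects empty ones", {
  cs <- tiny_cases(seed = 47)
  g <- model_grid(families = "decision_tree", seed = 1, cv_folds = 3)
  both <- run_subset_comparison(cs, subset_all_pass, g,
                                feature_set = "opi_only")
  expect_identical(both$all_a$per_family, both$all_b$per_family)
  roles <- run_subset_comparison(cs, subset_by_role, g,
                                 feature_set = "opi_only")
  expect_identical(roles$attending$subset_label, "attending")
  expect_error(
    run_subset_comparison(cs, function(x)
      list(a = rep(TRUE, nrow(x)), b = rep(FALSE, nrow(x))), g),
    "empty subset 'b'")
})
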