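# Iterative multi-family model competition for 3-class case complexity.
# Families available in this environment: random forest (ranger), extreme
# gradient boosting (xgboost), decision tree (rpart), radial SVM (e1071),
# k-nearest neighbours (caret::knn3) and multinomial logistic regression
# (nnet::multinom). Each family's small hyperparameter grid is scored by
# stratified k-fold cross-validated mean F1; the winner is the argmax
# across families with ties broken by macro recall, then family name.

model_families <- c("decision_tree", "knn", "logistic", "random_forest",
                    "svm", "xgboost")

default_grids <- function() {
  list(
    random_forest = expand.grid(num_trees = c(200, 500),
                                mtry_frac = c(NA, 1 / 3)),
    xgboost = expand.grid(max_depth = c(3, 6), nrounds = c(60, 150),
                          eta = 0.3),
    decision_tree = expand.grid(cp = c(0.01, 0.001), maxdepth = c(5, 30)),
    svm = expand.grid(cost = c(1, 10), gamma_scale = c(1, 0.5)),
    knn = expand.grid(k = c(5, 11, 21)),
    logistic = expand.grid(decay = c(0, 0.1))
  )
}

#' Define the model competition grid
#'
#' @param families Subset of the supported families.
#' @param cv_folds Number of stratified cross-validation folds.
#' @param scoring F1 averaging: support-`"weighted"` (default; the three
#'   complexity classes are imbalanced) or `"macro"`.
#' @param seed Seed controlling fold assignment and stochastic learners.
#' @param grids Optional named list of per-family hyperparameter data
#'   frames overriding the defaults (each must be nonempty).
#' @return A list of class `model_grid`.
#' @export
model_grid <- function(families = model_families, cv_folds = 5,
                       scoring = c("weighted", "macro"), seed = 0L,
                       grids = NULL) {
  scoring <- match.arg(scoring)
  families <- match.arg(families, model_families, several.ok = TRUE)
  g <- default_grids()[families]
  if (!is.null(grids)) g[names(grids)] <- grids
  if (cv_folds < 2) stop("cv_folds must be >= 2", call. = FALSE)
  for (f in families)
    if (is.null(g[[f]]) || nrow(g[[f]]) == 0)
      stop(sprintf("empty hyperparameter grid for family '%s'", f),
           call. = FALSE)
  structure(list(families = families, cv_folds = as.integer(cv_folds),
                 scoring = scoring, seed = as.integer(seed), grids = g),
            class = "model_grid")
}

#' Stratified cross-validation folds
#'
#' @param y Class label factor.
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return Integer vector of fold ids in `1..k`, one per observation; every
#'   class is represented in every fold.
#' @export
stratified_folds <- function(y, k, seed = 0L) {
  y <- factor(y)
  tab <- table(droplevels(y))
  if (length(tab) < 2)
    stop("degenerate single-class label vector", call. = FALSE)
  short <- names(tab)[tab < k]
  if (length(short))
    stop(sprintf("stratification error: class '%s' has %d < %d cases",
                 short[1], tab[[short[1]]], k), call. = FALSE)
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in names(tab)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Support-weighted (or macro) multiclass F1 score
#'
#' Per class, precision and recall are computed from the confusion matrix
#' and combined as their harmonic mean; class F1 values are averaged with
#' support weights (default) or uniformly (macro) over the classes present
#' in `y_true`.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param average `"weighted"` or `"macro"`.
#' @return Scalar in `[0, 1]`.
#' @export
compute_f1 <- function(y_true, y_pred, average = c("weighted", "macro")) {
  average <- match.arg(average)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred lengths differ", call. = FALSE)
  if (!length(y_true)) stop("empty label vectors", call. = FALSE)
  lev <- union(levels(factor(y_true)), levels(factor(y_pred)))
  yt <- factor(y_true, levels = lev)
  yp <- factor(y_pred, levels = lev)
  pcs <- per_class_scores(yt, yp)
  present <- pcs$support > 0
  if (average == "weighted")
    sum(pcs$f1[present] * pcs$support[present]) / sum(pcs$support[present])
  else mean(pcs$f1[present])
}

per_class_scores <- function(yt, yp) {
  cm <- table(true = yt, pred = yp)
  tp <- diag(cm)
  support <- rowSums(cm)
  predn <- colSums(cm)
  precision <- ifelse(predn > 0, tp / predn, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  data.frame(class = rownames(cm), support = as.numeric(support),
             precision = as.numeric(precision), recall = as.numeric(recall),
             f1 = as.numeric(f1), stringsAsFactors = FALSE)
}

standardize_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}
standardize_apply <- function(X, s) scale(X, s$center, s$scale)

needs_scaling <- function(family) family %in% c("svm", "knn", "logistic")

fit_variant <- function(family, params, X, y, seed = 0L) {
  y <- droplevels(factor(y))
  scaler <- NULL
  if (needs_scaling(family)) {
    scaler <- standardize_fit(X)
    X <- standardize_apply(X, scaler)
  }
  model <- switch(
    family,
    random_forest = {
      mtry <- if (is.na(params$mtry_frac)) NULL
              else max(1L, floor(params$mtry_frac * ncol(X)))
      ranger::ranger(x = X, y = y, num.trees = params$num_trees,
                     mtry = mtry, probability = TRUE, seed = seed,
                     num.threads = 1)
    },
    xgboost = {
      dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L)
      xgboost::xgb.train(
        params = list(objective = "multi:softprob",
                      num_class = nlevels(y),
                      max_depth = params$max_depth, eta = params$eta,
                      nthread = 1, seed = seed),
        data = dtrain, nrounds = params$nrounds, verbose = 0)
    },
    decision_tree = {
      df <- data.frame(X, check.names = FALSE)
      df$.y <- y
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(cp = params$cp,
                                                  maxdepth = params$maxdepth,
                                                  xval = 0))
    },
    svm = {
      gamma <- params$gamma_scale / ncol(X)
      e1071::svm(x = X, y = y, kernel = "radial", cost = params$cost,
                 gamma = gamma, scale = FALSE)
    },
    knn = caret::knn3(x = X, y = y, k = params$k),
    logistic = {
      df <- data.frame(X, check.names = FALSE)
      df$.y <- y
      nnet::multinom(.y ~ ., data = df, decay = params$decay,
                     trace = FALSE, maxit = 300, MaxNWts = 100000)
    },
    stop("unknown family: ", family, call. = FALSE)
  )
  structure(list(family = family, model = model, scaler = scaler,
                 levels = levels(y), feature_names = colnames(X)),
            class = "opilearn_model")
}

predict_variant <- function(fit, X, type = c("prob", "class")) {
  type <- match.arg(type)
  if (!is.null(fit$scaler)) X <- standardize_apply(X, fit$scaler)
  lev <- fit$levels
  prob <- switch(
    fit$family,
    random_forest = predict(fit$model, data = X,
                            num.threads = 1)$predictions,
    xgboost = {
      p <- predict(fit$model, xgboost::xgb.DMatrix(X))
      if (is.null(dim(p)))
        p <- matrix(p, ncol = length(lev), byrow = TRUE)
      colnames(p) <- lev
      p
    },
    decision_tree = predict(fit$model, data.frame(X, check.names = FALSE),
                            type = "prob"),
    svm = {
      # deterministic pseudo-probabilities: softmax over summed pairwise
      # decision values (libsvm's Platt scaling is internally randomised)
      pr <- predict(fit$model, X, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      score <- matrix(0, nrow(X), length(lev),
                      dimnames = list(NULL, lev))
      for (cn in colnames(dv)) {
        ab <- strsplit(cn, "/", fixed = TRUE)[[1]]
        score[, ab[1]] <- score[, ab[1]] + dv[, cn]
        score[, ab[2]] <- score[, ab[2]] - dv[, cn]
      }
      es <- exp(score - apply(score, 1, max))
      p <- es / rowSums(es)
      attr(p, "hard_label") <- factor(as.character(pr), levels = lev)
      p
    },
    knn = predict(fit$model, X, type = "prob"),
    logistic = {
      p <- predict(fit$model, data.frame(X, check.names = FALSE),
                   type = "probs")
      if (is.null(dim(p))) {
        if (length(lev) == 2) p <- cbind(1 - p, p)
        else p <- matrix(p, nrow = 1)
      }
      colnames(p) <- lev
      p
    }
  )
  hard <- attr(prob, "hard_label")
  prob <- as.matrix(prob)[, lev, drop = FALSE]
  if (type == "prob") return(prob)
  if (!is.null(hard)) return(hard)
  factor(lev[max.col(prob, ties.method = "first")], levels = lev)
}

#' Run the multi-family model competition
#'
#' Every hyperparameter variant of every family in the grid is scored by
#' stratified k-fold cross-validated mean F1 (all families share the same
#' seeded folds). The best variant per family is retained; the overall
#' winner is the argmax across families, ties broken by higher macro
#' recall, then lexicographic family name. The winner is refit on the full
#' data for downstream SHAP ranking.
#'
#' @param fm A `feature_matrix` from [encode_features()].
#' @param grid A [model_grid()].
#' @param subset_label Optional label carried into the report.
#' @return An object of class `model_report`: `per_family` summary table,
#'   `winner` (family, params, cv F1, per-class precision/recall, fitted
#'   model), `feature_set`, `subset_label`.
#' @export
run_competition <- function(fm, grid, subset_label = "all") {
  stopifnot(inherits(fm, "feature_matrix"), inherits(grid, "model_grid"))
  y <- droplevels(fm$y)
  n <- nrow(fm$X)
  if (n < 5 * grid$cv_folds)
    stop(sprintf("need at least %d cases for %d-fold CV, got %d",
                 5 * grid$cv_folds, grid$cv_folds, n), call. = FALSE)
  if (nlevels(y) < 2)
    stop("degenerate single-class label vector", call. = FALSE)
  fold <- stratified_folds(y, grid$cv_folds, grid$seed)

  family_best <- list()
  for (fam in grid$families) {
    gtab <- grid$grids[[fam]]
    best <- NULL
    for (v in seq_len(nrow(gtab))) {
      params <- gtab[v, , drop = FALSE]
      f1s <- recs <- numeric(grid$cv_folds)
      pooled_true <- pooled_pred <- character(0)
      ok <- TRUE
      for (kf in seq_len(grid$cv_folds)) {
        tr <- fold != kf
        fit <- tryCatch(
          fit_variant(fam, params, fm$X[tr, , drop = FALSE], y[tr],
                      seed = grid$seed + kf),
          error = function(e) NULL)
        if (is.null(fit)) { ok <- FALSE; break }
        pred <- predict_variant(fit, fm$X[!tr, , drop = FALSE], "class")
        f1s[kf] <- compute_f1(y[!tr], pred, grid$scoring)
        recs[kf] <- mean(per_class_scores(
          factor(y[!tr], levels = levels(y)),
          factor(pred, levels = levels(y)))$recall)
        pooled_true <- c(pooled_true, as.character(y[!tr]))
        pooled_pred <- c(pooled_pred, as.character(pred))
      }
      if (!ok) next
      cand <- list(family = fam, params = params, cv_f1 = mean(f1s),
                   macro_recall = mean(recs),
                   per_class = per_class_scores(
                     factor(pooled_true, levels = levels(y)),
                     factor(pooled_pred, levels = levels(y))))
      if (is.null(best) || cand$cv_f1 > best$cv_f1) best <- cand
    }
    if (is.null(best))
      stop(sprintf("all variants of family '%s' failed to fit", fam),
           call. = FALSE)
    family_best[[fam]] <- best
  }

  per_family <- do.call(rbind, lapply(names(family_best), function(f) {
    b <- family_best[[f]]
    data.frame(family = f, cv_f1 = b$cv_f1, macro_recall = b$macro_recall,
               params = paste(names(b$params), unlist(b$params),
                              sep = "=", collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  # winner: max F1, then macro recall, then lexicographic family name
  ord <- order(-per_family$cv_f1, -per_family$macro_recall,
               per_family$family)
  win_fam <- per_family$family[ord[1]]
  winner <- family_best[[win_fam]]
  winner$model <- fit_variant(win_fam, winner$params, fm$X, y,
                              seed = grid$seed)

  structure(list(per_family = per_family, winner = winner,
                 feature_set = fm$feature_set, subset_label = subset_label,
                 scoring = grid$scoring, y_levels = levels(y), fm = fm),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("Model competition [%s, subset: %s]\n", x$feature_set,
              x$subset_label))
  print(x$per_family[order(-x$per_family$cv_f1), ], row.names = FALSE)
  cat(sprintf("Winner: %s (CV %s F1 = %.3f)\n", x$winner$family,
              x$scoring, x$winner$cv_f1))
  invisible(x)
}

#' Per-class SHAP feature ranking of a competition winner
#'
#' For gradient-boosted winners the exact tree-path SHAP values are used
#' (per-sample contributions plus the base value reproduce the model's
#' margin output). Other families fall back to a model-agnostic
#' Monte-Carlo permutation Shapley estimator on the predicted class
#' probabilities, with a message noting the fallback. Features are ranked
#' per class by mean absolute SHAP value.
#'
#' @param report A `model_report` (with fitted winner).
#' @param X Optional matrix of cases to explain (default: the report's
#'   design matrix).
#' @param top_k Number of top-ranked features to keep per class.
#' @param nsim Permutations for the sampling estimator.
#' @param explain_n Maximum number of rows explained (subsampled, seeded).
#' @param seed RNG seed for the sampling estimator.
#' @return Named list (one element per class) of data frames
#'   `(feature, mean_abs_shap)` sorted descending, plus attribute
#'   `method` (`"treeshap"` or `"sampling"`).
#' @export
rank_shap <- function(report, X = NULL, top_k = 20, nsim = 20,
                      explain_n = 100, seed = 0L) {
  stopifnot(inherits(report, "model_report"))
  if (is.null(X)) X <- report$fm$X
  if (!nrow(X)) stop("no cases to explain", call. = FALSE)
  fit <- report$winner$model
  lev <- report$y_levels
  set.seed(seed)
  idx <- if (nrow(X) > explain_n) sort(sample(nrow(X), explain_n))
         else seq_len(nrow(X))

  if (fit$family == "xgboost") {
    contrib <- predict(fit$model, xgboost::xgb.DMatrix(X[idx, , drop = FALSE]),
                       predcontrib = TRUE)
    # one matrix (n x p+1) per class, as a list or a 3-d array
    if (is.list(contrib)) {
      arr <- simplify2array(contrib)            # n x (p+1) x K
    } else if (length(dim(contrib)) == 3) {
      arr <- aperm(contrib, c(1, 3, 2))         # n x (p+1) x K
      if (dim(contrib)[2] != length(lev)) arr <- contrib
    } else {
      arr <- array(contrib, dim = c(nrow(contrib), ncol(contrib), 1))
    }
    phi <- arr[, seq_len(ncol(X)), , drop = FALSE]
    method <- "treeshap"
  } else {
    message(sprintf(
      "family '%s' has no exact SHAP path; using Monte-Carlo sampling Shapley",
      fit$family))
    predfun <- function(M) predict_variant(fit, M, "prob")
    phi <- shap_sampling(predfun, X, idx, nsim = nsim)
    method <- "sampling"
  }
  out <- lapply(seq_along(lev), function(k) {
    mabs <- apply(abs(phi[, , min(k, dim(phi)[3]), drop = FALSE]), 2, mean)
    d <- data.frame(feature = colnames(X), mean_abs_shap = as.numeric(mabs),
                    stringsAsFactors = FALSE)
    d <- d[order(-d$mean_abs_shap, d$feature), ]
    rownames(d) <- NULL
    head(d, top_k)
  })
  names(out) <- lev
  attr(out, "method") <- method
  out
}

# Monte-Carlo permutation Shapley (Strumbelj & Kononenko): for each random
# feature ordering, features of the explained row replace a background row
# one at a time; the prediction increments are unbiased Shapley estimates.
shap_sampling <- function(predfun, X, explain_idx, nsim = 20) {
  p <- ncol(X)
  n_e <- length(explain_idx)
  K <- ncol(predfun(X[seq_len(min(2, nrow(X))), , drop = FALSE]))
  phi <- array(0, dim = c(n_e, p, K),
               dimnames = list(NULL, colnames(X), NULL))
  Xe <- X[explain_idx, , drop = FALSE]
  for (s in seq_len(nsim)) {
    perm <- sample(p)
    cur <- X[sample(nrow(X), n_e, replace = TRUE), , drop = FALSE]
    prev <- predfun(cur)
    for (j in perm) {
      cur[, j] <- Xe[, j]
      nxt <- predfun(cur)
      phi[, j, ] <- phi[, j, ] + (nxt - prev)
      prev <- nxt
    }
  }
  phi / nsim
}

#' Run independent model competitions on two case subsets
#'
#' @param cases Filtered cohort data frame.
#' @param subset_fn Function mapping `cases` to a named list of two logical
#'   vectors (the subsets); see [subset_by_role()].
#' @param grid A [model_grid()].
#' @param feature_set Feature set for both competitions.
#' @return Named list of two `model_report`s.
#' @export
run_subset_comparison <- function(cases, subset_fn, grid,
                                  feature_set = "opi_only") {
  sel <- subset_fn(cases)
  stopifnot(is.list(sel), length(sel) == 2, !is.null(names(sel)))
  out <- lapply(names(sel), function(nm) {
    keep <- sel[[nm]]
    if (!any(keep))
      stop(sprintf("empty subset '%s'", nm), call. = FALSE)
    fm <- encode_features(cases[keep, , drop = FALSE], feature_set)
    run_competition(fm, grid, subset_label = nm)
  })
  names(out) <- names(sel)
  out
}

#' Subset constructors for [run_subset_comparison()]
#'
#' `subset_by_role()` splits on attending versus non-attending primary
#' surgeon; `subset_all_pass()` returns the full cohort twice (a plumbing
#' identity); `subset_by_date()` splits at a transition date (cases before
#' it in the first group).
#'
#' @param cases Cohort data frame.
#' @return Named list of two logical vectors.
#' @export
subset_by_role <- function(cases) {
  list(attending = cases$primary_surgeon_role == "attending",
       non_attending = cases$primary_surgeon_role == "non_attending")
}

#' @rdname subset_by_role
#' @export
subset_all_pass <- function(cases) {
  list(all_a = rep(TRUE, nrow(cases)), all_b = rep(TRUE, nrow(cases)))
}

#' @rdname subset_by_role
#' @param transition_date Date; cases strictly before it form the first
#'   (Novice) group.
#' @export
subset_by_date <- function(cases, transition_date) {
  force(transition_date)
  list(novice = cases$date < transition_date,
       expert = cases$date >= transition_date)
}
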