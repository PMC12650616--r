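# Classifier families, stratified cross-validated grid search, and
# evaluation. Ten families are supported: random forest, (penalized)
# logistic regression, k-nearest neighbors, decision tree, Gaussian naive
# Bayes, gradient boosting, AdaBoost, and three networks (MLP, 1-D CNN,
# Transformer encoder). Established implementations back the classical
# families (randomForest, glmnet, rpart, e1071, xgboost); AdaBoost (SAMME
# over depth-1 rpart stumps), KNN scoring and the networks are implemented
# in-package. CRC is the positive class (label 1) throughout.

#' The ten supported classifier family names
#' @export
MODEL_FAMILIES <- c("random_forest", "logistic_regression", "knn",
                    "decision_tree", "naive_bayes", "gradient_boosting",
                    "adaboost", "mlp", "cnn", "transformer")

# families whose inputs are standardized with train-fold statistics
.scaled_families <- c("logistic_regression", "knn", "mlp", "cnn", "transformer")

#' Default hyperparameter grid for a model family
#'
#' Desk-scale grids (1-3 values per tunable); the naive Bayes grid is empty
#' by design (the Gaussian classifier is used with default settings). Larger
#' grids can be passed to [model_spec()] directly.
#'
#' @param family one of `MODEL_FAMILIES`.
#' @return named list mapping hyperparameter name to candidate values.
#' @export
default_grid <- function(family) {
  switch(family,
    random_forest = list(n_estimators = c(200L), max_depth = c(0L, 10L),
                         max_features = c("sqrt")),
    logistic_regression = list(C = c(0.1, 1, 10), penalty = c("l2")),
    knn = list(n_neighbors = c(3L, 5L, 7L),
               weights = c("uniform", "distance")),
    decision_tree = list(max_depth = c(3L, 10L), min_samples_split = c(2L, 10L)),
    naive_bayes = list(),
    gradient_boosting = list(n_estimators = c(100L), learning_rate = c(0.1),
                             max_depth = c(2L, 3L)),
    adaboost = list(n_estimators = c(50L, 100L), learning_rate = c(0.5, 1)),
    mlp = list(hidden_sizes = list(c(32L), c(64L, 32L)), dropout = c(0.2),
               learning_rate = c(1e-3), epochs = c(30L), batch_size = c(32L)),
    cnn = list(conv_layers = c(1L), filters = c(8L), kernel_size = c(5L, 9L),
               pooling = c("max"), dropout = c(0.2), learning_rate = c(1e-3),
               epochs = c(30L), batch_size = c(32L)),
    transformer = list(d_model = c(8L), nhead = c(2L), num_layers = c(1L),
                       dropout = c(0.1), learning_rate = c(3e-2),
                       epochs = c(12L), batch_size = c(32L)),
    stop("unknown model family: ", family, call. = FALSE))
}

#' Specify a classifier family with its hyperparameter grid
#'
#' @param family one of `MODEL_FAMILIES`.
#' @param grid named list of candidate values per hyperparameter; defaults
#'   to [default_grid()]. Must be empty for `naive_bayes`.
#' @param seed master seed for this family's randomness.
#' @return a `tcr_model_spec`.
#' @export
model_spec <- function(family = MODEL_FAMILIES, grid = NULL, seed = 1) {
  family <- match.arg(family)
  if (is.null(grid)) grid <- default_grid(family)
  valid <- names(default_grid(family))
  bad <- setdiff(names(grid), valid)
  if (family == "naive_bayes" && length(grid))
    stop("naive_bayes takes no tunable hyperparameters", call. = FALSE)
  if (length(bad))
    stop("invalid hyperparameter(s) for ", family, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(family = family, grid = grid, seed = seed),
            class = "tcr_model_spec")
}

# expand a grid (supports list-valued entries) into a list of param lists,
# in column-major grid order so earlier entries win ties
.expand_grid_points <- function(grid) {
  if (length(grid) == 0) return(list(list()))
  counts <- vapply(grid, length, integer(1))
  idx <- do.call(expand.grid, lapply(counts, seq_len))
  lapply(seq_len(nrow(idx)), function(r) {
    pt <- lapply(seq_along(grid), function(j) grid[[j]][[idx[r, j]]])
    names(pt) <- names(grid)
    pt
  })
}

.fit_scaler <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd)
}

.apply_scaler <- function(scaler, X)
  sweep(sweep(X, 2, scaler$mu, "-"), 2, scaler$sd, "/")

# ---- AdaBoost (SAMME over depth-1 rpart stumps) ---------------------------

.fit_adaboost <- function(X, y, n_estimators = 50, learning_rate = 1,
                          seed = 1) {
  df <- data.frame(X)
  df$.y <- factor(y, levels = c(0, 1))
  n <- nrow(df)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  with_seed(seed, {
    for (t in seq_len(n_estimators)) {
      fit <- rpart::rpart(.y ~ ., data = df, weights = w * n,
                          method = "class",
                          control = rpart::rpart.control(maxdepth = 1,
                                                         cp = -1, xval = 0,
                                                         minsplit = 2))
      pred <- as.integer(as.character(predict(fit, df, type = "class")))
      err <- sum(w * (pred != y))
      err <- min(max(err, 1e-10), 1 - 1e-10)
      if (err >= 0.5 && t > 1) break
      alpha <- learning_rate * 0.5 * log((1 - err) / err)
      stumps[[t]] <- fit
      alphas[t] <- alpha
      w <- w * exp(alpha * ifelse(pred != y, 1, -1))
      w <- w / sum(w)
    }
  })
  list(stumps = stumps, alphas = alphas)
}

.predict_adaboost <- function(fit, X) {
  df <- data.frame(X)
  if (length(fit$stumps) == 0) return(rep(0.5, nrow(df)))
  votes <- vapply(seq_along(fit$stumps), function(t) {
    pred <- as.integer(as.character(predict(fit$stumps[[t]], df,
                                            type = "class")))
    fit$alphas[t] * (2 * pred - 1)
  }, numeric(nrow(df)))
  margin <- if (is.matrix(votes)) rowSums(votes) else sum(votes)
  .sigmoid(2 * margin / max(sum(abs(fit$alphas)), 1e-12) * 3)
}

# ---- KNN scoring ----------------------------------------------------------

.predict_knn <- function(fit, X) {
  d2 <- outer(rowSums(X^2), rowSums(fit$X^2), "+") - 2 * X %*% t(fit$X)
  d2 <- pmax(d2, 0)
  vapply(seq_len(nrow(X)), function(i) {
    ord <- order(d2[i, ], seq_len(ncol(d2)))[seq_len(fit$k)]
    if (fit$weights == "uniform") mean(fit$y[ord])
    else {
      w <- 1 / pmax(sqrt(d2[i, ord]), 1e-12)
      sum(w * fit$y[ord]) / sum(w)
    }
  }, numeric(1))
}

# ---- family dispatch -------------------------------------------------------

#' Fit one classifier family with fixed hyperparameters
#'
#' @param family one of `MODEL_FAMILIES`.
#' @param params named list of hyperparameter values (missing entries fall
#'   back to each family's defaults).
#' @param fm_train training `tcr_feature_matrix`.
#' @param seed fit seed.
#' @return a `tcr_model` exposing class-1 probability scoring via
#'   [predict_score()].
#' @export
fit_model <- function(family, params, fm_train, seed = 1) {
  X <- fm_train$X; y <- fm_train$y
  scaler <- if (family %in% .scaled_families) .fit_scaler(X) else NULL
  Xs <- if (is.null(scaler)) X else .apply_scaler(scaler, X)
  g <- function(nm, dflt) params[[nm]] %||% dflt
  fit <- switch(family,
    random_forest = with_seed(seed, {
      mf <- g("max_features", "sqrt")
      mtry <- if (identical(mf, "sqrt")) max(1, floor(sqrt(ncol(Xs))))
              else max(1, floor(as.numeric(mf) * ncol(Xs)))
      md <- as.integer(g("max_depth", 0L))
      args <- list(x = Xs, y = factor(y, levels = c(0, 1)),
                   ntree = as.integer(g("n_estimators", 200L)), mtry = mtry)
      if (md > 0) args$maxnodes <- 2L^md
      do.call(randomForest::randomForest, args)
    }),
    logistic_regression = {
      lam <- 1 / (as.numeric(g("C", 1)) * nrow(Xs))
      alpha <- if (identical(g("penalty", "l2"), "l1")) 1 else 0
      glmnet::glmnet(Xs, y, family = "binomial", alpha = alpha,
                     lambda = sort(unique(c(lam * 100, lam * 10, lam)),
                                   decreasing = TRUE),
                     standardize = FALSE)
    },
    knn = list(X = Xs, y = y, k = as.integer(g("n_neighbors", 5L)),
               weights = g("weights", "uniform")),
    decision_tree = with_seed(seed, {
      df <- data.frame(Xs); df$.y <- factor(y, levels = c(0, 1))
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     maxdepth = as.integer(g("max_depth", 10L)),
                     minsplit = as.integer(g("min_samples_split", 2L)),
                     cp = 0, xval = 0))
    }),
    naive_bayes = {
      nb <- e1071::naiveBayes(Xs, factor(y, levels = c(0, 1)))
      # variance floor so zero-variance (class-constant) features stay finite
      floor_sd <- 1e-6 * max(apply(Xs, 2, stats::sd), 1e-12)
      nb$tables <- lapply(nb$tables, function(tb) {
        tb[, 2] <- pmax(tb[, 2], floor_sd); tb
      })
      nb
    },
    gradient_boosting = with_seed(seed, {
      dtrain <- xgboost::xgb.DMatrix(Xs, label = y)
      xgboost::xgb.train(params = list(objective = "binary:logistic",
                                       eta = as.numeric(g("learning_rate", 0.1)),
                                       max_depth = as.integer(g("max_depth", 3L)),
                                       nthread = 1),
                         data = dtrain,
                         nrounds = as.integer(g("n_estimators", 100L)),
                         verbose = 0)
    }),
    adaboost = .fit_adaboost(Xs, y,
                             n_estimators = as.integer(g("n_estimators", 50L)),
                             learning_rate = as.numeric(g("learning_rate", 1)),
                             seed = seed),
    mlp = fit_mlp(Xs, y, hidden_sizes = g("hidden_sizes", c(32L)),
                  dropout = as.numeric(g("dropout", 0.2)),
                  learning_rate = as.numeric(g("learning_rate", 1e-3)),
                  epochs = as.integer(g("epochs", 30L)),
                  batch_size = as.integer(g("batch_size", 32L)), seed = seed),
    cnn = fit_cnn(Xs, y, conv_layers = as.integer(g("conv_layers", 1L)),
                  filters = as.integer(g("filters", 8L)),
                  kernel_size = as.integer(g("kernel_size", 5L)),
                  pooling = g("pooling", "max"),
                  dropout = as.numeric(g("dropout", 0.2)),
                  learning_rate = as.numeric(g("learning_rate", 1e-3)),
                  epochs = as.integer(g("epochs", 30L)),
                  batch_size = as.integer(g("batch_size", 32L)), seed = seed),
    transformer = fit_transformer(Xs, y,
                  d_model = as.integer(g("d_model", 8L)),
                  nhead = as.integer(g("nhead", 2L)),
                  num_layers = as.integer(g("num_layers", 1L)),
                  dropout = as.numeric(g("dropout", 0.1)),
                  learning_rate = as.numeric(g("learning_rate", 3e-2)),
                  epochs = as.integer(g("epochs", 12L)),
                  batch_size = as.integer(g("batch_size", 32L)), seed = seed),
    stop("unknown model family: ", family, call. = FALSE))
  structure(list(family = family, fit = fit, scaler = scaler,
                 params = params, features = colnames(fm_train$X)),
            class = "tcr_model")
}

#' Score samples with a fitted model
#'
#' @param model a `tcr_model`.
#' @param fm a `tcr_feature_matrix` (or bare matrix) over the model's
#'   feature set.
#' @return class-1 (CRC) probabilities in `[0, 1]`.
#' @export
predict_score <- function(model, fm) {
  X <- if (inherits(fm, "tcr_feature_matrix")) fm$X else as.matrix(fm)
  if (!identical(colnames(X), model$features))
    stop("feature columns do not match the fitted model", call. = FALSE)
  Xs <- if (is.null(model$scaler)) X else .apply_scaler(model$scaler, X)
  p <- switch(model$family,
    random_forest = predict(model$fit, Xs, type = "prob")[, "1"],
    logistic_regression = {
      lam <- min(model$fit$lambda)
      as.numeric(predict(model$fit, Xs, s = lam, type = "response"))
    },
    knn = .predict_knn(model$fit, Xs),
    decision_tree = predict(model$fit, data.frame(Xs), type = "prob")[, "1"],
    naive_bayes = predict(model$fit, Xs, type = "raw")[, "1"],
    gradient_boosting = predict(model$fit, xgboost::xgb.DMatrix(Xs)),
    adaboost = .predict_adaboost(model$fit, Xs),
    mlp = nn_predict(model$fit, Xs),
    cnn = nn_predict(model$fit, Xs),
    transformer = nn_predict(model$fit, Xs))
  unname(pmin(pmax(as.numeric(p), 0), 1))
}

# ---- cross-validation ------------------------------------------------------

#' Stratified k-fold assignment
#'
#' Within each class, samples are shuffled (seeded) and dealt round-robin
#' into k folds, so per-fold class counts differ from balance by at most
#' one sample.
#'
#' @param y per-sample labels (any type).
#' @param k number of folds (default 5).
#' @param seed shuffle seed.
#' @return list of k elements, each `list(train_idx, val_idx)`; validation
#'   folds partition the samples.
#' @export
stratified_kfold <- function(y, k = 5, seed = 1) {
  classes <- unique(y)
  too_small <- classes[vapply(classes, function(cl) sum(y == cl), 0) < k]
  if (length(too_small))
    stop("class smaller than k = ", k, ": ", paste(too_small, collapse = ", "),
         call. = FALSE)
  fold_of <- integer(length(y))
  with_seed(seed, {
    for (cl in classes) {
      members <- sample(which(y == cl))
      fold_of[members] <- rep_len(seq_len(k), length(members))
    }
  })
  lapply(seq_len(k), function(f)
    list(train_idx = which(fold_of != f), val_idx = which(fold_of == f)))
}

#' Exhaustive hyperparameter search under stratified k-fold CV
#'
#' Every grid point is scored by mean validation AUC across the folds; the
#' winner is the argmax (ties broken by earlier grid order). A grid point
#' whose fit fails is scored AUC 0.5 and flagged, never dropped. The empty
#' grid (naive Bayes) evaluates the defaults once.
#'
#' @param spec a `tcr_model_spec`.
#' @param fm_train training `tcr_feature_matrix`.
#' @param k folds (default 5).
#' @return a `tcr_cv_result`: `best_params`, `best_mean_auc`, and a `table`
#'   with per-point mean/sd AUC and accuracy plus failure flags.
#' @export
grid_search_cv <- function(spec, fm_train, k = 5) {
  stopifnot(inherits(spec, "tcr_model_spec"))
  points <- .expand_grid_points(spec$grid)
  folds <- stratified_kfold(fm_train$y, k,
                            seed = derive_seed(spec$seed, "cvfolds"))
  res <- lapply(seq_along(points), function(pi) {
    aucs <- numeric(k); accs <- numeric(k); failed <- FALSE
    for (f in seq_len(k)) {
      out <- tryCatch({
        m <- fit_model(spec$family, points[[pi]],
                       fm_subset(fm_train, folds[[f]]$train_idx),
                       seed = derive_seed(spec$seed, paste0("fit", pi, "_", f)))
        s <- predict_score(m, fm_subset(fm_train, folds[[f]]$val_idx))
        yv <- fm_train$y[folds[[f]]$val_idx]
        c(auc_score(s, yv), mean((s >= 0.5) == yv))
      }, error = function(e) {
        warning("grid point ", pi, " fold ", f, " failed: ",
                conditionMessage(e), call. = FALSE)
        c(NA_real_, NA_real_)
      })
      if (any(is.na(out))) { failed <- TRUE; out <- c(0.5, 0.5) }
      aucs[f] <- out[1]; accs[f] <- out[2]
    }
    list(mean_auc = mean(aucs), sd_auc = stats::sd(aucs),
         mean_acc = mean(accs), sd_acc = stats::sd(accs),
         fold_aucs = aucs, failed = failed)
  })
  mean_aucs <- vapply(res, `[[`, numeric(1), "mean_auc")
  best <- which.max(mean_aucs)  # first max -> earlier grid order wins ties
  tab <- data.frame(point = seq_along(points),
                    params = vapply(points, function(p)
                      paste(names(p), vapply(p, function(v)
                        paste(v, collapse = ":"), ""), sep = "=",
                        collapse = ", "), ""),
                    mean_auc = mean_aucs,
                    sd_auc = vapply(res, `[[`, numeric(1), "sd_auc"),
                    mean_accuracy = vapply(res, `[[`, numeric(1), "mean_acc"),
                    failed = vapply(res, `[[`, logical(1), "failed"),
                    stringsAsFactors = FALSE)
  structure(list(family = spec$family, best_params = points[[best]],
                 best_mean_auc = mean_aucs[best],
                 best_fold_aucs = res[[best]]$fold_aucs, table = tab),
            class = "tcr_cv_result")
}

#' Refit a family on the full training partition with chosen hyperparameters
#'
#' @param spec a `tcr_model_spec`.
#' @param params winning hyperparameter list (e.g. from [grid_search_cv()]).
#' @param fm_train training `tcr_feature_matrix`.
#' @return a `tcr_model`.
#' @export
fit_final <- function(spec, params, fm_train) {
  fit_model(spec$family, params, fm_train,
            seed = derive_seed(spec$seed, "final"))
}

# ---- evaluation ------------------------------------------------------------

#' Pair-counting AUC (ties count one half)
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 labels (both classes present).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: evaluation set has a single class", call. = FALSE)
  r <- rank(scores)  # midranks for ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Thresholds sweep the distinct score values from high to low; tied scores
#' move together. The curve starts at (0, 0) and ends at (1, 1) and is
#' monotone nondecreasing in both coordinates.
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 labels.
#' @return data.frame with `fpr` and `tpr`.
#' @export
roc_points <- function(scores, labels) {
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  keep <- c(diff(s) != 0, TRUE)  # last index of each tied block
  tpr <- cumsum(y == 1)[keep] / max(sum(labels == 1), 1)
  fpr <- cumsum(y == 0)[keep] / max(sum(labels == 0), 1)
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Evaluate a fitted model on a labeled feature matrix
#'
#' Accuracy, recall and F1 use the stated probability threshold with CRC
#' (label 1) as the positive class; AUC is threshold-free (pair counting).
#' If the evaluation set has a single class the AUC is `NA` with a warning;
#' the thresholded metrics are still reported.
#'
#' @param model a `tcr_model`.
#' @param fm_eval evaluation `tcr_feature_matrix`.
#' @param threshold classification threshold on the probability scale.
#' @return a `tcr_eval`: `accuracy`, `auc`, `recall`, `f1`, `roc` points,
#'   per-sample `scores`, `n`.
#' @export
evaluate <- function(model, fm_eval, threshold = 0.5) {
  s <- predict_score(model, fm_eval)
  y <- fm_eval$y
  pred <- as.integer(s >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0
        else 2 * precision * recall / (precision + recall)
  auc <- if (length(unique(y)) < 2) {
    warning("single-class evaluation set: AUC undefined", call. = FALSE)
    NA_real_
  } else auc_score(s, y)
  structure(list(accuracy = mean(pred == y), auc = auc, recall = recall,
                 f1 = f1, precision = precision,
                 roc = roc_points(s, y), scores = s, threshold = threshold,
                 n = length(y)),
            class = "tcr_eval")
}

#' @export
print.tcr_eval <- function(x, ...) {
  cat(sprintf("<tcr_eval> n=%d  accuracy=%.3f  AUC=%.3f  recall=%.3f  F1=%.3f\n",
              x$n, x$accuracy, x$auc, x$recall, x$f1))
  invisible(x)
}

#' Benchmark several classifier families
#'
#' For each spec: stratified k-fold grid search on the training partition,
#' refit of the winner on all training samples, evaluation on the test
#' partition. Per-family failures become flagged rows; the table is ranked
#' by test AUC.
#'
#' @param specs list of `tcr_model_spec` (default: all ten families with
#'   their default grids, seeds derived per family from `seed`).
#' @param fm_train,fm_test train and test `tcr_feature_matrix`.
#' @param k CV folds.
#' @param seed master seed used when `specs` is `NULL`.
#' @return a `tcr_benchmark`: `table` (family, cv_mean_auc, test metrics,
#'   rank), `models`, `cv_results`, `evals`.
#' @export
benchmark_all <- function(specs = NULL, fm_train, fm_test, k = 5, seed = 1) {
  if (is.null(specs))
    specs <- lapply(MODEL_FAMILIES, function(f)
      model_spec(f, seed = derive_seed(seed, f)))
  rows <- list(); models <- list(); cvs <- list(); evals <- list()
  for (spec in specs) {
    fam <- spec$family
    message("benchmark: ", fam)
    out <- tryCatch({
      cv <- grid_search_cv(spec, fm_train, k = k)
      mod <- fit_final(spec, cv$best_params, fm_train)
      ev <- evaluate(mod, fm_test)
      list(cv = cv, mod = mod, ev = ev, ok = TRUE)
    }, error = function(e) {
      warning("family ", fam, " failed: ", conditionMessage(e), call. = FALSE)
      list(ok = FALSE, msg = conditionMessage(e))
    })
    if (out$ok) {
      rows[[fam]] <- data.frame(family = fam,
                                cv_mean_auc = out$cv$best_mean_auc,
                                accuracy = out$ev$accuracy, auc = out$ev$auc,
                                recall = out$ev$recall, f1 = out$ev$f1,
                                failed = FALSE, stringsAsFactors = FALSE)
      models[[fam]] <- out$mod; cvs[[fam]] <- out$cv; evals[[fam]] <- out$ev
    } else {
      rows[[fam]] <- data.frame(family = fam, cv_mean_auc = NA, accuracy = NA,
                                auc = NA, recall = NA, f1 = NA, failed = TRUE,
                                stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(-ifelse(is.na(tab$auc), -Inf, tab$auc)), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(table = tab, models = models, cv_results = cvs,
                 evals = evals),
            class = "tcr_benchmark")
}

#' @export
print.tcr_benchmark <- function(x, ...) {
  print(x$table, digits = 3)
  invisible(x)
}
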