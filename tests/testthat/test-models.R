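# synthetic tabular fixture: one informative feature block + noise
make_fm <- function(n = 80, m = 12, shift = 2, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), n / 2)
  X <- matrix(rnorm(n * m), n, m)
  X[, 1] <- X[, 1] + shift * y
  X[, 2] <- X[, 2] + shift / 2 * y
  colnames(X) <- paste0("C", sprintf("%02d", seq_len(m)), "F")
  vocab <- data.frame(cdr3_aa = colnames(X), v_gene = "TRBV9",
                      j_gene = "TRBJ2-3", total_freq = 1, presence = 1,
                      rank = seq_len(m))
  class(vocab) <- c("tcr_vocabulary", "data.frame")
  structure(list(X = X, y = y, sample_ids = paste0("s", seq_len(n)),
                 vocabulary = vocab),
            class = "tcr_feature_matrix")
}

test_that("stratified k-fold partitions samples with balanced class counts", {
  y <- rep(c(1, 0), c(50, 50))
  folds <- stratified_kfold(y, 5, seed = 3)
  val_all <- sort(unlist(lapply(folds, `[[`, "val_idx")))
  expect_equal(val_all, seq_along(y))
  for (f in folds) {
    expect_equal(sum(y[f$val_idx] == 1), 10)
    expect_length(intersect(f$train_idx, f$val_idx), 0)
  }
  # 37/56: case count per fold must be 7 or 8
  y2 <- rep(c(1, 0), c(37, 56))
  folds2 <- stratified_kfold(y2, 5, seed = 1)
  crc_per_fold <- vapply(folds2, function(f) sum(y2[f$val_idx] == 1), 0)
  expect_true(all(crc_per_fold %in% c(7, 8)))
  expect_equal(sum(crc_per_fold), 37)
  expect_error(stratified_kfold(c(1, 1, 0, 0), 5), "smaller than k")
})

test_that("pair-counting AUC matches hand cases and the trapezoidal ROC area", {
  expect_equal(auc_score(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_score(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(auc_score(1:3, c(1, 1, 1)), "single class")
  set.seed(17)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    y <- c(0, 1, sample(0:1, n - 2, TRUE))
    s <- round(runif(n), sample(1:3, 1))  # induce ties
    expect_equal(auc_score(s, y), roc_trapezoid(s, y), tolerance = 1e-10)
  }
})

test_that("ROC curves are monotone from (0,0) to (1,1)", {
  set.seed(5)
  s <- runif(30); y <- sample(0:1, 30, TRUE, prob = c(0.4, 0.6))
  pts <- roc_points(s, y)
  expect_equal(unlist(pts[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
})

test_that("every family fits, scores in [0,1], and deterministic families reproduce", {
  fm <- make_fm()
  for (fam in MODEL_FAMILIES) {
    params <- lapply(default_grid(fam), `[[`, 1)
    if (fam %in% c("mlp", "cnn", "transformer")) params$epochs <- 3L
    m1 <- fit_model(fam, params, fm, seed = 11)
    s1 <- predict_score(m1, fm)
    expect_length(s1, nrow(fm$X))
    expect_true(all(s1 >= 0 & s1 <= 1), info = fam)
    m2 <- fit_model(fam, params, fm, seed = 11)
    expect_equal(predict_score(m2, fm), s1, tolerance = 1e-12, info = fam)
  }
})

test_that("separable data is learned by the linear family near-perfectly", {
  fm <- make_fm(n = 100, shift = 4)
  spec <- model_spec("logistic_regression", seed = 2)
  cv <- grid_search_cv(spec, fm)
  expect_gte(cv$best_mean_auc, 0.99)
  expect_true(cv$best_mean_auc >= max(cv$table$mean_auc) - 1e-12)
})

test_that("grid search returns the argmax point and honors tie order", {
  fm <- make_fm()
  spec <- model_spec("knn", grid = list(n_neighbors = c(3L, 5L),
                                        weights = "uniform"), seed = 4)
  cv <- grid_search_cv(spec, fm)
  expect_equal(which.max(cv$table$mean_auc), cv$table$point[
    cv$table$params == paste0("n_neighbors=", cv$best_params$n_neighbors,
                              ", weights=uniform")])
  one <- grid_search_cv(model_spec("decision_tree",
                                   grid = list(max_depth = 3L,
                                               min_samples_split = 2L),
                                   seed = 1), fm)
  expect_equal(one$best_params$max_depth, 3L)
  # empty grid (naive Bayes) evaluates defaults once
  nb <- grid_search_cv(model_spec("naive_bayes", seed = 1), fm)
  expect_equal(nrow(nb$table), 1)
})

test_that("evaluation metrics behave at the threshold and on degenerate sets", {
  fm <- make_fm(n = 60, shift = 5)
  m <- fit_model("logistic_regression", list(C = 1), fm, seed = 1)
  ev <- evaluate(m, fm)
  expect_gte(ev$auc, 0.99)
  expect_gte(ev$f1, 0.9)
  one_class <- fm_subset(fm, which(fm$y == 1))
  expect_warning(ev1 <- evaluate(m, one_class), "single-class")
  expect_true(is.na(ev1$auc))
  expect_true(ev1$accuracy >= 0 && ev1$accuracy <= 1)
})

test_that("model spec validates grids", {
  expect_error(model_spec("naive_bayes", grid = list(var = 1)),
               "no tunable")
  expect_error(model_spec("knn", grid = list(bogus = 1)), "invalid")
  expect_error(model_spec("svm"), "arg")
})

test_that("benchmark table is complete, ranked by test AUC, and seed-stable", {
  fm <- make_fm(n = 90, shift = 3)
  sp <- stratified_split(fm, 0.3, seed = 5)
  fams <- c("logistic_regression", "decision_tree", "naive_bayes")
  specs <- lapply(fams, function(f)
    model_spec(f, seed = derive_seed(31, f)))
  b1 <- benchmark_all(specs, sp$train, sp$test)
  expect_equal(nrow(b1$table), 3)
  expect_false(any(b1$table$failed))
  expect_true(all(diff(b1$table$auc) <= 1e-12))
  b2 <- benchmark_all(specs, sp$train, sp$test)
  expect_equal(b1$table, b2$table)
})
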