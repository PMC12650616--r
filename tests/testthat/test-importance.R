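make_imp_fm <- function(n = 120, m = 10, seed = 2) {
  set.seed(seed)
  y <- rep(0:1, n / 2)
  X <- matrix(rnorm(n * m), n, m)
  X[, 1] <- y + 0.15 * rnorm(n)       # feature 1 ~ the label
  X[, 5] <- 1                          # constant column
  colnames(X) <- paste0("C", sprintf("%02d", seq_len(m)), "F")
  vocab <- data.frame(cdr3_aa = colnames(X), v_gene = "TRBV9",
                      j_gene = "TRBJ2-3", total_freq = 1, presence = 1,
                      rank = seq_len(m))
  class(vocab) <- c("tcr_vocabulary", "data.frame")
  structure(list(X = X, y = y, sample_ids = paste0("s", seq_len(n)),
                 vocabulary = vocab),
            class = "tcr_feature_matrix")
}

test_that("a label-identical feature dominates noise features in importance", {
  ok <- vapply(1:8, function(run) {
    fm <- make_imp_fm(seed = 100 + run)
    spec <- model_spec("logistic_regression", seed = run)
    imp <- permutation_importance_cv(spec, fm, seed = 50 + run)
    sc <- imp$scores$importance
    sc[1] > max(sc[-1])
  }, logical(1))
  expect_gte(mean(ok), 7 / 8)
})

test_that("constant columns and label-independent features have zero-ish importance", {
  fm <- make_imp_fm(seed = 3)
  spec <- model_spec("logistic_regression", seed = 5)
  imp <- permutation_importance_cv(spec, fm, seed = 7)
  # permuting a constant is the identity, so the drop is exactly zero
  expect_identical(unname(imp$raw[5, , ]), matrix(0, 5, 5))
  noise <- imp$scores$importance[c(2:4, 6:10)]
  expect_true(all(abs(noise) < 0.02))
})

test_that("the stored matrix is never mutated and the report is deterministic", {
  fm <- make_imp_fm(seed = 9)
  X_before <- fm$X + 0  # deep copy
  spec <- model_spec("logistic_regression", seed = 2)
  imp1 <- permutation_importance_cv(spec, fm, seed = 11)
  expect_identical(fm$X, X_before)
  imp2 <- permutation_importance_cv(spec, fm, seed = 11)
  expect_identical(imp1$raw, imp2$raw)
  # report geometry: folds x repeats per feature; mean consistency
  expect_equal(dim(imp1$raw), c(10, 5, 5))
  per_fold <- apply(imp1$raw, c(1, 2), mean)
  expect_equal(unname(rowMeans(per_fold)), imp1$scores$importance)
})

test_that("select_panel is a stable top-k with lexicographic tie-break", {
  fm <- make_imp_fm(seed = 4)
  spec <- model_spec("logistic_regression", seed = 3)
  imp <- permutation_importance_cv(spec, fm, seed = 13)
  p3 <- select_panel(imp, 3)
  expect_equal(nrow(p3), 3)
  expect_true(all(diff(p3$importance) <= 1e-15))
  expect_identical(select_panel(imp, 3), p3)  # idempotent
  expect_equal(p3$cdr3_aa[1], "C01F")
  full <- select_panel(imp, 10)
  expect_equal(nrow(full), 10)
  expect_error(select_panel(imp, 11), "exceeds")
  # forced tie: all-zero importances fall back to lexicographic order
  imp0 <- imp
  imp0$scores$importance <- rep(0, 10)
  expect_equal(select_panel(imp0, 4)$cdr3_aa, sort(imp$scores$cdr3_aa)[1:4])
})

test_that("retraining on the full feature set reproduces the all-features run", {
  fm <- make_imp_fm(seed = 6)
  sp <- stratified_split(fm, 0.3, seed = 2)
  spec <- model_spec("logistic_regression", seed = 8)
  imp <- permutation_importance_cv(spec, sp$train, seed = 15)
  panel_full <- select_panel(imp, 10)
  # restrict to a panel equal to the full feature set, in vocabulary order
  panel_ord <- panel_full[match(colnames(fm$X), panel_full$cdr3_aa), ]
  class(panel_ord) <- class(panel_full)
  ev_panel <- retrain_on_panel(spec, sp$train, sp$test, panel_ord)
  cv <- grid_search_cv(spec, sp$train)
  ev_all <- evaluate(fit_final(spec, cv$best_params, sp$train), sp$test)
  expect_equal(ev_panel$auc, ev_all$auc)
  expect_equal(ev_panel$scores, ev_all$scores)
  expect_equal(attr(ev_panel, "panel_size"), 10)
})

test_that("panel recovery scoring counts the overlap fraction", {
  panel <- data.frame(cdr3_aa = c("CAF", "CDF", "CEF"), v_gene = "V",
                      j_gene = "J", importance = 3:1)
  class(panel) <- c("tcr_panel", "data.frame")
  truth <- list(signature = data.frame(cdr3_aa = c("CAF", "CDF", "CHF",
                                                   "CIF")))
  expect_equal(panel_recovery_score(panel, truth), 2 / 3)
  truth2 <- list(signature = data.frame(cdr3_aa = c("CXF")))
  expect_equal(panel_recovery_score(panel, truth2), 0)
  expect_error(panel_recovery_score(panel,
                                    list(signature = data.frame(cdr3_aa = character(0)))),
               "no signature")
})
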