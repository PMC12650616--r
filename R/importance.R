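# Cross-validated permutation importance and biomarker-panel selection.
#
# Within stratified k-fold CV: fit on the training part, score the intact
# validation part, then shuffle each validation column n_repeats times
# (fresh seeded permutation per fold x feature x repeat) and record the
# baseline-minus-permuted metric. A feature's importance is the mean drop
# over repeats, then over folds. Shuffling happens on a copy; the stored
# matrix is never mutated.

#' Permutation feature importance under stratified cross-validation
#'
#' @param spec a `tcr_model_spec`; its default (or supplied) first grid
#'   point's hyperparameters are used for the per-fold fits unless
#'   `params` is given.
#' @param fm a `tcr_feature_matrix`.
#' @param n_repeats shuffles per feature per fold (default 5).
#' @param k folds (default 5).
#' @param metric `"auc"` (default) or `"accuracy"`.
#' @param seed master seed for folds, fits and shuffles.
#' @param params optional fixed hyperparameters for the per-fold fits.
#' @return a `tcr_importance`: data.frame `scores` (`cdr3_aa`, `v_gene`,
#'   `j_gene`, `importance`, per-fold means), `raw` array
#'   (feature x fold x repeat), `metric`, `baseline` per fold.
#' @export
permutation_importance_cv <- function(spec, fm, n_repeats = 5, k = 5,
                                      metric = c("auc", "accuracy"),
                                      seed = 1, params = NULL) {
  stopifnot(inherits(spec, "tcr_model_spec"), inherits(fm, "tcr_feature_matrix"))
  metric <- match.arg(metric)
  if (is.null(params)) params <- .expand_grid_points(spec$grid)[[1]]
  score_fun <- function(s, y) {
    if (metric == "auc") auc_score(s, y) else mean((s >= 0.5) == y)
  }
  m <- ncol(fm$X)
  folds <- stratified_kfold(fm$y, k, seed = derive_seed(seed, "impfolds"))
  raw <- array(NA_real_, dim = c(m, k, n_repeats),
               dimnames = list(colnames(fm$X), NULL, NULL))
  baseline <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    val_idx <- folds[[f]]$val_idx
    yv <- fm$y[val_idx]
    if (length(unique(yv)) < 2 && metric == "auc") {
      warning("fold ", f, " validation part has a single class; skipped",
              call. = FALSE)
      next
    }
    mod <- fit_model(spec$family, params, fm_subset(fm, folds[[f]]$train_idx),
                     seed = derive_seed(seed, paste0("impfit", f)))
    Xv <- fm$X[val_idx, , drop = FALSE]
    baseline[f] <- score_fun(predict_score(mod, Xv), yv)
    nv <- length(val_idx)
    block <- rep(seq_len(n_repeats), each = nv)
    for (j in seq_len(m)) {
      # all repeats for one feature are scored in a single stacked call;
      # the stored matrix is only ever copied, never mutated
      Xp <- Xv[rep(seq_len(nv), n_repeats), , drop = FALSE]
      for (r in seq_len(n_repeats)) {
        perm <- with_seed(derive_seed(seed, paste0("sh", f, "_", j, "_", r)),
                          sample.int(nv))
        Xp[block == r, j] <- Xv[perm, j]
      }
      s_all <- predict_score(mod, Xp)
      for (r in seq_len(n_repeats))
        raw[j, f, r] <- baseline[f] - score_fun(s_all[block == r], yv)
    }
  }
  used <- which(!is.na(baseline))
  if (length(used) == 0) stop("no usable folds", call. = FALSE)
  per_fold <- apply(raw[, used, , drop = FALSE], c(1, 2), mean)
  importance <- rowMeans(per_fold)
  vocab <- fm$vocabulary
  scores <- data.frame(cdr3_aa = colnames(fm$X),
                       v_gene = vocab$v_gene[match(colnames(fm$X),
                                                   vocab$cdr3_aa)],
                       j_gene = vocab$j_gene[match(colnames(fm$X),
                                                   vocab$cdr3_aa)],
                       importance = unname(importance),
                       stringsAsFactors = FALSE)
  fold_cols <- as.data.frame(per_fold)
  names(fold_cols) <- paste0("fold", used)
  scores <- cbind(scores, fold_cols)
  structure(list(scores = scores, raw = raw, metric = metric,
                 baseline = baseline, n_repeats = n_repeats, k = k,
                 family = spec$family),
            class = "tcr_importance")
}

#' Select the top-k biomarker panel from an importance report
#'
#' @param report a `tcr_importance`.
#' @param k panel size (default 50). Ties at the boundary break
#'   lexicographically on CDR3.
#' @return a `tcr_panel` data.frame: `cdr3_aa`, `v_gene`, `j_gene`,
#'   `importance`, sorted by importance descending.
#' @export
select_panel <- function(report, k = 50) {
  stopifnot(inherits(report, "tcr_importance"))
  sc <- report$scores
  if (k > nrow(sc))
    stop("k (", k, ") exceeds feature count (", nrow(sc), ")", call. = FALSE)
  ord <- order(-sc$importance, sc$cdr3_aa)
  out <- sc[ord[seq_len(k)], c("cdr3_aa", "v_gene", "j_gene", "importance")]
  rownames(out) <- NULL
  class(out) <- c("tcr_panel", "data.frame")
  out
}

#' Retrain and evaluate a family on a biomarker panel
#'
#' Restricts both matrices to the panel columns, reruns the grid search and
#' final fit, and evaluates on the restricted test matrix.
#'
#' @param spec a `tcr_model_spec`.
#' @param fm_train,fm_eval feature matrices over the full vocabulary.
#' @param panel a `tcr_panel` (its CDR3s must be vocabulary members).
#' @param k CV folds for the rerun grid search.
#' @return a `tcr_eval` with attribute `"panel_size"`.
#' @export
retrain_on_panel <- function(spec, fm_train, fm_eval, panel, k = 5) {
  stopifnot(inherits(panel, "tcr_panel"))
  tr <- fm_select_features(fm_train, panel$cdr3_aa)
  ev <- fm_select_features(fm_eval, panel$cdr3_aa)
  cv <- grid_search_cv(spec, tr, k = k)
  mod <- fit_final(spec, cv$best_params, tr)
  out <- evaluate(mod, ev)
  attr(out, "panel_size") <- nrow(panel)
  out
}

#' Fraction of ground-truth signature clonotypes recovered by a panel
#'
#' `|panel intersect signature| / min(|panel|, |signature|)` — 1 means the
#' panel contains every spiked clonotype it could.
#'
#' @param panel a `tcr_panel`.
#' @param truth ground-truth list from [generate_cohort()].
#' @return recovery fraction in `[0, 1]`.
#' @export
panel_recovery_score <- function(panel, truth) {
  sig <- truth$signature$cdr3_aa
  if (length(sig) == 0) stop("ground truth has no signature clonotypes",
                             call. = FALSE)
  length(intersect(panel$cdr3_aa, sig)) / min(nrow(panel), length(sig))
}
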