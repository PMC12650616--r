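# Clonotype feature construction: a global CDR3 vocabulary ranked by summed
# frequency, ANOVA F-value reduction, per-sample frequency vectors with zero
# imputation for absent sequences, and stratified train/test splitting.

#' Build a CDR3 feature vocabulary
#'
#' Ranks unique CDR3 amino-acid sequences by their summed per-sample
#' frequency (or, optionally, by presence count) across the in-scope samples
#' and keeps the top `top_k`. Ties break lexicographically. Each vocabulary
#' entry carries a majority V/J annotation (the V-J pair holding the largest
#' share of that CDR3's reads).
#'
#' `scope = "train_only"` restricts ranking to `train_idx` (leakage-safe
#' default for model building); `scope = "global"` ranks over every sample.
#'
#' @param cohort a `tcr_cohort`.
#' @param top_k vocabulary size (default 1000).
#' @param scope `"train_only"` or `"global"`.
#' @param train_idx integer indices of training samples (required for
#'   `train_only` scope).
#' @param rank_by `"frequency"` (summed relative frequency, default) or
#'   `"presence"` (number of samples carrying the sequence).
#' @return a `tcr_vocabulary` data.frame: `cdr3_aa`, `v_gene`, `j_gene`,
#'   `total_freq`, `presence`, `rank`.
#' @export
build_vocabulary <- function(cohort, top_k = 1000,
                             scope = c("train_only", "global"),
                             train_idx = NULL,
                             rank_by = c("frequency", "presence")) {
  stopifnot(inherits(cohort, "tcr_cohort"), top_k >= 1)
  scope <- match.arg(scope)
  rank_by <- match.arg(rank_by)
  idx <- if (scope == "train_only") {
    if (is.null(train_idx))
      stop("train_idx is required for scope = 'train_only'", call. = FALSE)
    train_idx
  } else seq_along(cohort$repertoires)
  message("build_vocabulary: ranking over ", length(idx), " sample(s), scope=",
          scope)
  freqs <- lapply(cohort$repertoires[idx], cdr3_frequencies)
  all_cdr3 <- unlist(lapply(freqs, names), use.names = FALSE)
  all_val <- unlist(freqs, use.names = FALSE)
  tot <- rowsum(all_val, all_cdr3)
  pres <- rowsum(rep(1L, length(all_cdr3)), all_cdr3)
  total_freq <- stats::setNames(tot[, 1], rownames(tot))
  presence <- stats::setNames(pres[, 1], rownames(pres))[names(total_freq)]
  score <- if (rank_by == "frequency") total_freq else presence
  ord <- order(-score, names(score))
  if (length(ord) < top_k)
    warning("only ", length(ord), " unique CDR3s available for top_k = ",
            top_k, "; returning all", call. = FALSE)
  keep <- names(score)[ord][seq_len(min(top_k, length(ord)))]

  # majority V/J annotation, weighted by read frequency across in-scope samples
  recs <- do.call(rbind, lapply(cohort$repertoires[idx], function(r)
    r$records[r$records$cdr3_aa %in% keep,
              c("cdr3_aa", "v_gene", "j_gene", "frequency")]))
  vj_key <- paste(recs$cdr3_aa, recs$v_gene, recs$j_gene, sep = "\r")
  vj_tot <- rowsum(recs$frequency, vj_key)
  parts <- strsplit(rownames(vj_tot), "\r", fixed = TRUE)
  vj <- data.frame(cdr3_aa = vapply(parts, `[`, "", 1),
                   v_gene = vapply(parts, `[`, "", 2),
                   j_gene = vapply(parts, `[`, "", 3),
                   w = vj_tot[, 1], stringsAsFactors = FALSE)
  vj <- vj[order(vj$cdr3_aa, -vj$w, vj$v_gene, vj$j_gene), , drop = FALSE]
  vj <- vj[!duplicated(vj$cdr3_aa), , drop = FALSE]
  m <- match(keep, vj$cdr3_aa)
  out <- data.frame(cdr3_aa = keep,
                    v_gene = vj$v_gene[m], j_gene = vj$j_gene[m],
                    total_freq = unname(total_freq[keep]),
                    presence = unname(presence[keep]),
                    rank = seq_along(keep), stringsAsFactors = FALSE)
  class(out) <- c("tcr_vocabulary", "data.frame")
  out
}

#' Two-group one-way ANOVA F statistics per feature column
#'
#' Closed-form between-over-within mean-square ratio, vectorized over
#' columns. All-constant columns get `F = 0`; columns separating the groups
#' perfectly (zero within-group variance, nonzero between) get `Inf`.
#'
#' @param X numeric matrix (samples x features).
#' @param y binary labels (two distinct values).
#' @return numeric vector of F scores, one per column.
#' @export
anova_f_scores <- function(X, y) {
  X <- as.matrix(X)
  groups <- unique(y)
  if (length(groups) != 2) stop("y must contain exactly two classes",
                                call. = FALSE)
  n <- nrow(X)
  idx1 <- y == groups[1]
  n1 <- sum(idx1); n2 <- n - n1
  m1 <- colMeans(X[idx1, , drop = FALSE])
  m2 <- colMeans(X[!idx1, , drop = FALSE])
  gm <- (n1 * m1 + n2 * m2) / n
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ssw <- colSums((X[idx1, , drop = FALSE] - rep(m1, each = n1))^2) +
         colSums((X[!idx1, , drop = FALSE] - rep(m2, each = n2))^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  f[ssb == 0] <- 0          # constant or equal-mean columns
  f[ssb > 0 & ssw == 0] <- Inf
  f
}

#' Reduce a feature matrix's vocabulary by ANOVA F-value selection
#'
#' Keeps the `m_out` columns with the highest two-group F statistic
#' (ties lexicographic on CDR3).
#'
#' @param fm a `tcr_feature_matrix` over the candidate vocabulary.
#' @param m_out target number of features (default 500).
#' @return the reduced `tcr_vocabulary` with an `f_score` column.
#' @export
anova_reduce <- function(fm, m_out = 500) {
  stopifnot(inherits(fm, "tcr_feature_matrix"))
  vocab <- fm$vocabulary
  if (m_out > nrow(vocab))
    stop("m_out (", m_out, ") exceeds vocabulary size (", nrow(vocab), ")",
         call. = FALSE)
  f <- anova_f_scores(fm$X, fm$y)
  ord <- order(-f, vocab$cdr3_aa)
  keep <- sort(ord[seq_len(m_out)])  # preserve original rank order
  out <- vocab[keep, , drop = FALSE]
  out$f_score <- f[keep]
  rownames(out) <- NULL
  class(out) <- c("tcr_vocabulary", "data.frame")
  out
}

#' Vectorize a cohort against a feature vocabulary
#'
#' `X[i, j]` is sample i's aggregated frequency of vocabulary CDR3 j, zero
#' when the sample lacks the sequence. Labels are encoded 1 = CRC, 0 = HC.
#'
#' @param cohort a `tcr_cohort`.
#' @param vocab a `tcr_vocabulary`.
#' @return a `tcr_feature_matrix`: list with matrix `X` (dimnames = sample
#'   ids x CDR3s), integer `y`, `sample_ids`, and the `vocabulary`.
#' @export
vectorize <- function(cohort, vocab) {
  stopifnot(inherits(cohort, "tcr_cohort"), inherits(vocab, "tcr_vocabulary"))
  X <- t(vapply(cohort$repertoires, function(r) {
    p <- cdr3_frequencies(r)
    out <- numeric(nrow(vocab))
    m <- match(vocab$cdr3_aa, names(p))
    hit <- !is.na(m)
    out[hit] <- p[m[hit]]
    out
  }, numeric(nrow(vocab))))
  dimnames(X) <- list(cohort$sample_ids, vocab$cdr3_aa)
  structure(list(X = X, y = as.integer(cohort$labels == "CRC"),
                 sample_ids = cohort$sample_ids, vocabulary = vocab),
            class = "tcr_feature_matrix")
}

#' @export
print.tcr_feature_matrix <- function(x, ...) {
  cat(sprintf("<tcr_feature_matrix> %d samples x %d features (%d positive)\n",
              nrow(x$X), ncol(x$X), sum(x$y)))
  invisible(x)
}

#' Subset a feature matrix by row (sample) indices
#' @param fm a `tcr_feature_matrix`.
#' @param idx integer row indices.
#' @return a `tcr_feature_matrix` restricted to those samples.
#' @export
fm_subset <- function(fm, idx) {
  structure(list(X = fm$X[idx, , drop = FALSE], y = fm$y[idx],
                 sample_ids = fm$sample_ids[idx],
                 vocabulary = fm$vocabulary),
            class = "tcr_feature_matrix")
}

#' Restrict a feature matrix to a subset of features
#' @param fm a `tcr_feature_matrix`.
#' @param cdr3s character vector of vocabulary CDR3s to keep (order kept as
#'   given).
#' @return a `tcr_feature_matrix` over the restricted vocabulary.
#' @export
fm_select_features <- function(fm, cdr3s) {
  missing_f <- setdiff(cdr3s, colnames(fm$X))
  if (length(missing_f))
    stop("features absent from the vocabulary: ",
         paste(utils::head(missing_f, 5), collapse = ", "), call. = FALSE)
  vocab <- fm$vocabulary[match(cdr3s, fm$vocabulary$cdr3_aa), , drop = FALSE]
  rownames(vocab) <- NULL
  class(vocab) <- c("tcr_vocabulary", "data.frame")
  structure(list(X = fm$X[, cdr3s, drop = FALSE], y = fm$y,
                 sample_ids = fm$sample_ids, vocabulary = vocab),
            class = "tcr_feature_matrix")
}

#' Stratified train/test index split
#'
#' Per-class test counts are the largest-remainder apportionment of
#' `round(n * test_fraction)` across classes (floors first, remaining seats
#' by descending fractional remainder), so overall and per-class proportions
#' are both honored to within one sample. Sample assignment within a class
#' is a seeded shuffle.
#'
#' @param labels per-sample class labels.
#' @param test_fraction fraction of samples held out (default 0.30).
#' @param seed split seed.
#' @return list with integer `train_idx` and `test_idx`.
#' @export
stratified_split_idx <- function(labels, test_fraction = 0.30, seed = 1) {
  n <- length(labels)
  classes <- sort(unique(labels))
  n_by <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  if (any(n_by < 2))
    stop("every class needs >= 2 samples to stratify", call. = FALSE)
  target_total <- round(n * test_fraction)
  raw <- n_by * test_fraction
  base <- floor(raw)
  rem <- target_total - sum(base)
  if (rem > 0) {
    extra_ord <- order(-(raw - base), classes)
    base[extra_ord[seq_len(rem)]] <- base[extra_ord[seq_len(rem)]] + 1
  } else if (rem < 0) {
    cut_ord <- order(raw - base, classes)
    base[cut_ord[seq_len(-rem)]] <- base[cut_ord[seq_len(-rem)]] - 1
  }
  test_idx <- integer(0)
  with_seed(seed, {
    for (ci in seq_along(classes)) {
      members <- which(labels == classes[ci])
      test_idx <- c(test_idx, sample(members)[seq_len(base[ci])])
    }
  })
  test_idx <- sort(test_idx)
  list(train_idx = setdiff(seq_len(n), test_idx), test_idx = test_idx)
}

#' Stratified split of a feature matrix
#'
#' @param fm a `tcr_feature_matrix`.
#' @param test_fraction fraction held out (default 0.30).
#' @param seed split seed.
#' @return list with `train` and `test` feature matrices and the index split.
#' @export
stratified_split <- function(fm, test_fraction = 0.30, seed = 1) {
  stopifnot(inherits(fm, "tcr_feature_matrix"))
  idx <- stratified_split_idx(fm$y, test_fraction, seed)
  list(train = fm_subset(fm, idx$train_idx),
       test = fm_subset(fm, idx$test_idx),
       train_idx = idx$train_idx, test_idx = idx$test_idx)
}
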