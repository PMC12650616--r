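# Per-sample repertoire statistics and case/control comparison machinery.
#
# Diversity and clonality are defined on the per-CDR3 frequency distribution
# (V/J variants of the same amino-acid sequence aggregated):
#   H = -sum_i p_i log2 p_i          (Shannon diversity, bits)
#   clonality = 1 - H / log2(N)      (0 = perfectly even, -> 1 oligoclonal)
# N is the number of unique CDR3 amino-acid sequences. Clonality is defined
# as 0 for N = 1: a single-clone repertoire has no evenness deficit to
# normalize, and the 0/0 limit is taken as 0 by convention.

#' Shannon diversity of a repertoire (bits)
#'
#' @param rep a `tcr_repertoire`.
#' @return entropy of the aggregated per-CDR3 frequency distribution, in
#'   bits, with the `0 * log 0 = 0` convention.
#' @export
shannon_diversity <- function(rep) {
  p <- cdr3_frequencies(rep)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Clonality of a repertoire
#'
#' `1 - H / log2(N)`; 0 for a perfectly even repertoire and approaching 1
#' under extreme clonal expansion. Defined as 0 when `N = 1`.
#'
#' @param rep a `tcr_repertoire`.
#' @return clonality in `[0, 1]`.
#' @export
clonality <- function(rep) {
  n <- rep$n_unique
  if (n <= 1) return(0)
  1 - shannon_diversity(rep) / log2(n)
}

#' High-expansion clone (HEC) statistics
#'
#' A HEC is a unique CDR3 whose aggregated frequency is strictly above the
#' threshold (default 0.5% of a sample's reads).
#'
#' @param rep a `tcr_repertoire`.
#' @param threshold frequency threshold (default `0.005`).
#' @return list with `hec_count` and `hec_ratio` (= count / n_unique).
#' @export
hec_stats <- function(rep, threshold = 0.005) {
  p <- cdr3_frequencies(rep)
  cnt <- sum(p > threshold)
  list(hec_count = cnt, hec_ratio = cnt / rep$n_unique)
}

#' Frequency-weighted CDR3 length spectrum
#'
#' @param rep a `tcr_repertoire`.
#' @param split_at length dichotomy point (default 14).
#' @return list with `length_histogram` (named numeric, mass per length,
#'   summing to 1) and `fraction_le_split` (mass at lengths `<= split_at`).
#' @export
cdr3_length_summary <- function(rep, split_at = 14) {
  p <- cdr3_frequencies(rep)
  lens <- nchar(names(p))
  h <- rowsum(unname(p), lens)
  hist <- stats::setNames(h[, 1], rownames(h))
  list(length_histogram = hist,
       fraction_le_split = sum(hist[as.integer(names(hist)) <= split_at]))
}

#' V or J gene segment usage of a repertoire
#'
#' @param rep a `tcr_repertoire`.
#' @param segment `"V"` or `"J"`.
#' @param weighting `"read"` (sum of clone frequencies) or `"clone"`
#'   (fraction of unique clonotype records).
#' @return named numeric usage fractions summing to 1.
#' @export
gene_usage <- function(rep, segment = c("V", "J"),
                       weighting = c("read", "clone")) {
  segment <- match.arg(segment)
  weighting <- match.arg(weighting)
  genes <- if (segment == "V") rep$records$v_gene else rep$records$j_gene
  w <- if (weighting == "read") rep$records$frequency
       else rep(1 / nrow(rep$records), nrow(rep$records))
  u <- rowsum(w, genes)
  u <- stats::setNames(u[, 1], rownames(u))
  u / sum(u)
}

#' Summarize one repertoire
#'
#' @param rep a `tcr_repertoire`.
#' @param hec_threshold HEC frequency threshold.
#' @param length_split CDR3 length dichotomy point.
#' @return one-row data.frame: `sample_id`, `n_unique`, `total_reads`,
#'   `shannon_bits`, `clonality`, `hec_count`, `hec_ratio`,
#'   `fraction_le_14`.
#' @export
summarize_repertoire <- function(rep, hec_threshold = 0.005,
                                 length_split = 14) {
  hec <- hec_stats(rep, hec_threshold)
  len <- cdr3_length_summary(rep, length_split)
  data.frame(sample_id = rep$sample_id, n_unique = rep$n_unique,
             total_reads = rep$total_reads,
             shannon_bits = shannon_diversity(rep),
             clonality = clonality(rep),
             hec_count = hec$hec_count, hec_ratio = hec$hec_ratio,
             fraction_le_14 = len$fraction_le_split,
             stringsAsFactors = FALSE)
}

#' Per-sample summary table for a cohort
#'
#' @param cohort a `tcr_cohort`.
#' @param ... passed to [summarize_repertoire()].
#' @return data.frame with one row per sample plus `label` and `batch`.
#' @export
cohort_summary <- function(cohort, ...) {
  stopifnot(inherits(cohort, "tcr_cohort"))
  out <- do.call(rbind, lapply(cohort$repertoires, summarize_repertoire, ...))
  out$label <- cohort$labels
  out$batch <- cohort$batch_ids
  out
}

#' Rank disease-specific CDR3 sequences by occurrence
#'
#' Keeps CDR3s seen in at least one case sample and no control sample, ranked
#' by the number of case samples containing them (descending; ties broken
#' lexicographically).
#'
#' @param cohort a `tcr_cohort` containing both classes.
#' @param top_n maximum number of sequences returned.
#' @return data.frame with `cdr3_aa` and `occurrence` (number of case
#'   samples carrying the sequence).
#' @export
disease_specific_ranking <- function(cohort, top_n = 30) {
  stopifnot(inherits(cohort, "tcr_cohort"))
  if (length(unique(cohort$labels)) < 2)
    stop("cohort must contain both CRC and HC samples", call. = FALSE)
  seqs_by_sample <- lapply(cohort$repertoires,
                           function(r) unique(r$records$cdr3_aa))
  crc_seqs <- unlist(seqs_by_sample[cohort$labels == "CRC"])
  hc_seqs <- unique(unlist(seqs_by_sample[cohort$labels == "HC"]))
  occ <- table(crc_seqs[!(crc_seqs %in% hc_seqs)])
  if (length(occ) == 0)
    return(data.frame(cdr3_aa = character(0), occurrence = integer(0)))
  out <- data.frame(cdr3_aa = names(occ), occurrence = as.integer(occ),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$occurrence, out$cdr3_aa), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_n)
}

#' Two-sided Mann-Whitney U test
#'
#' Thin wrapper around [stats::wilcox.test()] returning the U statistic and
#' two-sided p value: exact for tie-free small samples, normal approximation
#' with tie and continuity correction otherwise.
#'
#' @param x,y numeric group samples (non-empty).
#' @return list with `U` (statistic for `x`) and `p`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  if (all(x == x[1]) && all(y == y[1]) && x[1] == y[1])
    return(list(U = length(x) * length(y) / 2, p = 1))
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            exact = NULL, correct = TRUE))
  list(U = unname(wt$statistic), p = min(1, wt$p.value))
}

#' Benjamini-Hochberg (or Benjamini-Yekutieli) FDR adjustment
#'
#' @param pvalues numeric vector of p values in `[0, 1]`.
#' @param method `"BH"` (default) or `"BY"`.
#' @return adjusted q values, same order as input.
#' @export
fdr_adjust <- function(pvalues, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = method)
}

.significance_tier <- function(q) {
  cut(q, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", "ns"), right = FALSE) |> as.character()
}

#' Case/control comparison of per-sample features with FDR control
#'
#' Runs a two-sided Mann-Whitney U test per feature column and adjusts the
#' p values jointly across the supplied feature family. All-constant
#' features are flagged with `p = 1`.
#'
#' @param features data.frame or matrix of per-sample feature values (rows
#'   aligned with `labels`).
#' @param labels character vector of `"CRC"` / `"HC"` per row.
#' @param method FDR method passed to [fdr_adjust()].
#' @return data.frame with one row per feature: `feature`, `median_crc`,
#'   `median_hc`, `U`, `p`, `q`, `tier` (`***`/`**`/`*`/`ns`), `degenerate`.
#' @export
compare_groups <- function(features, labels, method = "BH") {
  features <- as.data.frame(features)
  stopifnot(nrow(features) == length(labels))
  if (length(unique(labels)) < 2)
    stop("both classes must be represented", call. = FALSE)
  crc <- labels == "CRC"
  rows <- lapply(names(features), function(nm) {
    v <- as.numeric(features[[nm]])
    degenerate <- length(unique(v)) == 1L
    mw <- if (degenerate) list(U = sum(crc) * sum(!crc) / 2, p = 1)
          else mann_whitney_u(v[crc], v[!crc])
    data.frame(feature = nm,
               median_crc = stats::median(v[crc]),
               median_hc = stats::median(v[!crc]),
               U = mw$U, p = mw$p, degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- fdr_adjust(out$p, method = method)
  out$tier <- .significance_tier(out$q)
  out[c("feature", "median_crc", "median_hc", "U", "p", "q", "tier",
        "degenerate")]
}

#' Cohort-wide gene-usage table
#'
#' One row per sample, one column per gene segment observed anywhere in the
#' cohort (absent segments at 0); useful as input to [compare_groups()].
#'
#' @param cohort a `tcr_cohort`.
#' @param segment `"V"` or `"J"`.
#' @param weighting passed to [gene_usage()].
#' @return data.frame of usage fractions, rows aligned with cohort samples.
#' @export
cohort_gene_usage <- function(cohort, segment = c("V", "J"),
                              weighting = c("read", "clone")) {
  segment <- match.arg(segment)
  weighting <- match.arg(weighting)
  per_sample <- lapply(cohort$repertoires, gene_usage,
                       segment = segment, weighting = weighting)
  genes <- sort(unique(unlist(lapply(per_sample, names))))
  m <- t(vapply(per_sample, function(u) {
    out <- stats::setNames(numeric(length(genes)), genes)
    out[names(u)] <- u
    out
  }, numeric(length(genes))))
  out <- as.data.frame(m)
  rownames(out) <- cohort$sample_ids
  out
}
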