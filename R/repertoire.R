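# Core containers: a repertoire (one sample's clonotype table) and a cohort
# (labeled, batch-annotated collection of repertoires).

#' Construct a repertoire from clonotype records
#'
#' A repertoire holds one sample's clonotypes: each record is a unique
#' (CDR3 amino-acid sequence, V gene, J gene) triple with a read count and,
#' after finalization, a frequency (fraction of the sample's total reads).
#' Duplicate triples are merged by summing counts; zero-count records are
#' kept only if `keep_zero = TRUE` (scaled pseudo-counts are real-valued, so
#' counts need not be integer).
#'
#' @param sample_id sample identifier.
#' @param records data.frame with columns `cdr3_aa`, `v_gene`, `j_gene`,
#'   `count` (and optionally `frequency`, which is recomputed).
#' @param keep_zero keep zero-count records (default drops them).
#' @return an object of class `tcr_repertoire` with fields `sample_id`,
#'   `records`, `total_reads` and `n_unique` (distinct CDR3 amino-acid
#'   sequences, the N of the diversity formulas).
#' @export
repertoire <- function(sample_id, records, keep_zero = FALSE) {
  stopifnot(is.data.frame(records))
  needed <- c("cdr3_aa", "v_gene", "j_gene", "count")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("records is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  rec <- records[needed]
  rec$cdr3_aa <- as.character(rec$cdr3_aa)
  rec$v_gene <- as.character(rec$v_gene)
  rec$j_gene <- as.character(rec$j_gene)
  rec$count <- as.numeric(rec$count)
  if (any(rec$count < 0)) stop("negative clonotype counts", call. = FALSE)
  if (!all(is_productive_cdr3(rec$cdr3_aa)))
    stop("records contain empty or nonproductive CDR3 sequences; ",
         "use read_clonotype_table() to filter at ingest", call. = FALSE)
  # merge duplicate (cdr3, V, J) triples
  key <- paste(rec$cdr3_aa, rec$v_gene, rec$j_gene, sep = "\r")
  if (anyDuplicated(key)) {
    cnt <- rowsum(rec$count, key)
    ord <- match(rownames(cnt), key)
    rec <- rec[ord, , drop = FALSE]
    rec$count <- cnt[, 1]
  }
  if (!keep_zero) rec <- rec[rec$count > 0, , drop = FALSE]
  rec <- rec[order(-rec$count, rec$cdr3_aa, rec$v_gene, rec$j_gene), ,
             drop = FALSE]
  rownames(rec) <- NULL
  total <- sum(rec$count)
  if (total <= 0)
    stop("empty repertoire: total read count is zero for sample ",
         sample_id, call. = FALSE)
  rec$frequency <- rec$count / total
  structure(
    list(sample_id = as.character(sample_id), records = rec,
         total_reads = total,
         n_unique = length(unique(rec$cdr3_aa))),
    class = "tcr_repertoire")
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat(sprintf("<tcr_repertoire> %s: %d records, %d unique CDR3, %.0f reads\n",
              x$sample_id, nrow(x$records), x$n_unique, x$total_reads))
  invisible(x)
}

#' Per-CDR3 aggregated frequencies of a repertoire
#'
#' Sums record frequencies over V/J variants of the same CDR3 amino-acid
#' sequence. This is the distribution on which diversity, clonality and
#' high-expansion-clone statistics are defined.
#'
#' @param rep a `tcr_repertoire`.
#' @return named numeric vector of frequencies (names are CDR3 sequences),
#'   summing to 1.
#' @export
cdr3_frequencies <- function(rep) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  f <- rowsum(rep$records$frequency, rep$records$cdr3_aa)
  stats::setNames(f[, 1], rownames(f))
}

#' Assemble a labeled cohort from repertoires and a metadata table
#'
#' @param repertoires list of `tcr_repertoire` objects.
#' @param metadata data.frame with columns `sample_id`, `label` (one of
#'   `"CRC"`, `"HC"`) and `batch`.
#' @return a `tcr_cohort`: list with `repertoires`, `labels`, `batch_ids`
#'   and `sample_ids`, all aligned positionally with the input repertoires.
#' @export
assemble_cohort <- function(repertoires, metadata) {
  stopifnot(is.list(repertoires), is.data.frame(metadata))
  needed <- c("sample_id", "label", "batch")
  missing_cols <- setdiff(needed, names(metadata))
  if (length(missing_cols))
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  ids <- vapply(repertoires, function(r) r$sample_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate sample_id among repertoires: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata", call. = FALSE)
  bad_label <- setdiff(unique(as.character(metadata$label)), c("CRC", "HC"))
  if (length(bad_label))
    stop("unknown label(s): ", paste(bad_label, collapse = ", "),
         "; labels must be 'CRC' or 'HC'", call. = FALSE)
  absent <- setdiff(metadata$sample_id, ids)
  if (length(absent))
    stop("metadata lists sample(s) with no repertoire: ",
         paste(absent, collapse = ", "), call. = FALSE)
  unlabeled <- setdiff(ids, metadata$sample_id)
  if (length(unlabeled))
    stop("repertoire(s) missing from metadata: ",
         paste(unlabeled, collapse = ", "), call. = FALSE)
  m <- match(ids, metadata$sample_id)
  structure(
    list(repertoires = repertoires,
         sample_ids = ids,
         labels = as.character(metadata$label)[m],
         batch_ids = as.character(metadata$batch)[m]),
    class = "tcr_cohort")
}

#' @export
print.tcr_cohort <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<tcr_cohort> %d samples (%s), %d batch(es)\n",
              length(x$repertoires),
              paste(names(tab), tab, sep = ":", collapse = ", "),
              length(unique(x$batch_ids))))
  invisible(x)
}

#' Number of samples in a cohort
#' @param cohort a `tcr_cohort`.
#' @return integer sample count.
#' @export
n_samples <- function(cohort) length(cohort$repertoires)

#' Proportional-scaling depth normalization across cohorts
#'
#' Rescales every sample's clone counts so that its total matches the
#' baseline batch's anchor total (the median, or optionally mean, of the
#' baseline samples' totals). Scaling is uniform within a sample, so every
#' per-clone frequency is unchanged; scaled counts are real-valued
#' pseudo-counts.
#'
#' @param cohort a `tcr_cohort`.
#' @param baseline_batch batch id whose depth anchors the others.
#' @param anchor `"median"` (default, robust to depth outliers) or `"mean"`.
#' @return a new `tcr_cohort` with rescaled counts.
#' @export
proportional_scale_normalize <- function(cohort, baseline_batch,
                                         anchor = c("median", "mean")) {
  stopifnot(inherits(cohort, "tcr_cohort"))
  anchor <- match.arg(anchor)
  in_base <- cohort$batch_ids == baseline_batch
  if (!any(in_base))
    stop("baseline batch '", baseline_batch, "' has no samples", call. = FALSE)
  totals <- vapply(cohort$repertoires, function(r) r$total_reads, numeric(1))
  target <- if (anchor == "median") stats::median(totals[in_base])
            else mean(totals[in_base])
  reps <- lapply(cohort$repertoires, function(r) {
    s <- target / r$total_reads
    rec <- r$records
    rec$count <- rec$count * s
    repertoire(r$sample_id, rec)
  })
  out <- cohort
  out$repertoires <- reps
  out
}
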