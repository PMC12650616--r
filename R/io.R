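# Clonotype-table ingest/egress. Three dialects are recognized:
#   airr   — AIRR Rearrangement TSV (junction_aa, v_call, j_call,
#            duplicate_count)
#   mixcr  — MiXCR clone export TSV (aaSeqCDR3, allVHitsWithScore,
#            allJHitsWithScore, cloneCount)
#   simple — the package's own 4-column TSV (cdr3_aa, v_gene, j_gene, count)
# Rows with empty or nonproductive CDR3s (stop '*' / frameshift '_') are
# dropped at read time and counted in a skip tally.

.dialect_columns <- list(
  airr   = c(cdr3_aa = "junction_aa", v_gene = "v_call",
             j_gene = "j_call", count = "duplicate_count"),
  mixcr  = c(cdr3_aa = "aaSeqCDR3", v_gene = "allVHitsWithScore",
             j_gene = "allJHitsWithScore", count = "cloneCount"),
  simple = c(cdr3_aa = "cdr3_aa", v_gene = "v_gene",
             j_gene = "j_gene", count = "count")
)

#' Read a per-sample clonotype table
#'
#' Parses one sample's clonotype export into a finalized [repertoire()].
#' V/J names are normalized (allele suffixes and alignment-score annotations
#' stripped; multi-hit fields keep the best hit), nonproductive rows are
#' skipped, and duplicate (CDR3, V, J) rows are merged by summing counts.
#'
#' @param path path to a TSV file.
#' @param dialect one of `"simple"`, `"airr"`, `"mixcr"`.
#' @param sample_id sample identifier; defaults to the file name without
#'   extension.
#' @return a `tcr_repertoire`; the number of skipped (nonproductive) rows is
#'   attached as attribute `"skipped"`.
#' @export
read_clonotype_table <- function(path, dialect = c("simple", "airr", "mixcr"),
                                 sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cols <- .dialect_columns[[dialect]]
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(unname(cols), names(tab))
  if (length(missing_cols))
    stop("clonotype table (dialect '", dialect, "') is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  rec <- data.frame(cdr3_aa = as.character(tab[[cols[["cdr3_aa"]]]]),
                    v_gene = normalize_gene(tab[[cols[["v_gene"]]]]),
                    j_gene = normalize_gene(tab[[cols[["j_gene"]]]]),
                    count = as.numeric(tab[[cols[["count"]]]]),
                    stringsAsFactors = FALSE)
  keep <- is_productive_cdr3(rec$cdr3_aa)
  skipped <- sum(!keep)
  rec <- rec[keep, , drop = FALSE]
  if (nrow(rec) == 0 || sum(rec$count) <= 0)
    stop("empty repertoire: no productive clonotypes with positive counts in ",
         path, call. = FALSE)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  rep <- repertoire(sample_id, rec)
  attr(rep, "skipped") <- skipped
  rep
}

#' Write a repertoire as a simple-dialect clonotype TSV
#'
#' Emits the 4+1 column simple dialect (`cdr3_aa`, `v_gene`, `j_gene`,
#' `count`, `frequency`); frequencies are always the finalized values
#' recomputed from counts. Reading the file back reproduces the record set.
#'
#' @param rep a `tcr_repertoire`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_clonotype_table <- function(rep, path) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  out <- rep$records[c("cdr3_aa", "v_gene", "j_gene", "count", "frequency")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' @param path CSV or TSV file with header `sample_id,label,batch`.
#' @return data.frame with those three character columns.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  md <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  needed <- c("sample_id", "label", "batch")
  missing_cols <- setdiff(needed, names(md))
  if (length(missing_cols))
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  md[needed]
}

#' Write a cohort to a directory (simple TSVs plus metadata CSV)
#'
#' @param cohort a `tcr_cohort`.
#' @param dir destination directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tcr_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in cohort$repertoires)
    write_clonotype_table(r, file.path(dir, paste0(r$sample_id, ".tsv")))
  md <- data.frame(sample_id = cohort$sample_ids, label = cohort$labels,
                   batch = cohort$batch_ids)
  utils::write.csv(md, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort previously written by [write_cohort()]
#'
#' @param dir directory containing `metadata.csv` and one simple-dialect TSV
#'   per sample.
#' @return a `tcr_cohort`.
#' @export
read_cohort <- function(dir) {
  md <- read_metadata(file.path(dir, "metadata.csv"))
  reps <- lapply(md$sample_id, function(id)
    read_clonotype_table(file.path(dir, paste0(id, ".tsv")),
                         dialect = "simple", sample_id = id))
  assemble_cohort(reps, md)
}
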