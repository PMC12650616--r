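# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed and a tag
#'
#' All stochastic stages draw their seeds through this function so that adding
#' or reordering stages never perturbs another stage's random stream. The
#' result is always a valid 32-bit R seed.
#'
#' @param master integer master seed.
#' @param tag character tag naming the consumer (e.g. "split", "fold3").
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  val <- (abs(master) %% 2147483647) * 48271 + (h %% 2147483647)
  as.integer(val %% 2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# strip allele suffix ("*01") and MiXCR score annotation ("(123.4)"); keep
# first hit of a comma-separated multi-hit field
normalize_gene <- function(x) {
  x <- vapply(strsplit(as.character(x), ",", fixed = TRUE),
              function(p) p[[1]], character(1))
  x <- sub("\\(.*\\)$", "", x)
  x <- sub("\\*.*$", "", x)
  trimws(x)
}

# amino-acid validation: uppercase 20-letter alphabet only; '*' (stop) and
# '_' (frameshift) mark nonproductive junctions and are rejected
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

is_productive_cdr3 <- function(x) {
  nzchar(x) & !is.na(x) & grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", x)
}
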