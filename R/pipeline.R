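# End-to-end orchestration: simulate (or load) a cohort, compute repertoire
# statistics, build the feature matrix, benchmark classifiers, derive the
# permutation-importance biomarker panel, retrain on it, and optionally
# score an external validation cohort against the frozen vocabulary and
# model. Every stage's artifact is persisted under the output directory and
# the run is summarized in a machine-readable JSON report.

.known_config_keys <- c("simulation", "data_dir", "outdir", "seed", "top_k",
                        "m_out", "scope", "test_fraction", "families",
                        "cv_folds", "k_panel", "n_repeats", "importance_metric",
                        "importance_family", "importance_params",
                        "panel_sizes", "external",
                        "hec_threshold", "length_split")

#' Build and validate a pipeline run configuration
#'
#' Exactly one of `simulation` (a [simulation_config()] or list of overrides
#' for one) or `data_dir` (a directory readable by [read_cohort()]) must be
#' supplied. Unknown keys are rejected before any computation.
#'
#' @param ... configuration entries; recognized keys: `simulation`,
#'   `data_dir`, `outdir`, `seed`, `top_k`, `m_out`, `scope`,
#'   `test_fraction`, `families`, `cv_folds`, `k_panel`, `n_repeats`,
#'   `importance_metric`, `importance_family`, `importance_params`,
#'   `panel_sizes`, `external`
#'   (a simulation config or data dir for external validation),
#'   `hec_threshold`, `length_split`.
#' @return a validated `tcr_run_config` with defaults filled in.
#' @export
run_config <- function(...) {
  cfg <- list(...)
  if (length(cfg) == 1 && is.null(names(cfg)) && is.list(cfg[[1]]))
    cfg <- cfg[[1]]
  unknown <- setdiff(names(cfg), .known_config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(cfg$simulation) && is.null(cfg$data_dir))
    stop("config needs either a 'simulation' block or a 'data_dir'",
         call. = FALSE)
  defaults <- list(outdir = tempfile("tcrdx_run_"), seed = 1, top_k = 1000,
                   m_out = 500, scope = "train_only", test_fraction = 0.30,
                   families = c("logistic_regression", "transformer"),
                   cv_folds = 5, k_panel = 50, n_repeats = 5,
                   importance_metric = "auc",
                   importance_family = "logistic_regression",
                   importance_params = NULL,
                   panel_sizes = NULL, external = NULL,
                   hec_threshold = 0.005, length_split = 14)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  stopifnot(cfg$scope %in% c("train_only", "global"),
            cfg$test_fraction > 0, cfg$test_fraction < 1,
            all(cfg$families %in% MODEL_FAMILIES),
            cfg$importance_family %in% MODEL_FAMILIES)
  if (!is.null(cfg$simulation) && !inherits(cfg$simulation, "tcr_sim_config"))
    cfg$simulation <- do.call(simulation_config, cfg$simulation)
  class(cfg) <- "tcr_run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys follow [run_config()].
#' @return a `tcr_run_config`.
#' @export
read_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

.load_cohort <- function(spec_or_dir, seed_override = NULL) {
  if (inherits(spec_or_dir, "tcr_sim_config")) {
    if (!is.null(seed_override)) spec_or_dir$seed <- seed_override
    generate_cohort(spec_or_dir)
  } else if (is.character(spec_or_dir)) {
    list(cohort = read_cohort(spec_or_dir), truth = NULL)
  } else if (is.list(spec_or_dir)) {
    cfg <- do.call(simulation_config, spec_or_dir)
    if (!is.null(seed_override)) cfg$seed <- seed_override
    generate_cohort(cfg)
  } else stop("cannot interpret cohort source", call. = FALSE)
}

#' Run the full diagnostic pipeline
#'
#' Stages: cohort acquisition -> per-sample repertoire statistics and group
#' comparisons -> vocabulary / ANOVA reduction / vectorization -> stratified
#' split -> classifier benchmark -> permutation-importance panel -> panel
#' retraining -> optional external validation (frozen vocabulary and model,
#' never refit). Deterministic given the config (all seeds derive from
#' `config$seed`).
#'
#' @param config a `tcr_run_config` (or list coercible to one).
#' @return a `tcr_run_report` (also written to `outdir/run_report.json`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "tcr_run_config")) config <- run_config(config)
  t0 <- Sys.time()
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  tick <- function(stage, start) {
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), start, units = "secs"))
  }

  s <- Sys.time()
  src <- .load_cohort(config$simulation %||% config$data_dir)
  cohort <- src$cohort
  tick("cohort", s)

  s <- Sys.time()
  summ <- cohort_summary(cohort, hec_threshold = config$hec_threshold,
                         length_split = config$length_split)
  utils::write.table(summ, file.path(config$outdir, "repertoire_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stat_cols <- c("n_unique", "shannon_bits", "clonality", "hec_ratio",
                 "fraction_le_14")
  stat_cmp <- compare_groups(summ[stat_cols], cohort$labels)
  vu <- cohort_gene_usage(cohort, "V")
  vu_cmp <- compare_groups(vu, cohort$labels)
  utils::write.table(stat_cmp, file.path(config$outdir, "stat_comparisons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(vu_cmp, file.path(config$outdir, "v_usage_comparisons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tick("stats", s)

  s <- Sys.time()
  split_idx <- stratified_split_idx(cohort$labels, config$test_fraction,
                                    seed = derive_seed(config$seed, "split"))
  vocab0 <- build_vocabulary(cohort, top_k = config$top_k,
                             scope = config$scope,
                             train_idx = split_idx$train_idx)
  fm_cand <- vectorize(cohort, vocab0)
  m_out <- min(config$m_out, nrow(vocab0))
  vocab <- if (config$scope == "train_only")
    anova_reduce(fm_subset(fm_cand, split_idx$train_idx), m_out)
  else anova_reduce(fm_cand, m_out)
  fm <- vectorize(cohort, vocab)
  fm_train <- fm_subset(fm, split_idx$train_idx)
  fm_test <- fm_subset(fm, split_idx$test_idx)
  utils::write.table(vocab, file.path(config$outdir, "vocabulary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(data.frame(sample_id = fm$sample_ids,
                              partition = ifelse(seq_len(nrow(fm$X)) %in%
                                                 split_idx$train_idx,
                                                 "train", "test")),
                   file.path(config$outdir, "split_manifest.csv"),
                   row.names = FALSE)
  tick("features", s)

  s <- Sys.time()
  specs <- lapply(config$families, function(f)
    model_spec(f, seed = derive_seed(config$seed, f)))
  bench <- benchmark_all(specs, fm_train, fm_test, k = config$cv_folds,
                         seed = config$seed)
  utils::write.table(bench$table, file.path(config$outdir, "benchmark.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tick("benchmark", s)

  s <- Sys.time()
  imp_spec <- model_spec(config$importance_family,
                         seed = derive_seed(config$seed, "importance"))
  # default probe: the sparse (lasso) linear model; otherwise the family's
  # CV winner when benchmarked, else its first default grid point
  imp_params <- config$importance_params %||%
    (if (config$importance_family == "logistic_regression")
       list(C = 1, penalty = "l1")
     else bench$cv_results[[config$importance_family]]$best_params %||%
       .expand_grid_points(imp_spec$grid)[[1]])
  imp <- permutation_importance_cv(imp_spec, fm_train,
                                   n_repeats = config$n_repeats,
                                   k = config$cv_folds,
                                   metric = config$importance_metric,
                                   seed = derive_seed(config$seed, "imp"),
                                   params = imp_params)
  panel <- select_panel(imp, k = min(config$k_panel, ncol(fm$X)))
  utils::write.table(imp$scores,
                     file.path(config$outdir, "importance_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(panel, file.path(config$outdir, "panel.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  panel_sizes <- config$panel_sizes %||% nrow(panel)
  panel_evals <- lapply(panel_sizes, function(ps) {
    retrain_on_panel(imp_spec, fm_train, fm_test,
                     structure(panel[seq_len(min(ps, nrow(panel))), ],
                               class = class(panel)),
                     k = config$cv_folds)
  })
  names(panel_evals) <- paste0("top", panel_sizes)
  tick("panel", s)

  external_eval <- NULL
  if (!is.null(config$external)) {
    s <- Sys.time()
    ext_src <- config$external
    # an external simulation block draws new samples from the same disease:
    # unless told otherwise it inherits the training signature
    if (is.list(ext_src) && !inherits(ext_src, "tcr_sim_config") &&
        is.null(ext_src$signature_seed) &&
        inherits(config$simulation, "tcr_sim_config"))
      ext_src$signature_seed <- config$simulation$signature_seed
    best_fam <- bench$table$family[1]
    external_eval <- external_validate(
      list(vocabulary = vocab, model = bench$models[[best_fam]]),
      .load_cohort(ext_src)$cohort)
    tick("external", s)
  }

  report <- structure(list(
    config = config, timings = timings,
    class_counts = as.list(table(cohort$labels)),
    stat_comparisons = stat_cmp,
    benchmark = bench$table,
    panel = panel,
    panel_evals = lapply(panel_evals, function(e)
      list(panel_size = attr(e, "panel_size"), accuracy = e$accuracy,
           auc = e$auc, recall = e$recall, f1 = e$f1)),
    external = if (!is.null(external_eval))
      list(accuracy = external_eval$accuracy, auc = external_eval$auc,
           recall = external_eval$recall, f1 = external_eval$f1),
    truth_recovery = if (!is.null(src$truth) &&
                         nrow(src$truth$signature) > 0)
      panel_recovery_score(panel, src$truth),
    version = as.character(utils::packageVersion("tcrdx"))),
    class = "tcr_run_report")
  json <- report
  json$config$simulation <- unclass(json$config$simulation)
  json$config <- unclass(json$config)
  jsonlite::write_json(
    lapply(unclass(json), function(x) if (is.data.frame(x)) x else x),
    file.path(config$outdir, "run_report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, null = "null",
    force = TRUE)
  attr(report, "objects") <- list(cohort = cohort, fm = fm,
                                  fm_train = fm_train, fm_test = fm_test,
                                  benchmark = bench, importance = imp,
                                  truth = src$truth, split_idx = split_idx)
  report
}

#' Score an external cohort with frozen artifacts
#'
#' Vectorizes the new cohort against the frozen vocabulary (CDR3s unseen at
#' training contribute nothing, per the zero-imputation rule) and scores it
#' with the frozen model. Nothing is refit.
#'
#' @param artifacts list with `vocabulary` (a `tcr_vocabulary`) and `model`
#'   (a `tcr_model`), e.g. persisted from a prior [run_pipeline()] run.
#' @param cohort the external `tcr_cohort`.
#' @return a `tcr_eval` on the external cohort.
#' @export
external_validate <- function(artifacts, cohort) {
  if (is.null(artifacts$vocabulary) || is.null(artifacts$model))
    stop("artifacts must carry a frozen 'vocabulary' and 'model'",
         call. = FALSE)
  fm_ext <- vectorize(cohort, artifacts$vocabulary)
  evaluate(artifacts$model, fm_ext)
}
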