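test_that("generated cohorts honor arm sizes, labels and repertoire invariants", {
  g <- generate_cohort(fast_sim_config(seed = 3))
  expect_equal(n_samples(g$cohort), 16)
  expect_equal(as.vector(table(g$cohort$labels)[c("CRC", "HC")]), c(8, 8))
  expect_equal(nrow(g$truth$signature), 10)
  for (r in g$cohort$repertoires) {
    expect_equal(sum(r$records$frequency), 1, tolerance = 1e-9)
    expect_true(all(r$records$count > 0))
    expect_true(all(is_productive <- grepl("^C[A-Z]+F$", r$records$cdr3_aa)))
  }
})

test_that("generation is deterministic under a fixed seed and seed-sensitive otherwise", {
  cfg <- fast_sim_config(seed = 12)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$cohort$repertoires[[5]]$records,
                   g2$cohort$repertoires[[5]]$records)
  cfg2 <- fast_sim_config(seed = 13)
  g3 <- generate_cohort(cfg2)
  expect_false(identical(g1$cohort$repertoires[[5]]$records,
                         g3$cohort$repertoires[[5]]$records))
})

test_that("steeper case clone-size law yields the reported effect directions", {
  # moderate-size Monte-Carlo: the sign pattern (cases fewer unique clones,
  # higher clonality, higher HEC ratio, more mass at length <= 14) must hold
  g <- generate_cohort(simulation_config(
    n_cases = 25, n_controls = 25, repertoire_size_hc = 400,
    repertoire_size_crc = 300, total_reads = 6000, seed = 31))
  s <- cohort_summary(g$cohort)
  med <- function(col, lab) median(s[[col]][s$label == lab])
  expect_gt(med("n_unique", "HC"), med("n_unique", "CRC"))
  expect_gt(med("clonality", "CRC"), med("clonality", "HC"))
  expect_gt(med("hec_ratio", "CRC"), med("hec_ratio", "HC"))
  expect_gt(med("fraction_le_14", "CRC"), med("fraction_le_14", "HC"))
  expect_gt(med("shannon_bits", "HC"), med("shannon_bits", "CRC"))
})

test_that("signature clonotypes are enriched in cases relative to controls", {
  g <- generate_cohort(simulation_config(
    n_cases = 30, n_controls = 30, repertoire_size_hc = 300,
    repertoire_size_crc = 300, zipf_exponent_crc = 0.9,
    total_reads = 8000, n_signature = 10, seed = 17))
  sig <- g$truth$signature$cdr3_aa
  mean_freq <- function(lab) {
    reps <- g$cohort$repertoires[g$cohort$labels == lab]
    mean(vapply(reps, function(r) {
      p <- cdr3_frequencies(r)
      sum(p[intersect(names(p), sig)])
    }, numeric(1)))
  }
  enr <- g$truth$config$signature_enrichment
  expect_gt(mean_freq("CRC"), enr / 2 * mean_freq("HC"))
})

test_that("null configuration produces exchangeable arms", {
  # with no injected differences, diversity comparisons should be flat
  pvals <- vapply(1:12, function(i) {
    g <- generate_cohort(null_simulation_config(
      n_cases = 10, n_controls = 10, repertoire_size_hc = 200,
      repertoire_size_crc = 200, total_reads = 3000, seed = 100 + i))
    s <- cohort_summary(g$cohort)
    mann_whitney_u(s$shannon_bits[s$label == "CRC"],
                   s$shannon_bits[s$label == "HC"])$p
  }, numeric(1))
  # nominal false-positive behavior at alpha = 0.01
  expect_lte(sum(pvals < 0.01), 2)
})

test_that("label permutation preserves class balance but shuffles assignment", {
  g <- generate_cohort(fast_sim_config(seed = 8))
  p <- permute_labels(g$cohort, seed = 4)
  expect_equal(table(p$labels), table(g$cohort$labels))
  expect_false(identical(p$labels, g$cohort$labels))
  expect_identical(p$repertoires, g$cohort$repertoires)
})

test_that("cohorts round-trip through the on-disk layout", {
  g <- generate_cohort(fast_sim_config(n_cases = 3, n_controls = 3, seed = 2))
  dir <- withr::local_tempdir()
  write_cohort(g$cohort, dir)
  back <- read_cohort(dir)
  expect_equal(back$labels, g$cohort$labels)
  expect_equal(back$sample_ids, g$cohort$sample_ids)
  i <- 2
  a <- g$cohort$repertoires[[i]]$records
  b <- back$repertoires[[i]]$records
  key <- function(d) paste(d$cdr3_aa, d$v_gene, d$j_gene, d$count)
  expect_setequal(key(a), key(b))
})

test_that("held-out classification strengthens with signature enrichment", {
  # paired seeds across a 3-point enrichment grid; the downstream linear
  # classifier's held-out AUC must be nondecreasing (small MC slack)
  auc_at <- function(enr) {
    g <- generate_cohort(simulation_config(
      n_cases = 40, n_controls = 40, repertoire_size_hc = 400,
      repertoire_size_crc = 300, total_reads = 4000, n_signature = 15,
      signature_enrichment = enr, seed = 91))
    idx <- stratified_split_idx(g$cohort$labels, 0.3, seed = 92)
    v <- suppressMessages(build_vocabulary(g$cohort, 300, "train_only",
                                           idx$train_idx))
    fm0 <- vectorize(g$cohort, v)
    fm <- vectorize(g$cohort,
                    anova_reduce(fm_subset(fm0, idx$train_idx), 150))
    m <- fit_model("logistic_regression", list(C = 1),
                   fm_subset(fm, idx$train_idx), seed = 93)
    evaluate(m, fm_subset(fm, idx$test_idx))$auc
  }
  aucs <- vapply(c(1, 3, 10), auc_at, numeric(1))
  expect_gte(aucs[2], aucs[1] - 0.05)
  expect_gte(aucs[3], aucs[2] - 0.05)
  expect_gt(aucs[3], 0.8)
})

test_that("a fixed signature seed defines the same disease across cohort draws", {
  a <- generate_cohort(fast_sim_config(seed = 11, signature_seed = 99))
  b <- generate_cohort(fast_sim_config(seed = 12, signature_seed = 99))
  expect_identical(a$truth$signature, b$truth$signature)
  expect_false(identical(a$cohort$repertoires[[1]]$records,
                         b$cohort$repertoires[[1]]$records))
})
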