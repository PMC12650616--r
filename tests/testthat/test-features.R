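test_that("vocabulary ranks by summed frequency with lexicographic ties", {
  tab <- function(seqs, counts) data.frame(cdr3_aa = seqs, v_gene = "TRBV9",
                                           j_gene = "TRBJ1-1", count = counts)
  co <- make_toy_cohort(
    list(tab(c("CAAAF", "CCCCF", "CGGGF"), c(6, 3, 1)),
         tab(c("CAAAF", "CCCCF", "CGGGF"), c(6, 3, 1)),
         tab(c("CAAAF", "CCCCF"), c(1, 1))),
    c("CRC", "CRC", "HC"))
  v <- build_vocabulary(co, top_k = 2, scope = "global")
  expect_equal(v$cdr3_aa, c("CAAAF", "CCCCF"))
  # tie: two sequences with equal summed frequency -> lexicographic
  co2 <- make_toy_cohort(list(tab(c("CTTTF", "CAAAF"), c(5, 5))), "CRC")
  expect_warning(v2 <- build_vocabulary(co2, top_k = 10, scope = "global"),
                 "returning all")
  expect_equal(v2$cdr3_aa, c("CAAAF", "CTTTF"))
})

test_that("train-only scope ignores the test partition entirely (leakage audit)", {
  g <- generate_cohort(fast_sim_config(seed = 44))
  idx <- stratified_split_idx(g$cohort$labels, 0.3, seed = 1)
  v_scoped <- build_vocabulary(g$cohort, top_k = 200, scope = "train_only",
                               train_idx = idx$train_idx)
  # delete the test partition and rebuild: vocabulary must be unchanged
  keep <- idx$train_idx
  md <- data.frame(sample_id = g$cohort$sample_ids[keep],
                   label = g$cohort$labels[keep],
                   batch = g$cohort$batch_ids[keep])
  co_train <- assemble_cohort(g$cohort$repertoires[keep], md)
  v_train <- build_vocabulary(co_train, top_k = 200, scope = "global")
  expect_equal(v_scoped$cdr3_aa, v_train$cdr3_aa)
})

test_that("ANOVA F matches explicit sums-of-squares arithmetic", {
  expect_equal(anova_f_scores(matrix(c(0, 1, 2, 3), 4, 1),
                              c(0, 0, 1, 1))[1], 8)
  expect_equal(anova_f_scores(matrix(1, 6, 1), rep(c(0, 1), 3))[1], 0)
  expect_equal(anova_f_scores(matrix(c(0, 1, 0, 1), 4, 1),
                              c(0, 0, 1, 1))[1], 0)
  set.seed(13)
  for (rep_i in 1:25) {
    X <- matrix(rnorm(20 * 10), 20, 10)
    y <- sample(rep(0:1, 10))
    f <- anova_f_scores(X, y)
    oracle <- apply(X, 2, anova_f_oracle, y = y)
    expect_equal(f, oracle, tolerance = 1e-10)
  }
})

test_that("anova_reduce keeps exactly m_out top-F features", {
  g <- generate_cohort(fast_sim_config(seed = 19))
  v <- build_vocabulary(g$cohort, top_k = 300, scope = "global")
  fm <- vectorize(g$cohort, v)
  red <- anova_reduce(fm, 120)
  expect_equal(nrow(red), 120)
  f <- anova_f_scores(fm$X, fm$y)
  names(f) <- colnames(fm$X)
  expect_gte(min(f[red$cdr3_aa]), max(f[setdiff(names(f), red$cdr3_aa)]) - 1e-12)
  expect_error(anova_reduce(fm, 1000), "exceeds")
})

test_that("vectorize zero-imputes absent sequences and round-trips frequencies bit-exactly", {
  g <- generate_cohort(fast_sim_config(seed = 23))
  v <- build_vocabulary(g$cohort, top_k = 150, scope = "global")
  fm <- vectorize(g$cohort, v)
  expect_true(all(fm$X >= 0 & fm$X <= 1))
  expect_equal(fm$y, as.integer(g$cohort$labels == "CRC"))
  expect_true(all(rowSums(fm$X) <= 1 + 1e-9))
  for (i in c(1, 9)) {
    p <- cdr3_frequencies(g$cohort$repertoires[[i]])
    present <- intersect(v$cdr3_aa, names(p))
    expect_identical(unname(fm$X[i, present]), unname(p[present]))
    absent <- setdiff(v$cdr3_aa, names(p))
    if (length(absent)) expect_true(all(fm$X[i, absent] == 0))
  }
})

test_that("stratified split honors the largest-remainder apportionment", {
  labels <- c(rep("CRC", 123), rep("HC", 187))
  idx <- stratified_split_idx(labels, 0.30, seed = 6)
  expect_equal(length(idx$test_idx), 93)
  expect_equal(sum(labels[idx$test_idx] == "CRC"), 37)
  expect_equal(sum(labels[idx$test_idx] == "HC"), 56)
  expect_length(intersect(idx$train_idx, idx$test_idx), 0)
  expect_setequal(c(idx$train_idx, idx$test_idx), seq_along(labels))
  # determinism
  idx2 <- stratified_split_idx(labels, 0.30, seed = 6)
  expect_identical(idx, idx2)
  expect_false(identical(idx,
                         stratified_split_idx(labels, 0.30, seed = 7)))
  expect_error(stratified_split_idx(c("CRC", rep("HC", 5)), 0.3, 1), ">= 2")
})

test_that("feature-matrix split wrapper subsets rows consistently", {
  g <- generate_cohort(fast_sim_config(seed = 29))
  v <- build_vocabulary(g$cohort, top_k = 100, scope = "global")
  fm <- vectorize(g$cohort, v)
  sp <- stratified_split(fm, 0.25, seed = 3)
  expect_equal(nrow(sp$train$X) + nrow(sp$test$X), nrow(fm$X))
  expect_identical(sp$test$X, fm$X[sp$test_idx, , drop = FALSE])
  # class proportions within one sample's worth
  expect_lte(abs(mean(sp$train$y) - mean(sp$test$y)), 1 / min(table(fm$y)) + 0.2)
})

test_that("feature restriction preserves column data and errors on unknowns", {
  g <- generate_cohort(fast_sim_config(seed = 37))
  v <- build_vocabulary(g$cohort, top_k = 50, scope = "global")
  fm <- vectorize(g$cohort, v)
  pick <- v$cdr3_aa[c(5, 2, 9)]
  sub <- fm_select_features(fm, pick)
  expect_equal(colnames(sub$X), pick)
  expect_identical(sub$X[, 2], fm$X[, pick[2]])
  expect_error(fm_select_features(fm, "CNOTINVOCABF"), "absent")
})
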