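test_that("Shannon diversity matches closed forms and aggregates over V/J variants", {
  expect_equal(shannon_diversity(make_rep(rep(1, 4))), 2)
  expect_equal(shannon_diversity(make_rep(5)), 0)
  expect_equal(shannon_diversity(make_rep(c(2, 1, 1))), 1.5)
  # uniform N in bits for N in {2, 4, 8, 16}
  for (N in c(2, 4, 8, 16))
    expect_equal(shannon_diversity(make_rep(rep(3, N))), log2(N))
  # same CDR3 under two V genes counts once, with summed frequency
  rep_vj <- repertoire("s", data.frame(
    cdr3_aa = c("CASSLF", "CASSLF", "CASSMF"),
    v_gene = c("TRBV9", "TRBV16", "TRBV9"),
    j_gene = "TRBJ2-3", count = c(1, 1, 2)))
  expect_equal(rep_vj$n_unique, 2)
  expect_equal(shannon_diversity(rep_vj), 1)  # (0.5, 0.5)
})

test_that("clonality matches its definition with the N = 1 convention", {
  expect_equal(clonality(make_rep(rep(7, 10))), 0)
  expect_equal(clonality(make_rep(c(2, 1, 1))), 1 - 1.5 / log2(3))
  expect_equal(clonality(make_rep(100)), 0)  # single clone
  # near-point-mass approaches 1
  expect_gt(clonality(make_rep(c(1e7, 1, 1))), 0.99)
  # random repertoires stay in [0, 1]
  set.seed(11)
  for (i in 1:50) {
    cl <- clonality(make_rep(sample(1:1000, sample(2:40, 1), TRUE)))
    expect_true(cl >= 0 && cl <= 1)
  }
})

test_that("HEC counting is strictly-above-threshold", {
  r <- make_rep(c(990, 5, 3, 2))  # 0.5% boundary exactly at count 5
  h <- hec_stats(r)
  expect_equal(h$hec_count, 1)
  expect_equal(hec_stats(make_rep(rep(10, 10)))$hec_ratio, 1)
  expect_equal(hec_stats(make_rep(c(4, 3, 2, 1), id = "x"),
                         threshold = 0.5)$hec_count, 0)
})

test_that("CDR3 length spectrum is frequency weighted and length 14 is inclusive", {
  # lengths are 12 and 16
  r <- repertoire("s", data.frame(
    cdr3_aa = c(paste0("C", strrep("A", 10), "F"),
                paste0("C", strrep("A", 14), "F")),
    v_gene = "TRBV9", j_gene = "TRBJ1-1", count = c(7, 3)))
  out <- cdr3_length_summary(r)
  expect_equal(out$fraction_le_split, 0.7)
  expect_equal(sum(out$length_histogram), 1, tolerance = 1e-9)
  r14 <- repertoire("s", data.frame(cdr3_aa = paste0("C", strrep("A", 12), "F"),
                                    v_gene = "V", j_gene = "J", count = 5))
  expect_equal(cdr3_length_summary(r14)$fraction_le_split, 1)
})

test_that("gene usage supports read and clone weighting and sums to one", {
  r <- repertoire("s", data.frame(
    cdr3_aa = c("CASSLF", "CASSMF", "CASSNF"),
    v_gene = c("TRBV9", "TRBV9", "TRBV16"),
    j_gene = "TRBJ1-1", count = c(8, 1, 1)))
  clone_u <- gene_usage(r, "V", "clone")
  expect_equal(unname(clone_u[c("TRBV9", "TRBV16")]), c(2 / 3, 1 / 3))
  read_u <- gene_usage(r, "V", "read")
  expect_equal(unname(read_u[c("TRBV9", "TRBV16")]), c(0.9, 0.1))
  expect_equal(sum(read_u), 1, tolerance = 1e-9)
})

test_that("disease-specific ranking drops shared sequences and breaks ties lexicographically", {
  tab <- function(seqs) data.frame(cdr3_aa = seqs, v_gene = "TRBV9",
                                   j_gene = "TRBJ1-1", count = 1)
  co <- make_toy_cohort(
    list(tab(c("CASSTAF", "CASSGAF")), tab(c("CASSTAF", "CASSYSF")),
         tab(c("CASSTAF", "CASSGAF")),
         tab(c("CASSGAF", "CASSQQF")), tab(c("CASSQQF"))),
    c("CRC", "CRC", "CRC", "HC", "HC"))
  rk <- disease_specific_ranking(co)
  expect_equal(rk$cdr3_aa, c("CASSTAF", "CASSYSF"))
  expect_equal(rk$occurrence, c(3L, 1L))
  # tie at equal occurrence -> lexicographic
  co2 <- make_toy_cohort(
    list(tab(c("CASSTTF", "CASSAAF")),
         tab(c("CASSTTF", "CASSAAF")), tab("CASSQQF")),
    c("CRC", "CRC", "HC"))
  rk2 <- disease_specific_ranking(co2)
  expect_equal(rk2$cdr3_aa, c("CASSAAF", "CASSTTF"))
  expect_error(disease_specific_ranking(
    make_toy_cohort(list(tab("CASSAAF")), "CRC")), "both")
})

test_that("Mann-Whitney U matches enumeration on canonical cases", {
  out <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$U, 0)
  expect_equal(out$p, 0.1)
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1, tolerance = 1e-6)
  # U_x + U_y = n1 n2
  set.seed(3)
  for (i in 1:10) {
    x <- sample(1:20, 5, TRUE); y <- sample(1:20, 7, TRUE)
    expect_equal(mann_whitney_u(x, y)$U + mann_whitney_u(y, x)$U, 35)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(c(0.5, 1.0)), c(1.0, 1.0))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # permutation invariance and monotonicity
  set.seed(9)
  p <- runif(15)
  q <- fdr_adjust(p)
  perm <- sample(15)
  expect_equal(fdr_adjust(p[perm]), q[perm])
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("compare_groups flags degenerate features and assigns tiers from q", {
  set.seed(21)
  n <- 40
  labels <- rep(c("CRC", "HC"), each = n / 2)
  feats <- data.frame(signal = c(rnorm(n / 2, 3), rnorm(n / 2, 0)),
                      noise = rnorm(n), constant = rep(1, n))
  out <- compare_groups(feats, labels)
  expect_equal(out$p[out$feature == "constant"], 1)
  expect_true(out$degenerate[out$feature == "constant"])
  expect_equal(out$tier[out$feature == "constant"], "ns")
  expect_lt(out$q[out$feature == "signal"], 0.001)
  expect_equal(out$tier[out$feature == "signal"], "***")
  expect_true(all(out$q >= out$p - 1e-12))
})

test_that("summary table reproduces per-sample statistics and labels", {
  cfg <- fast_sim_config(seed = 5)
  g <- generate_cohort(cfg)
  summ <- cohort_summary(g$cohort)
  expect_equal(nrow(summ), 16)
  expect_equal(summ$label, g$cohort$labels)
  i <- 3
  expect_equal(summ$shannon_bits[i],
               shannon_diversity(g$cohort$repertoires[[i]]))
  expect_equal(summ$clonality[i], clonality(g$cohort$repertoires[[i]]))
})
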