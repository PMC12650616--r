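# fixtures and independent oracles shared across tests

make_rep <- function(counts, cdr3 = NULL, v = NULL, j = NULL, id = "s1") {
  n <- length(counts)
  if (is.null(cdr3)) cdr3 <- paste0("CASS", strrep("A", seq_len(n)), "F")
  if (is.null(v)) v <- rep("TRBV9", n)
  if (is.null(j)) j <- rep("TRBJ2-3", n)
  repertoire(id, data.frame(cdr3_aa = cdr3, v_gene = v, j_gene = j,
                            count = counts, stringsAsFactors = FALSE))
}

# cohort of hand-built repertoires with alternating labels
make_toy_cohort <- function(sample_tables, labels, batch = "b1") {
  reps <- lapply(seq_along(sample_tables), function(i)
    repertoire(paste0("s", i), sample_tables[[i]]))
  md <- data.frame(sample_id = paste0("s", seq_along(reps)),
                   label = labels, batch = batch)
  assemble_cohort(reps, md)
}

fast_sim_config <- function(...) {
  args <- utils::modifyList(
    list(n_cases = 8, n_controls = 8, repertoire_size_hc = 250,
         repertoire_size_crc = 180, total_reads = 4000, n_signature = 10),
    list(...))
  do.call(simulation_config, args)
}

# exhaustive-enumeration Mann-Whitney oracle: U for x plus exact two-sided p
# computed over all C(n1+n2, n1) group assignments of the pooled values
mwu_enumerate <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(n, n1)
  us <- apply(combos, 2, u_of)
  mu <- n1 * (n - n1) / 2
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  list(U = u_obs, p = min(1, p))
}

# hand-applied Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# brute-force two-group one-way ANOVA F from explicit sums of squares
anova_f_oracle <- function(v, y) {
  groups <- split(v, y)
  gm <- mean(v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  dfb <- length(groups) - 1
  dfw <- length(v) - length(groups)
  if (ssb == 0) return(0)
  if (ssw == 0) return(Inf)
  (ssb / dfb) / (ssw / dfw)
}

# trapezoidal area under the ROC polygon
roc_trapezoid <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}
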