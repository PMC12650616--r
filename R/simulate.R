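# Synthetic repertoire cohort generator. Emulates the case/control structure
# seen in peripheral-blood TCRbeta repertoires of colorectal-cancer patients
# versus healthy controls: fewer unique clones and steeper (more clonal)
# power-law clone-size distributions in cases, a CDR3 length spectrum shifted
# toward lengths <= 14, skewed V-gene usage, and a set of public
# disease-associated clonotypes enriched in cases. All randomness flows
# through one master seed; per-sample substreams are derived from the sample
# index, so generation is reproducible and order-independent.

# functional TRBV segments used as the simulated gene pool, with heavy-ish
# base usage on common segments
.default_v_pool <- function() {
  genes <- c("TRBV1", "TRBV2", "TRBV3-1", "TRBV4-1", "TRBV4-3", "TRBV5-1",
             "TRBV5-2", "TRBV5-3", "TRBV5-7", "TRBV6-1", "TRBV6-7", "TRBV6-8",
             "TRBV6-9", "TRBV7-1", "TRBV7-2", "TRBV7-3", "TRBV7-5", "TRBV9",
             "TRBV10-1", "TRBV11-2", "TRBV12-1", "TRBV12-2", "TRBV13",
             "TRBV14", "TRBV15", "TRBV16", "TRBV18", "TRBV19", "TRBV20-1",
             "TRBV21-1", "TRBV22-1", "TRBV23-1", "TRBV24-1", "TRBV25-1",
             "TRBV27", "TRBV28", "TRBV29-1", "TRBV30")
  w <- 0.4 + 0.6 * exp(-0.05 * seq_along(genes))
  stats::setNames(w / sum(w), genes)
}

.default_j_pool <- function() {
  genes <- c(paste0("TRBJ1-", 1:6), paste0("TRBJ2-", 1:7))
  stats::setNames(rep(1 / 13, 13), genes)
}

# usage multipliers applied to case samples: segments reported enriched in
# cases get >1, segments enriched in controls get <1
.default_v_skew <- c("TRBV6-7" = 1.6, "TRBV16" = 1.6, "TRBV23-1" = 1.5,
                     "TRBV30" = 1.5, "TRBV1" = 0.6, "TRBV5-2" = 0.6,
                     "TRBV7-3" = 0.7, "TRBV12-1" = 0.7)

#' Configuration for the synthetic repertoire cohort generator
#'
#' Defaults describe a desk-scale two-arm cohort with a strong public
#' disease signature: 100 cases / 100 controls, mean latent richness 1500
#' clones (controls) vs 1100 (cases), Zipf clone-size exponents 0.9 vs 1.1
#' (cases steeper, hence more clonal), 4,000 reads per sample (matching the
#' few-reads-per-clone saturation of real repertoire sequencing at this
#' richness), 30 public signature clonotypes carried by 50% of samples and
#' enriched 10-fold in responder cases (90% of cases), a one-residue
#' downward CDR3 length shift in cases, and V-usage multipliers matching
#' the reported direction of differential segment usage.
#'
#' @param n_cases,n_controls arm sizes.
#' @param repertoire_size_hc,repertoire_size_crc mean latent unique-clone
#'   counts (Poisson means) for controls and cases.
#' @param zipf_exponent_hc,zipf_exponent_crc clone-size power-law exponents;
#'   clone probability is proportional to rank^(-exponent).
#' @param total_reads sequencing depth per sample (multinomial draw size).
#' @param n_signature number of public disease-associated clonotypes.
#' @param signature_enrichment multiplicative frequency boost of signature
#'   clonotypes in case samples (>= 1).
#' @param signature_carrier_rate probability a sample (either arm) carries a
#'   given signature clonotype.
#' @param signature_response_rate fraction of cases mounting the signature
#'   response; non-responder cases carry signature clonotypes at control
#'   (baseline) frequency. Models the clinical heterogeneity that keeps
#'   real case/control repertoires from being perfectly separable.
#' @param length_center_hc,length_sd center/width of the truncated discrete
#'   Gaussian CDR3 length distribution for controls, on `[8, 24]`.
#' @param length_shift downward shift (residues) of the case length center.
#' @param v_usage_skew named numeric vector of per-gene case usage
#'   multipliers.
#' @param n_batches number of batches samples are dealt into (round-robin).
#' @param seed master seed for the cohort.
#' @param signature_seed seed defining the disease signature clonotypes;
#'   defaults to `seed`. Hold it fixed while varying `seed` to draw new
#'   cohorts from the *same* disease (e.g. an external validation cohort).
#' @return a `tcr_sim_config` list.
#' @export
simulation_config <- function(n_cases = 100, n_controls = 100,
                              repertoire_size_hc = 1500,
                              repertoire_size_crc = 1100,
                              zipf_exponent_hc = 0.9,
                              zipf_exponent_crc = 1.1,
                              total_reads = 4000,
                              n_signature = 30,
                              signature_enrichment = 10,
                              signature_carrier_rate = 0.5,
                              signature_response_rate = 0.90,
                              length_center_hc = 15,
                              length_sd = 2.2,
                              length_shift = 1,
                              v_usage_skew = .default_v_skew,
                              n_batches = 1,
                              seed = 42,
                              signature_seed = NULL) {
  cfg <- list(n_cases = n_cases, n_controls = n_controls,
              repertoire_size_hc = repertoire_size_hc,
              repertoire_size_crc = repertoire_size_crc,
              zipf_exponent_hc = zipf_exponent_hc,
              zipf_exponent_crc = zipf_exponent_crc,
              total_reads = total_reads, n_signature = n_signature,
              signature_enrichment = signature_enrichment,
              signature_carrier_rate = signature_carrier_rate,
              signature_response_rate = signature_response_rate,
              length_center_hc = length_center_hc, length_sd = length_sd,
              length_shift = length_shift, v_usage_skew = v_usage_skew,
              n_batches = n_batches, seed = seed,
              signature_seed = signature_seed %||% seed)
  sizes <- c(cfg$n_cases, cfg$n_controls, cfg$repertoire_size_hc,
             cfg$repertoire_size_crc, cfg$total_reads, cfg$n_batches)
  assert_that(all(sizes > 0), "all size parameters must be positive")
  assert_that(cfg$n_signature >= 0, "n_signature must be >= 0")
  assert_that(cfg$signature_carrier_rate >= 0 && cfg$signature_carrier_rate <= 1,
              "signature_carrier_rate must lie in [0, 1]")
  assert_that(cfg$signature_response_rate >= 0 && cfg$signature_response_rate <= 1,
              "signature_response_rate must lie in [0, 1]")
  assert_that(cfg$signature_enrichment >= 1,
              "signature_enrichment must be >= 1")
  assert_that(cfg$length_shift >= 0, "length_shift must be >= 0")
  class(cfg) <- "tcr_sim_config"
  cfg
}

#' A null simulation configuration (no case/control differences)
#'
#' Both arms share richness, clone-size law, length spectrum and V usage;
#' the signature mechanism is switched off. Case and control samples are
#' exchangeable, so any downstream classifier should perform at chance.
#'
#' @param ... overrides passed to [simulation_config()].
#' @return a `tcr_sim_config`.
#' @export
null_simulation_config <- function(...) {
  args <- utils::modifyList(
    list(repertoire_size_crc = 1500, zipf_exponent_crc = 0.9,
         n_signature = 0, signature_enrichment = 1,
         signature_carrier_rate = 0, length_shift = 0,
         v_usage_skew = numeric(0)),
    list(...))
  # a null config equalizes the arms: any case-side override applies to both
  if (!is.null(args$repertoire_size_hc) && is.null(list(...)$repertoire_size_crc))
    args$repertoire_size_crc <- args$repertoire_size_hc
  if (!is.null(args$zipf_exponent_hc) && is.null(list(...)$zipf_exponent_crc))
    args$zipf_exponent_crc <- args$zipf_exponent_hc
  do.call(simulation_config, args)
}

# truncated discrete Gaussian over lengths 8..24
.length_probs <- function(center, sd) {
  lens <- 8:24
  p <- exp(-0.5 * ((lens - center) / sd)^2)
  stats::setNames(p / sum(p), lens)
}

# vectorized random productive CDR3s: "C" + random core + "F"
.random_cdr3 <- function(lens) {
  core_len <- pmax(lens - 2L, 1L)
  letters_all <- sample(AA20, sum(core_len), replace = TRUE)
  idx <- rep.int(seq_along(core_len), core_len)
  cores <- vapply(split(letters_all, idx), paste, character(1), collapse = "")
  paste0("C", cores, "F")
}

# cohort-level signature clonotype table, deterministic given the config seed
.signature_table <- function(config) {
  if (config$n_signature == 0)
    return(data.frame(cdr3_aa = character(0), v_gene = character(0),
                      j_gene = character(0), base_freq = numeric(0)))
  with_seed(derive_seed(config$signature_seed %||% config$seed, "signature"), {
    lens <- sample(10:16, config$n_signature, replace = TRUE)
    cdr3 <- .random_cdr3(lens)
    vp <- .default_v_pool(); jp <- .default_j_pool()
    data.frame(cdr3_aa = cdr3,
               v_gene = sample(names(vp), config$n_signature, TRUE, prob = vp),
               j_gene = sample(names(jp), config$n_signature, TRUE, prob = jp),
               base_freq = stats::runif(config$n_signature, 1e-4, 5e-4),
               stringsAsFactors = FALSE)
  })
}

#' Draw one synthetic repertoire
#'
#' Latent richness is Poisson around the arm mean; clone probabilities follow
#' a Zipf law over rank; CDR3s are built as C + random core + F with lengths
#' from a truncated discrete Gaussian (shifted down for cases); V/J segments
#' are drawn from the usage pools (case pools reweighted by `v_usage_skew`);
#' signature clonotypes are spliced in at their base frequency (times
#' `signature_enrichment` for cases) before the multinomial read draw, so
#' spiked clones experience the same sampling noise as background clones.
#'
#' @param config a `tcr_sim_config`.
#' @param label `"CRC"` or `"HC"`.
#' @param seed integer seed for this sample's substream.
#' @param sample_id sample identifier.
#' @param signature optional signature table (from the cohort generator); if
#'   `NULL` it is derived from `config$seed`.
#' @return a `tcr_repertoire`.
#' @export
sample_repertoire <- function(config, label = c("HC", "CRC"), seed,
                              sample_id = "sim", signature = NULL) {
  stopifnot(inherits(config, "tcr_sim_config"))
  label <- match.arg(label)
  if (is.null(signature)) signature <- .signature_table(config)
  is_case <- label == "CRC"
  with_seed(seed, {
    mean_size <- if (is_case) config$repertoire_size_crc else config$repertoire_size_hc
    zipf <- if (is_case) config$zipf_exponent_crc else config$zipf_exponent_hc
    n_clones <- max(2L, stats::rpois(1, mean_size))
    p_bg <- seq_len(n_clones)^(-zipf)
    p_bg <- p_bg / sum(p_bg)

    center <- config$length_center_hc - if (is_case) config$length_shift else 0
    lp <- .length_probs(center, config$length_sd)
    lens <- as.integer(sample(names(lp), n_clones, TRUE, prob = lp))
    cdr3 <- .random_cdr3(lens)

    vp <- .default_v_pool()
    if (is_case && length(config$v_usage_skew)) {
      hit <- intersect(names(config$v_usage_skew), names(vp))
      vp[hit] <- vp[hit] * config$v_usage_skew[hit]
      vp <- vp / sum(vp)
    }
    jp <- .default_j_pool()
    vg <- sample(names(vp), n_clones, TRUE, prob = vp)
    jg <- sample(names(jp), n_clones, TRUE, prob = jp)

    # splice in carried signature clonotypes before the read draw; a case
    # boosts them only if it is a responder
    if (nrow(signature)) {
      responder <- is_case &&
        stats::runif(1) < config$signature_response_rate
      carried <- stats::runif(nrow(signature)) < config$signature_carrier_rate
      sig <- signature[carried, , drop = FALSE]
      if (nrow(sig)) {
        f_sig <- sig$base_freq * if (responder) config$signature_enrichment else 1
        f_sig <- f_sig / max(1, sum(f_sig) * 2)  # guard: keep total mass < 0.5
        p <- c(p_bg * (1 - sum(f_sig)), f_sig)
        cdr3 <- c(cdr3, sig$cdr3_aa)
        vg <- c(vg, sig$v_gene)
        jg <- c(jg, sig$j_gene)
      } else p <- p_bg
    } else p <- p_bg

    counts <- as.numeric(stats::rmultinom(1, config$total_reads, p))
    rec <- data.frame(cdr3_aa = cdr3, v_gene = vg, j_gene = jg,
                      count = counts, stringsAsFactors = FALSE)
    repertoire(sample_id, rec)
  })
}

#' Generate a labeled synthetic cohort with ground truth
#'
#' @param config a `tcr_sim_config`.
#' @return list with `cohort` (a `tcr_cohort`; cases first, then controls,
#'   batches dealt round-robin) and `truth` (list with the `signature`
#'   clonotype table and the per-sample seeds used).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "tcr_sim_config"))
  signature <- .signature_table(config)
  n <- config$n_cases + config$n_controls
  labels <- c(rep("CRC", config$n_cases), rep("HC", config$n_controls))
  ids <- sprintf("sim%03d_%s", seq_len(n), labels)
  seeds <- vapply(seq_len(n), function(i)
    derive_seed(config$seed, paste0("sample", i)), integer(1))
  reps <- lapply(seq_len(n), function(i)
    sample_repertoire(config, labels[i], seed = seeds[i], sample_id = ids[i],
                      signature = signature))
  md <- data.frame(sample_id = ids, label = labels,
                   batch = paste0("batch", (seq_len(n) - 1L) %% config$n_batches + 1L),
                   stringsAsFactors = FALSE)
  list(cohort = assemble_cohort(reps, md),
       truth = list(signature = signature, sample_seeds = seeds,
                    config = config))
}

#' Randomly permute a cohort's labels (null-calibration helper)
#'
#' Repertoires stay fixed; only the label vector is shuffled, which severs
#' any repertoire-label association while preserving class balance.
#'
#' @param cohort a `tcr_cohort`.
#' @param seed permutation seed.
#' @return a `tcr_cohort` with permuted labels.
#' @export
permute_labels <- function(cohort, seed) {
  stopifnot(inherits(cohort, "tcr_cohort"))
  out <- cohort
  out$labels <- with_seed(seed, sample(cohort$labels))
  out
}
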