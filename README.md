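# tcrdx — TCR repertoire diagnostics for case/control classification

`tcrdx` is an R package for building blood-based diagnostic models from
T cell receptor (TCR) beta-chain repertoires. The motivating application is
colorectal cancer (CRC) versus healthy controls (HC): tumor-driven clonal
expansion leaves measurable traces in the peripheral repertoire — fewer
unique clones, lower Shannon diversity, higher clonality, more
high-expansion clones, a shift toward short CDR3s, and skewed V-segment
usage — and the frequencies of individual public CDR3 clonotypes carry
enough signal to train a classifier.

The package covers the full analysis:

* **IO** — AIRR Rearrangement TSV, MiXCR clone exports, and a simple
  4-column dialect; metadata tables; cohort assembly; proportional-scaling
  depth normalization across cohorts.
* **Repertoire statistics** — per-sample Shannon diversity
  (H = −Σ pᵢ log₂ pᵢ, in bits), clonality (1 − H/log₂N), high-expansion
  clone (HEC, frequency > 0.5%) burden, CDR3 length spectra, V/J usage;
  Mann–Whitney U contrasts with Benjamini–Hochberg FDR control;
  disease-specific CDR3 occurrence ranking.
* **Features** — global top-1000 CDR3 vocabulary by summed frequency,
  ANOVA F reduction to 500, zero-imputed frequency matrix, leakage-safe
  stratified 70/30 split.
* **Models** — ten classifier families (random forest, logistic
  regression, KNN, decision tree, Gaussian naive Bayes, gradient boosting,
  AdaBoost, MLP, 1-D CNN, Transformer encoder) under stratified 5-fold
  cross-validated grid search selected by mean AUC; accuracy / AUC /
  recall / F1 and ROC curves on held-out data.
* **Biomarker panels** — permutation importance within cross-validation
  (5 repeats × 5 folds), top-k panel selection, panel retraining, and
  ground-truth recovery scoring on synthetic cohorts.
* **Synthetic cohorts** — a seeded generator producing case/control
  repertoires with power-law clone sizes, length-spectrum shifts, V-usage
  skew, and a spiked public-clonotype disease signature, so the entire
  pipeline is testable without patient data.

The MLP, CNN and Transformer are compact, fully seeded implementations in
base R matrix algebra (Adam, binary cross-entropy, hand-derived and
numerically verified gradients).

## Worked example

```r
library(tcrdx)

# a small synthetic study: 30 cases / 30 controls
cfg <- simulation_config(n_cases = 30, n_controls = 30, seed = 7)
g   <- generate_cohort(cfg)

# per-sample statistics and group contrasts
summ <- cohort_summary(g$cohort)
aggregate(cbind(n_unique, clonality, hec_ratio) ~ label, summ, median)
#>   label n_unique clonality  hec_ratio
#> 1   CRC    632.5 0.2683874 0.03921629
#> 2    HC    980.5 0.1672408 0.02351778

compare_groups(summ[c("shannon_bits", "clonality")], g$cohort$labels)
#>        feature median_crc median_hc   U            p            q tier degenerate
#> 1 shannon_bits  6.8180573 8.2772274   0 1.691123e-17 1.691123e-17  ***      FALSE
#> 2    clonality  0.2683874 0.1672408 900 1.691123e-17 1.691123e-17  ***      FALSE

# features: top-300 vocabulary -> ANOVA to 150 -> stratified 70/30 split
idx <- stratified_split_idx(g$cohort$labels, 0.3, seed = 1)
v   <- build_vocabulary(g$cohort, 300, "train_only", idx$train_idx)
fm  <- vectorize(g$cohort, anova_reduce(
         fm_subset(vectorize(g$cohort, v), idx$train_idx), 150))

# classify: logistic regression with grid search, evaluate held out
spec <- model_spec("logistic_regression", seed = 11)
cv   <- grid_search_cv(spec, fm_subset(fm, idx$train_idx))
ev   <- evaluate(fit_final(spec, cv$best_params,
                           fm_subset(fm, idx$train_idx)),
                 fm_subset(fm, idx$test_idx))
ev
#> <tcr_eval> n=18  accuracy=0.944  AUC=1.000  recall=0.889  F1=0.941
```

The medians show the expected direction pattern (cases: fewer unique
clones, higher clonality, more high-expansion clones), both contrasts are
significant after FDR control, and the perfect held-out ranking (AUC 1.0 on
this small test set) reflects the spiked public-clonotype signature the
generator plants.

`run_pipeline(run_config(...))` executes the same stages end to end —
statistics, features, a multi-family benchmark, the permutation-importance
panel, and optional external validation against frozen artifacts — and
persists every intermediate table plus a JSON run report. A thin subcommand
wrapper lives at `inst/cli/tcrdx.R`.

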