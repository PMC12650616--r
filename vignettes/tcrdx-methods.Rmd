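---
title: "Repertoire diagnostics with tcrdx: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repertoire diagnostics with tcrdx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

T lymphocytes recognize antigen through the T cell receptor (TCR); the
hypervariable CDR3 loop of the beta chain, created by V(D)J recombination,
is diverse enough that its amino-acid sequence serves as a clonotype
identifier. A blood sample therefore yields a *repertoire*: a table of
clonotypes with read counts. Malignancy reshapes this repertoire — selective
expansion of tumor-reactive clones lowers diversity, raises clonality, and
enriches particular public clonotypes — so repertoire features can act as a
minimally invasive diagnostic signal for colorectal cancer (CRC) against
healthy controls (HC).

`tcrdx` implements that analysis end to end: clonotype-table ingest,
per-sample repertoire statistics with nonparametric group comparisons,
construction of a clonotype-frequency feature matrix, a ten-family
classifier benchmark including a self-attention (Transformer encoder)
network, and biomarker-panel selection by cross-validated permutation
importance. A seeded synthetic cohort generator stands in for patient data
so that every stage is testable.

# Per-sample statistics

All diversity quantities are computed on the per-CDR3 frequency
distribution, with V/J variants of the same amino-acid sequence aggregated.
For frequencies $p_i$ over the $N$ unique CDR3 sequences of one sample:

$$H = -\sum_{i=1}^{N} p_i \log_2 p_i, \qquad
  \mathrm{clonality} = 1 - \frac{H}{\log_2 N}.$$

$H$ is reported in bits. Clonality is 0 for a perfectly even repertoire and
approaches 1 under extreme oligoclonal expansion. At $N = 1$ the ratio is
0/0; we define clonality to be 0 there, since a single-clone repertoire has
no evenness deficit to normalize — this degenerate case is covered by a
dedicated test.

A high-expansion clone (HEC) is a CDR3 whose aggregated frequency is
*strictly above* 0.5% of the sample's reads (the boundary case sits exactly
at threshold and is excluded; a test pins this). The CDR3 length spectrum is
frequency-weighted, and the summary dichotomizes it at length 14, inclusive
on the short side. V/J segment usage supports read weighting (frequency
mass) and clone weighting (unique clonotype counts); gene names are
normalized by stripping allele suffixes (`*01`) and alignment-score
annotations, keeping the best hit of multi-hit fields.

Group contrasts use the two-sided Mann–Whitney U test (exact for tie-free
small samples, normal approximation with tie and continuity correction
otherwise — `stats::wilcox.test` underneath) with Benjamini–Hochberg FDR
adjustment applied jointly within each feature family, and the usual
`*`/`**`/`***` tiers at q < 0.05/0.01/0.001. The
Benjamini–Yekutieli variant is selectable for dependent feature families.

# Feature construction

The feature set is the global CDR3 vocabulary: unique sequences ranked by
their summed per-sample frequency (ties broken lexicographically), truncated
to the top 1000, then reduced to 500 by the two-group ANOVA F statistic.
Each sample becomes a vector of aggregated CDR3 frequencies over that
vocabulary, with zeros for absent sequences; labels are encoded 1 = CRC,
0 = HC.

Two scope modes exist because global selection before splitting leaks test
information into the features. `scope = "global"` reproduces the
selection-before-split recipe; `scope = "train_only"` (the default
everywhere in this package) restricts both the ranking and the ANOVA step to
the training partition. A dedicated test deletes the test partition outright
and verifies the train-only vocabulary is unchanged.

The stratified 70/30 split apportions per-class test counts by largest
remainder around `round(n * 0.3)`: with 123 cases and 187 controls this
yields a 93-sample test set of 37 cases and 56 controls. Stratified 5-fold
cross-validation deals shuffled class members round-robin, so per-fold class
counts differ from balance by at most one sample.

# Classifier families

Seven classical families (random forest, penalized logistic regression,
k-nearest neighbors, decision tree, Gaussian naive Bayes, gradient
boosting, AdaBoost) and three networks (MLP, 1-D CNN, Transformer encoder)
share one interface: `fit_model()` returns an object whose
`predict_score()` maps a feature vector to a CRC probability. Classical
families are backed by `randomForest`, `glmnet`, `rpart`, `e1071` and
`xgboost`; AdaBoost (SAMME over depth-1 stumps), the KNN scorer, and all
three networks are implemented in the package with seeded, hand-derived
training (Adam optimizer, binary cross-entropy; the Transformer's gradients
are verified against numerical differentiation in the test suite).

Inputs to the distance- and gradient-based families (KNN, logistic, MLP,
CNN, Transformer) are standardized with training-partition statistics; tree
ensembles see raw frequencies.

The Transformer treats each of the $m$ selected clonotypes as one token:
token $j$'s input is a learned identity embedding plus the sample's
standardized frequency $x_j$ passed through a learned value-projection
vector. Post-norm encoder layers (multi-head scaled dot-product
self-attention, position-wise ReLU feed-forward, residuals, layer
normalization) are mean-pooled into a dense sigmoid readout. Because every
token carries its identity embedding through a per-token nonlinearity, the
pooled representation can express general additive effects of individual
clonotype frequencies, with attention supplying cross-clonotype
interactions. The CNN reads the feature vector as a 1-D signal in
vocabulary-rank order (rank is a meaningful axis: global abundance), which
is the documented ordering convention.

Hyperparameters are tuned by exhaustive grid search under stratified 5-fold
CV, selecting the assignment with the highest mean validation AUC (ties go
to the earlier grid point; a failed fit scores 0.5 and is flagged, never
dropped). Shipped grids are deliberately small (1–3 values per tunable) for
desk-scale runs; larger grids are plain R lists. Gaussian naive Bayes has no
tunables and is evaluated once at defaults, with a variance floor
(`1e-6` of the largest feature deviation) so class-constant features keep
finite likelihoods. The winner is refit on the full training partition and
evaluated on the held-out test set: accuracy, recall and F1 at probability
threshold 0.5 with CRC positive, plus threshold-free AUC computed by pair
counting with ties at one half (a property test checks exact agreement with
the trapezoidal area under the constructed ROC).

Default network training runs 30 epochs, batch size 32, Adam at $10^{-3}$.
The Transformer defaults to 12 epochs at $3 \times 10^{-2}$: mean-pooling
over hundreds of tokens shrinks the readout's per-step signal, so it needs
the larger step size to calibrate its output probabilities (not just their
ranking) within a desk-scale epoch budget.
Per-family seeds derive from one master seed through a tagged hash, so
adding a family never perturbs another's randomness.

# Permutation importance and biomarker panels

Within stratified 5-fold CV, the model is fit on the training part and
scored on the intact validation part; each validation column is then
shuffled 5 times (fresh seeded permutation per fold × feature × repeat) and
the importance of a feature is the mean drop in validation performance,
averaged over repeats and then folds. Shuffling operates on copies — a
purity test hashes the matrix before and after. The top-50 features by mean
importance (ties lexicographic) form the biomarker panel, which is then
retrained and evaluated as its own model.

The default importance pipeline is an L1-regularized logistic model (lasso
probe, C = 1). Sparse linear probes are the standard biomarker-selection
device, and in our synthetic benchmarks they are the only pipeline whose
positive-importance set is consistently free of noise features. Any family
can be substituted; note that the attention model at 500 tokens makes the
~12,500 scored permutations per run computationally unreasonable, which is
a practical reason the probe default is linear.

**A structural caveat worth knowing.** Validation-fold permutation
importance degrades in two opposite regimes, both of which the synthetic
cohorts can reach. If the classes separate perfectly with wide margins,
permuting any single one of several redundant informative features changes
no ranking: every drop is exactly zero and the panel degenerates to the
tie-break order. If instead the errors are concentrated in cases that
*lack* the informative signal (non-responders), a rank metric can move the
wrong way: permutation occasionally hands a misranked, signature-poor case
a high value, repairing many discordant pairs at once, so truly informative
features can receive systematically *negative* scores while noise stays at
zero. In our experiments the same spiked cohort shows both effects
depending on sequencing depth and response heterogeneity. Practically:
inspect the sign structure of the importance distribution, prefer the
sparse probe, and treat panel recovery on synthetic data as a stress test
of the procedure rather than a guaranteed property. The package reports
recovery against ground truth (`panel_recovery_score()`) so this behavior
is measurable rather than hidden.

# The synthetic cohort generator

`simulation_config()` defines the study conditions; `generate_cohort()`
draws labeled repertoires plus ground truth. Per sample: latent richness is
Poisson (means 1500 HC / 1100 CRC); clone probabilities follow a Zipf law
over rank (exponents 0.9 HC / 1.1 CRC — steeper in cases, forcing higher
clonality and HEC burden); CDR3s are `C` + random core + `F` with lengths
from a truncated discrete Gaussian on [8, 24] centered at 15 (HC), shifted
down 1 residue in cases; V/J segments come from a 38-segment functional
pool, with case usage multiplied up for TRBV6-7/TRBV16/TRBV23-1/TRBV30 and
down for TRBV1/TRBV5-2/TRBV7-3/TRBV12-1; reads are one multinomial draw of
4000 per sample, a depth chosen to match the few-reads-per-clone saturation
of real repertoire sequencing at this richness.

The disease signature is a set of 30 public clonotypes with base
frequencies drawn once per cohort from U(1e-4, 5e-4). Every sample carries
each of them with probability 0.5; in responder cases (90% of cases, a
clinical-heterogeneity parameter that keeps the arms from being perfectly
separable) carried signature clonotypes are enriched 10-fold before the
read draw, so spiked clones experience the same sampling noise as
background. Effect sizes for the arm contrasts are calibrated to reproduce
the reported sign pattern (fewer unique clones, higher clonality and HEC
ratio, more short CDR3 mass in cases) and an internal-test AUC in the
mid-0.9s for the default classifiers, not any specific magnitudes.

What the generator does *not* emulate: mechanistic V(D)J recombination
(insertions/trimming), nucleotide-level sequences, batch effects beyond a
uniform depth factor, age/sex structure, and realistic repertoire sizes
(~10^5 clones) — richness and depth are scaled down about two orders of
magnitude so the full pipeline runs on a desk machine. Passing tests
therefore demonstrate correctness and calibration of the *procedures*, not
clinical performance on real cohorts.

All randomness flows from one master seed; per-sample substreams derive
from the sample index, so cohorts are reproducible and insensitive to
evaluation order. `null_simulation_config()` removes every case/control
difference for calibration work, and `permute_labels()` severs
repertoire–label association while preserving balance.

# Numerical and interface choices

* Proportional-scaling depth normalization rescales each sample's counts to
  the baseline batch's *median* total (mean selectable); scaling is
  per-sample uniform, so frequencies are untouched — a test asserts this to
  1e-12.
* Nonproductive CDR3s (stop `*`, frameshift `_`, empty) are dropped at
  ingest and tallied; duplicate (CDR3, V, J) rows merge by summing counts.
* Clone counts are treated as opaque non-negative weights (UMI or read);
  scaled pseudo-counts are real-valued.
* All ranking operations (vocabulary, ANOVA, panels, disease-specific
  sequences) break ties lexicographically on the CDR3 string so outputs are
  deterministic.
* ComBat-seq-style batch adjustment is out of scope; externally adjusted
  tables enter through the same readers.
* Reference problem sizes used by the test suite: formula identities on
  1000 random repertoires; oracle sweeps of 200 (Mann–Whitney), 100 (BH),
  500 (AUC) random instances; feature-pipeline checks on 20-sample cohorts
  (>2000 clonotypes); calibration and recovery on the default 100/100
  cohorts with 10 replicate draws.

# Known limitations

Single-chain (beta) repertoires only; no clonotype network or k-mer/motif
features; no probability calibration of classifier scores; the permutation
importance caveat above; and the generator's scale compromises. External
validation never refits: frozen vocabulary and model score the new cohort,
with unseen CDR3s contributing zeros by the imputation rule.
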