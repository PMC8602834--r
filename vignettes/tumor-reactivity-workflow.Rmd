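---
title: "Quantifying tumor-reactive T cells: models, choices and limits"
author: "TRSig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumor-reactive T cells: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TRSig)
```

# The problem and the model

Tumor-infiltrating CD8+ T cells mix genuinely tumor-reactive clones with
bystanders. TRSig operationalizes "tumor reactivity" as a gene signature
derived from the transcriptional state that marks reactive cells, scored
per sample or per cell, and validated against clonal expansion, survival
and immunotherapy response. The workflow is a chain of small statistical
primitives, each with an explicit contract:

1. **Gating and filtering.** CD8+ T cells are cells with mean CD8-chain
   expression strictly above 2 and CD4 strictly below 2 on the dataset's
   log-normalized scale. Full-length/bulk-like profiles keep genes with
   mean > 0.5 and detection rate > 0.1; droplet-style count profiles first
   keep cells with 500–3000 expressed genes (inclusive) and then genes
   detected in > 1% of surviving cells. "Expressed" always means strictly
   positive.
2. **Derivation.** One-vs-rest Wilcoxon rank-sum tests (one-sided,
   greater-in-target, because markers are over-expressed genes) flag
   candidates at BH FDR < 0.05; the signature is the top `k = 20`
   candidates by one-vs-rest ROC AUC.
3. **Scoring.** Five single-sample statistics (kernel-CDF KS walk,
   rank-weighted KS walk, combined z, first singular vector, mean) plus a
   per-cell ranking-recovery score.
4. **Refinement.** Backward elimination under a univariate Cox AIC
   objective, with full re-scoring after every candidate deletion.
5. **Clonality.** Exact alpha–beta pair clonotypes, a clone-size
   classification (1 / 2 / ≥ 3), and downsampling-rarefied Shannon entropy.
6. **Evaluation.** Kaplan–Meier, log-rank, Efron-ties Cox, Harrell's C,
   KM-weighted time-dependent AUC, RMST ratio, median-split stratification,
   response ROC, rank tests, Welch-t differential expression, Spearman
   association.

# Parameters that matter

| Parameter | Default | Units / meaning |
|---|---|---|
| `cd8Threshold`, `cd4Threshold` | 2, 2 | log-normalized expression; strict `>` / `<` |
| `alphaFdr` | 0.05 | BH-adjusted marker threshold |
| `k` | 20 | signature size (top AUC) |
| kernel bandwidth | `s_i / 4` | per-gene SD over 4 (Gaussian kernel) |
| Poisson offset `r` | 0.5 | kernel rate offset for counts |
| `tau` (walk exponent) | 1 | symmetrized-rank weight of the KS walk |
| `esMode` | `max_diff` | largest positive minus largest absolute negative deviation |
| `rwksAlpha` | 0.25 | rank-weight exponent of the rank-weighted walk |
| `recoveryTopFraction` | 0.05 | ranking threshold of the per-cell recovery score |
| `clonalMinSize` | 3 | cells per clonotype to call "clonal" |
| rarefaction depth | min repertoire | common downsampling depth; `reps = 1000` |
| Cox ties | Efron | Breslow behind a flag |
| median-split ties | low group | group sizes depend on it; documented |

The walk parameters (`tau = 1`, `esMode = "max_diff"`, `rwksAlpha = 0.25`,
range normalization) mirror the reference defaults of the corresponding
scorers, which are conventionally invoked as "default parameters" without
being printed; no published constants exist to recover, so parity is
asserted against literal step-by-step transcriptions of each walk in the
test suite rather than against external numbers.

# What the synthetic generators emulate

`simulateScDataset` draws a discrete landscape of `nStates = 7`
transcriptional states over 600 cells and 1000 genes, plants
`nSignatureGenes = 40` genes whose mean rises by `markerShift = 2` log2
units in one reactive state, applies independent Bernoulli dropout
(`dropoutRate = 0.3`) and truncates at zero to resemble log-normalized
single-cell data. Seven states and a ~1/7 reactive fraction mirror the
granularity of a typical CD8 T-cell landscape; shift 2 is a strong but not
degenerate marker effect (per-cell AUC ≈ 0.8 after dropout); the sizes keep
the full suite fast.

`simulateTcrTable` assigns cells to clonotypes sequentially with
preferential attachment (an occupied clonotype attracts proportionally to
its current size), multiplying the odds of joining an occupied clonotype by
`clonalEnrichment` for reactive-state cells. This produces the skewed
clone-size distributions and the reactive-state excess of expanded clones
that motivate clonality analysis, without modeling receptor sequences.

`simulateBulkCohort` gives each sample a latent reactivity score
`u ~ N(0, 1)` that (i) raises signature-gene expression by
`signatureLoading × u` (unit Gaussian noise), (ii) scales an exponential
hazard `baselineHazard · exp(latentEffect · u)` with independent
exponential censoring, and (iii) in `simulateResponseCohort` sets
`P(responder) = plogis(responseLogitSlope · u)`. The exponential survival
model was chosen over Weibull deliberately: its closed-form hazard makes
coefficient recovery exactly checkable (`latentEffect = −0.7` is recovered
within ±0.15 at n = 500 averaged over 20 cohorts).

**What passing tests do not show.** The generators deliberately omit batch
effects, library-size variation, gene–gene correlation beyond the planted
program, multi-dataset integration structure, realistic V(D)J sequences and
non-proportional hazards. Recovery of planted truth therefore demonstrates
the correctness of the estimators, not robustness to the full messiness of
real cohorts.

# Numerical choices and degenerate inputs

- **Exact rank-sum p-values** (pooled n ≤ 20) enumerate all group
  assignments of the midranks with the inclusive convention
  `P(statistic ≥ observed)`, matching `wilcox.test`; two-sided p doubles
  the smaller tail with the same convention. Constant genes get p = 1.
- **Zero-variance genes** receive a constant 0.5 kernel-CDF row instead of
  being dropped, keeping gene universes aligned across scoring methods; in
  z-score-based scorers they contribute 0.
- **Singular-vector orientation**: the first right singular vector is
  defined only up to sign, so scores are oriented to correlate
  non-negatively with the mean signature z-score; the raw vector is
  available (`plageOrient = FALSE`), and higher oriented scores should
  still be interpreted cautiously — orientation is a convention, not a
  guarantee of direction.
- **Per-cell ranking ties** break at random under a recorded seed (the
  reference behavior); a deterministic first-occurrence mode exists for
  exact tests.
- **Cox fitting** converges when every score component falls below 1e-9
  (at most 50 Newton–Raphson iterations); non-convergence is reported,
  never silent. Coefficients drifting past |β| > 15 are treated as
  monotone likelihood (perfect separation), capped and flagged.
- **Harrell's C**: pairs with tied times and two events are unusable; a
  tied event–censored pair counts the event as shorter; risk ties count ½.
- **Time-dependent AUC** uses the KM-weighted cumulative/dynamic estimator
  — the parameter-free choice — rather than nearest-neighbor smoothing;
  its ROC points are not guaranteed monotone and are clamped to [0, 1]
  before trapezoid integration.
- **RMST** integrates the step KM curve exactly; a horizon beyond an arm's
  last observed time is an error unless the curve has already reached zero
  there, in which case the integral is identified (e.g. all subjects dead
  at t = 1 gives RMST = 1 for any τ ≥ 1). Variances are Greenwood-based;
  the ratio CI uses the delta method on the log scale.
- **Median split**: scores equal to the median go low, so with duplicated
  median values the low group absorbs all of them; all-identical scores
  are an error, not a silent single group.
- **Stepwise AIC**: removal requires a *strict* AIC decrease (equality
  stops, as in a pure "until it didn't decrease" reading); argmin ties
  break to the lexicographically smallest gene; because every fit is
  univariate, each accepted removal is asserted to coincide with a partial
  log-likelihood increase. Whether a planted pure-noise gene is removed at
  step 1 is itself a stochastic event — with 5 informative genes (loading
  1) and one noise gene at n = 400 it occurs in roughly 80% of generator
  seeds — so tests verify it on a documented seeded instance and verify
  the loop against an exhaustive single-deletion evaluation.
- **Rarefied entropy** is estimated by seeded Monte-Carlo downsampling
  (B = 1000 by default) rather than the analytic interpolation some
  packages use; an exhaustive-subsample enumeration validates the
  estimator on small repertoires. Samples below depth are reported missing
  — never extrapolated. Note the field often calls 1 − normalized entropy
  "clonality"; the value reported here is entropy (diversity), and the
  naming difference is surfaced rather than resolved.
- **Exact Spearman p-values** are available for n ≤ 8 (full permutation
  enumeration); beyond that the t-approximation is used — at n = 10 the
  3.6 M permutations buy no practical accuracy over the approximation.

# Design decisions that were genuinely open

- The CD8 level averages CD8A and CD8B by default, but the gene list is
  configurable because chain nomenclature is a convention ("CD8" alone is
  ambiguous between CD8B and the A/B mean).
- `k = 20` is the default signature size; a 22-gene variant circulates in
  narrative descriptions of such signatures, and `k` is an explicit
  argument precisely so either reading is reproducible.
- BH adjustment spans all genes tested after filtering (the common
  single-cell marker practice); the candidate universe is recorded in the
  provenance.
- Differential expression uses Welch's unequal-variance t-test ("t-test"
  alone underdetermines this) and |log2FC| by default, with a signed mode,
  since DE between score-stratified groups is typically asymmetric.
- Pairwise rank tests are reported unadjusted by default (figure-star
  convention); a `p.adjust` method can be requested.
- C-index comparison uses a seeded paired bootstrap rather than the
  analytic U-statistic variance — a documented substitution affecting only
  significance stars, not the indices themselves.
- The evaluation horizons of the time-dependent AUC and the RMST ratio are
  configuration, defaulting to the median observed time and the
  minimum-over-arms largest observed time; no canonical values exist to
  hard-code.

# Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
the scale the generator defaults define: 1000 × 600 single-cell matrices
for derivation, 200-sample cohorts (plus 200 background genes) for scoring
and survival evaluation, 500-sample cohorts × 20 seeds for coefficient
recovery, n = 2000 for null-calibration and closed-form ROC checks, and
B = 10000 downsampling replicates against an exhaustive rarefaction oracle.
These sizes were chosen so each statistical property is comfortably
resolvable (e.g. a ±0.03 AUC band at n = 2000 is ≈ 3 standard errors) while
the whole suite stays interactive.

# Known limitations

- Cluster labels are inputs; no clustering, integration or embedding is
  provided or validated.
- The Vision-style signed-signature scorer and analytic C-index variance
  are intentionally absent.
- Scoring statistics are reported without permutation nulls; their
  downstream use (survival, response) provides the inference.
- The synthetic generators are structural stand-ins, not biological
  simulators; see the scope notes above.
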