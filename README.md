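# TRSig

Tumor-infiltrating CD8+ T cells are a mixture of genuinely tumor-reactive
cells and bystanders that recognize unrelated antigens. TRSig implements a
complete, testable workflow for quantifying tumor reactivity from
transcriptomes: derive a tumor-reactive signature (TRS) from cluster-labeled
single-cell expression, score bulk cohorts and single cells with standard
single-sample gene-set statistics, refine the signature against survival,
quantify T cell receptor (TCR) clonal expansion, and evaluate prognostic and
immunotherapy-response value. It is written for computational immunologists
and bioinformaticians who want each step as an explicit, unit-tested
primitive rather than a chain of opaque package calls.

## What it computes

- **Signature derivation.** Candidate markers of the reactive cluster are
  genes over-expressed one-vs-rest by Wilcoxon rank-sum test at
  Benjamini–Hochberg FDR < 0.05. Each candidate's discriminative power is
  its one-vs-rest ROC AUC, `AUC = U / (n1 n2)` with ties counted ½; the TRS
  is the top *k* = 20 genes by AUC.
- **Single-sample scoring.** Five statistics: the kernel-CDF KS walk
  (`ẑ_ij = (1/n) Σ_k Φ((x_ij − x_ik)/h_i)`, `h_i = s_i/4`, Gaussian or
  Poisson kernel, followed by a symmetrized-rank-weighted enrichment walk);
  the rank-weighted KS walk (weight `rank^0.25`, integrated running
  difference, cohort-range normalization); combined z (`Σ_i z_ij / √k`);
  the first right singular vector of the z-scored signature submatrix
  (sign-oriented); the signature mean; and a per-cell ranking-recovery score
  (area under the signature recovery curve within the top 5% of ranks).
- **Refinement.** Backward elimination: score the cohort on the current gene
  set, fit a univariate Cox model on the score, and remove the gene whose
  deletion lowers the AIC most, stopping when no deletion strictly lowers
  it. Every deletion triggers full re-scoring before the refit.
- **TCR clonality.** A clonotype is an exact alpha–beta chain pair; cells in
  clones of size ≥ 3 are "clonal" (2 = "repeated", 1 = "unique"). Repertoire
  diversity is downsampling-rarefied Shannon entropy at a common depth.
- **Survival and response evaluation.** Kaplan–Meier curves, log-rank tests,
  Newton–Raphson Cox fits with Efron ties, Harrell's C, KM-weighted
  cumulative/dynamic time-dependent ROC AUC, restricted-mean-survival-time
  (RMST) ratios with delta-method CIs, median-split stratification,
  coefficient-based risk scores, response ROC, Kruskal–Wallis/rank-sum group
  tests, Welch-t differential expression and Spearman association.
- **Synthetic data.** Seeded generators plant a reactive transcriptional
  state, clonally enriched TCR repertoires, and bulk/response cohorts whose
  latent reactivity drives expression, hazard and response — every
  downstream claim is testable against planted ground truth.

## Worked example

```r
library(TRSig)

sc  <- simulateScDataset(scDesign(seed = 7))        # 1000 genes x 600 cells
sig <- deriveTRS(sc, target = metadata(sc)$reactiveState)
sig
length(intersect(sigGenes(sig), metadata(sc)$plantedGenes))

coh <- simulateBulkCohort(cohortDesign(nSamples = 200, seed = 8), sig)
sv  <- scoreSamples(coh$expr, sig, scoringConfig())  # kernel-CDF KS scores
grp <- stratifyMedian(sv)
logrankTest(coh$survival$time, coh$survival$event, grp)$p_value

risk <- linearRiskScore(sv, negate = TRUE)           # high risk = low TRS
coxFit(risk, coh$survival$time, coh$survival$event)
concordanceIndex(risk, coh$survival$time, coh$survival$event)
```

prints

```
GeneSignature of 20 gene(s) (k = 20)
  top genes: G00852 (AUC 0.841), G00050 (AUC 0.784), G00912 (AUC 0.764), ...
planted-gene overlap: 20 / 20
log-rank p (median split): 1.93e-07
CoxFit (efron ties): n = 200, events = 125, converged in 5 iter
  x: beta = 1.4295 (se 0.2141), HR = 4.1764 [2.7449, 6.3545]
  logLik = -524.4777, AIC = 1050.9553
C-index: 0.694
```

The derived signature recovers all 20 planted genes; the median split of the
kernel-CDF scores separates survival sharply (higher TRS, longer survival,
so the negated-score risk has HR > 1); and the risk score ranks survival
times with C ≈ 0.69.

`runPipeline(pipelineConfig(seed = 1), outDir = "out")` chains all stages
(simulate → filter → derive → clonality → score → survival evaluation →
refinement → response) and writes a JSON report plus TSV/GMT artifacts with
provenance headers; `inst/scripts/reactsig.R` is a thin command-line wrapper.

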