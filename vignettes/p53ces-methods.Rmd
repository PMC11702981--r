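---
title: "Predicting non-mutational p53 functional deficiency: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting non-mutational p53 functional deficiency: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Tumor DNA sequencing classifies a tumor as *TP53* wild-type when no mutation
is found, but p53's tumor-suppressor activity can also be lost through
non-mutational routes (regulator amplification, post-translational control,
missed variant calls). Because p53 is a transcription factor, its activity
leaves a footprint in the expression of its target genes. `p53ces`
implements a workflow that reads that footprint:

1. **Gene selection.** Starting from a literature-derived candidate list of
   p53-regulated genes, keep those expressed in the reference tissue
   (median TPM strictly above 1) and run a two-group differential
   expression between adjacent normal tissue (NT) and tumors with *TP53*
   truncating mutations (TM). Candidates that are significantly
   down-regulated in TM (adjusted p ≤ 0.05, fold change ≤ 1/2) form the
   cohort-specific **DR** set; significantly up-regulated ones
   (fold change ≥ 2) form the **UR** set. Both boundaries are inclusive.
2. **Composite expression scores (CES).** Each sample is summarized by
   seven scores: GSVA, ssGSEA and a combined Z-score for the DR and UR sets
   separately, plus the first principal component over the union of both
   sets. These condense hundreds of genes into a seven-dimensional feature
   vector and damp single-gene noise.
3. **Classification.** A linear-kernel support vector machine is trained on
   NT (coded 0 = normal function) versus TM (coded 1 = reduced function)
   and then applied to the wild-type (WT) and missense/in-frame (MM)
   tumors, which never enter training. Samples with positive decision
   values are labeled **pRF** (predicted reduced function), the rest
   **pN**. When NT/TM samples are too few to train (xenograft panels),
   two-group Ward clustering on the standardized CES features takes over,
   anchored by reference centroids.
4. **Downstream evaluation.** Therapy-sensitivity signatures (RPS, RSS)
   are scored per sample by GSVA on TPM; reported variant sites are
   re-genotyped from RNA-seq allele counts; xenograft radiotherapy
   response is classified from RT/placebo median-survival ratios and
   tested for association with the predicted status by Fisher's exact
   test.

Every stage operates on synthetic cohorts shipped with the package, so the
whole workflow is testable without any data download.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes, not any particular dataset:

* Each sample carries a latent p53 activity `a` (1 normal, 0 reduced). NT
  samples always have `a = 1`, TM samples `a = 0`; WT and MM samples have
  `a = 0` with probability `phi_wt_rf` (default 0.9) and `phi_mm_rf`
  (default 0.99). The defaults mirror the reported real-data finding that
  most wild-type tumors behave like truncating-mutant ones, with missense
  tumors closer still to TM; MM shares the WT generative family rather
  than having its own expression model.
* Genes are 116 activated targets, 31 repressed targets, and 853
  background genes by default (the candidate-list proportions). In a
  reduced-activity sample, activated targets are multiplied by
  `2^-delta` and repressed targets by `2^delta` (`delta = 1.5` by
  default); background genes are untouched.
* Counts are negative binomial (dispersion 0.1) around log-normal per-gene
  baselines (meanlog `log(100)`, sdlog 1) scaled by log-normal per-sample
  library-size factors (sdlog 0.25). The baseline floor keeps candidate
  genes above the median-TPM filter, as a curated target list would be.
* The TPM and log2-FPKM layers are derived **from the sampled counts**
  with a fixed 1-kb length for every gene (so FPKM and TPM coincide
  numerically). Deriving these layers from the noiseless latent means was
  considered and rejected: it makes every background gene constant across
  samples — which breaks any cross-sample standardization or kernel
  density — and makes all same-group columns identical. Keeping the
  sampling noise in every layer is both more realistic and numerically
  well-posed.
* One global seed fans out to fixed per-generator child seeds, so the
  three simulators (`simulate_cohort()`, `simulate_allele_counts()`,
  `simulate_pdx()`) are reproducible and mutually independent.

Within-group variance of real tumor cohorts is not publicly characterized
at the level needed to fit it; the defaults were chosen once to give
separability comparable to the published score distributions (clearly
separated NT and TM groups, WT intermediate and widely dispersed). What
passing tests show is that the workflow recovers a *known* truth of this
structure; they do not certify performance on real cohorts with batch
effects, purity gradients, or copy-number structure, none of which are
simulated.

The PDX simulator draws RT/placebo survival ratios from a two-mode normal
mixture (non-responders near 1.0, responders near 2.0) and attaches a
latent pRF/pN status associated with responder membership at a
configurable odds ratio (default 20 against a 0.3 baseline pRF rate) — a
deliberately strong association so that recovery tests have an unambiguous
truth.

## Numerical and algorithmic choices

**Combined Z-score.** Per gene, `z = (x - mu) / sigma` across samples;
per sample, the set score is `sum(z_i) / sqrt(k)`. The formula as commonly
typeset is ambiguous between dividing by `k` and by `sqrt(k)`; the package
adopts `sqrt(k)`, the convention of the established GSVA toolchain, which
keeps the null variance independent of set size. Zero-variance genes are
dropped with a warning rather than erroring.

**ssGSEA.** Within-sample ranking (average ranks for ties), walk in
decreasing expression order with ties broken stably by gene id; in-set
steps weighted `rank^alpha` with `alpha = 0.25` (the published
single-sample default), uniform out-of-set steps; the score is the
integrated running-sum difference, finally divided by the score range
across the reference samples.

**GSVA.** Per gene, a Gaussian-kernel estimate of the cross-sample
cumulative distribution with bandwidth `sd/4` (the published default for
continuous expression); an `ecdf` kernel option exists so that desk-scale
oracles are exact. Per sample, genes are ordered by the kernel statistic
and given symmetric rank weights `|position - n/2|` with `tau = 1`; the
enrichment statistic is the sum of the largest positive and largest
negative running-sum deviations (the "difference of extreme deviations"
default form). Constant genes get a flat CDF value of 0.5.

**PC1.** Genes standardized over the reference samples, principal axis
from those samples, all samples projected. Eigenvector sign is arbitrary,
and the published description does not state a convention; the package orients the score
so the NT reference mean exceeds the TM reference mean, making "reduced
activity" always point downward.

**Leakage control.** Every cross-sample statistic — standardization
means/sds, kernel CDFs, ssGSEA rescaling range, PC1 loadings, feature
scaler — accepts a `ref` argument. During hold-out validation all of them
are estimated on the training partition only, and the differential
expression that selects the gene sets is re-run inside every repeat on the
training samples alone. The production model is then fit once on all NT
and TM samples with the full-cohort gene sets.

**Classifier.** Linear kernel makes the RBF width parameter inert, so the
internal grid search covers only the cost `C` (default
`{0.01, 0.1, 1, 10, 100}`) by stratified 5-fold cross-validation; ties
prefer the smallest `C`. Splits are stratified by class — a design choice
of this package — because unstratified splits of small
cohorts can lose a class entirely. Accuracy is implemented as
`(TP + TN) / total`; the published formula as typeset reads `TP + FN` in the
numerator, which is not accuracy and is treated as a typo. Degenerate
metric ratios (zero denominators) are reported as `NaN` with a warning,
never silently as 0.

**Differential expression.** Median-of-ratios size factors (geometric-mean
reference), Welch's t-test on `log2(normalized count + 1)`, BH adjustment.
The reference analysis used a full negative-binomial DE engine; this
package deliberately uses the lighter test because acceptance is truth
recovery on synthetic data, not numerical equality with an external tool.
The pseudo-count keeps fold changes finite for all-zero groups (such genes
are flagged `all_zero_group`).

**Re-genotyping.** A site is excluded below 10 mapped reads; it is called
mutant when the mutant-allele fraction is at least 0.1 **and** at least 5
high-quality reads support the mutant allele — both thresholds inclusive,
and the conjunction of both rules is required since the published filters apply
both. Reported percentages round half-up (44/98 → 45%).

**Responder cutoff.** The "changing point" of the ratio density is
interpreted as the deepest minimum between the two largest modes of a
Gaussian kernel density with Silverman's bandwidth. Two guards avoid
spurious calls: candidate modes must reach 10% of the maximum density
height, and the valley must dip below half the smaller mode's height.
Otherwise — including at realistic panel sizes around 35 models, where
Silverman's bandwidth often over-smooths the valley — the documented
default cutoff of 1.52 is returned with a warning. Responder
classification is inclusive (`ratio >= cutoff`).

**Fisher's exact test.** Two-sided p-value by probability ordering: the
sum of hypergeometric probabilities of all tables (fixed margins) no more
probable than the observed one, with the customary `1 + 1e-7` relative
tolerance; the sample (cross-product) odds ratio is reported, as the
convention choice is the package's own. Degenerate margins give p = 1 with
a warning.

**Wilcoxon comparisons.** Exact null distribution when the combined sample
size is at most 20 and tie-free; tie-corrected normal approximation with
continuity correction otherwise.

## Signature scoring

RPS is the negated GSVA enrichment of the four DNA-repair genes RIF1,
PARI (*F2R*), RAD51 and Ku80 (*XRCC5*), computed on TPM — the only
signature whose full membership is public and compact, so it is
the only one shipped. The RSS panel is published as 51 genes split into
positive and negative subsets, but the membership is not reproduced in the
text; `rss_scores()` therefore takes user-supplied subsets (two GMT sets)
and validates that they are disjoint. Each subset is scored independently,
matching the separate positive/negative presentation of the published signature. An
`exclude` argument removes genes overlapping the classifier features, so
the robustness check "does the group difference survive dropping shared
genes" is one call.

## Problem sizes and runtime

The test-suite and acceptance-script cohorts use the generator defaults:
1000 genes × 270 samples (60 NT / 100 WT / 50 MM / 60 TM), 10 hold-out
repeats, and 10 generator seeds for the recovery suite; negative controls
use 5 (suite) or 3 (script) label permutations × 2 repeats and one
`delta = 0` cohort; the PDX association uses 200 simulated models, and the
re-genotyping recall 500 sites at depth 100. These sizes give stable
means on a single CPU in a few minutes while keeping every distributional
assumption at its default.

## Known limitations

* The generator has no batch effects, tumor purity, copy-number
  structure, or read-level error model; recovery rates on it are upper
  bounds on real-data behavior.
* The DE stage has no dispersion shrinkage or covariate adjustment and
  supports only two-group designs.
* Pan-cancer pooling is plain concatenation with a cohort tag; no batch
  correction is applied (the published workflow applies none).
* The classifier offers no probability calibration; decisions are signed
  distances only.
* MM samples are modeled as a higher-penetrance copy of the WT family;
  real missense mutations have allele-specific effects the generator does
  not represent.
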