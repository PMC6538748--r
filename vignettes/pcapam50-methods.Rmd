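---
title: "PCA-guided iterative PAM50 subtyping: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PCA-guided iterative PAM50 subtyping: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

PAM50 assigns a breast tumor to one of five intrinsic subtypes — Basal-like,
Her2-enriched, Luminal A (LumA), Luminal B (LumB), Normal-like — by
correlating its expression profile over a 50-gene panel with five subtype
centroids and taking the best-correlated centroid. Before classification the
cohort must be *gene-centered*: each gene's reference level is subtracted so
the data sit on the scale the centroids were trained on. Because the
centroids were built on an estrogen-receptor (ER) balanced cohort, the
reference level is conventionally the per-gene **median of an ER-balanced
subset** — equal numbers of ER-negative and ER-positive cases — and that
subset is chosen using clinical (immunohistochemistry, IHC) ER status.

IHC ER status is a protein-level call and disagrees with expression-level ER
status in a few percent of cases. Each mislabeled case that enters the
balanced subset tilts the per-gene medians — and with a bimodal gene and an
exactly balanced subset, the median sits between the two modes, where a
one-sample imbalance can move it by the width of the inter-mode gap. The
result is systematic distortion of the luminal calls.

This package implements an iterative remedy that derives the ER-balanced
subset from the expression data itself:

1. **Conventional stage.** Build the *primary* subset from IHC: all TN and
   HER2+ cases as the ER− half, an equal random draw from LA ∪ LB1 ∪ LB2 as
   the ER+ half. Center, classify. These are the conventional calls.
2. **PC1 cutoff.** Run PCA on the panel (samples as observations, per-gene
   mean-centered, unscaled). Orient PC1 so ER+ cases sit on the negative
   side (the orientation is fixed by class means, not by input order). Scan
   the axis for the point minimizing the misclassification percentage
   `Px(x) = (Rx/R + Nx/N) × 100`, where `Rx` counts IHC-ER+ cases with
   PC1 ≥ x and `Nx` counts IHC-ER− cases with PC1 < x. Px is a step
   function changing only at observed coordinates, so the scan evaluates
   every observed value, every midpoint of consecutive values, and one
   sentinel beyond each extreme — an exact minimization; ties resolve to
   the smallest x.
3. **Intermediate stage.** Build the *secondary* subset from cases whose
   PC1 side agrees with IHC: TN/HER2+ on the right of the cutoff (ER− half)
   and an equal draw from LA/LB1/LB2 on the left (ER+ half). Center,
   classify: intermediate calls.
4. **Refined stage.** Build the *tertiary* subset from the intermediate
   calls alone — all intermediate Basal cases (ER− half) against an equal
   draw from intermediate LumA cases. No IHC information enters this stage.
   Center, classify: refined calls.

## Clinical subtyping and the MKI67 surrogate

IHC subtypes follow the standard grid: TN (ER−/PR−/HER2−), HER2+
(ER−/PR−/HER2+), LA (ER+/HER2−/Ki67−), LB1 (ER+/HER2−/Ki67+), LB2
(ER+/HER2+). Marker thresholds: ER/PR positive iff nuclear staining
strictly exceeds 1%; HER2 negative at IHC 0/1+, positive at 3+, and at 2+
arbitrated by FISH; Ki67 positive iff staining ≥ 15%. Any combination
outside the grid (notably ER−/PR+) is `unassignable` and is excluded from
balanced subsets and concordance denominators — public cohorts likewise
contain cases that cannot be IHC-subtyped.

When Ki67 IHC is absent, MKI67 gene expression substitutes for it. The
cutoff is derived from a reference cohort with known LA/LB1 labels: Gaussian
kernel densities are fitted to the two groups' MKI67 expression (Silverman's
rule per group unless overridden) and the cutoff is the point between the
two density modes where the curves are equal. Where two densities are
equal, their pooled mixture crosses both simultaneously (up to mixture
weights), so the equality point coincides with the pooled-curve intersection
while being better conditioned numerically; it is found by `uniroot` on the
density difference, and an error is raised if the LA mode is not below the
LB1 mode or no crossing exists between them. The surrogate is applied only
to ER+/HER2− samples with missing Ki67, boundary inclusive (≥ cutoff →
LB1), mirroring the Ki67 convention.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `uq_target` | 1000 | value the per-sample 75th percentile of nonzero expression is scaled to; recorded in metadata because log-scale classification is only approximately invariant to it |
| `log2_transform` | TRUE | log2(x+1) after normalization; raw-count correlations are dominated by magnitude outliers |
| `corr_method` | spearman | classification correlation; the single-sample convention of common PAM50 deployments. Pearson available |
| `er_pr_pct_threshold` | 1 (%) | ER/PR positivity, exclusive |
| `ki67_pct_threshold` | 15 (%) | Ki67 positivity, inclusive |
| `kde bandwidth` | silverman | per-group `bw.nrd0`; numeric override |
| `seed` | 1 | pipeline seed; per-stage seeds derive from it by stage-name hashing so stages replay independently |

Percentiles use linear interpolation between order statistics
(`quantile(..., type = 7)`); upper-quartile values differ across
conventions, so the choice is fixed and documented. Correlation ties break
by the fixed order Basal, Her2, LumA, LumB, Normal with a warning; ties are
measure-zero on real data. A constant (zero-variance) profile is
unclassifiable, not an error. Classification requires ≥ 40 genes shared
with the centroid panel and rejects samples missing > 20% of it. When an
eligible ER+ pool is smaller than its ER− counterpart (possible in the
PC1-filtered and intermediate-call-based subsets), the subset is capped at
the smaller size with a warning rather than failing: the method assumes
ER+-rich cohorts and the reverse case should degrade gracefully.

## The synthetic world

Everything is validated on generated cohorts with known truth, because the
cohorts behind the published evaluations are controlled-access. The
generator emulates the features the method actually exercises, and its
construction is deliberate:

* **Sparse gene modules.** Panel genes split into an ER/luminal module
  (~40%), a proliferation module (~25%, containing MKI67), a HER2-amplicon
  module (~15%) and normal-tissue genes (~20%), with random signed per-gene
  loadings — the module structure of the real panel. Subtype centroids are
  linear combinations of the modules chosen so the published correlation
  structure holds (LumA–LumB correlated, Basal anti-correlated with the
  luminals, Her2 intermediate, Normal-like near the mean with its own
  signal).
* **A luminal proliferation continuum.** Luminal tumors do not form two
  point clouds; they span a proliferation continuum on which the LumA/LumB
  distinction is a cutpoint. Luminal samples therefore interpolate between
  the LumA and LumB centroids, with per-sample blends drawn uniformly from
  a 0.6-wide window on each side of the panel's own rank-correlation
  crossover, leaving a 0.3 gap. Boundary-adjacent cases exist, so the
  luminal call is sensitive to centering error — the phenomenon the
  refinement exists to repair. MKI67 rides the same axis and is further
  shifted (+1.5 log2 units by default) in LumB-truth samples, so samples
  reclassified LumA→LumB carry elevated MKI67 *by construction*.
* **Stage-coherent references.** The method re-centers three times with
  differently composed subsets. In the real world all three approximate
  the same balanced reference; in a carelessly built synthetic world they
  do not, and the refined stage would relabel luminal samples even on
  clean data — an artifact of the world, not a property of the method.
  Three constructions enforce coherence: centroids are expressed relative
  to the per-gene *median* of an idealized balanced population (50%
  Basal/Her2, 50% luminal continuum); Basal's proliferation weight is
  solved so the tertiary (Basal ∪ LumA-call) reference coincides with the
  balanced one in the discordance-free limit (Basal duly ends up the most
  proliferative profile, as in real tumors); and proliferation genes are
  generated at a low expression baseline so the 50-gene panel's upper
  quartile — the normalization anchor — is independent of proliferation
  state, as a transcriptome-wide upper quartile is in real data.
* **ER discordance.** Each sample's clinical ER (and PR, which follows it)
  is flipped with probability `er_discordance_rate` (default 0.1) relative
  to expression truth; flips land the sample in the wrong ER-balanced pool,
  which is exactly the failure mode of IHC-based centering.
* **Normal-like samples** are assigned ER truth by a fair coin (a
  bookkeeping choice; they are neither class) and present equivocal
  pathology (ER−/PR+ pattern, or unscorable Ki67), making them clinically
  unassignable — as a fraction of real cases are — so they do not enter
  balanced subsets.
* **Defaults**: n = 300, σ = 0.3 on log2 scale, proportions
  0.17/0.08/0.40/0.25/0.10 (Basal/Her2/LumA/LumB/Normal, loosely shadowing
  large public cohorts), LB2 fraction 0.3 of LumB.

What a green test establishes: the implementation's internal contracts
(exact Px minimization, centering identities, boundary conventions,
determinism) and the method's qualitative behavior (noiseless cohorts are
recovered exactly at every stage; injected ER discordance degrades
conventional calls and the refinement recovers part of the loss; switched
LumA→LumB cases carry elevated MKI67). What it does not establish: the
published effect sizes on real cohorts, platform noise, probe effects, or
batch structure — none of which the generator attempts to model.

## Numerical choices and edge cases

* Px boundary conventions are inherited exactly: ER+ misclassified when
  PC1 ≥ x (inclusive), ER− when PC1 < x (strict); the sample at the cutoff
  falls on the right side, keeping `split_by_cutoff` consistent with `Rx`.
* The PC1 orientation rule (ER+ class mean ≤ ER− class mean) replaces any
  dependence on input row order; reflected input produces identical
  oriented coordinates.
* Duplicate gene rows collapse to the highest-variance row, following the
  highest-variability probe policy used for array data; dropped counts are
  reported.
* Missing values propagate (never imputed), are excluded pairwise from
  quantiles and medians, and a centroid panel below 40 genes is a hard
  error (40–49 warns).
* All writers emit 15 significant digits so read-back round-trips at float
  precision, and a fixed seed makes `calls.tsv` byte-identical across runs.

## Known limitations

* Cross-cohort harmonization (batch adjustment before pooling a reference
  and a target cohort for the MKI67 cutoff) is the caller's responsibility;
  the cutoff object records the reference cohort id for audit.
* The method requires both ER classes in the cohort; single-class cohorts
  are rejected at the PCA step by design.
* Risk-of-relapse scoring, survival analysis, and centroid re-training are
  out of scope.
* The ER+ halves of the balanced subsets are drawn uniformly from the
  eligible pool (not stratified by luminal subclass); a multi-draw
  consensus mode is deliberately not the default, matching the single-draw
  method description.
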