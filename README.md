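# pcapam50

Iterative, PCA-guided PAM50 intrinsic subtyping of breast tumor expression
cohorts — for bioinformaticians who need PAM50 calls on cohorts whose
clinical ER status is skewed or imperfectly concordant with expression.

## Why

PAM50 classifies a tumor by Spearman correlation of its 50-gene profile
with five subtype centroids (Basal, Her2, LumA, LumB, Normal-like). Before
classification each gene is centered on the median of an **ER-balanced
subset** (50% ER−, 50% ER+), conventionally chosen by immunohistochemistry
(IHC). IHC ER status disagrees with expression-level ER status in a few
percent of cases, and every mislabeled case in the balanced subset tilts
the per-gene medians, distorting the luminal calls in particular.

This package derives the balanced subset from the expression data itself,
in three stages:

1. **conventional** — center on the IHC-derived subset, classify;
2. **intermediate** — find the ER boundary on PC1 of the panel by
   minimizing the misclassification percentage

   `Px(x) = (Rx/R + Nx/N) × 100`

   (`Rx` = IHC-ER+ cases with PC1 ≥ x, `Nx` = IHC-ER− cases with PC1 < x),
   rebuild the subset from cases whose PC1 side agrees with IHC, center,
   classify;
3. **refined** — rebuild the subset from the intermediate Basal and LumA
   calls only (no IHC), center, classify.

The refined calls typically reassign a proliferative, MKI67-high slice of
conventional LumA to LumB and agree better with clinical subtypes. Also
included: IHC subtyping rules (TN, HER2+, LA, LB1, LB2), an MKI67
expression surrogate for missing Ki67 (kernel-density equality cutoff
between reference LA and LB1 groups), upper-quartile normalization,
concordance tables, and a synthetic cohort generator with known truth.

## Worked example

```r
library(pcapam50)

ex  <- example_cohort(n_samples = 60, seed = 42)   # synthetic, known truth
fit <- run_pipeline(ex$cohort$expression,          # genes x samples, counts
                    ex$cohort$clinical,            # sample_id + IHC fields
                    ex$centroids,                  # 50 x 5 centroid matrix
                    pcapam50_config(seed = 42))
print(fit)
#> PCA-PAM50 fit: 60 samples
#>   PC1 cutoff: -1.82704 (Px = 28.57 %)
#>   subset sizes (neg+pos): primary 24+24, secondary 18+18, tertiary 10+10
#>   refined calls:
#>  Basal   Her2   LumA   LumB Normal
#>     10      9     19     14      8

concordance(fit$calls$ihc_subtype, fit$calls$conventional.label)$consistency_percent
#> [1] 82.69231
concordance(fit$calls$ihc_subtype, fit$calls$refined.label)$consistency_percent
#> [1] 86.53846
```

The printout reads: the ER boundary on PC1 sits at −1.83 with 28.6% summed
misclassification (the synthetic cohort carries 10% deliberate IHC-ER
discordance); the three ER-balanced centering subsets were 24+24, 18+18 and
10+10 samples; and agreement with the clinical subtypes rises from 82.7%
(conventional) to 86.5% (refined) — the refinement converted two
discordantly-centered luminal/HER2 calls to their clinical matches.

Per-sample output: `fit$calls` has one row per sample with the IHC label,
all three stage labels, five per-centroid correlations per stage, and the
PC1 coordinate; `write_outputs(fit, dir)` writes `calls.tsv`,
`subsets.tsv`, `px_scan.tsv`, two concordance tables, and
`run_metadata.yaml` (fixed column orders, 15 significant digits, byte-stable
under a fixed seed).

Reading your own data:

```r
m        <- read_expression("expression.tsv")   # genes in rows, TSV/CSV
clinical <- read_clinical("clinical.tsv")       # sample_id, er_ihc, pr_ihc,
                                                # her2_ihc, her2_fish, ki67_pct
ctr      <- read_centroids("pam50_centroids.tsv")
fit      <- run_pipeline(m, clinical, ctr, pcapam50_config(seed = 1))
```

If Ki67 IHC is unavailable, derive an MKI67 cutoff from a harmonized
reference cohort with known LA/LB1 labels and pass it to the pipeline:

```r
cut <- derive_mki67_cutoff(reference_matrix, reference_ihc_table)
fit <- run_pipeline(m, clinical, ctr, pcapam50_config(seed = 1),
                    mki67_cutoff = cut)
```

A command-line front end is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/pcapam50.R", package="pcapam50"))')" \
    run --expr expression.tsv --clinical clinical.tsv \
    --centroids centroids.tsv --out results/ --seed 1
```

(`simulate --out DIR --n 300 --seed 1` writes a synthetic cohort; exit
codes: 0 success, 2 validation error, 3 stage failure.)

## Output column order (`calls.tsv`)

`sample_id`, `ihc_subtype`, `conventional.label`,
`conventional.cor.{Basal,Her2,LumA,LumB,Normal}`, `intermediate.label`,
`intermediate.cor.*`, `refined.label`, `refined.cor.*`, `pc1`.
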