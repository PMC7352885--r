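# baxloc

Scoring of BAX/BAK subcellular localization from fractionation western
blots, and classification of "BAX-protected" tumors in paired
tumor/non-tumor cohorts.

## The problem

Cells restrain the proapoptotic BCL-2 effectors BAX and BAK by constantly
retrotranslocating them from the mitochondria into the cytosol. At
steady state the mitochondrial fraction of either protein is

    mito / total = k_trans / (k_trans + k_retro)

so the retrotranslocation rate `k_retro` sets the mitochondrial pool and
with it the apoptotic predisposition of the cell. Some tumors accelerate
BAX retrotranslocation, shifting BAX almost entirely into the cytosol —
typically by about two orders of magnitude relative to matched non-tumor
tissue — and thereby protect themselves from BAX-mediated apoptosis.

`baxloc` quantifies that shift from subcellular-fractionation western
blots. Band intensities are calibrated against a per-blot HeLa
whole-cell-lysate titration (ordinary least squares; amounts in
HeLa-equivalent units are comparable across blots), normalized to the
fraction loading controls (COX IV mitochondrial, β-ACTIN cytosolic), and
combined into the relative localization quotient

    rel_loc = (analyte_mito / COXIV_mito) / (analyte_cyto / ACTIN_cyto)

reported on the log10 scale. A patient is called **protected** when the
paired shift Δ = log10 rel_loc(tumor) − log10 rel_loc(non-tumor) for BAX
is ≤ −1 (configurable, or fitted by 1-D 2-means with `threshold = "auto"`).
Cohorts are additionally rank-partitioned by non-tumor mitochondrial BAX
into four balanced categories (8/9/9/8 for n = 34). Downstream tooling
covers Pearson correlation, Student's t tests, one-way ANOVA with
Holm–Šidák adjustment, quantile normalization, presence filtering,
per-gene differential expression, hierarchical clustering, kNN imputation,
Kaplan–Meier estimation and log-rank testing.

A shuttling-kinetics simulator generates complete synthetic cohorts —
ground-truth localizations, rendered noisy blot lane tables with titration
standards, matched expression matrices and survival times with a planted
protected subgroup — so the entire pipeline is testable without any
external data.

## Worked example

```r
library(baxloc)

cfg <- cohort_config(seed = 7)   # 34 patients, 11 planted protected
res <- run_all(cfg)              # simulate -> render -> calibrate ->
                                 # score -> classify -> DE -> survival

res$manifest$n_protected_calls
#> [1] 12

head(res$calls, 4)
#>   patient_id delta_log10         label      category
#> 1        P01  -3.1622266     protected  high_extreme
#> 2        P02   0.1578896 non_protected high_moderate
#> 3        P03  -0.3165845 non_protected   low_extreme
#> 4        P04  -2.5681832     protected  high_extreme

evaluate_calls(res$calls, res$truth)$confusion
#>                called
#> planted         non_protected protected
#>   non_protected            21         2
#>   protected                 1        10

res$projection$test
#> log-rank (Mantel-Cox) test: statistic = 3.64093, df = 1, p = 0.05638 (n = 11, 23)
```

The classifier calls 12 of 34 tumors protected, recovering 10 of the 11
planted ones (3 errors at the default blot noise of 0.15 log10 units per
band). `delta_log10` is the paired BAX shift: P01's tumor moved BAX about
3 log units to the cytosol. The protected calls concentrate in the
high-mitochondrial-BAX categories, and the signature-projection workflow
(cluster samples on the differential genes, compare the clusters'
survival) shows the corresponding survival separation.

A thin command-line wrapper around the same pipeline is installed at
`inst/scripts/run_pipeline.R`:

```sh
Rscript inst/scripts/run_pipeline.R --out results/run1 --seed 7
```

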