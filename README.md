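# stagewise

Stage-specific differential expression analysis for staged cancer
transcriptomes.

When tumors are compared to controls as a single class, the information
about *which stage* of the disease a gene's dysregulation belongs to is
lost. `stagewise` recovers it: starting from a normalized, log2-transformed
expression matrix (e.g. TCGA RSEM data) annotated with AJCC/TNM pathologic
stages, it identifies genes that are differentially expressed specifically
in one stage — candidate drivers of initiation (stage I), progression
(II–III) or metastasis (IV) — and genes whose mean expression rises or
falls strictly monotonically with stage, candidate markers of progression.

It is written for computational biologists analysing staged bulk RNA-Seq
cohorts, in a tidyverse style: data frames in, tibbles out, `tidy()` /
`glance()` / `autoplot()` methods on every fitted object.

## The model

For each gene, expression *y* is modelled over controls and the four
stages in three parameterizations:

- **Baseline (genome-wide scan)**
  `y = α + β₁x₁ + β₂x₂ + β₃x₃ + β₄x₄`, where `xₖ` indicates membership in
  stage k; the intercept α is the control baseline and `βₖ` the stage-k
  log2 fold-change (lfc) versus control. Optional mean–variance precision
  weights (lowess trend of √SD on average expression, weight =
  predicted⁻⁴) can precede this fit.
- **Cell means (contrasts)** `y = β₀x₀ + … + β₄x₄` with one indicator per
  group; each coefficient is a group mean. Stage-vs-control contrasts
  `(−1, …, +1, …)` and all six inter-stage contrasts are propagated through
  this fit.
- **Numeric stage (trend)** `y = aX + b` with `X ∈ {0,1,2,3,4}` for
  control, I–IV.

Per-gene residual variances `s²` (df *d*) are shrunk by empirical Bayes
toward a prior `s₀²` (df *d₀*) estimated by method of moments on
`log s²` (digamma/trigamma matching):
`s̃² = (d₀s₀² + d·s²)/(d₀ + d)`, giving moderated t statistics with
`d₀ + d` degrees of freedom, and a moderated F for the joint stage effect.
P-values are Benjamini–Hochberg adjusted per statistic family across genes.

Stage specificity is then decided by:

1. **Stage string** — a four-bit code, bit k = 1 iff `|lfcₖ| > 2`
   (absolute value, since drivers may be up- or downregulated). Genes with
   string `0000` are eliminated; the rest are **assigned** to their
   argmax-|lfc| stage.
2. **Four-pronged cascade** — (i) BH-adjusted p of the assigned stage's
   control contrast `< 0.001`; (ii)–(iv) raw p of each inter-stage
   contrast involving the assigned stage `< 0.05`. A gene is
   stage-specific iff all four pass.
3. **Stage-IV prune** — the stage-IV group is typically tiny; its
   survivors must additionally show a strictly monotone group-mean
   trajectory and are cut to the top 10 by genome-wide adjusted p.

The monotonic screen keeps genes with strictly ordered group means
(control < I < II < III < IV, or the reverse) whose numeric-stage slope is
significant (adjusted p < 0.05), ranked by that p-value.

## Worked example

The built-in simulator plants ground truth with the statistical structure
the pipeline assumes — gene variances from a scaled-inverse-chi-square
prior, stage-specific / monotonic / globally-DE / null genes:

```r
library(stagewise)
run <- run_pipeline(sim = sim_config(n_genes = 2000, seed = 42),
                    out_dir = "demo_out")
run$analysis
#> <stage_analysis> 2000 genes, 396 samples
#> stage-assigned: 400 (1600 eliminated as '0000')
#> stage-specific: 340 (I=60, II=60, III=60, IV=160)
#> significant monotonic: 117
```

2000 genes were simulated over 396 samples (50 controls, 170/85/85/6 in
stages I–IV). 1600 genes never exceed |lfc| 2 and are eliminated; 400 are
assigned a stage. All 60 planted genes per stage I–III are recovered as
stage-specific. The stage-IV bin (160) collects both the planted
stage-IV genes and the planted monotonic genes — whose maximal |lfc| is
necessarily in stage IV — which is exactly what the monotone-prune step is
for:

```r
dplyr::as_tibble(run$analysis$stage4_pruned)[1:3,
    c("gene", "lfc_IV", "direction", "adj_p")]
#>   gene      lfc_IV direction adj_p
#> 1 GSIM01854   4.02 UP            0
#> 2 GSIM01918  -4.02 DOWN          0
#> 3 GSIM01920  -4.04 DOWN          0

glance(run$analysis$baseline_stats)
#>   n_genes df_prior var_prior df_residual df_total
#> 1    2000     3.94     0.809         391     395.
```

The moderation recovered a prior df of 3.94 against the simulated truth
of 4 (the prior variance is on the precision-weighted scale here). Real
data enter through the same front door:

```r
run <- run_pipeline(expression = "LIHC_expression.tsv",
                    clinical = "LIHC_clinical.tsv",
                    out_dir = "results")
```

which parses the `Hybridization REF` barcodes (first 10 characters patient
id, next two the tumor/normal code), merges the clinical
`pathologic stage` (substages collapsed), filters genes with σ < 1,
drops stage-missing tumors, and writes `results_linear_model.tsv`,
`results_monotonic.tsv`, `stage_strings.tsv`, `stage_specific.tsv`,
`partition_counts.tsv` and a JSON run manifest. A thin CLI wrapper lives
at `inst/scripts/stagewise-pipeline.R`.

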