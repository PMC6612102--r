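---
title: "Stage-specific differential expression: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-specific differential expression: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagewise)
```

## The problem

Two-class tumor-versus-control testing collapses all disease stages into
one label, discarding the question this package exists to answer: *in
which stage* is a gene's dysregulation concentrated? `stagewise`
implements a staged analysis of a normalized log2 expression matrix
(genes × samples) annotated with controls and AJCC stages I–IV, producing
three result families: a genome-wide moderated-F scan of any stage
effect, a stage-specific gene list controlled for confounding
differential expression in the other stages, and a monotonic-trend screen
across the ordered stages.

## Preprocessing

Input follows the firebrowse/TCGA layout. Barcodes are parsed by
dropping `-`/`.` separators and reading the first 10 characters as the
patient identifier and characters 11–12 as the sample-type code (01–09
tumor, 10–19 normal). Raw clinical stage strings are matched
case-insensitively after stripping a `stage` prefix and substages A–C
are collapsed into the parent stage; unrecognized non-empty values are
treated as missing with a warning. The filter order is fixed: clinical
merge, then removal of genes with sample standard deviation (all samples,
denominator $n-1$, log2 scale) strictly below `sigma_min = 1`, then
removal of tumor samples without stage annotation. Controls are never
dropped, and a tumor sample without a clinical row is recorded as
stage-missing rather than aborting the run. The standard-deviation
estimator and the merge-time application of the variance filter are
package choices; the quantity filtered on is the dispersion of each gene
across *all* samples, controls included.

## Linear models and moderation

Each gene is fit under three designs over groups
$(\mathrm{control}, I, II, III, IV)$:

* baseline: $y = \alpha + \sum_k \beta_k x_k$, intercept = control
  baseline, $\beta_k$ = stage-$k$ log2 fold-change;
* cell means: $y = \sum_k \beta_k x_k$ without intercept, coefficients =
  group means (the two designs span the same column space, and the
  package tests their fitted values for exact agreement);
* numeric stage: $y = aX + b$, $X \in \{0,\dots,4\}$.

Fits are per-gene least squares, vectorized through a single QR when
unweighted and per-gene `lm.wfit` when precision weights are supplied.
A rank-deficient design is an error that names the collinear columns.

**Precision weights.** A mean–variance trend (lowess of
$\sqrt{\mathrm{residual\ SD}}$ on average log2 expression, span 0.5) can
be estimated from an initial unweighted fit; each observation's weight is
the trend prediction at its fitted value raised to the $-4$th power.
Weighting already-normalized RSEM-style log2 data is statistically
unusual — the mean–variance trend of such data is typically nearly flat,
making the weights close to constant — so the step is exposed as a
per-model switch: on by default only for the genome-wide baseline scan,
off for the cell-means and numeric fits. With fewer than 10 genes the
trend is unfittable and unit weights are used with a warning. Note that
weighted residual variances live on the weighted scale, so the estimated
prior variance is only interpretable on that scale.

**Empirical Bayes.** The variance-prior hyperparameters $(d_0, s_0^2)$
are estimated by method of moments on $\log s^2$, using the digamma /
trigamma moments of the scaled-F marginal implied by a
scaled-inverse-chi-square prior; the trigamma inversion is a Newton
iteration. When the observed log-variance dispersion does not exceed its
sampling component, $d_0 = \infty$ and the prior variance is the pooled
mean variance. Posterior variances
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0+d)$ give moderated t (df
$d_0+d$, capped at the pooled residual df) and a moderated F comparing
the full fit to an intercept-only fit. Residual variances of exactly zero
are floored at $10^{-12}$ so a constant gene yields an infinite-t-free
ranking rather than an error. Setting $d_0 = 0$ recovers ordinary t and
classical F exactly; $d_0 = \infty$ fully pools — both limits are tested
as closed forms, and the whole moderation path is cross-checked against
an independent reference implementation on a fixture.

BH adjustment is applied per statistic family (per contrast, per model F)
across genes, via the standard step-up procedure; the implementation is
verified against a brute-force oracle over all p-vector permutations of
length ≤ 6.

## Contrasts and the stage string

Stage-vs-control contrasts $(−1$ on control, $+1$ on the stage$)$ and the
six inter-stage pairs (earlier stage $+1$; orientation affects only the
estimate's sign, never $|t|$ or p) are propagated through the cell-means
fit: estimate $c'\hat\beta$, unscaled SD $\sqrt{c'(X'WX)^{-1}c}$,
moderated inference as above. Inter-stage p-values are two-sided and are
used *raw* in the cascade, while the control contrast uses BH-adjusted
p — mirroring the asymmetric roles the significance criteria give them.

The four-bit stage string sets bit $k$ iff $|\mathrm{lfc}_k| > 2$
(strict; a gene at exactly 2 is not called). `0000` genes are
eliminated; the rest are assigned to the stage of maximal $|\mathrm{lfc}|$,
with ties broken toward the earliest stage and flagged — ties have
measure zero in continuous data, so the rule is a determinism device, not
a modelling statement. The significance cascade then requires, for the
assigned stage: adjusted control-contrast p $< 0.001$ (a driver's profile
should depart markedly from controls) and raw p $< 0.05$ for each of the
three inter-stage contrasts involving that stage (relaxed, for
sensitivity). Survivor counts after each prong are retained. Because only
the assigned stage's contrasts are tested, specificity is exclusive by
construction: at most one stage per gene.

## Monotonic screen and the stage-IV prune

A gene is monotonically up (down) when its five group means are strictly
increasing (decreasing); any tie or reversal breaks the call. Strict
monotonicity implies the maximal absolute deviation from control occurs
in stage IV, so that property is asserted as an invariant rather than
applied as an extra filter. Significance comes from the numeric-stage
slope's moderated t (BH-adjusted $p < 0.05$) — the slope t and the model
F are equivalent up to squaring here (1 numerator df), and the slope was
chosen for its sign information. Ranked output is sorted by adjusted p.

Stage-IV specificity inherits very low power from the tiny stage-IV
group, and planted-truth simulations show why a prune is needed: any
strongly monotone gene has its largest $|\mathrm{lfc}|$ in stage IV and
passes the cascade there. Stage-IV survivors are therefore additionally
required to be strictly monotone and are cut to the top `stage4_top_n`
(default 10) by the genome-wide scan's adjusted p.

## The synthetic-data generator

The generator is first-class, tested code and defines the study
conditions used throughout validation:

* group sizes $(50, 170, 85, 85, 6)$ for (control, I, II, III, IV) —
  a staged cohort with many early-stage samples, ~50 controls and a very
  small stage-IV group, the imbalance that motivates the prune;
* gene variances $s_0^2 d_0 / \chi^2_{d_0}$ with $d_0 = 4$,
  $s_0^2 = 0.05$ — the scaled-inverse-chi-square prior the moderation
  step assumes, enabling parameter-recovery tests;
* baselines uniform on $[4, 12]$ log2 units; class mixture 80% null, 3%
  per stage-specific class, 3% + 2% monotonic up/down, 3% global DE;
* planted effects: a single offset of magnitude `effect_lfc = 3`
  (random sign) for stage-specific genes, equal per-stage steps of
  `monotone_step = 1` for monotonic genes (strict ordering, not
  curvature, is what the detector tests), and a uniform offset in all
  four stages for global-DE genes — the class the cascade must reject.

Identical configurations (including seed) give bit-identical matrices.
The writer emits firebrowse-style TSVs (barcode header row, a second
data-type header row, lowercase clinical keys, substage letters planted
on stages III/IV) that round-trip losslessly through the ingest path.

What the generator does *not* emulate: sequencing counts, library-size
effects, correlated genes, batch structure, or outlier samples. Passing
tests therefore demonstrate correctness of the estimators and decision
rules under the assumed model, not robustness to real-data pathologies.
One consequence of the chosen noise scale deserves note: with planted
residual SDs near 0.25 log2 units, the real-data variance filter
($\sigma < 1$) would remove essentially every null gene, so simulated
runs skip that filter and the validation exercises the modelling core on
all genes — a stricter check than filtering would allow.

## Problem sizes and numerical choices

Validation uses 10,000 genes for hyperparameter recovery (estimates
within a few percent of truth), 2,000 genes at the default group sizes
for planted-gene recovery (precision and recall 1.0 for stages I–III in
the shipped runs; stage IV is exempt because its six samples cannot
separate it from monotone behaviour — by design), 800-gene all-null
replicates for type-I behaviour, and small hand-built fixtures for the
exact oracles. Tolerances: $10^{-10}$ relative for algebraic identities,
20% for stochastic hyperparameter recovery, strict equality for the
discrete classifications.

## Limitations

* Stage is treated as an ordered label; no survival or time-to-event
  information enters the model.
* The cascade tests only the assigned stage's contrasts; a gene strongly
  but not maximally dysregulated in a second stage is invisible to it.
* A constant variance prior is used (no trend on the prior, no robust
  down-weighting of variance outliers).
* The |lfc| > 2 threshold is a hard decision boundary; genes near it are
  classified unstably under resampling.
* Replicating the published cohort's counts requires the authors'
  deposited merged dataset, which must be downloaded separately.
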