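---
title: "Network-pair enrichment analysis of functional connectivity: models and methods"
author: "fcea authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-pair enrichment analysis of functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcea)
```

## The problem

Brain-wide association studies relate resting-state functional connectivity
(fc) — correlations between the time series of regions of interest (ROIs) —
to individual differences in behavior. With ~300 ROIs there are ~42,000 ROI
pairs, so per-pair ("mass-univariate") testing is both underpowered after
multiplicity correction and hard to interpret. Enrichment analysis (EA)
borrows the logic of gene-set testing: ROI pairs are grouped into
*network-pair blocks* (all pairs whose two ROIs belong to a given pair of
functional networks, e.g. salience-visual), and inference is performed at
the block level, asking whether association signal *clusters* in a block.

`fcea` implements this workflow end to end: per-pair regression screening,
three block-level enrichment statistics, permutation inference that respects
the correlational structure of the data, the surrounding quality-control and
reporting steps, and a synthetic cohort generator that reproduces the data
structure the method assumes, so that its calibration and power can be
studied without access to subject data.

## Screening model

For each ROI pair $q$, connectivity is Fisher-z transformed
($z = \operatorname{atanh} r$, a variance-stabilizing choice; the transform
is applied before screening) and regressed on the behaviors and covariates:

$$ z_{iq} = \beta_0 + \beta_{SA} SA_i + \beta_{RRB} RRB_i
  + \gamma_1 GAD_i + \gamma_2 CONP_i + \gamma_3 LIMB_i + \gamma_4 DAS_i
  + \text{site}_i + \text{sex}_i + \text{age}_i + \varepsilon_{iq}. $$

SA and RRB are the ADOS-2 calibrated severity scores for social affect and
restricted/repetitive behavior (ordinal 1-10, floor-inflated); GAD, CONP,
LIMB and DAS are continuous adjustment behaviors (anxiety, inattention,
motor coordination, matrix reasoning); site, sex and age at scan enter as
fixed effects (sites reference-coded against the alphabetically first site;
age mean-centered for conditioning, which changes neither t nor F).

The screening statistics per pair are the two-sided t statistics for SA and
RRB and the partial F for dropping both (numerator df 2, denominator df
$n - \mathrm{rank}(X)$; 85 for 97 subjects with 4 sites, 77 for 89). All
pairs share one design, so the fits reuse a single QR decomposition with the
tested columns placed last; the vectorized path is contractually identical
(to $10^{-8}$) to per-pair least squares, which the tests verify against
`lm()` and a normal-equations solver.

## Enrichment statistics

For a block $S$ with $k$ member pairs, with screening statistics $s_q$ over
all $P$ pairs:

* **ORA** (over-representation): the fraction of members whose two-sided
  screening p-value clears $\alpha = 0.05$, i.e.
  $|t_q| > t_{1-\alpha/2,\,df}$ (F channel: $F_q > F_{1-\alpha;\,2,df}$).
  Null expectation is exactly 5%. A hypergeometric upper-tail p-value is
  available as a fast analytic cross-check; permutation p-values are the
  primary inference.
* **max-mean**: directional, t channels only. The default form is
  Efron-Tibshirani's: $\max(\sum_q s_q^+ , \sum_q s_q^-)/k$, the larger of
  the one-sided means taken over the full block size. A literal
  signed-difference variant $(\sum_q s_q^+ - \sum_q s_q^-)/k$ is available
  as a configuration option. The Efron-Tibshirani form is the default
  because its permutation null is positive with median near 0.5 for t
  screening — consistent with reported null envelopes for this statistic in fcMRI
  enrichment analyses (median ~0.54, 0.1%-99.9% quantiles ~[0.31, 1.25]) — whereas the signed
  difference has a symmetric null centered at 0. The acceptance tests
  recompute both null medians and document this contrast.
* **GSEA**: a weighted Kolmogorov-Smirnov running sum. All pairs are ranked
  by decreasing $|t|$ (F channel: by $F$); walking the ranking, the sum
  gains $|s_q|^w / \sum_{S} |s|^w$ at members and loses $1/(P-k)$
  elsewhere; the enrichment score is the maximum positive deviation,
  in $[0, 1]$. The default weight is $w = 1$; $w = 0$ reduces to the
  classic unweighted KS statistic (verified against a direct running-sum
  oracle). Weighted-vs-classic and absolute-vs-signed ranking are design
  choices this statistic's literature leaves open; the defaults are
  recorded in the output metadata.

## Permutation inference

The data are heavily cross-correlated (pairs share ROIs, subjects, and
block structure), so analytic nulls are untrustworthy. Inference is by
subject-level permutation: within one replicate a *single* relabeling is
applied brain-wide, all pairs are re-screened under it, and every block
statistic is evaluated, so the inter-pair correlation structure is carried
into the null. Two schemes are provided:

* **Freedman-Lane** (default): connectivity is decomposed into the
  covariates-only (reduced-model) fit plus residuals; residual rows are
  permuted, the data reconstructed, and the full model refitted. This is
  the standard way to permute in the presence of nuisance covariates.
* **joint behavior shuffle**: the six behavior rows are permuted jointly
  against fixed connectivity and covariates.

Neither scheme is canonical for this analysis; both are exchangeable
under the global null and agree distributionally (tested), and the choice
is recorded in the analysis configuration. P-values use the
add-one estimator $p = (\#\{null \ge obs\} + 1)/(B+1)$, upper tail;
two-sided behavior is inherited from the $|t|$-based statistics rather than
from separate tails. Default permutation counts follow the scale such analyses are run at
(250,000 for ORA and max-mean, 25,000 for the compute-heavier GSEA); statistics
sharing a count share one ensemble, distinct counts get independent
streams. The per-permutation cost is kept low by an algebraic identity: with
the tested columns last in the QR, every statistic depends on the permuted
data only through $U = (P^\top Q)^\top R_W$, so the small $Q$ factor is
permuted rather than the large residual matrix (implemented in compiled
code and verified element-wise against the plain reconstruction).

With 13 networks there are 91 blocks (78 between- plus 13 within-network;
within-network blocks are included by default; excluding them is a
subsetting of the result table). Declaring a block
significant at a per-test level of $\alpha_{pt} = 0.0005$ gives an
experiment-wide false-positive rate near
$1 - (1-\alpha_{pt})^{91} \approx 0.045$; `calibrate_fwer()` estimates the
realized rate (the Westfall-Young min-p distribution's tail) by direct
replication — each simulated null cohort receives its own permutation test
of every block, with early stopping once no block can still resolve the
threshold — and the acceptance suite confirms the estimate sits at this
closed form. The calibration uses the continuous max-mean statistic: the
ORA statistic's discrete lattice (counts out of $k$) makes its permutation
p-values conservative at desk-scale block sizes, which would understate the
rate the procedure attains on a continuous statistic.
A finding is reported as *convergent* when every statistic available for a
channel clears $\alpha_{pt}$.

## The synthetic cohort generator

`sim_config()` fixes the study conditions the package is exercised under:

* **Manifest**: 97 subjects across 4 sites (proportions 34/23/23/17),
  65% at high familial likelihood, 57% male, ages 8.1-12.0 (truncated
  normal, mean 10.1), diagnosis rates 17.5%/11.8% by group, 8 sleep-flagged
  subjects drawn among the non-diagnosed, 12 medication-flagged. A
  deterministic 121-subject QC fixture encodes the canonical attrition
  7 (motion) + 1 (clinical) + 16 (incomplete behavior) = 24, retaining 97.
* **Behaviors**: a Gaussian copula (exchangeable latent correlation 0.3)
  links six measures. SA and RRB use floor-inflated ordinal marginals on
  1-10 — floor mass 0.60 and 0.55 with a geometric tail (decay 0.75) that
  puts ~15% of subjects at 5 or above, matching the qualitative pattern
  that most subjects score at floor while a tail reaches the
  moderate-to-high range. The continuous scores use instrument-like scales
  (T-score-style mean 50, SD 10; LIMB 15, SD 5). Behavior-behavior
  correlations and site distributions of scores are not observable
  quantities here, so the copula correlation is a configurable assumption,
  not a calibrated value.
* **Connectivity**: subjects-by-pairs Fisher-z values from a block model:
  population means 0.30 within networks, 0.05 between, 0.02 for the
  salience-visual block (weak at the group level, as observed); a
  subject-by-block random effect (SD `tau_block`, default 0.02) supplies
  within-block covariance; independent pair noise (SD 0.18) dominates.
  The default within-block covariance is deliberately weak so that block
  statistics operate near their nominal resolution at desk scale; real
  data likely carries stronger block-shared variance (global signal,
  arousal), which widens permutation nulls — the knob is exposed precisely
  so users can study that regime.
* **Planted effect**: an optional coupling adds
  $\text{slope} \times (b_i - \bar b)$ to the target block's mean, linear
  in a chosen behavior, matching the linear screening model so power is
  analyzable; slope 0 is an exact exchangeable null.
  `calibrate_slope()` converts a target mean within-block $|t|$ into a
  slope through the design-based standard error
  ($\delta$ solves $E|N(\delta,1)| = $ target;
  slope $= \delta\,\sigma_{tot}\sqrt{(X^\top X)^{-1}_{jj}}$).
* **Time series** (optional slower path): ROI series from a network factor
  model whose correlations converge to the block model, with nine AR(1)
  nuisance channels (CSF, white matter, global, six motion parameters)
  injected at configurable loadings, and framewise-displacement traces with
  motion spikes. Direct connectivity simulation is the default test path;
  the time-series path exists to exercise the post-processing chain.

What the generator does *not* emulate: spatial autocorrelation and
distance-dependence of fc, site/scanner effects on connectivity (sites
affect only the design), heavy-tailed motion artifacts, and subject-level
network topography. Tests passing on synthetic data therefore demonstrate
the statistical machinery's calibration and power under the stated model,
not robustness to every property of real fcMRI data.

## Time-series post-processing

The pipeline order is fixed: censor, nuisance-regress, band-pass, correlate
on retained frames.

* **Censoring**: frames with framewise displacement above 0.2 mm are
  removed; no neighbor augmentation — censoring is defined by the
  threshold alone. A subject passes QC with at least 7 usable minutes
  (inclusive at the boundary — a convention this package fixes) out of an
  11.2-minute acquisition at TR = 2 s (TR is a configuration parameter).
* **Nuisance regression**: per-ROI OLS on intercept, linear trend (these
  realize demeaning/detrending), nine nuisance signals and their
  backward-difference derivatives (first frame 0). The fit uses retained
  frames only — a censored spike cannot leverage the fit (tested by spike
  injection) — while residuals are formed for all frames.
* **Band-pass**: zero-phase Butterworth (order 2 per pass,
  forward-backward) at 0.009-0.08 Hz, applied to a series linearly
  interpolated over censored gaps and re-masked downstream; this avoids
  spectral leakage from gap discontinuities. Stop-band attenuation
  (>=20 dB at 0.2 Hz with TR 2 s) and pass-band flatness (<=1 dB at
  0.03 Hz) are verified on pure sinusoids.
* **Connectivity**: Pearson correlation over retained frames, Fisher-z;
  zero-variance ROIs and perfectly correlated (duplicate) ROIs are errors
  naming the offenders; the diagonal is undefined (`NA`).

## Reporting

* **Hits**: ROI pairs in the brain-wide top/bottom 2.5% tails of the t
  distribution, intersected with the queried block. Tails could instead be
  computed within-block; brain-wide is the default and the choice is
  recorded in the output. Ties at a threshold are excluded
  (strict inequality — deterministic and conservative).
* **Classification**: L-R pairs are contralateral, L-L left, R-R right;
  pairs involving a midline ROI go to a separate "midline-involved" class
  (rather than being folded into the three lateralized classes); a pair is
  cortico-cortical iff both ROIs are cortical.
* **Stratified summaries**: block connectivity pooled within behavioral
  strata (e.g. SA >= 5 versus below) with location statistics and the
  between-stratum shift.
* **Matrix export**: network-major ordering with subcortical and cerebellar
  ROIs first within each network, plus a block-boundary sidecar.
* **Motion check**: per-pair correlation of connectivity with subject mean
  FD within a block, to exclude motion-driven findings.

`run_pipeline()` composes all stages with presets (`null`, `planted`,
`study-dims`), end-to-end seeded determinism (including permutation
streams), logged attrition counts, and a sensitivity rerun excluding
sleep-flagged subjects that preserves pair ordering so tables remain
comparable.

## Numerical and design choices

* Tested columns (SA, RRB) are last in the design so the partial F reuses
  the sequential QR; the permuted-Q identity above makes the permutation
  engine O(npP) with a small constant.
* Pairs with zero connectivity variance are dropped from screening with a
  logged list rather than failing the run; they are an error in the
  enrichment step, which requires a complete block partition.
* Empty within-network blocks (a one-ROI network at reduced dimensions) are
  kept in the block table with `NA` statistics rather than erroring.
* The GSEA running-sum maximum is attained immediately after a member
  increment, so only member positions are inspected; all blocks are scored
  in one ranked pass.
* `calibrate_fwer()` requires $(B+1)\,\alpha_{pt} \ge 2$, otherwise the
  add-one p-value cannot resolve the threshold and the function errors with
  the minimum B.
* Medication (yes/no on scan day) is an optional design column, off by
  default — the main model is behaviors + site + sex + age, with
  medication reserved for sensitivity analyses.

## Problem sizes used in the tests

The standard desk-scale conditions are 60 subjects x 100 ROIs (4,950 pairs,
91 blocks), the package's chosen reduced dimensions for simulation studies;
the full 97 x 288 layout is available as the `study-dims` preset. The
calibration suite uses 200 null replicates for the ORA mean, a shared
4,000-permutation ensemble with 500-600 fresh null cohorts for the
experiment-wide rate, 500-permutation ensembles for null-magnitude checks,
and 50 planted-effect runs at B = 2,999 (the smallest count that resolves
p < 0.0005) for recovery. The planted preset's calibration targets a mean
within-block |t| of 2: at desk scale the salience-visual block holds ~78
pairs rather than ~500, and calibrating to a decisive *detection margin*
(p-values well below the 0.0005 threshold) rather than to a raw
enrichment proportion keeps recovery robust at the smaller block size; a coupling at mean |t| ~ 1 (barely above the null expectation of
0.8) is still identified as the minimum-p block in >=90% of runs, which the
property suite checks.

## Known limitations

* The permutation schemes are exchangeable under the global null; under
  strong non-null structure the Freedman-Lane null carries the planted
  signal into the permuted data (as it should), which widens block nulls —
  power statements are therefore scheme-specific.
* ORA is discrete for small blocks; its p-values are conservative there,
  and the hypergeometric cross-check ignores inter-pair correlation by
  construction.
* The generator's independence of pairs across blocks makes the
  independent-blocks closed form for the family-wise rate nearly exact;
  real data with cross-block correlation would push the realized rate
  below it. Even on synthetic data the estimate tends to sit at or
  slightly below the closed form in the far tail: residual-permutation
  schemes are only asymptotically exact, and at 60 subjects with 12 design
  columns the approximation is visible at the 0.0005 level while
  calibration at milder levels (e.g. 0.01) is nominal — the calibration
  functions expose both regimes.
* The time-series generator uses temporally white network factors; spectral
  realism (1/f, physiological bands) is out of scope.
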