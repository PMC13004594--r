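---
title: "Methods: delta-delta-Cq differential expression for EV miRNA arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delta-delta-Cq differential expression for EV miRNA arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evmircq)
```

## The measurement model

A TaqMan array experiment yields, per reaction well, a quantification cycle
Cq together with two instrument quality metrics, the amplification score
(AmpScore) and the Cq confidence (CqConf). Lower Cq means more template,
roughly one cycle per two-fold. The experiments this package targets compare,
for one receptor at a time, matched pairs of vehicle-control and
agonist-treated EV preparations (5–6 pairs), flanked by 6–8 cell-free media
controls that carry the serum background.

We model the observed Cq of assay $a$ in sample $s$ as

$$\mathrm{Cq}_{as} = \beta_a + \delta_a \mathbf{1}[s \in \text{agonist}]
  + u_{p(s)} + \kappa \mathbf{1}[\text{card}(a) = B] + \varepsilon_{as},$$

with assay baseline $\beta_a$, treatment effect $\delta_a$ (the
$\Delta\Delta \mathrm{Cq}$ of interest), a shared pair offset $u_{p}$, a card
batch shift $\kappa$, and well noise $\varepsilon$. Measurements are censored
at a detection ceiling and additionally lost near it, which is why every
downstream statistic must tolerate incomplete pairs.

## Quality control and filtering

Three rules, all strict inequalities so boundary wells are kept:

* well level: discard (set missing) wells with Cq > `cq_max` (34 cycles),
  CqConf < 0.8 or AmpScore < 1;
* expression rate: keep assays detected in at least `expr_rate` (80%) of
  samples in *both* the vehicle and agonist groups. The alternative reading —
  at least 80% of *either* group — is available as
  `qc_thresholds(expr_rule = "either_group")`; we default to the stricter
  both-groups rule, with `>=` so that 5 of 6 (0.833) passes;
* media-control exclusion: drop assays detected only in media controls, and
  drop assays present in media controls (detection rate ≥
  `mc_presence_rate`, 50%) unless the vehicle control is at least
  `mc_delta_min` = 3.3 cycles (10-fold) more abundant. The rule is
  directional by default — the point is to remove serum-derived background,
  so the *vehicle* side must be enriched — with an absolute-difference mode
  for sensitivity checks. Group means use detected wells only; no imputation
  of censored values is attempted. "Only present in the media control" is
  implemented as zero detections across all vehicle/agonist samples.

The expression-rate and media filters are computed independently on the
QC-applied matrix and the analysis set is their intersection; the QC report
labels each rejected assay with one reason, giving the expression-rate rule
precedence when both would fire.

## Normalization

qPCR arrays of EV cargo have no validated reference miRNA, so the package
uses a global-mean endogenous background. An assay qualifies as a normalizer
when (1) it is absent, or detected in under half of the media controls, (2)
it is fully observed in every vehicle and agonist sample, and (3) when it is
rare-but-present in media, its media mean differs from the vehicle mean by
more than 3.3 cycles (two-sided, matching the neutral wording "different
from"). Qualifying assays are pooled across both cards and

$$\Delta \mathrm{Cq}_{as} = \mathrm{Cq}_{as} - \overline{\mathrm{Cq}}^{\,\text{norm}}_{s}.$$

The normalizer mean is computed *per sample*, not per group: a per-group mean
would cancel out of every within-pair difference and make the matched-pairs
estimator blind to sample-level loading, contradicting the pairing rationale.
Because this choice is not the only defensible one (per-run or per-group
alignment could mitigate run-to-run drift at the cost of inflating
missing-data complications), the normalizer set and per-sample means are
exposed in the fit object, and an explicit normalizer list can be supplied
when the automatic criteria select nothing — the pipeline refuses to fall
back silently.

## Effect estimation and testing

The per-assay effect is the matched-pairs estimator: with complete pairs
$i = 1..n$,

$$\widehat{\Delta\Delta \mathrm{Cq}} = \frac{1}{n}\sum_i
  (\Delta \mathrm{Cq}^{\text{ag}}_i - \Delta \mathrm{Cq}^{\text{ve}}_i),
  \qquad \log_2 \mathrm{FC} = -\widehat{\Delta\Delta \mathrm{Cq}},$$

identical to the treatment coefficient of a least-squares fit with pair fixed
effects (verified against that oracle in the tests). Pairs with a missing
side are dropped and counted; fewer than two complete pairs yields "not
estimable" rather than an error. Both dispersion readings are reported —
the per-pair SD and the standard error SD/√n — because a table column named
"SD of log2(FC)" is ambiguous between them; at n = 5–6 the standard error is
the reading whose magnitude matches typical published values (≈ 0.07–0.27),
so it is the default comparator.

Significance uses a from-scratch Skillings–Mack rank test, the
incomplete-block generalization of the Friedman test. Within each usable
block (≥ 2 observed treatments) observations get midranks; the adjusted
score of treatment $j$ is

$$A_j = \sum_{i} \sqrt{\tfrac{12}{k_i + 1}}\left(r_{ij} - \tfrac{k_i+1}{2}\right)$$

and the statistic $A^\top \Sigma^- A$ uses the null covariance
$\Sigma$ (diagonal: co-occurrence counts; off-diagonal: minus pairwise
co-occurrence), inverted generalizedly because the scores sum to zero. On
complete two-treatment data the statistic collapses to
$(S_+ - S_-)^2 / n$ where $S_\pm$ count the pair directions — six fully
concordant pairs give 6.0 (χ²₁ tail 0.0143) and five give 5.0 (0.0253),
which is why those two p-values recur in small concordant datasets. Blocks
with one observed side carry no rank information and are dropped, consistent
with the test's $k_i \ge 2$ requirement.

The chi-square reference is an approximation; at these block counts it is
somewhat conservative-to-liberal depending on the missingness pattern, so a
within-block permutation Monte-Carlo p-value (`skillings_mack_mc`, add-one
corrected) is provided, alongside the sensitivity grid of paired and
unpaired alternatives (`alternative_tests`): exact sign-flip permutation
(enumeration up to 12 pairs, i.e. ≤ 4096 evaluations), Wilcoxon signed-rank,
Welch's t, Mann–Whitney and unpaired label permutation. All p-values are
two-sided. The published analysis this design follows names six
estimator-by-test combinations without enumerating them; the implemented
grid (paired/unpaired estimator × the tests above) is a superset of the
named methods rather than a certified match.

## Selection and reporting

Assays are ranked by |log2 FC| (ties: ascending p, then assay id). Flags:
discovery screen p < 0.2 (strict; deliberately liberal, emphasizing
discovery power over false-positive avoidance), effect-size rule
|log2 FC| ≥ 0.585 (1.5-fold; the cutoff lives on the log2/cycle scale — a
1.5 *log2* cutoff would contradict published signature members with
|log2 FC| ≈ 0.6), and nominal p < 0.05. The signature is the conjunction of
the first two. Heatmap inputs are row-z-scored with the sample (n−1) SD —
the convention under which (1, 2, 3) maps to (−1, 0, 1) — with zero-variance
rows mapped to zero, and ordered by agglomerative clustering on Euclidean
distance. Average linkage is the default since only the metric is part of
the published description; the linkage is configurable.

## The synthetic-data generator

`simulate_experiment()` emulates the study conditions: 754 assays split over
two cards, 6 matched pairs, 6 media controls, assay baselines
$\beta_a \sim N(33.5, 3^2)$ cycles, 10% media-only assays, 50%
serum-background assays shared between media and cells (media excess
$N(0, 1)$, removed by the 3.3-cycle rule), 15% cell-derived assays
(media 4–8 cycles *higher*, retained), the remainder absent from media;
pair offsets $N(0, 0.5^2)$, card-B shift 0.3, well noise $N(0, 0.3^2)$,
censoring at 34 cycles, logistic detection dropout
$\Pr(\text{miss}) = \text{logit}^{-1}(\text{slope} \cdot (\mathrm{Cq} - 34))$
with slope 1, and 2% random QC failures realized as failing
AmpScore/CqConf values so the QC filter, not the generator, removes them.
The baseline location and class fractions were fixed so that the default
configuration passes 90–110 assays through the full filter cascade across
seeds, the scale reported for real receptor experiments (86–105 of 754);
they were frozen before the acceptance checks were written. Unnamed planted
effects are assigned to the lowest-baseline assays of the retained classes
(cell-derived or media-absent) — planting a "recoverable" effect on a
serum-background assay would be removed by the media filter by construction.
An optional one-sided pair-dropout rate removes one randomly chosen side of
a pair, the missingness pattern under which the incomplete-block test earns
its keep.

One RNG stream is consumed in a fixed documented order (baselines, class
assignment, media shifts, offsets, residuals, dropout, QC failures, pair
dropout), so a seed gives bit-identical output within this implementation.
The generator does *not* emulate pre-amplification bias, card-position
effects, sequence-dependent amplification efficiency, or run-to-run
normalizer drift — so passing recovery checks on synthetic data demonstrates
the statistical pipeline's correctness, not robustness to those technical
artifacts in real exports.

## Numerical choices

* Generalized inverse via symmetric eigendecomposition; eigenvalues below
  1e-8 × (largest eigenvalue) are treated as zero and the degrees of freedom
  are the resulting rank (t − 1 for connected designs).
* Ties get midranks; the score covariance is not tie-corrected (a documented
  limitation — the Monte-Carlo p-value is the remedy for tie-heavy data).
* Disconnected designs (treatment groups sharing no block) raise an error
  naming the components rather than returning a misleading pooled statistic.
* Threshold comparisons use a 1e-12 guard so that values stored at the
  printed precision (0.585, 3.3, 80%) compare as intended.
* Monte-Carlo p-values use the add-one correction
  (1 + #{≥ obs}) / (1 + draws) and per-assay seeds derived from the global
  seed, so results do not depend on assay evaluation order.
* Zero p-values are clamped to the smallest positive double before
  −log10 transformation, with a warning.

## Problem sizes used in the checks

The packaged checks run at desk scale: calibration of the null rejection
rate uses 2000 simulated assays with 6 pairs and 30% one-sided pair
missingness; bias/power recovery uses 500 assays per planted effect level
in {−1.5, −1.0, −0.585, 0, 0.585, 1.0} cycles at well noise 0.3; end-to-end
signature recovery uses 100 assays with 8 planted effects (|ΔΔCq| ≥ 1) and
10 media-only assays; and the full-array pass-rate check uses the default
754-assay configuration. These sizes give Monte-Carlo standard errors
comfortably inside the tolerances asserted, while the whole suite runs in
well under a minute.

## Known limitations

* The chi-square approximation for the rank statistic is coarse below ~5
  usable blocks; use the Monte-Carlo p-value there.
* The media-control filter assumes media controls were processed in the same
  runs as the treated samples; batch confounding between media and treated
  samples is not modeled.
* The per-sample global-mean normalizer assumes enough qualifying assays to
  stabilize the mean (tens, in practice); with very few normalizers the
  per-pair differences inherit normalizer noise.
* No multiple-testing adjustment is applied by design: the p < 0.2 screen is
  a discovery device, and its false-discovery behaviour should be judged via
  the recovery metrics on simulations, not treated as an error rate.
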