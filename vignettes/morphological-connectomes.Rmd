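---
title: "Morphological similarity connectomes: models, estimators and design choices"
author: "morphconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological similarity connectomes: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphconn)
```

## The analysis this package implements

`morphconn` implements a single-subject structural-connectome analysis for
clinical cohorts. Each subject contributes, per scan, a sample of gray-matter
density values for each of 90 anatomical regions (AAL parcellation). From
these the pipeline derives, in order:

1. **A 90 x 90 morphological similarity matrix per scan.** The edge between
   regions $i$ and $j$ is the Kullback–Leibler-based similarity
   $$\mathrm{KLS}(p_i, p_j) = \exp\{-[\mathrm{KL}(p_i \| p_j) +
   \mathrm{KL}(p_j \| p_i)]\} \in (0, 1],$$
   where $p_i$ is the region's gray-matter density distribution. KLS is 1
   exactly when two regions have identical density distributions.
2. **Binary graphs across a sparsity range.** Each matrix is thresholded at
   sparsities $S = 0.10, 0.11, \dots, 0.34$, keeping the strongest
   $\mathrm{round}(S \cdot 4005)$ edges. Global metrics (clustering
   coefficient $C_p$, characteristic path length $L_p$, global/local
   efficiency, and the rewired-null-normalized $\gamma$, $\lambda$,
   $\sigma = \gamma/\lambda$) and nodal metrics (degree, nodal efficiency,
   betweenness) are computed at each threshold and summarized by the
   trapezoidal area under the curve (AUC) over $S$, giving threshold-free
   per-subject scalars.
3. **Group inference on the AUCs.** Nonparametric permutation tests for
   case-control contrasts, a 2-of-3 rule for nodal abnormality screening,
   mixed-effects group-by-time models, symptom-change correlations with
   Benjamini–Hochberg FDR control, and ICC reliability screening.
4. **Treatment-response prediction.** A linear SVM on the 4005 edge features
   of the baseline matrices under stratified 10-fold cross-validation, with
   permutation significance and a per-region weight ranking.

No imaging data accompany the package; a synthetic cohort generator
(`generate_cohort()`) produces data with the statistical structure the
analysis assumes, so every stage is testable end to end. This vignette
documents the estimators, conventions, and the design choices that were
genuinely open.

## The KLS estimator

The density of each region is estimated by a Gaussian kernel density
estimate with Silverman's rule-of-thumb bandwidth, evaluated on a single
256-point grid shared by all regions of a subject (spanning the pooled
sample range extended by three pooled-sample bandwidths). Mass is floored at
$10^{-10}$ and renormalized, because KL divergence is undefined at zeros;
the two KL directions are then discrete sums over the grid. The diagonal of
the similarity matrix is set to 1 by convention but never participates in
thresholding or metrics.

Two properties of this estimator matter for interpretation:

- **Noise floor.** When two regional distributions share no support within
  the sampling resolution (separation beyond roughly six standard deviations
  at 500 samples/region), the estimated divergence saturates at a value set
  by the mass floor. All such pairs receive near-identical similarities and
  their relative order is effectively random. In thresholded graphs these
  pairs supply the long-range "random" edges.
- **Finite-sample bias.** With $n$ samples per region the estimated
  divergence of two *identical* distributions is positive (of order
  "effective bins / n"), so self-similarity of two independent draws from
  one distribution is slightly below 1, converging as $n$ grows. At 500
  samples/region the mean estimate at any fixed separation is within 0.05 of
  the closed-form Gaussian value, and ~95% of the 4005 pairs of a subject
  lie within 0.05 of their generating-parameter oracle; individual extreme
  pairs can deviate more, which is sampling noise rather than bias. Group
  comparisons are unaffected because the bias is common to all subjects.

For Gaussian regional densities the package provides the closed form
`gaussian_kls()` — $\mathrm{KL}(N_1 \| N_2) = \log(\sigma_2/\sigma_1) +
(\sigma_1^2 + (\mu_1 - \mu_2)^2)/(2\sigma_2^2) - \tfrac12$ — which the test
suite uses as an independent oracle for the sample-based estimator.

## Graph conventions

Decisions the source methodology leaves open are fixed as follows and
verified against exhaustive brute-force oracles on all graphs with up to 8
nodes:

- **Edge count** at sparsity $S$: round-half-up of $S \cdot N(N-1)/2$; ties
  broken by descending weight then ascending (row, column) index, so
  thresholding is deterministic.
- **$C_p$**: mean over all nodes of $2t_i/(k_i(k_i-1))$, nodes with degree
  < 2 contributing 0.
- **$L_p$**: mean shortest-path length over connected ordered pairs only.
  Disconnected graphs are not given an infinite-distance convention; the
  sparsity range is instead chosen so networks stay estimable, and each
  curve records which thresholds were connected. Note the consequence:
  fragmentation *lowers* $L_p$ under this convention, because distances
  within small components are short.
- **Efficiencies**: global efficiency is the mean inverse distance over
  ordered pairs (unreachable pairs contribute 0); local efficiency is the
  mean over nodes of the global efficiency of the neighbor-induced subgraph;
  nodal efficiency is the row mean of inverse distances.
- **Betweenness**: unnormalized shortest-path betweenness.
- **Null models**: degree-preserving double-edge-swap randomization with
  10 x edge-count attempted swaps, not connectedness-enforced; ensembles of
  100 by default, with null $i$ seeded as `seed + i` so an ensemble is
  exactly reproducible. $\gamma$ and $\lambda$ divide by the null means.
- Shortest paths, betweenness and rewiring are computed by igraph; the test
  suite pins igraph's conventions to the package definitions by comparing
  against independent Floyd–Warshall and path-enumeration oracles.

## Inference conventions

- Permutation tests reallocate the pooled per-subject AUC values into two
  groups of the original sizes, 10,000 times by default, and use the
  add-one-corrected two-tailed p-value $(1 + \#\{|d^*| \ge |d|\})/(1 + B)$,
  which is valid (never anti-conservative beyond Monte-Carlo error) under
  the null. Covariates do not enter the permutation tests; they enter the
  regression models.
- The nodal screening rule flags a region when at least two of its three
  centrality p-values (degree, efficiency, betweenness) fall below 0.05,
  uncorrected — a reporting rule, not a corrected inference.
- Longitudinal models are linear mixed models with a subject random
  intercept, fixed effects for group, timepoint, their interaction, age and
  sex, fitted by REML; interaction F-tests use Satterthwaite degrees of
  freedom. The same machinery serves arm-by-time contrasts.
- FDR adjustment is Benjamini–Hochberg.
- Treatment response is a >= 50% YMRS reduction from baseline; the rule is
  scale-invariant.
- ICC is the two-way mixed, consistency, single-measure form ICC(3,1)
  computed from the two-way ANOVA mean squares, with Cicchetti's bins
  (< 0.40 poor, 0.40–0.59 fair, 0.60–0.74 good, >= 0.75 excellent). A
  degenerate variance decomposition returns an explicit "undefined" result.

## Prediction conventions

The classifier is a linear-kernel SVM with C = 1 (configurable); a linear
kernel is required for the weight-map interpretation. Features are the 4005
upper-triangle edges in row-major order. Within each of 10 stratified folds,
features are standardized using training-fold statistics only — a leakage
canary test in the suite verifies that chance-level data stay at chance.
Performance is the mean across folds of the balanced accuracy (mean of
per-class recalls); significance is permutation-based on the mean balanced
accuracy. The edge-weight map is the mean absolute weight across folds, and
a region's nodal weight is the mean over its 89 incident edges; ties in the
ranking break by region index.

With ~4000 correlated features and ~100 subjects, a linear SVM recovers a
signal only when it spans enough features for the aggregate class
separation to dominate the noise dimensionality; a signal confined to a
single edge is invisible at this sample size no matter how strong. This is
intrinsic to the p >> n regime, not an implementation artifact, and shapes
the synthetic responder signal below.

## What the synthetic cohort emulates

`cohort_config()` defaults encode the study conditions: 100 patients
(baseline YMRS >= 20, 1:1 randomization to two arms) and 63 controls, scans
at baseline, week 1 and week 6, 90 regions, 500 density samples per region.

**Regional densities** are truncated Gaussians on [0, 1] — a modeling
convenience that admits the closed-form KLS oracle; nothing is claimed about
the distributional form of real gray-matter density. Region means live in 18
latent blocks of 5 regions whose centers are evenly spaced; two regions per
block sit midway toward the next block, acting as bridges. Within-block
spacing is small against the regional spread (strong edges), between-block
spacing about three spreads (weak but resolvable for adjacent blocks), and
pairs beyond the estimator's resolution supply effectively random long-range
edges — together yielding connected, small-world control networks
($\sigma > 1.5$ across the entire threshold range).

**The patient perturbation** (magnitude `patient_effect`, default 0.6) must
raise both $C_p$ and $L_p$ at fixed sparsity. Because thresholding keeps only
the *rank order* of edges, uniform rescalings of the latent geometry change
nothing, and several superficially plausible mechanisms fail: tightening
blocks alone fragments patient networks at low sparsity, which *lowers*
$L_p$ under the connected-pairs convention. The mechanism adopted operates on
rank composition: patients' within-block jitter tightens (cohesion), regional
spreads widen, and block centers compress toward each other. Widening and
compression pull the second- and third-neighbor block bands inside the
estimator's resolvable separation, so patient edge budgets fill with
lattice-like proximity edges that displace the effectively random long-range
ones — the network regularizes: more triangles (higher $C_p$) and longer
paths (higher $L_p$), while staying connected. At study scale the shift is
detected by the permutation tests in essentially every replicate.

**Treatment dynamics.** Responder status is assigned first
(`responder_fraction`, default 0.5), so both classes always exist; YMRS
trajectories are drawn conditional on it (responders' final reduction
>= 50%, non-responders' < 50%, with integer rounding that never crosses the
boundary). Each patient has a normalization propensity mixing their YMRS
percent reduction (weight `coupling`, default 0.6) with noise; at week 1 and
week 6 the patient effect is scaled down by `normalization_rate` (defaults
0.3 and 0.85) times that propensity. This produces the built-in
group-by-time interaction and the positive correlation between metric
normalization and symptom improvement.

**The responder signal** plants a baseline-only perturbation at one region
(default 30, right insula in AAL order): responders' regional mean shifts up
by half `responder_signal` and their spread inflates by
`3 * responder_signal`; non-responders' mean shifts down by half. Both
components are needed: the spread inflation widens the set of informative
incident edges so the signal spans enough dimensions for the linear SVM (see
above). At the default 0.08 the cross-validated balanced accuracy at n = 100
is about 0.8 and the planted region tops the nodal weight ranking. The
signal is a separate knob from `patient_effect`; null-calibration
experiments should set both to zero.

**What the generator does not emulate:** voxel-level spatial structure,
scanner or registration artifacts, dropout, demographic confounding (age and
sex are drawn independently of group, mirroring a matched design), arm
differences (both arms share dynamics by construction), and any real
anatomical correlation structure — the latent geometry is one-dimensional,
which limits how "random" long-range structure can arise (only through the
estimator's noise floor). Passing tests therefore demonstrate that the
pipeline recovers effects of the assumed form at realistic sizes, not that
real gray-matter networks behave this way.

## Numerical choices and degenerate inputs

- Density estimation requires >= 30 finite samples and positive variance per
  region; violations raise errors naming the region.
- KLS on mismatched grids is an error, not a silent regrid.
- `threshold_scheme()` requires strictly increasing sparsities in (0, 1);
  AUC requires at least two thresholds.
- `rewire_null()` requires at least two edges; `global_metrics()` at least
  one edge and one null.
- Permutation tests never return p = 0 (add-one correction).
- ICC returns "undefined" rather than a number when the variance
  decomposition is degenerate.
- All stochastic steps take explicit integer seeds; cohort generation, fold
  assignment, rewiring ensembles and permutation tests are bit-reproducible
  given them.

## Problem sizes used by the tests

The test suite exercises the full pipeline at the study scale where the
claim depends on it (50 replicate cohorts of 163 subjects for effect
recovery; 100 patients for prediction; 500 null datasets for calibration)
and uses reduced ensembles elsewhere (25 rewired nulls per threshold in the
small-world suite, against 100 in `scripts/acceptance.R`; graphs of <= 8
nodes for the brute-force oracle equivalences). The analysis scripts under
`analysis/` run the same stages once, at full scale, from a single seed.

## Known limitations

- The 1-D latent geometry of the generator cannot produce genuinely
  long-range *structured* shortcuts; small-worldness arises from cliques
  plus noise-floor edges. This is sufficient for the regime the analysis
  assumes but is a caricature of cortical covariance.
- The KLS noise floor makes the weakest edges' identities unstable across
  resamples of the same subject; metrics at the sparse end of the range
  inherit that variability. The AUC summarization is the mitigation.
- Balanced accuracy and the weight ranking are reported for the default
  C = 1; no hyperparameter search is performed (none is part of the
  analysis).
- The mixed models assume a subject random intercept only; random slopes
  are not identifiable with three timepoints at these sizes.
- The patient perturbation is global (every block compresses, every region
  widens), so at study-scale power the nodal screening rule flags most
  regions, not a focal subset as in real cohorts where effects are
  anatomically localized. The screening rule itself is exercised against
  focal synthetic patterns in the tests.
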