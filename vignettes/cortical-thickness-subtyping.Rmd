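---
title: "Cortical thickness subtyping and the mechanisms of longitudinal thinning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cortical thickness subtyping and the mechanisms of longitudinal thinning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortsub)
```

## The analysis in one paragraph

Regional cortical thickness in aging cohorts is heterogeneous: distinct
spatial patterns of thinning (limbic-predominant versus hippocampal-sparing
phenotypes) carry different clinical trajectories. `cortsub` implements a
complete pipeline for discovering such subtypes and probing what drives
their progression: (1) non-negative matrix factorization (NMF) of inverted
baseline thickness with multi-restart consensus clustering and rank
selection; (2) longitudinal characterization — logistic models of subtype
membership, random-intercept linear mixed models (LMMs) of repeated
outcomes, follow-up re-assignment and Krippendorff's alpha for stability;
(3) per-region subtype-specific thinning maps (time-by-subtype LMMs);
(4) coordinated deformation models (CDMs) that ask whether a region's
thinning is predicted by its connected neighbors' thinning, tested against
two nulls — geometry-preserving rewired networks and spatial-autocorrelation
(SA)-preserving surrogate maps; and (5) imaging transcriptomics — spatial
correlation of thinning maps with regional gene-expression maps, surrogate
significance, and hypergeometric over-representation analysis (ORA). A
synthetic-cohort generator with planted ground truth makes every stage
testable without access-restricted imaging data.

## The subtyping model

Let $T \in \mathbb{R}^{S \times R}_{>0}$ be baseline thickness (subjects
$\times$ regions, mm). Because atrophy should load *positively* in a
non-negative factorization, each region is inverted against its own
across-subject maximum,

$$X_{sr} = \max_s T_{sr} + m - T_{sr}, \qquad m = 0.01\ \mathrm{mm},$$

which guarantees $X \ge m > 0$ on raw thickness and exactly reverses the
subject ordering within each region (a global-maximum variant is available).
NMF then solves $\min_{W, H \ge 0} \lVert X - WH \rVert_F^2$ with Lee–Seung
multiplicative updates from random non-negative initializations; the best of
`n_restarts = 50` runs (lowest RSS) is kept. Subjects are assigned to
$\arg\max_k W_{sk}$, with soft probabilities $W_{sk} / \sum_k W_{sk}$;
regions are assigned to $\arg\max_k H_{kr}$. Numerical choices worth
knowing:

* $X$ is divided by its mean before the updates and $W$ rescaled after, so
  assignments and probabilities are *exactly* invariant to rescaling the
  input — useful when thickness arrives in different units.
* Convergence stops when the relative RSS decrease falls below `tol = 1e-6`
  or at `max_iter = 500`; the updates never increase the RSS.
* All-zero score rows (possible only for degenerate inputs) get uniform
  probabilities and an `unassignable` flag; score ties break toward the
  lower subtype index with a warning.

**Rank selection.** For each candidate rank, component labels are matched
across restarts by greedy correlation of the regional profiles (rows of
$H$), and a subjects-by-subjects consensus matrix records co-assignment
frequencies. The rank is chosen by the cophenetic coefficient of the
consensus matrix (correlation between consensus dissimilarities and the
cophenetic distances of their average-linkage clustering), with the mean
silhouette on consensus dissimilarities as tie-break, then the smaller
rank. The relative RSS decrease is reported but not used for automatic
selection: it decreases monotonically and has no natural elbow criterion
that is stable across noise levels. A perfectly stable consensus (all
entries 1) has zero dissimilarity everywhere; its cophenetic coefficient is
defined as 1. Silhouettes can optionally be computed on raw feature
distances instead (`silhouette_on = "features"`).

## Longitudinal models

All longitudinal models are REML random-intercept LMMs (via `lme4`) with
Wald $z$ inference on the fixed effects. No small-sample degrees-of-freedom
correction is applied — a documented limitation that is immaterial at the
cohort sizes this pipeline targets (hundreds of subjects). On balanced
designs the GLS fixed effects coincide with OLS, which the test suite
checks to $10^{-8}$.

Per-region thinning maps come from
`thickness ~ time * subtype + age + sex + centiloid + nmf_probability +
(1 | subject)`; the within-subtype marginal time slopes are linear
contrasts of the time and interaction coefficients under dummy coding,
equivalent to estimated-marginal-means linear trends (checked against
`emmeans` in the tests). Baseline Centiloid is used as the amyloid
covariate. Regional p-values are uncorrected by default, matching the
common practice of reporting uncorrected regional maps; Benjamini–Hochberg
is available by flag.

Follow-up scans are assigned to baseline subtypes by inverting the
follow-up thickness vector with the *baseline* inversion constants and
Pearson-correlating it with each subtype's regional profile (row of $H$);
correlating in the fitted (inverted) space keeps the comparison consistent
with what NMF actually factorized, and a raw-thickness switch exists.
Agreement between baseline and follow-up labels is Krippendorff's alpha
(nominal metric, coincidence-matrix formulation), $\alpha = 1 - D_o / D_e$,
defined as 1 when expected disagreement vanishes (single unit or single
code, with a warning). The subtype-membership logistic model codes
*subtype-1 membership* as the outcome, so with the generator's defaults
(subtype 1 older, more amyloid) age and Centiloid odds ratios exceed 1.

## Coordinated deformation models and their nulls

The CDM predicts each region's change from its connected neighbors,

$$\hat\beta_i = \frac{\sum_{j \ne i} w_{ij} \beta_j}{\sum_{j \ne i} w_{ij}},$$

and the test statistic is the spatial Pearson correlation between
$\hat\beta$ and $\beta$ across regions. The strength-normalized neighbor
mean is the default reading of the model; an unnormalized weighted-sum
variant sits behind `normalized = FALSE`. Two complementary nulls:

* **Rewired networks** preserve, exactly, the degree sequence, the weight
  multiset and the node coordinates, and approximately the distance–weight
  relationship: edges are binned by length into `n_bins` quantile bins,
  degree-preserving double-edge swaps are accepted only when both
  replacement edges fall in the same bins as the edges they replace, and
  the original weights are re-assigned by rank-matching weight to distance
  within bins. Candidate pairs are proposed *within* a bin — accepted swaps
  can never move an edge between bins, so this discards only guaranteed
  rejections and roughly triples acceptance on geometric graphs.
  `n_bins = 5` is the default, chosen by a type-I calibration study on
  SA-noise maps independent of the template: with few bins the swap chains
  mix well and the null's rejection rate sits at the nominal level (the
  validation suite re-measures this), while with many bins the chains mix
  too slowly, the null hugs the observed network, and the test inflates.
* **Variogram-matched surrogates** preserve the map's spatial
  autocorrelation: the map is permuted, smoothed by distance-weighted
  $k$-nearest-neighbor averaging at candidate scales
  $k \in \{10, 20, 30, 50\}$, and affinely recalibrated so the surrogate's
  smoothed variogram (25 Gaussian-kernel lags up to the 25th percentile of
  distances) matches the original's; the best-fitting scale is kept and the
  surrogate is recentered to the original mean (Pearson statistics are
  shift-invariant). This surrogate family is mildly *conservative* for the
  CDM statistic — under SA-noise maps its rejection rate at $\alpha = 0.05$
  is near 0 — because the smoothed-permutation-plus-noise construction
  slightly over-disperses the null correlations. It never anti-conserves,
  which is the property the test suite asserts; power against genuinely
  network-driven maps remains high (both nulls reject at the smallest
  attainable p-values with 500 permutations under the generator's default
  coupling, as the validation suite measures).

P-values use the one-sided "greater" counting rule with a +1 continuity
correction, $p = (\#\{r_\mathrm{null} \ge r_\mathrm{obs}\} + 1)/(n + 1)$ —
the correction is a deliberate deviation from the literal "fraction
greater" so that $p = 0$ is impossible; non-strict $\ge$ is used, and a
two-sided option exists for negative-coupling questions.

## Imaging transcriptomics

For gene expression, surrogates of the *thinning map* (not the genes) are
generated once and correlated against every gene's regional expression; the
default per-gene p-value is two-sided on $|r|$ (both signs of spatial
coupling are biologically meaningful), with the one-sided rule available.
Genes passing `alpha_threshold = 0.05` (uncorrected by default, BH by flag)
feed a hypergeometric ORA,

$$p = \sum_{i \ge x} \binom{K}{i}\binom{N-K}{n-i} \Big/ \binom{N}{n},$$

with BH q-values across the tested sets. The intended universe is the
analyzed candidate panel (the pipeline emulates a ~250-gene
neurodegeneration panel), not the genome; gene sets are plain GMT files.

## What the synthetic generator emulates — and what it does not

The generator plants the study conditions the pipeline is validated
against: 400 subjects, 100 regions on a jittered 70 mm sphere shell with
mirrored hemispheres and seven canonical network labels by angular sector;
two vulnerability subtypes defined on disjoint network sectors
(limbic/default-mode-like versus the rest), separated by a 0.3 mm baseline
reduction on the vulnerable set; visits at 0/2/4 years; thinning of
$-0.02$ mm/year (vulnerable set) versus $-0.005$ mm/year elsewhere, with
80% of the rate map propagated along the connectome
($\beta = (1-c)\,t + c\,W_n t$, $c = 0.8$); measurement noise of 0.05 mm
per visit and a persistent 0.08 mm subject offset; subtype 1 drawn older
(70.5 vs 65.5 years), with higher Centiloid (30 vs 12 CL), faster amyloid
accumulation (1.8 vs 1.33 CL/year) and more frequent APOE-e4 carriership
(0.50 vs 0.33); gene panels of 20 coupled plus 229 SA-null genes with
exponential-covariance fields of 30 mm correlation length. Where the
emulated study design does not pin a value (baseline effect sizes are not
reported in such cohorts), defaults were chosen once for testability at
realistic magnitudes and are not revisited.

Simulated connectomes are distance-decaying random graphs
(density 0.2, 30 mm decay) made connected by a minimum spanning tree; the
three modalities are independent realizations, so cross-modality
selectivity can be tested but modality-specific topology (hubs, modules,
hemispheric asymmetries) is not modeled. Also not modeled: site batch
effects beyond a label, missing visits and dropout, non-linear
trajectories, spatially structured measurement noise, and subject-level
(as opposed to group-level) spread processes. Passing tests on this
generator therefore demonstrate the *statistical machinery* — recovery,
calibration, invariances — not performance on any real cohort.

## Problem sizes used by the test and acceptance runs

The validation suite runs rank selection (ranks 2–6, 50 restarts) on five
independent 400-by-100 cohorts; thinning-map calibration pools five
zero-thinning cohorts (1000 region-level tests); CDM calibration uses 200
SA-noise replicates at 200 permutations each, and power runs use 500
permutations; the gene pipeline uses 500 surrogates (200 for the
five-seed enrichment replication); the end-to-end determinism check runs a
reduced 150-subject, 60-region configuration twice and compares every
output byte. These sizes were chosen so that each property is measured
with adequate resolution while the whole suite stays comfortably
re-runnable on a laptop.

## Known limitations

* Wald $z$ inference for LMM fixed effects (no Satterthwaite correction).
* The surrogate (autocorrelation) null is conservative for the CDM
  statistic at this scale, as described above.
* The rewiring null's acceptance rate on sparse geometric graphs is
  modest; with the default 10 swap attempts per edge roughly a third of
  edges move. Raising `swaps_per_edge` deepens mixing at linear cost.
* The surrogate family cannot reproduce the long-range variogram rise of
  *very* smooth maps (e.g. a two-level sector map after heavy connectome
  smoothing): the smoothed-permutation construction flattens beyond the
  largest neighborhood radius. The variogram-match guarantee is asserted
  on the spatially autocorrelated (random-field) map class the surrogate
  test actually nulls against. Relatedly, because the rewired null
  preserves geometry, the CDM power against such smooth sector maps is
  realization-dependent; the validation suite evaluates power on the fixed
  reference realization.
* Krippendorff's alpha is implemented for the two-coding nominal case the
  stability analysis needs, not for general m-coder incomplete data.
* `k_true > 2` cohorts are supported by the generator (networks are split
  round-robin into vulnerability sets), but the logistic characterization
  requires exactly two subtypes, as in the emulated design.
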