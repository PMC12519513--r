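# cortsub

Cortical thickness subtyping and the mechanisms of longitudinal cortical
thinning.

Aging and preclinical-dementia cohorts do not thin uniformly: distinct
spatial patterns of cortical vulnerability (a limbic-predominant and a
hippocampal-sparing phenotype) appear before any clinical diagnosis, stay
stable over time, and progress through different biological routes.
`cortsub` is an R package for researchers who have regional cortical
thickness tables (subjects x visits x ROIs, plus covariates such as age,
sex, amyloid Centiloid and APOE-e4) and want to

1. **discover subtypes** — non-negative matrix factorization (NMF) of
   inverted baseline thickness, `X ≈ W H` with `W, H ≥ 0`, multi-restart
   consensus clustering and rank selection by the cophenetic coefficient
   (silhouette tie-break, ΔRSS reported);
2. **characterize them longitudinally** — logistic models of subtype
   membership, random-intercept linear mixed models of repeated outcomes
   (Centiloid, cognition) with subtype-by-time interactions, follow-up
   re-assignment by Pearson correspondence to the subtype profiles, and
   Krippendorff's alpha for assignment stability;
3. **map subtype-specific thinning** — per-ROI time-by-subtype mixed models
   with within-subtype marginal slopes `β` (mm/year);
4. **test network drivers** — coordinated deformation models
   `β̂_i = Σ_j w_ij β_j / Σ_j w_ij`, with significance against (a)
   degree-, weight- and geometry-preserving rewired networks and (b)
   variogram-matched spatially autocorrelated surrogate maps;
5. **test transcriptomic drivers** — spatial correlation of `β` maps with
   regional gene-expression maps, surrogate-based p-values, and
   hypergeometric over-representation analysis (ORA) on GMT gene sets.

A synthetic-cohort generator (`generate_parcellation()`,
`generate_connectomes()`, `generate_cohort()`, `generate_expression()`)
plants two regional-vulnerability subtypes with known thinning rates,
network coupling and gene coupling, so the entire pipeline is testable with
no external data.

## Worked example

```r
library(cortsub)

parc      <- generate_parcellation(100, seed = 1)
templates <- generate_connectomes(parc, density = 0.2, distance_decay = 30, seed = 1)
cohort    <- generate_cohort(sim_config(seed = 1), parc, templates$functional)

# subtype discovery
X      <- invert_thickness(baseline_matrix(cohort$thickness))
report <- rank_selection(X, k_range = 2:4, n_restarts = 20, seed = 1)
report
selected_rank(report)
model <- selected_model(report)
model

# stability and per-region thinning maps
subtype_stability(cohort$thickness, model)
bm <- thinning_betamaps(cohort$thickness, model)

# is the planted subtype-1 thinning map network-driven on the generating template?
spatial_test(cohort$beta_true[1, ], templates$functional, n_perm = 500, seed = 1)

# gene screen against the estimated map of the matching fitted subtype
expr  <- generate_expression(parc, cohort$beta_true[1, ], seed = 1)
genes <- gene_significance(beta_vector(bm, 2, rownames(expr$expr)), expr,
                           parcellation_distances(parc), n_surr = 500, seed = 1)
sum(genes$significant)
```

Output from this exact script (warnings about skipped degenerate models and
the rewiring acceptance rate omitted):

```
# A tibble: 3 x 5
      k cophenetic_coefficient mean_silhouette   rss delta_rss
  <int>                  <dbl>           <dbl> <dbl>     <dbl>
1     2                  1               1      99.4   NA
2     3                  0.998           0.758  96.2    0.0331
3     4                  0.995           0.613  94.5    0.0172
[1] 2
<subtype_model> k = 2, 400 subjects x 100 regions, RSS = 99.45
subjects per subtype: 200 200
<stability_result> alpha = 1.000, 0/400 unstable (0.0%)
<spatial_test_result> functional: r = 0.971, p_rewired = 0.0040, p_autocorr = 0.0020 (n_perm = 500, greater)
[1] 41
```

Reading it: the consensus fit statistics peak at `k = 2` (cophenetic
coefficient 1.000), matching the two planted subtypes, and the 400 subjects
split 200/200 exactly as planted (fitted label 2 is the planted
limbic/default-vulnerable subtype here — component order is arbitrary).
Every subject keeps its subtype at follow-up (alpha = 1, 0% unstable). The
planted subtype-1 rate map correlates with its connectivity-predicted map
at r = 0.97, and both the rewired-network and autocorrelation nulls reject
(p < 0.005): the thinning is network-driven, as planted. The gene screen on
the estimated thinning map flags 41 of 249 expression maps, including the
20 genes whose maps were coupled to the thinning pattern.

Each result type has `tidy()`/`glance()` methods and an `autoplot()`
(rank-selection curves, subtype profiles, thinning maps with error bars,
null distributions, gene volcano), and `run_pipeline(pipeline_config(...),
out_dir)` executes every stage end-to-end, writing TSV/JSON artifacts plus
a checksummed manifest that is byte-identical across reruns with the same
seed.

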