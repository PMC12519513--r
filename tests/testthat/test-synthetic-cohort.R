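# Synthetic cohort generator: determinism, geometry, planted structure.

test_that("parcellation generation is deterministic and geometrically sane", {
  p1 <- generate_parcellation(100, seed = 1)
  p2 <- generate_parcellation(100, seed = 1)
  expect_identical(p1, p2)
  expect_false(identical(p1, generate_parcellation(100, seed = 2)))

  d <- parcellation_distances(p1)
  expect_true(all(d <= 2 * (70 + 5 * 3 + 5 * 2)))  # shell + jitter bound
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(is.finite(as.matrix(p1[, c("x_mm", "y_mm", "z_mm")]))))
  expect_identical(p1$roi_id, 0:99)
  expect_setequal(unique(p1$network_label),
                  intersect(unique(p1$network_label),
                            c("Visual", "Somatomotor", "DorsalAttention",
                              "VentralAttention", "Limbic", "Control", "Default")))

  d4 <- parcellation_distances(generate_parcellation(4, seed = 7))
  expect_equal(d4, t(d4))
  expect_true(all(diag(d4) == 0))
  expect_error(generate_parcellation(3), class = "cortsub_invalid_argument")
})

test_that("connectome templates are symmetric, connected, distinct and deterministic", {
  parc <- small_parc()
  t1 <- generate_connectomes(parc, 0.2, 30, seed = 3)
  t2 <- generate_connectomes(parc, 0.2, 30, seed = 3)
  expect_identical(t1, t2)
  for (tpl in t1) {
    w <- tpl$weights
    expect_equal(w, t(w))
    expect_true(all(diag(w) == 0))
    expect_true(all(w >= 0))
    expect_true(all(rowSums(w > 0) >= 1))  # spanning tree keeps every node connected
    g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
    expect_equal(igraph::components(g)$no, 1L)
  }
  ut <- upper.tri(t1$functional$weights)
  r_fs <- cor(t1$functional$weights[ut], t1$structural$weights[ut])
  expect_lt(r_fs, 1)
  expect_error(generate_connectomes(parc, density = 1.5),
               class = "cortsub_invalid_argument")
})

test_that("a complete template has distance-decaying weights", {
  parc <- small_parc()
  tpl <- generate_connectomes(parc, density = 1, distance_decay = 30, seed = 5)
  w <- tpl$functional$weights
  ut <- upper.tri(w)
  expect_true(all(w[ut] > 0))  # complete graph
  # monotone decay up to the log-normal noise: strong negative rank correlation
  expect_lt(cor(w[ut], tpl$functional$distances[ut], method = "spearman"), -0.8)
})

test_that("cohort generation is deterministic with exact no-change limit", {
  parc <- small_parc()
  tpl <- small_templates()$functional
  cfg <- sim_config(n_subjects = 30, n_rois = 40, seed = 7)
  c1 <- generate_cohort(cfg, parc, tpl)
  c2 <- generate_cohort(cfg, parc, tpl)
  expect_identical(c1$thickness, c2$thickness)
  expect_identical(c1$labels, c2$labels)

  cfg0 <- sim_config(n_subjects = 20, n_rois = 40, seed = 8, noise_sd = 0,
                     thinning_rate = c(0, 0))
  c0 <- generate_cohort(cfg0, parc, tpl)
  rois <- grep("^roi_", names(c0$thickness), value = TRUE)
  base <- c0$thickness[c0$thickness$time_years == 0, rois]
  for (v in unique(c0$thickness$visit_index)) {
    vis <- c0$thickness[c0$thickness$visit_index == v, rois]
    expect_equal(as.matrix(vis), as.matrix(base), ignore_attr = TRUE)
  }
})

test_that("planted subtype separation reaches large effect sizes when asked", {
  parc <- small_parc()
  tpl <- small_templates()$functional
  cfg <- sim_config(n_subjects = 80, n_rois = 40, seed = 9,
                    subtype_profile_effect = 0.5, noise_sd = 0.02,
                    subject_intercept_sd = 0)
  coh <- generate_cohort(cfg, parc, tpl)
  base <- coh$thickness[coh$thickness$time_years == 0, ]
  lab <- coh$labels$subtype[match(base$subject_id, coh$labels$subject_id)]
  vuln1 <- which(parc$network_label %in% c("Limbic", "Default"))
  d_cohen <- sapply(vuln1, function(r) {
    x <- base[[paste0("roi_", parc$roi_id[r])]]
    (mean(x[lab == 2]) - mean(x[lab == 1])) /
      sqrt((var(x[lab == 1]) + var(x[lab == 2])) / 2)
  })
  expect_true(all(d_cohen > 3))
})

test_that("between-group separation increases with the planted profile effect", {
  parc <- small_parc()
  tpl <- small_templates()$functional
  vuln1 <- paste0("roi_", parc$roi_id[parc$network_label %in% c("Limbic", "Default")])
  gap <- function(effect, seed) {
    cfg <- sim_config(n_subjects = 60, n_rois = 40, seed = seed,
                      subtype_profile_effect = effect)
    coh <- generate_cohort(cfg, parc, tpl)
    base <- coh$thickness[coh$thickness$time_years == 0, ]
    lab <- coh$labels$subtype[match(base$subject_id, coh$labels$subject_id)]
    m <- as.matrix(base[, vuln1])
    mean(m[lab == 2, ]) - mean(m[lab == 1, ])
  }
  for (s in 1:5) {
    gaps <- sapply(c(0.1, 0.3, 0.6), gap, seed = 40 + s)
    expect_true(all(diff(gaps) > 0))
  }
})

test_that("full network coupling reproduces the neighbor-weighted average exactly", {
  parc <- small_parc()
  tpl <- small_templates()$functional
  cfg <- sim_config(n_subjects = 20, n_rois = 40, seed = 10, network_coupling = 1)
  coh <- generate_cohort(cfg, parc, tpl)
  Wn <- tpl$weights / rowSums(tpl$weights)
  template_rate <- matrix(cfg$thinning_rate[2], 2, 40)
  vuln <- list(which(parc$network_label %in% c("Limbic", "Default")),
               which(!parc$network_label %in% c("Limbic", "Default")))
  for (j in 1:2) template_rate[j, vuln[[j]]] <- cfg$thinning_rate[1]
  expected <- template_rate %*% t(Wn)
  expect_equal(unname(coh$beta_true), unname(expected), tolerance = 1e-12)
})

test_that("cohort covariates carry the planted subtype differences", {
  coh <- acc_cohort(1)
  base <- coh$thickness[coh$thickness$time_years == 0, ]
  lab <- coh$labels$subtype[match(base$subject_id, coh$labels$subject_id)]
  expect_gt(mean(base$age_baseline[lab == 1]), mean(base$age_baseline[lab == 2]))
  expect_gt(mean(base$centiloid[lab == 1]), mean(base$centiloid[lab == 2]))
  expect_gt(mean(base$apoe4[lab == 1]), mean(base$apoe4[lab == 2]))
  # every subject appears at every scheduled visit, baseline at time 0
  expect_true(all(table(coh$thickness$subject_id) == 3))
  expect_true(all(base$time_years == 0))
})

test_that("expression maps are z-scored with controlled coupling", {
  parc <- small_parc()
  bmap <- sa_map(parc, seed = 5)
  ex <- generate_expression(parc, bmap, n_coupled = 8, n_null = 40,
                            coupling_r = 0.9, sa_length = 30, seed = 6)
  expect_equal(unname(colMeans(ex$expr)), rep(0, 48), tolerance = 1e-6)
  expect_equal(unname(apply(ex$expr, 2, sd)), rep(1, 48), tolerance = 1e-6)
  r_coupled <- cor(bmap, ex$expr[, ex$gene_info$coupled])
  expect_true(all(r_coupled >= 0.7 & r_coupled <= 1))

  # a fully null panel is not engineered to correlate with the map
  ex0 <- generate_expression(parc, bmap, n_coupled = 0, n_null = 60, seed = 7)
  expect_lt(max(abs(cor(bmap, ex0$expr))), 0.75)
  expect_identical(ex0$expr, generate_expression(parc, bmap, n_coupled = 0,
                                                 n_null = 60, seed = 7)$expr)
  expect_error(generate_expression(parc, bmap, n_coupled = 0, n_null = 0),
               class = "cortsub_invalid_argument")
})
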