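# Coordinated deformation models, rewired nulls, variogram surrogates.

toy_template <- function(w, coords = NULL) {
  n <- nrow(w)
  if (is.null(coords)) {
    set.seed(1)
    coords <- matrix(rnorm(3 * n, sd = 20), n, 3)
  }
  connectivity_template(w, as.matrix(dist(coords)), "functional")
}

test_that("neighbor-mean predictions match hand-computed sums", {
  # star graph: center is the arithmetic mean of the leaves
  w <- matrix(0, 4, 4)
  w[1, 2:4] <- w[2:4, 1] <- 1
  pred <- cdm_predict(c(0, 1, 2, 3), toy_template(w))
  expect_equal(pred[1], 2)

  # constant map: any normalized prediction is that constant
  w2 <- matrix(runif(25), 5, 5); w2 <- w2 + t(w2); diag(w2) <- 0
  expect_equal(cdm_predict(rep(3.5, 5), toy_template(w2)),
               rep(3.5, 5), tolerance = 1e-12)

  # 4-node weighted graph against an explicit double-loop oracle
  w3 <- matrix(c(0, 2, 1, 0,
                 2, 0, 3, 1,
                 1, 3, 0, 2,
                 0, 1, 2, 0), 4, 4)
  beta <- c(0.5, -1, 2, 0.25)
  oracle <- sapply(1:4, function(i) {
    num <- 0; den <- 0
    for (j in 1:4) if (j != i) { num <- num + w3[i, j] * beta[j]; den <- den + w3[i, j] }
    num / den
  })
  expect_equal(cdm_predict(beta, toy_template(w3)), oracle, tolerance = 1e-12)
  expect_equal(cdm_predict(beta, toy_template(w3), normalized = FALSE),
               sapply(1:4, function(i) sum(w3[i, -i] * beta[-i])),
               tolerance = 1e-12)

  w_iso <- w3; w_iso[4, ] <- w_iso[, 4] <- 0
  err <- expect_error(cdm_predict(beta, toy_template(w_iso)),
                      class = "cortsub_invalid_input")
  expect_match(conditionMessage(err), "4")
})

test_that("spatial correlation is 1 for a self-consistent map and sign-stable", {
  # two disjoint cliques with constant map per clique: each region's neighbor
  # mean equals its own value, so predicted == observed
  w <- matrix(0, 6, 6)
  w[1:3, 1:3] <- 1; w[4:6, 4:6] <- 1; diag(w) <- 0
  beta <- c(1, 1, 1, 2, 2, 2)
  tpl <- toy_template(w)
  expect_equal(cdm_correlation(beta, tpl), 1, tolerance = 1e-12)
  # negation flips predictions too, so r is unchanged in both variants
  w3 <- matrix(c(0, 2, 1, 0, 2, 0, 3, 1, 1, 3, 0, 2, 0, 1, 2, 0), 4, 4)
  b <- c(0.5, -1, 2, 0.25)
  expect_equal(cdm_correlation(b, toy_template(w3)),
               cdm_correlation(-b, toy_template(w3)), tolerance = 1e-12)
  expect_equal(cdm_correlation(b, toy_template(w3), normalized = FALSE),
               cdm_correlation(-b, toy_template(w3), normalized = FALSE),
               tolerance = 1e-12)
  expect_error(cdm_correlation(rep(1, 6), tpl), class = "cortsub_invalid_input")
})

test_that("random maps on a random graph give near-zero correlations", {
  set.seed(12)
  w <- matrix(rbinom(100 * 100, 1, 0.2) * runif(1e4), 100, 100)
  w <- w + t(w); diag(w) <- 0
  w[1, 2] <- w[2, 1] <- pmax(w[1, 2], 0.5)  # avoid isolated nodes
  deg <- rowSums(w); w[deg == 0, 1] <- w[1, deg == 0] <- 0.5
  tpl <- toy_template(w)
  rs <- replicate(100, cdm_correlation(rnorm(100), tpl))
  expect_lt(abs(mean(rs)), 0.1)
  expect_lt(quantile(abs(rs), 0.9), 0.4)
})

test_that("rewired nulls preserve degrees, weights and geometry", {
  tpl <- small_templates()$functional
  nulls <- suppressWarnings(rewire_null(tpl, 20, seed = 5))
  w <- tpl$weights
  ut <- upper.tri(w)
  sp_orig <- cor(w[ut][w[ut] > 0], tpl$distances[ut][w[ut] > 0],
                 method = "spearman")
  for (m in nulls) {
    expect_equal(rowSums(m > 0), rowSums(w > 0))              # degree sequence
    expect_equal(sort(m[ut][m[ut] > 0]), sort(w[ut][w[ut] > 0]))  # weight multiset
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 0))
    e <- m[ut] > 0
    sp_null <- cor(m[ut][e], tpl$distances[ut][e], method = "spearman")
    expect_lt(abs(sp_null - sp_orig), 0.1)                    # distance-weight link
  }
  expect_identical(nulls, suppressWarnings(rewire_null(tpl, 20, seed = 5)))
  expect_false(identical(nulls[[1]], nulls[[2]]))
})

test_that("surrogate maps preserve moments and the smoothed variogram", {
  parc <- acc_parc()
  d <- parcellation_distances(parc)
  map <- sa_map(parc, seed = 31) * 0.01 - 0.012   # thinning-scale SA map
  surr <- variogram_surrogates(map, d, 100, seed = 32)
  expect_identical(surr, variogram_surrogates(map, d, 100, seed = 32))
  expect_equal(unname(colMeans(surr)), rep(mean(map), 100), tolerance = 1e-12)
  expect_lt(abs(mean(apply(surr, 2, sd)) - sd(map)) / sd(map), 0.2)

  eng <- cortsub:::variogram_engine(d)
  g_emp <- drop(cortsub:::smoothed_variogram_cols(eng, matrix(map)))
  g_surr <- rowMeans(cortsub:::smoothed_variogram_cols(eng, surr))
  expect_lte(mean(abs(g_surr - g_emp) / g_emp), 0.25)

  # the permutation core leaves surrogates uncorrelated with the original
  rs <- cor(map, surr)
  expect_lt(abs(mean(rs)), 0.15)
  expect_error(variogram_surrogates(rep(1, 100), d, 10),
               class = "cortsub_invalid_input")
})

test_that("spatial tests expose both nulls with the counting p-value rule", {
  tpl <- small_templates()$functional
  Wn <- tpl$weights / rowSums(tpl$weights)
  beta <- drop(Wn %*% sa_map(small_parc(), seed = 41))  # network-consistent map
  res <- suppressWarnings(spatial_test(beta, tpl, n_perm = 100, seed = 42))
  expect_s3_class(res, "spatial_test_result")
  expect_length(res$null_r_rewired, 100)
  expect_length(res$null_r_autocorr, 100)
  expect_true(res$observed_r >= -1 && res$observed_r <= 1)
  # the +1-corrected counting rule, recomputed from the returned nulls
  expect_equal(res$p_rewired,
               (sum(res$null_r_rewired >= res$observed_r) + 1) / 101)
  expect_equal(res$p_autocorr,
               (sum(res$null_r_autocorr >= res$observed_r) + 1) / 101)
  expect_gte(res$p_rewired, 1 / 101)
  expect_lte(res$p_rewired, 1)
  # identical seeds reproduce identical null distributions
  res2 <- suppressWarnings(spatial_test(beta, tpl, n_perm = 100, seed = 42))
  expect_identical(res$null_r_rewired, res2$null_r_rewired)
  expect_identical(res$null_r_autocorr, res2$null_r_autocorr)
  expect_error(spatial_test(beta, tpl, n_perm = 10),
               class = "cortsub_invalid_argument")
})

test_that("maps generated on one template test weaker on an independent one", {
  tpls <- acc_templates()
  larger <- 0
  for (s in 1:10) {
    b1 <- acc_seed_beta(s)
    pa <- suppressWarnings(spatial_test(b1, tpls$functional, n_perm = 100,
                                        seed = s))
    pb <- suppressWarnings(spatial_test(b1, tpls$structural, n_perm = 100,
                                        seed = s))
    larger <- larger + (pb$p_rewired > pa$p_rewired)
  }
  expect_gte(larger, 9)
})
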