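# Shared fixtures, built once per test session and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small cohort for fast unit tests -------------------------------------------
small_parc <- function() fixture("small_parc", function()
  generate_parcellation(40, seed = 11))

small_templates <- function() fixture("small_templates", function()
  generate_connectomes(small_parc(), density = 0.25, distance_decay = 30,
                       seed = 11))

small_cohort <- function() fixture("small_cohort", function()
  generate_cohort(sim_config(n_subjects = 120, n_rois = 40, seed = 21),
                  small_parc(), small_templates()$functional))

small_model <- function() fixture("small_model", function() {
  X <- invert_thickness(baseline_matrix(small_cohort()$thickness))
  fit_nmf(X, 2, n_restarts = 10, seed = 31)
})

# reference-scale fixtures for the acceptance suite ---------------------------
acc_parc <- function() fixture("acc_parc", function()
  generate_parcellation(100, seed = 1))

acc_templates <- function() fixture("acc_templates", function()
  generate_connectomes(acc_parc(), density = 0.2, distance_decay = 30, seed = 1))

acc_cohort <- function(seed) fixture(paste0("acc_cohort_", seed), function()
  generate_cohort(sim_config(seed = seed), acc_parc(),
                  acc_templates()$functional))

# full rank-selection report per seed; its k = 2 model doubles as the fitted
# subtype model for that seed
acc_rank_report <- function(seed) fixture(paste0("acc_rank_", seed), function() {
  X <- invert_thickness(baseline_matrix(acc_cohort(seed)$thickness))
  rank_selection(X, k_range = 2:6, n_restarts = 50, seed = seed)
})

acc_model <- function(seed) attr(acc_rank_report(seed), "models")[["2"]]

acc_betamaps <- function(seed) fixture(paste0("acc_betamaps_", seed), function()
  thinning_betamaps(acc_cohort(seed)$thickness, acc_model(seed)))

# map planted subtype labels to estimated component labels (by majority vote)
match_planted <- function(model, labels) {
  tab <- table(model$subject_assignment, labels$subtype)
  apply(tab, 2, which.max)
}

# adjusted Rand index against the planted labels (mclust is the oracle)
planted_ari <- function(model, labels) {
  mclust::adjustedRandIndex(model$subject_assignment, labels$subtype)
}

# a network-driven thinning map on the reference functional template:
# random regional base rates propagated by the neighbor-weighted average
# with coupling 0.8 (the generator's coupling rule)
acc_seed_beta <- function(seed) {
  tpl <- acc_templates()$functional
  Wn <- tpl$weights / rowSums(tpl$weights)
  withr::with_seed(seed, {
    base <- runif(nrow(Wn), -0.03, 0)
    0.2 * base + 0.8 * drop(Wn %*% base)
  })
}

# a spatially autocorrelated random map on a parcellation (GRF with
# exponential covariance), drawn through the expression generator
sa_map <- function(parc, sa_length = 30, seed = 1) {
  ex <- generate_expression(parc, as.numeric(seq_len(nrow(parc))),
                            n_coupled = 0, n_null = 1, sa_length = sa_length,
                            seed = seed)
  drop(ex$expr[, 1])
}
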