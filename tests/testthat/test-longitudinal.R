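# Mixed models, subtype characterization, follow-up assignment, agreement.

make_long <- function(S, visits, slope = 0.5, intercept = 2, b_sd = 0.5,
                      noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  b <- rnorm(S, 0, b_sd)
  tidyr::expand_grid(subject_id = sprintf("s%03d", 1:S), time_years = visits) |>
    dplyr::mutate(y = intercept + slope * time_years +
                    b[match(subject_id, sprintf("s%03d", 1:S))] +
                    rnorm(dplyr::n(), 0, noise_sd))
}

test_that("the zero-noise limit recovers the slope to machine precision", {
  dat <- make_long(10, c(0, 1, 2), b_sd = 0, noise_sd = 0)
  fit <- fit_random_intercept_lmm(dat, y ~ time_years)
  expect_equal(fit$fixed$estimate[fit$fixed$term == "time_years"], 0.5,
               tolerance = 1e-8)
})

test_that("slope recovery on simulated random-intercept data", {
  dat <- make_long(200, c(0, 1, 2), slope = 0.5, seed = 2)
  fit <- fit_random_intercept_lmm(dat, y ~ time_years)
  row <- fit$fixed[fit$fixed$term == "time_years", ]
  expect_lt(abs(row$estimate - 0.5), 3 * row$std_error)
  g <- glance(fit)
  expect_gt(g$sigma2_subject, 0)
  expect_gt(g$sigma2_residual, 0)
})

test_that("balanced-design GLS fixed effects equal OLS", {
  dat <- make_long(60, c(0, 1, 2, 3), slope = -0.2, seed = 3)
  fit <- fit_random_intercept_lmm(dat, y ~ time_years)
  ols <- stats::lm(y ~ time_years, data = dat)
  expect_equal(fit$fixed$estimate, unname(coef(ols)), tolerance = 1e-8)
})

test_that("degenerate designs are refused with informative errors", {
  dat <- make_long(10, 0)
  expect_error(fit_random_intercept_lmm(dat, y ~ time_years),
               "repeated measures", class = "cortsub_invalid_input")
  dat2 <- make_long(10, c(0, 1))
  dat2$dup <- dat2$time_years * 2
  err <- expect_error(fit_random_intercept_lmm(dat2, y ~ time_years + dup),
                      class = "cortsub_invalid_input")
  expect_match(conditionMessage(err), "dup")
})

test_that("per-region thinning maps recover the planted rates", {
  coh <- small_cohort()
  m <- small_model()
  bm <- thinning_betamaps(coh$thickness, m)
  expect_s3_class(bm, "beta_maps")
  perm <- match_planted(m, coh$labels)
  for (j in 1:2) {
    est <- bm[bm$subtype == perm[j], ]
    truth <- coh$beta_true[j, est$roi_name]
    expect_gte(mean(abs(est$beta - truth) <= 3 * est$se), 0.9)
  }
  expect_true(all(bm$se > 0))
  expect_true(all(is.finite(bm$beta)))
})

test_that("marginal slope contrasts agree with emmeans linear trends", {
  skip_if_not_installed("emmeans")
  coh <- small_cohort()
  m <- small_model()
  covars <- cortsub:::subject_covariates(coh$thickness, m)
  dat <- dplyr::inner_join(
    dplyr::select(coh$thickness, subject_id, time_years, .y = roi_0),
    covars, by = "subject_id")
  fit <- lme4::lmer(.y ~ time_years * subtype + age_baseline + sex +
                      centiloid_baseline + nmf_probability + (1 | subject_id),
                    data = dat, REML = TRUE)
  ours <- cortsub:::marginal_time_slopes(fit, 2)
  emm <- as.data.frame(emmeans::emtrends(fit, "subtype", var = "time_years",
                                         lmer.df = "asymptotic"))
  expect_equal(ours$beta, emm$time_years.trend, tolerance = 1e-6)
  expect_equal(ours$se, emm$SE, tolerance = 1e-6)
})

test_that("time units rescale thinning slopes exactly", {
  coh <- small_cohort()
  m <- small_model()
  bm_y <- thinning_betamaps(coh$thickness, m)
  th_days <- dplyr::mutate(coh$thickness, time_years = time_years * 365.25)
  bm_d <- suppressWarnings(thinning_betamaps(th_days, m))  # "years" column now holds days
  expect_equal(bm_d$beta * 365.25, bm_y$beta, tolerance = 1e-6)
  expect_equal(bm_d$p, bm_y$p, tolerance = 1e-6)
})

test_that("subtype characterization recovers planted covariate differences", {
  coh <- acc_cohort(1)
  m <- acc_model(1)
  ch <- characterize_subtypes(coh$thickness, m)
  perm <- match_planted(m, coh$labels)
  age <- ch[ch$term == "age_baseline", ]
  # outcome is subtype-1 membership; planted subtype 1 (older) maps to
  # estimated component perm[1]
  if (perm[1] == 1) {
    expect_gt(age$or, 1)
  } else {
    expect_lt(age$or, 1)
  }
  expect_lt(age$p_value, 0.05)

  # permuted labels: no predictor should matter
  m_perm <- m
  set.seed(1)
  ord <- sample(nrow(m$W))
  m_perm$W <- m$W[ord, ]
  m_perm <- assign_subjects(m_perm)
  ch0 <- characterize_subtypes(coh$thickness, m_perm)
  covs <- ch0[ch0$term %in% c("age_baseline", "sexM", "centiloid_baseline", "apoe4"), ]
  expect_true(all(covs$ci_low <= 1 & covs$ci_high >= 1))
})

test_that("independent predictors cover the null odds ratio across seeds", {
  # sex is generated independently of subtype; its CI should cover OR = 1
  # in at least 90% of seeds
  cover <- logical(20)
  for (s in 1:20) {
    coh <- generate_cohort(sim_config(n_subjects = 200, n_rois = 40, seed = 300 + s),
                           small_parc(), small_templates()$functional)
    X <- invert_thickness(baseline_matrix(coh$thickness))
    m <- fit_nmf(X, 2, n_restarts = 5, seed = s)
    ch <- suppressWarnings(characterize_subtypes(coh$thickness, m))
    sexrow <- ch[ch$term == "sexM", ]
    cover[s] <- sexrow$ci_low <= 1 && sexrow$ci_high >= 1
  }
  expect_gte(mean(cover), 0.9)
})

test_that("longitudinal outcome models detect the planted amyloid interaction", {
  coh <- acc_cohort(1)
  m <- acc_model(1)
  fit <- longitudinal_outcome_model(coh$thickness, m, "centiloid")
  inter <- fit$fixed[grepl("subtype2:time_years|time_years:subtype2", fit$fixed$term), ]
  perm <- match_planted(m, coh$labels)
  # planted: subtype 1 accumulates faster (1.8 vs 1.33 CL/year); the sign of
  # the estimated interaction depends on which component is labeled 1
  expected_sign <- if (perm[1] == 1) -1 else 1
  expect_equal(sign(inter$estimate), expected_sign)
  expect_lt(inter$p_value, 0.05)

  # time translation leaves the interaction unchanged
  sh <- dplyr::mutate(coh$thickness, time_years = time_years + 5)
  sh$centiloid <- coh$thickness$centiloid
  fit2 <- suppressWarnings(fit_random_intercept_lmm(
    dplyr::inner_join(dplyr::select(sh, subject_id, time_years, .y = centiloid),
                      cortsub:::subject_covariates(coh$thickness, m),
                      by = "subject_id"),
    .y ~ subtype * time_years + age_baseline + sex + centiloid_baseline +
      nmf_probability))
  inter2 <- fit2$fixed[grepl("subtype2:time_years|time_years:subtype2",
                             fit2$fixed$term), ]
  expect_equal(inter$estimate, inter2$estimate, tolerance = 1e-6)

  # equal slopes planted: interaction CI covers zero in most seeds
  cover <- logical(10)
  for (s in 1:10) {
    cfg <- sim_config(n_subjects = 100, n_rois = 40, seed = 500 + s,
                      covariate_effects = list(centiloid_rate = c(1.5, 1.5)))
    coh0 <- generate_cohort(cfg, small_parc(), small_templates()$functional)
    m0 <- fit_nmf(invert_thickness(baseline_matrix(coh0$thickness)), 2,
                  n_restarts = 5, seed = s)
    f0 <- longitudinal_outcome_model(coh0$thickness, m0, "centiloid")
    it <- f0$fixed[grepl("subtype2:time_years|time_years:subtype2", f0$fixed$term), ]
    cover[s] <- abs(it$estimate) <= qnorm(0.975) * it$std_error
  }
  expect_gte(mean(cover), 0.9)
})

test_that("follow-up vectors are matched to subtype profiles by correlation", {
  m <- small_model()
  # a vector whose inverted pattern equals H row 2 must land in subtype 2
  x <- m$inversion_constant[m$roi_names] - m$H[2, ]
  res <- assign_followup(x, m)
  expect_equal(res$subtype, 2L)
  expect_equal(unname(res$correlations["subtype_2"]), 1, tolerance = 1e-12)

  # shift invariance
  res_shift <- assign_followup(x + 0.05, m)
  expect_equal(res_shift$subtype, res$subtype)
  expect_equal(res_shift$correlations, res$correlations, tolerance = 1e-12)

  # orthogonalized vector correlates with neither profile
  set.seed(9)
  v <- rnorm(length(m$roi_names))
  h1 <- m$H[1, ] - mean(m$H[1, ]); h2 <- m$H[2, ] - mean(m$H[2, ])
  v <- v - mean(v)
  v <- v - sum(v * h1) / sum(h1 * h1) * h1
  h2o <- h2 - sum(h2 * h1) / sum(h1 * h1) * h1
  v <- v - sum(v * h2o) / sum(h2o * h2o) * h2o
  x_orth <- m$inversion_constant[m$roi_names] - v
  res_o <- assign_followup(x_orth, m)
  expect_lt(max(abs(res_o$correlations)), 0.05)

  expect_error(assign_followup(rep(2.5, length(m$roi_names)), m),
               class = "cortsub_invalid_input")
})

test_that("Krippendorff's alpha matches the hand-computed coincidence oracle", {
  # oracle values derived by enumerating all within-unit pairs:
  # D_o = 4/10, D_e = 48/90 -> alpha = 0.25; and D_o = 1, D_e = 2/3 -> -0.5
  expect_equal(as.numeric(krippendorff_alpha(c(1, 1, 2, 2, 2),
                                             c(1, 2, 2, 2, 1))), 0.25,
               tolerance = 1e-12)
  expect_equal(as.numeric(krippendorff_alpha(c(1, 2), c(2, 1))), -0.5,
               tolerance = 1e-12)
  expect_lt(as.numeric(krippendorff_alpha(c(1, 2), c(2, 1))), 0)
  expect_equal(as.numeric(krippendorff_alpha(c(1, 2, 1), c(1, 2, 1))), 1)
  expect_warning(a1 <- krippendorff_alpha(c(1, 1), c(1, 1)), "degenerate|zero")
  expect_equal(as.numeric(a1), 1)
  expect_error(krippendorff_alpha(1:3, 1:2), class = "cortsub_invalid_argument")
})

test_that("stability analysis flags switches and ranks low-confidence subjects", {
  coh <- small_cohort()
  m <- small_model()
  st <- subtype_stability(coh$thickness, m)
  expect_gte(st$alpha, 0.9)
  expect_lte(st$unstable_fraction, 0.1)

  # forcing switches preferentially at low NMF probability: alpha drops and
  # the instability model points at low probability
  a <- st$assignments
  set.seed(3)
  p_switch <- (1 - a$nmf_probability)^2
  sw <- runif(nrow(a)) < p_switch / max(p_switch) * 0.8
  fu <- a$followup_subtype
  fu[sw] <- 3L - fu[sw]
  alpha_sw <- as.numeric(krippendorff_alpha(a$baseline_subtype, fu))
  expect_lt(alpha_sw, st$alpha)
  covars <- dplyr::distinct(coh$thickness[coh$thickness$time_years == 0,
                                          c("subject_id", "age_baseline", "sex")])
  dat <- dplyr::inner_join(
    dplyr::mutate(a, unstable = as.integer(baseline_subtype != fu)),
    covars, by = "subject_id")
  fit <- suppressWarnings(glm(unstable ~ age_baseline + sex + followup_time +
                                nmf_probability, data = dat, family = binomial()))
  expect_lt(unname(coef(fit)["nmf_probability"]), 0)  # higher confidence, fewer switches
})
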