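# Longitudinal characterization: mixed models, stability, thinning maps.

# Per-subject covariates at baseline, joined with subtype assignment and
# the NMF probability of the assigned subtype.
subject_covariates <- function(thickness, model) {
  base <- dplyr::filter(thickness, .data$time_years == 0)
  base <- base[!duplicated(base$subject_id), ]
  assign_tbl <- tidy(model)[, c("subject_id", "subtype", "nmf_probability")]
  out <- dplyr::inner_join(
    dplyr::select(base, "subject_id", "age_baseline", "sex",
                  centiloid_baseline = "centiloid", "apoe4"),
    assign_tbl, by = "subject_id")
  if (nrow(out) == 0) abort_input("no overlap between thickness table and model subjects")
  out$subtype <- factor(out$subtype, levels = seq_len(model$k))
  out
}

#' Fit a random-intercept linear mixed model
#'
#' REML fit (via lme4) of a fixed-effect formula plus a random intercept per
#' subject; fixed-effect inference uses Wald z statistics (no small-sample
#' degrees-of-freedom correction).
#'
#' @param data Data frame with outcome, predictors and a subject id column.
#' @param formula Fixed-effects formula, e.g. `y ~ time_years + age`.
#' @param subject Name of the subject id column.
#' @return An `lmm_fit`: list with `fixed` (tibble `term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`), `varcomp` (tibble with the subject
#'   intercept and residual variances), and the underlying `lme4` fit.
#' @export
fit_random_intercept_lmm <- function(data, formula, subject = "subject_id") {
  if (!subject %in% names(data)) abort_invalid(sprintf("no column `%s`", subject))
  reps <- table(data[[subject]])
  if (max(reps) < 2)
    abort_input("no repeated measures: every subject has a single row, a random-intercept model with time effects cannot be fit")
  mm <- model.matrix(formula, data)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    abort_input(sprintf("rank-deficient fixed-effect design; aliased: %s",
                        paste(aliased, collapse = ", ")))
  }
  full <- stats::update(formula,
                        paste(". ~ . + (1 |", subject, ")"))
  fit <- lme4::lmer(full, data = data, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  est <- lme4::fixef(fit)
  # vcov can fail or go NA on boundary fits (e.g. zero residual variance);
  # estimates remain valid, so report unavailable SEs as NA
  V <- tryCatch(suppressWarnings(as.matrix(vcov(fit))),
                error = function(e) matrix(NA_real_, length(est), length(est)))
  se <- sqrt(diag(V))
  z <- est / se
  vc <- as.data.frame(lme4::VarCorr(fit))
  out <- list(
    fixed = tibble::tibble(term = names(est), estimate = unname(est),
                           std_error = unname(se), statistic = unname(z),
                           p_value = 2 * pnorm(-abs(unname(z)))),
    varcomp = tibble::tibble(group = vc$grp, variance = vc$vcov),
    fit = fit
  )
  class(out) <- "lmm_fit"
  out
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit> random-intercept LMM (REML, Wald z)\n")
  print(x$fixed)
  invisible(x)
}

#' @rdname fit_random_intercept_lmm
#' @param x An `lmm_fit`.
#' @param ... Unused.
#' @method tidy lmm_fit
#' @export
tidy.lmm_fit <- function(x, ...) x$fixed

#' @rdname fit_random_intercept_lmm
#' @method glance lmm_fit
#' @export
glance.lmm_fit <- function(x, ...) {
  tibble::tibble(
    sigma2_subject = x$varcomp$variance[x$varcomp$group != "Residual"][1],
    sigma2_residual = x$varcomp$variance[x$varcomp$group == "Residual"][1],
    n_obs = stats::nobs(x$fit),
    logLik = as.numeric(stats::logLik(x$fit))
  )
}

# Within-subtype marginal time slopes from a time*subtype model: linear
# contrasts of the time coefficient and the time:subtype interactions under
# dummy coding (equivalent to estimated-marginal-means linear trends).
marginal_time_slopes <- function(fit, k, time = "time_years") {
  est <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  terms <- names(est)
  purrr::map_dfr(seq_len(k), function(j) {
    cvec <- setNames(numeric(length(est)), terms)
    cvec[time] <- 1
    if (j > 1) {
      inter <- intersect(c(paste0(time, ":subtype", j),
                           paste0("subtype", j, ":", time)), terms)
      if (length(inter) == 0) abort_input("interaction term not found")
      cvec[inter[1]] <- 1
    }
    beta <- sum(cvec * est)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    tibble::tibble(subtype = j, beta = beta, se = se,
                   p = 2 * pnorm(-abs(beta / se)))
  })
}

#' Per-region subtype-specific thinning maps
#'
#' For each region, fits a random-intercept LMM of thickness on time, subtype
#' and their interaction, adjusted for baseline age, sex, baseline global
#' Centiloid and the NMF assignment probability; the within-subtype marginal
#' time slopes (mm/year) are obtained as linear contrasts of the time and
#' interaction coefficients, with Wald two-sided p-values. Regional p-values
#' are uncorrected by default (Benjamini-Hochberg optionally).
#'
#' @param thickness Longitudinal thickness tibble.
#' @param model A `subtype_model` fitted on the baseline of the same table.
#' @param adjust_p `"none"` (default) or `"BH"` across regions within subtype.
#' @return A `beta_maps` tibble: `roi_name`, `subtype`, `beta`, `se`, `p`.
#'   Subtypes with no longitudinal subjects get `NA` maps with a warning.
#' @export
thinning_betamaps <- function(thickness, model, adjust_p = c("none", "BH")) {
  adjust_p <- match.arg(adjust_p)
  covars <- subject_covariates(thickness, model)
  long <- dplyr::inner_join(
    dplyr::select(thickness, "subject_id", "time_years",
                  dplyr::all_of(order_roi_names(roi_columns(thickness)))),
    covars, by = "subject_id")
  # subtypes represented among subjects with repeated visits
  nvis <- dplyr::summarise(dplyr::group_by(long, .data$subject_id),
                           n = dplyr::n(),
                           subtype = .data$subtype[1], .groups = "drop")
  has_long <- vapply(seq_len(model$k), function(j)
    any(nvis$n >= 2 & nvis$subtype == j), logical(1))
  if (!any(has_long)) abort_input("no subtype has longitudinal subjects")
  if (!all(has_long))
    warn(sprintf("subtype(s) %s have no longitudinal subjects; maps set to NA",
                 paste(which(!has_long), collapse = ", ")))
  rois <- order_roi_names(roi_columns(thickness))
  fml_rhs <- "time_years * subtype + age_baseline + sex + centiloid_baseline + nmf_probability + (1 | subject_id)"
  maps <- purrr::map_dfr(rois, function(rn) {
    dat <- long
    dat$.y <- dat[[rn]]
    fit <- suppressMessages(lme4::lmer(
      stats::as.formula(paste(".y ~", fml_rhs)), data = dat, REML = TRUE,
      control = lme4::lmerControl(calc.derivs = FALSE,
                                  check.conv.singular = "ignore")))
    res <- marginal_time_slopes(fit, model$k)
    res$roi_name <- rn
    res
  })
  maps[!has_long[maps$subtype], c("beta", "se", "p")] <- NA_real_
  if (adjust_p == "BH") {
    maps <- dplyr::mutate(dplyr::group_by(maps, .data$subtype),
                          p = p.adjust(.data$p, "BH"))
    maps <- dplyr::ungroup(maps)
  }
  out <- dplyr::select(maps, "roi_name", "subtype", "beta", "se", "p")
  class(out) <- c("beta_maps", class(out))
  out
}

#' Extract one subtype's thinning map as a named vector
#'
#' @param beta_maps A `beta_maps` tibble.
#' @param subtype Subtype label.
#' @param roi_order Optional character vector of region names giving the order.
#' @return Named numeric vector of slopes (mm/year).
#' @export
beta_vector <- function(beta_maps, subtype, roi_order = NULL) {
  sub <- beta_maps[beta_maps$subtype == subtype, ]
  if (nrow(sub) == 0) abort_invalid("subtype not present in beta_maps")
  v <- setNames(sub$beta, sub$roi_name)
  if (!is.null(roi_order)) {
    if (!all(roi_order %in% names(v))) abort_input("roi_order names missing from beta_maps")
    v <- v[roi_order]
  }
  v
}

#' Cross-sectional subtype characterization by logistic regression
#'
#' Logistic model of subtype-1 membership (vs subtype 2) on baseline
#' age, sex, global Centiloid and APOE-e4 carriership, adjusted for the NMF
#' assignment probability. Perfect or quasi-perfect separation is flagged
#' with a warning rather than an error.
#'
#' @param thickness Thickness tibble (baseline visits are used).
#' @param model A two-subtype `subtype_model`.
#' @return Tibble with `term`, `estimate` (log-odds), `or`, `ci_low`,
#'   `ci_high` (Wald 95%), `p_value`; attribute `separation` flags
#'   convergence/separation warnings.
#' @export
characterize_subtypes <- function(thickness, model) {
  if (model$k != 2) abort_invalid("characterize_subtypes() requires exactly 2 subtypes")
  dat <- subject_covariates(thickness, model)
  dat$y <- as.integer(dat$subtype == 1)
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ age_baseline + sex + centiloid_baseline + apoe4 + nmf_probability,
        data = dat, family = binomial()),
    warning = function(w) {
      separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separation || any(abs(coef(fit)) > 15))
    warn("possible separation in the subtype logistic model; coefficients may be unstable")
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  out <- tibble::tibble(
    term = names(est), estimate = unname(est),
    or = exp(unname(est)),
    ci_low = exp(unname(est) - qnorm(0.975) * unname(se)),
    ci_high = exp(unname(est) + qnorm(0.975) * unname(se)),
    p_value = 2 * pnorm(-abs(unname(est) / unname(se))))
  attr(out, "separation") <- separation
  out
}

#' Longitudinal outcome model with subtype-by-time interaction
#'
#' Random-intercept LMM of a repeated outcome (e.g. Centiloid or a cognitive
#' score) on subtype, time and their interaction, adjusted for baseline age,
#' sex, baseline Centiloid and NMF probability. Optionally, within each
#' subtype, the interaction of the (continuous) NMF score with time.
#'
#' @param thickness Thickness tibble carrying the outcome column.
#' @param model A `subtype_model`.
#' @param outcome Name of the outcome column.
#' @param score_by_time If `TRUE`, also fit per-subtype models with an
#'   `nmf_probability:time` interaction.
#' @return An `lmm_fit`; when `score_by_time`, a list with `overall` and
#'   `within_subtype` (list of `lmm_fit` per subtype).
#' @export
longitudinal_outcome_model <- function(thickness, model, outcome,
                                       score_by_time = FALSE) {
  if (!outcome %in% names(thickness))
    abort_invalid(sprintf("no outcome column `%s`", outcome))
  covars <- subject_covariates(thickness, model)
  dat <- dplyr::inner_join(
    dplyr::select(thickness, "subject_id", "time_years",
                  .y = dplyr::all_of(outcome)),
    covars, by = "subject_id")
  base_terms <- "age_baseline + sex + centiloid_baseline + nmf_probability"
  overall <- fit_random_intercept_lmm(
    dat, stats::as.formula(paste(".y ~ subtype * time_years +", base_terms)))
  if (!score_by_time) return(overall)
  within <- lapply(seq_len(model$k), function(j) {
    fit_random_intercept_lmm(
      dat[dat$subtype == j, ],
      stats::as.formula(paste(".y ~ nmf_probability * time_years + age_baseline + sex + centiloid_baseline")))
  })
  list(overall = overall, within_subtype = setNames(within,
       paste0("subtype_", seq_len(model$k))))
}

#' Assign a follow-up scan to a baseline subtype
#'
#' The follow-up regional thickness vector is inverted with the baseline
#' inversion constants stored in the model (so it lives in the fitted NMF
#' space; a raw-thickness variant is available) and Pearson-correlated with
#' each subtype's regional profile (row of H); the subtype with the highest
#' correlation wins, ties toward the lower index with a warning.
#'
#' @param x Named numeric thickness vector over the model's regions (mm).
#' @param model A `subtype_model` fitted on inverted thickness.
#' @param space `"inverted"` (default) or `"raw"`.
#' @return List with `subtype` and `correlations` (one r per subtype).
#' @export
assign_followup <- function(x, model, space = c("inverted", "raw")) {
  space <- match.arg(space)
  if (!is.null(names(x))) {
    if (!all(model$roi_names %in% names(x)))
      abort_input("follow-up vector is missing regions present in the model")
    x <- x[model$roi_names]
  } else if (length(x) != length(model$roi_names)) {
    abort_invalid("follow-up vector length does not match the model")
  }
  if (sd(x) == 0) abort_input("zero-variance follow-up vector: correlation undefined")
  if (space == "inverted") {
    if (is.null(model$inversion_constant))
      abort_input("model carries no inversion constants; fit on invert_thickness() output or use space = 'raw'")
    x <- model$inversion_constant[model$roi_names] - x
    if (sd(x) == 0) abort_input("zero-variance inverted follow-up vector: correlation undefined")
  }
  r <- vapply(seq_len(model$k), function(j) {
    h <- model$H[j, ]
    if (sd(h) == 0) abort_input(sprintf("subtype %d profile has zero variance", j))
    cor(x, h)
  }, numeric(1))
  best <- max(r)
  if (sum(r == best) > 1)
    warn("tied follow-up correlations; assigned to the lower subtype index")
  list(subtype = which.max(r), correlations = setNames(r, paste0("subtype_", seq_len(model$k))))
}

#' Krippendorff's alpha for nominal codes from two coders
#'
#' Chance-corrected agreement `alpha = 1 - D_o / D_e`, with observed and
#' expected disagreement computed from the coincidence matrix over all
#' pairable values (standard nominal-metric formulation for two codings per
#' unit). `alpha = 1` when disagreement is zero; degenerate inputs (a single
#' unit, or a single distinct code overall) have zero expected disagreement
#' and are defined as 1 with a warning.
#'
#' @param codes_t1,codes_t2 Equal-length vectors of nominal codes.
#' @return Alpha in `(-Inf, 1]`, with attributes `d_observed`, `d_expected`.
#' @export
krippendorff_alpha <- function(codes_t1, codes_t2) {
  if (length(codes_t1) != length(codes_t2))
    abort_invalid("code vectors must have equal length")
  ok <- !is.na(codes_t1) & !is.na(codes_t2)
  c1 <- as.character(codes_t1[ok]); c2 <- as.character(codes_t2[ok])
  n_units <- length(c1)
  if (n_units < 1) abort_invalid("no pairable units")
  vals <- sort(unique(c(c1, c2)))
  if (n_units == 1 || length(vals) == 1) {
    warn("degenerate agreement data (single unit or single code); alpha defined as 1")
    return(structure(1, d_observed = 0, d_expected = 0))
  }
  v <- length(vals)
  o <- matrix(0, v, v, dimnames = list(vals, vals))
  for (u in seq_len(n_units)) {
    i <- match(c1[u], vals); j <- match(c2[u], vals)
    o[i, j] <- o[i, j] + 1  # each unit contributes both ordered pairs,
    o[j, i] <- o[j, i] + 1  # divided by (m_u - 1) = 1
  }
  n_tot <- sum(o)            # = 2 * n_units pairable values
  marg <- rowSums(o)
  d_o <- sum(o) - sum(diag(o))
  d_o <- d_o / n_tot
  d_e <- (sum(outer(marg, marg)) - sum(marg^2)) / (n_tot * (n_tot - 1))
  if (d_e == 0) {
    warn("expected disagreement is zero; alpha defined as 1")
    return(structure(1, d_observed = d_o, d_expected = 0))
  }
  structure(1 - d_o / d_e, d_observed = d_o, d_expected = d_e)
}

#' Subtype stability between baseline and latest follow-up
#'
#' Assigns each longitudinal subject's latest follow-up scan to a baseline
#' subtype via [assign_followup()], flags subjects whose label changed,
#' quantifies agreement with Krippendorff's alpha, and fits a logistic model
#' of instability on baseline age, sex, follow-up time and the baseline NMF
#' assignment probability.
#'
#' @param thickness Longitudinal thickness tibble.
#' @param model A `subtype_model`.
#' @param space Passed to [assign_followup()].
#' @return A `stability_result`: list with `assignments` (per-subject tibble),
#'   `alpha`, `n_unstable`, `unstable_fraction`, and `logistic` (OR table for
#'   instability).
#' @export
subtype_stability <- function(thickness, model, space = "inverted") {
  rois <- order_roi_names(roi_columns(thickness))
  latest <- dplyr::slice_max(dplyr::group_by(thickness, .data$subject_id),
                             .data$time_years, n = 1, with_ties = FALSE)
  latest <- dplyr::ungroup(dplyr::filter(latest, .data$time_years > 0))
  if (nrow(latest) == 0) abort_input("no follow-up visits in the thickness table")
  base_assign <- tidy(model)
  latest <- dplyr::inner_join(latest,
                              base_assign[, c("subject_id", "subtype", "nmf_probability")],
                              by = "subject_id", suffix = c("", "_baseline"))
  fu <- purrr::map(seq_len(nrow(latest)), function(i) {
    x <- unlist(latest[i, rois])
    assign_followup(x, model, space = space)
  })
  assignments <- tibble::tibble(
    subject_id = latest$subject_id,
    baseline_subtype = latest$subtype,
    followup_subtype = vapply(fu, `[[`, integer(1), "subtype"),
    followup_time = latest$time_years,
    nmf_probability = latest$nmf_probability
  )
  assignments$stable <- assignments$baseline_subtype == assignments$followup_subtype
  alpha <- krippendorff_alpha(assignments$baseline_subtype,
                              assignments$followup_subtype)
  covars <- dplyr::distinct(
    dplyr::filter(thickness, .data$time_years == 0)[, c("subject_id", "age_baseline", "sex")])
  logit_dat <- dplyr::inner_join(assignments, covars, by = "subject_id")
  logit_dat$unstable <- as.integer(!logit_dat$stable)
  logistic <- NULL
  if (length(unique(logit_dat$unstable)) > 1) {
    fit <- suppressWarnings(glm(
      unstable ~ age_baseline + sex + followup_time + nmf_probability,
      data = logit_dat, family = binomial()))
    est <- coef(fit); se <- sqrt(diag(vcov(fit)))
    logistic <- tibble::tibble(
      term = names(est), estimate = unname(est), or = exp(unname(est)),
      ci_low = exp(unname(est) - qnorm(0.975) * unname(se)),
      ci_high = exp(unname(est) + qnorm(0.975) * unname(se)),
      p_value = 2 * pnorm(-abs(unname(est) / unname(se))))
  } else {
    warn("all subjects stable (or all unstable); instability logistic model skipped")
  }
  structure(list(assignments = assignments,
                 alpha = as.numeric(alpha),
                 n_unstable = sum(!assignments$stable),
                 unstable_fraction = mean(!assignments$stable),
                 logistic = logistic),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("<stability_result> alpha = %.3f, %d/%d unstable (%.1f%%)\n",
              x$alpha, x$n_unstable, nrow(x$assignments),
              100 * x$unstable_fraction))
  invisible(x)
}

#' @rdname subtype_stability
#' @param x A `stability_result`.
#' @param ... Unused.
#' @method tidy stability_result
#' @export
tidy.stability_result <- function(x, ...) {
  if (is.null(x$logistic)) return(tibble::tibble())
  x$logistic
}

#' @rdname subtype_stability
#' @method glance stability_result
#' @export
glance.stability_result <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, n = nrow(x$assignments),
                 n_unstable = x$n_unstable,
                 unstable_fraction = x$unstable_fraction)
}
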