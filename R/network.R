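# Coordinated deformation models and their two null models.

#' Predict regional change from connected neighbors
#'
#' The coordinated deformation model: each region's predicted change is the
#' connectivity-weighted mean of its connected neighbors' observed changes,
#' `pred_i = sum_j w_ij * beta_j / sum_j w_ij` (strength-normalized). An
#' unnormalized weighted-sum variant is selectable.
#'
#' @param betamap Numeric vector of observed per-region changes (mm/year).
#' @param template A [connectivity_template()] (or a bare weight matrix).
#' @param normalized If `TRUE` (default) divide by nodal strength.
#' @return Numeric vector of predicted changes.
#' @export
cdm_predict <- function(betamap, template, normalized = TRUE) {
  w <- if (inherits(template, "connectivity_template")) template$weights else template
  if (length(betamap) != nrow(w)) abort_invalid("betamap length does not match template")
  if (any(!is.finite(betamap))) abort_input("betamap contains non-finite values")
  strength <- rowSums(w)
  if (any(strength == 0))
    abort_input(sprintf("isolated region(s) with zero strength: %s",
                        paste(which(strength == 0), collapse = ", ")))
  pred <- drop(w %*% betamap)
  if (normalized) pred <- pred / strength
  unname(pred)
}

#' Spatial correlation of predicted and observed change maps
#'
#' @inheritParams cdm_predict
#' @return Pearson correlation across regions.
#' @export
cdm_correlation <- function(betamap, template, normalized = TRUE) {
  pred <- cdm_predict(betamap, template, normalized = normalized)
  if (sd(pred) == 0 || sd(betamap) == 0)
    abort_input("zero variance in predicted or observed map: correlation undefined")
  cor(pred, betamap)
}

#' Geometry-preserving rewired network nulls
#'
#' Generates random networks that exactly preserve the degree sequence, the
#' connection-weight multiset and the node coordinates, and approximately
#' preserve the distance-weight relationship. Existing edges are binned by
#' Euclidean length into `n_bins` quantile bins; degree-preserving
#' double-edge swaps are accepted only when both replacement edges fall in
#' the same distance bins as the edges they replace; finally the original
#' weight multiset is reassigned to the rewired edges by rank-matching
#' (within each bin, the largest weight goes to the shortest edge, matching
#' the empirical decay of weight with distance).
#'
#' @param template A [connectivity_template()].
#' @param n_perm Number of null networks.
#' @param n_bins Number of distance quantile bins (default 5; chosen by a
#'   type-I calibration study of the rewired null, see the vignette).
#' @param swaps_per_edge Target swap attempts per edge (default 10).
#' @param seed Integer seed.
#' @return List of `n_perm` weight matrices (same dimnames as the template).
#' @export
rewire_null <- function(template, n_perm, n_bins = 5, swaps_per_edge = 10,
                        seed = 1) {
  stopifnot(inherits(template, "connectivity_template"))
  n_perm <- check_count(n_perm, "n_perm")
  n_bins <- check_count(n_bins, "n_bins")
  w <- template$weights
  d <- template$distances
  n <- nrow(w)
  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  E <- nrow(ut)
  if (E < 2) abort_input("template has fewer than two edges")
  edge_d <- d[ut]
  edge_w <- w[ut]
  br <- unique(quantile(edge_d, probs = seq(0, 1, length.out = n_bins + 1)))
  bin_all <- matrix(findInterval(d, br, rightmost.closed = TRUE,
                                 all.inside = TRUE), n, n)
  edge_bin <- bin_all[ut]
  n_attempts <- as.integer(swaps_per_edge * E)
  weight_by_bin <- split(edge_w, edge_bin)
  nulls <- vector("list", n_perm)
  acc_frac <- numeric(n_perm)
  withr::with_seed(stream_seed(seed, "rewire"), {
    for (p in seq_len(n_perm)) {
      rw <- rewire_edges(ut[, 1] - 1L, ut[, 2] - 1L, edge_bin,
                         bin_all, n, n_attempts)
      acc_frac[p] <- rw$accepted / n_attempts
      i <- rw$i + 1L; j <- rw$j + 1L
      new_d <- d[cbind(i, j)]
      new_w <- numeric(E)
      for (b in names(weight_by_bin)) {
        idx <- which(edge_bin == as.integer(b))
        ord <- order(new_d[idx])
        new_w[idx[ord]] <- sort(weight_by_bin[[b]], decreasing = TRUE)
      }
      m <- matrix(0, n, n, dimnames = dimnames(w))
      m[cbind(i, j)] <- new_w
      m[cbind(j, i)] <- new_w
      nulls[[p]] <- m
    }
  })
  if (mean(acc_frac) < 0.5)
    warn(sprintf("rewiring accepted only %.0f%% of swap attempts on average",
                 100 * mean(acc_frac)))
  attr(nulls, "accepted_fraction") <- acc_frac
  nulls
}

# Precomputed machinery for variogram-matched surrogates on a fixed
# distance matrix: pair index, lag kernel weights, and k-nearest-neighbor
# smoothing operators for each candidate neighborhood scale.
variogram_engine <- function(distances, n_lag_bins = 25,
                             neighbor_scales = c(10, 20, 30, 50),
                             cutoff_quantile = 0.25) {
  n <- nrow(distances)
  if (n < 10) abort_invalid("need at least 10 regions for surrogates")
  pr <- which(upper.tri(distances), arr.ind = TRUE)
  pd <- distances[pr]
  dmax <- quantile(pd, cutoff_quantile)
  lags <- seq(dmax / n_lag_bins, dmax, length.out = n_lag_bins)
  bw <- 3 * (lags[2] - lags[1])
  K <- exp(-0.5 * (outer(lags, pd, `-`) / bw)^2)  # n_lag x n_pairs
  K <- K / rowSums(K)
  neighbor_scales <- neighbor_scales[neighbor_scales < n]
  smoothers <- lapply(neighbor_scales, function(k) {
    Sm <- matrix(0, n, n)
    for (i in seq_len(n)) {
      di <- distances[i, ]
      di[i] <- Inf
      nn <- order(di)[seq_len(k)]
      wgt <- exp(-di[nn] / di[nn][k])
      Sm[i, nn] <- wgt / sum(wgt)
    }
    Sm
  })
  list(pairs = pr, K = K, lags = lags, smoothers = smoothers,
       neighbor_scales = neighbor_scales, n = n)
}

smoothed_variogram_cols <- function(engine, X) {
  # X: n x m matrix of maps; returns n_lag x m smoothed variograms
  V <- 0.5 * (X[engine$pairs[, 1], , drop = FALSE] -
                X[engine$pairs[, 2], , drop = FALSE])^2
  engine$K %*% V
}

#' Spatial-autocorrelation-preserving surrogate maps
#'
#' Variogram-matching surrogates: the map is randomly permuted, smoothed by
#' distance-weighted k-nearest-neighbor averaging at several candidate
#' neighborhood scales, and each candidate is affinely calibrated
#' (`surrogate = sqrt(|b|) * smoothed + sqrt(|a|) * noise`) so that its
#' smoothed empirical variogram matches the original map's; the best-fitting
#' scale (least-squares on the variogram) is kept. Surrogates are recentered
#' to the original map's mean (Pearson correlations are unaffected).
#'
#' @param map Numeric vector over regions.
#' @param distances Euclidean distance matrix.
#' @param n_surr Number of surrogate maps (>= 1).
#' @param n_lag_bins Number of variogram lags (default 25), spanning
#'   distances up to their 25th percentile.
#' @param neighbor_scales Candidate neighbor counts (default 10/20/30/50).
#' @param seed Integer seed.
#' @return Matrix `length(map) x n_surr` of surrogate maps.
#' @export
variogram_surrogates <- function(map, distances, n_surr, n_lag_bins = 25,
                                 neighbor_scales = c(10, 20, 30, 50),
                                 seed = 1) {
  n_surr <- check_count(n_surr, "n_surr")
  if (sd(map) == 0) abort_input("constant map: variogram is identically zero")
  if (length(map) != nrow(distances))
    abort_invalid("map length does not match distance matrix")
  engine <- variogram_engine(distances, n_lag_bins, neighbor_scales)
  gamma_emp <- drop(smoothed_variogram_cols(engine, matrix(map)))
  n <- engine$n
  withr::with_seed(stream_seed(seed, "surrogates"), {
    P <- vapply(seq_len(n_surr), function(s) sample(map), numeric(n))
    Z <- matrix(rnorm(n * n_surr), n, n_surr)
    best_sse <- rep(Inf, n_surr)
    out <- matrix(0, n, n_surr)
    nl <- length(gamma_emp)
    wt <- 1 / pmax(gamma_emp, 1e-12 * max(gamma_emp))^2  # relative-error weights
    for (ki in seq_along(engine$smoothers)) {
      SM <- engine$smoothers[[ki]] %*% P
      G <- smoothed_variogram_cols(engine, SM)        # n_lag x n_surr
      # per-surrogate weighted least squares gamma_emp ~ a + b * G[, s],
      # constrained to a, b >= 0 (the realized surrogate variogram is
      # b * gamma_smoothed + a, so negative coefficients cannot be realized)
      sw <- sum(wt)
      gbar <- colSums(wt * G) / sw
      ebar <- sum(wt * gamma_emp) / sw
      Gc <- G - matrix(gbar, nl, n_surr, byrow = TRUE)
      Sxx <- colSums(wt * Gc^2)
      Sxy <- colSums(wt * Gc * (gamma_emp - ebar))
      b <- ifelse(Sxx > 0, pmax(Sxy / Sxx, 0), 0)
      a <- pmax(ebar - b * gbar, 0)
      refit <- ebar - b * gbar < 0  # intercept clipped: refit slope through origin
      if (any(refit)) {
        b0 <- colSums(wt * G * gamma_emp) / pmax(colSums(wt * G^2), 1e-300)
        b[refit] <- pmax(b0[refit], 0)
        a[refit] <- 0
      }
      fitted_sse <- colSums(wt * (gamma_emp -
        (matrix(a, nl, n_surr, byrow = TRUE) +
           G * matrix(b, nl, n_surr, byrow = TRUE)))^2)
      improve <- fitted_sse < best_sse
      if (any(improve)) {
        cand <- SM[, improve, drop = FALSE] *
          matrix(sqrt(b[improve]), n, sum(improve), byrow = TRUE) +
          Z[, improve, drop = FALSE] *
          matrix(sqrt(a[improve]), n, sum(improve), byrow = TRUE)
        out[, improve] <- cand
        best_sse[improve] <- fitted_sse[improve]
      }
    }
    out <- out - matrix(colMeans(out), n, n_surr, byrow = TRUE) + mean(map)
    rownames(out) <- rownames(distances)
    out
  })
}

#' Test a coordinated deformation model against both null models
#'
#' The observed statistic is the spatial (Pearson) correlation between the
#' neighbor-predicted and observed change maps. Two null distributions are
#' computed: (1) rewired -- the CDM correlation recomputed on
#' geometry-preserving rewired networks ([rewire_null()]); (2)
#' autocorrelation -- the CDM correlation recomputed with
#' variogram-matched surrogates of the observed map substituted for it
#' ([variogram_surrogates()]). P-values are the fraction of null
#' correlations at least as large as the observed one, with a +1
#' continuity correction on counts so p is never exactly 0
#' (`p = (#(null >= obs) + 1) / (n_perm + 1)`); one-sided "greater" by
#' default, two-sided optionally.
#'
#' @param betamap Named or ordered numeric change map over regions.
#' @param template A [connectivity_template()].
#' @param n_perm Permutations per null (>= 100; default 1000).
#' @param seed Integer seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param normalized Passed to [cdm_predict()].
#' @param n_bins,swaps_per_edge Passed to [rewire_null()].
#' @param n_lag_bins,neighbor_scales Passed to [variogram_surrogates()].
#' @return A `spatial_test_result`: list with `observed_r`, `p_rewired`,
#'   `p_autocorr`, `null_r_rewired`, `null_r_autocorr`, `n_perm`, `modality`.
#' @export
spatial_test <- function(betamap, template, n_perm = 1000, seed = 1,
                         alternative = c("greater", "two.sided"),
                         normalized = TRUE, n_bins = 5, swaps_per_edge = 10,
                         n_lag_bins = 25, neighbor_scales = c(10, 20, 30, 50)) {
  alternative <- match.arg(alternative)
  n_perm <- check_count(n_perm, "n_perm", min = 100)
  if (!is.null(names(betamap)) && !is.null(rownames(template$weights))) {
    if (!all(rownames(template$weights) %in% names(betamap)))
      abort_input("betamap names do not cover the template regions")
    betamap <- betamap[rownames(template$weights)]
  }
  observed_r <- cdm_correlation(betamap, template, normalized = normalized)
  nulls_rw <- rewire_null(template, n_perm, n_bins = n_bins,
                          swaps_per_edge = swaps_per_edge, seed = seed)
  null_r_rewired <- vapply(nulls_rw, function(m)
    cdm_correlation(betamap, m, normalized = normalized), numeric(1))
  surr <- variogram_surrogates(unname(betamap), template$distances, n_perm,
                               n_lag_bins = n_lag_bins,
                               neighbor_scales = neighbor_scales, seed = seed)
  null_r_autocorr <- vapply(seq_len(n_perm), function(s)
    cdm_correlation(surr[, s], template, normalized = normalized), numeric(1))
  pfun <- function(null_r) {
    if (alternative == "greater") (sum(null_r >= observed_r) + 1) / (n_perm + 1)
    else (sum(abs(null_r) >= abs(observed_r)) + 1) / (n_perm + 1)
  }
  structure(list(observed_r = observed_r,
                 p_rewired = pfun(null_r_rewired),
                 p_autocorr = pfun(null_r_autocorr),
                 null_r_rewired = null_r_rewired,
                 null_r_autocorr = null_r_autocorr,
                 n_perm = n_perm,
                 alternative = alternative,
                 modality = template$modality),
            class = "spatial_test_result")
}

#' @export
print.spatial_test_result <- function(x, ...) {
  cat(sprintf("<spatial_test_result> %s: r = %.3f, p_rewired = %.4f, p_autocorr = %.4f (n_perm = %d, %s)\n",
              x$modality, x$observed_r, x$p_rewired, x$p_autocorr, x$n_perm,
              x$alternative))
  invisible(x)
}

#' @rdname spatial_test
#' @param x A `spatial_test_result`.
#' @param ... Unused.
#' @method tidy spatial_test_result
#' @export
tidy.spatial_test_result <- function(x, ...) {
  tibble::tibble(modality = x$modality, observed_r = x$observed_r,
                 p_rewired = x$p_rewired, p_autocorr = x$p_autocorr,
                 n_perm = x$n_perm)
}

#' Run spatial tests for every subtype map against every template
#'
#' @param beta_maps A `beta_maps` tibble from [thinning_betamaps()].
#' @param templates Named list of [connectivity_template()]s.
#' @param ... Passed to [spatial_test()].
#' @return Tibble with one row per subtype x template; the full results are
#'   kept in a list-column `result`.
#' @export
cdm_spatial_tests <- function(beta_maps, templates, ...) {
  subtypes <- sort(unique(beta_maps$subtype))
  grid <- tidyr::expand_grid(subtype = subtypes,
                             modality = names(templates))
  dots <- list(...)
  grid$result <- purrr::pmap(grid, function(subtype, modality) {
    tpl <- templates[[modality]]
    bv <- beta_vector(beta_maps, subtype, roi_order = rownames(tpl$weights))
    do.call(spatial_test, c(list(bv, tpl), dots))
  })
  res <- purrr::map_dfr(grid$result, tidy)
  dplyr::bind_cols(grid[, "subtype"], res, tibble::tibble(result = grid$result))
}
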