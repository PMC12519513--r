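# NMF-based cortical thickness subtyping.

#' Extract the baseline thickness matrix from a long table
#'
#' @param thickness Thickness tibble (one row per subject-visit) with
#'   `roi_<id>` columns.
#' @return Numeric subjects x regions matrix, rownames = subject ids,
#'   colnames = `roi_<id>` in numeric id order.
#' @export
baseline_matrix <- function(thickness) {
  base <- dplyr::filter(thickness, .data$time_years == 0)
  base <- base[!duplicated(base$subject_id), , drop = FALSE]
  cols <- order_roi_names(roi_columns(base))
  if (length(cols) == 0) abort_input("no `roi_<id>` columns found")
  m <- as.matrix(base[, cols])
  rownames(m) <- base$subject_id
  m
}

#' Invert thickness so larger values mean more atrophy
#'
#' NMF requires nonnegative inputs in which the signal of interest loads
#' positively; raw thickness decreases with atrophy, so each region is
#' inverted against its own across-subject maximum:
#' `x_inv = max_s(x) + margin - x`. This guarantees positivity on raw
#' (uncorrected) thickness and exactly reverses the subject ordering within
#' every region. The per-region inversion constants are kept as an attribute
#' so follow-up scans can be mapped into the same space. A global-maximum
#' variant is available for sensitivity analyses.
#'
#' @param x Baseline thickness matrix (subjects x regions, mm, all > 0), or
#'   a thickness tibble (its baseline visit is extracted).
#' @param margin Positive offset, mm (default 0.01).
#' @param constants `"per_roi"` (default) or `"global"` maximum.
#' @return Nonnegative matrix with attributes `inversion_constant`
#'   (per-region constants) and `margin`.
#' @export
invert_thickness <- function(x, margin = 0.01, constants = c("per_roi", "global")) {
  constants <- match.arg(constants)
  if (is.data.frame(x)) x <- baseline_matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) abort_input("`x` must be a numeric matrix")
  bad <- which(x <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort_input(sprintf(
      "nonpositive thickness at [%s, %s] (value %g)",
      rownames(x)[bad[1, 1]] %||% bad[1, 1],
      colnames(x)[bad[1, 2]] %||% bad[1, 2],
      x[bad[1, , drop = FALSE]]))
  }
  if (margin <= 0) abort_invalid("`margin` must be > 0")
  cmax <- if (constants == "per_roi") apply(x, 2, max) else
    rep(max(x), ncol(x))
  const <- cmax + margin
  out <- sweep(-x, 2, const, `+`)
  attr(out, "inversion_constant") <- setNames(const, colnames(x))
  attr(out, "margin") <- margin
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

# Greedy matching of component rows of H2 to reference rows of H1 by
# correlation; returns the permutation p with H2[p[j], ] matched to H1[j, ].
match_components <- function(H_ref, H) {
  k <- nrow(H_ref)
  cm <- suppressWarnings(cor(t(H_ref), t(H)))
  cm[!is.finite(cm)] <- 0
  perm <- integer(k)
  used_r <- used_c <- rep(FALSE, k)
  for (step in seq_len(k)) {
    cm2 <- cm
    cm2[used_r, ] <- -Inf
    cm2[, used_c] <- -Inf
    idx <- arrayInd(which.max(cm2), dim(cm2))
    perm[idx[1]] <- idx[2]
    used_r[idx[1]] <- TRUE
    used_c[idx[2]] <- TRUE
  }
  perm
}

#' Fit NMF with multiplicative updates and multi-restart consensus
#'
#' Minimizes `||X - W H||_F^2` by Lee-Seung multiplicative updates from
#' nonnegative random initializations; the best of `n_restarts` runs (lowest
#' residual sum of squares) is retained. Subjects are assigned by their
#' highest subject score (row of W), and a subjects x subjects consensus
#' matrix records how often each pair was co-assigned across restarts, with
#' components matched across restarts by greedy correlation of the regional
#' profiles (rows of H). X is internally rescaled by its mean before the
#' updates and W rescaled back, so assignments and probabilities are exactly
#' invariant to multiplying X by a positive scalar.
#'
#' @param X Nonnegative subjects x regions matrix, usually from
#'   [invert_thickness()].
#' @param k Rank (number of subtypes), `1 <= k <= min(S, R)`.
#' @param n_restarts Number of random restarts (default 50).
#' @param max_iter Maximum update iterations per restart (default 500).
#' @param tol Relative RSS decrease convergence threshold (default 1e-6).
#' @param seed Integer seed.
#' @return A `subtype_model` with elements `k`, `W`, `H`, `rss`,
#'   `subject_assignment`, `subject_probability`, `region_assignment`,
#'   `consensus`, `subject_ids`, `roi_names`, plus the inversion constants of
#'   `X` when present.
#' @export
fit_nmf <- function(X, k, n_restarts = 50, max_iter = 500, tol = 1e-6,
                    seed = 1) {
  if (!is.matrix(X) || !is.numeric(X)) abort_input("`X` must be a numeric matrix")
  if (any(X < 0)) abort_input("`X` has negative entries; use invert_thickness()")
  S <- nrow(X); R <- ncol(X)
  k <- check_count(k, "k")
  if (k > min(S, R)) abort_invalid("`k` exceeds min(nrow, ncol) of X")
  n_restarts <- check_count(n_restarts, "n_restarts")
  scale_x <- mean(X)
  if (scale_x == 0) abort_input("`X` is all zero")
  Xs <- X / scale_x
  init_scale <- sqrt(mean(Xs) / k)
  runs <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    withr::with_seed(stream_seed(seed, sprintf("nmf_restart_%d", r)), {
      W0 <- matrix(runif(S * k, 0.1, 1) * init_scale, S, k)
      H0 <- matrix(runif(k * R, 0.1, 1) * init_scale, k, R)
      fit <- nmf_multiplicative(Xs, W0, H0, as.integer(max_iter), tol)
      runs[[r]] <- list(W = fit$W, H = fit$H, rss = fit$rss,
                        iterations = fit$iterations)
    })
  }
  best <- which.min(vapply(runs, `[[`, numeric(1), "rss"))
  H_ref <- runs[[best]]$H
  # consensus over restarts with components matched to the best run
  co <- matrix(0, S, S)
  for (r in seq_len(n_restarts)) {
    perm <- match_components(H_ref, runs[[r]]$H)
    Wp <- runs[[r]]$W[, perm, drop = FALSE]
    assign_r <- max.col(Wp, ties.method = "first")
    A <- matrix(0, S, k)
    A[cbind(seq_len(S), assign_r)] <- 1
    co <- co + tcrossprod(A)
  }
  consensus <- co / n_restarts
  W <- runs[[best]]$W * scale_x
  H <- runs[[best]]$H
  model <- structure(list(
    k = k,
    W = W, H = H,
    rss = runs[[best]]$rss * scale_x^2,
    iterations = runs[[best]]$iterations,
    n_restarts = n_restarts,
    consensus = consensus,
    subject_ids = rownames(X) %||% sprintf("s%03d", seq_len(S)),
    roi_names = colnames(X) %||% paste0("roi_", seq_len(R) - 1L),
    inversion_constant = attr(X, "inversion_constant"),
    margin = attr(X, "margin")
  ), class = "subtype_model")
  assign_subjects(model)
}

#' Assign subjects (and regions) to subtypes from NMF scores
#'
#' Subject probabilities are the L1 row-normalized subject scores
#' `W_s / sum_k W_sk`; the assignment is the highest-probability subtype,
#' with ties broken toward the lower subtype index (warning emitted). An
#' all-zero score row yields a uniform probability and an `unassignable`
#' flag. Regions are assigned to the subtype with the largest regional score
#' (column of H).
#'
#' @param model A `subtype_model`.
#' @return The model with `subject_assignment`, `subject_probability`,
#'   `region_assignment`, `unassignable` filled in.
#' @export
assign_subjects <- function(model) {
  stopifnot(inherits(model, "subtype_model"))
  W <- model$W
  rs <- rowSums(W)
  unassignable <- rs == 0
  prob <- W
  prob[!unassignable, ] <- W[!unassignable, , drop = FALSE] / rs[!unassignable]
  prob[unassignable, ] <- 1 / model$k
  rowmax <- apply(prob, 1, max)
  ties <- rowSums(prob == rowmax) > 1 & !unassignable
  if (any(ties))
    warn(sprintf("%d subject(s) with tied NMF scores assigned to the lower subtype index",
                 sum(ties)))
  model$subject_probability <- prob
  model$subject_assignment <- max.col(prob, ties.method = "first")
  model$unassignable <- unassignable
  model$region_assignment <- max.col(t(model$H), ties.method = "first")
  model
}

#' @export
print.subtype_model <- function(x, ...) {
  cat(sprintf("<subtype_model> k = %d, %d subjects x %d regions, RSS = %.4g\n",
              x$k, nrow(x$W), ncol(x$H), x$rss))
  cat("subjects per subtype:", table(factor(x$subject_assignment,
                                            levels = seq_len(x$k))), "\n")
  invisible(x)
}

#' @rdname fit_nmf
#' @param x A `subtype_model`.
#' @param ... Unused.
#' @method tidy subtype_model
#' @export
tidy.subtype_model <- function(x, ...) {
  prob <- tibble::as_tibble(x$subject_probability,
                            .name_repair = ~ paste0("p_subtype_", seq_len(x$k)))
  dplyr::bind_cols(
    tibble::tibble(subject_id = x$subject_ids,
                   subtype = x$subject_assignment,
                   nmf_probability = apply(x$subject_probability, 1, max),
                   unassignable = x$unassignable),
    prob
  )
}

#' @rdname fit_nmf
#' @method glance subtype_model
#' @export
glance.subtype_model <- function(x, ...) {
  tibble::tibble(k = x$k, rss = x$rss, n_restarts = x$n_restarts,
                 n_subjects = nrow(x$W), n_regions = ncol(x$H),
                 mean_probability = mean(apply(x$subject_probability, 1, max)))
}

# Mean silhouette width of `labels` under the distance matrix `dmat`.
mean_silhouette <- function(dmat, labels) {
  n <- length(labels)
  sil <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    if (!any(own)) { sil[i] <- 0; next }
    a <- mean(dmat[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(dmat[i, labels == l]), numeric(1)))
    denom <- max(a, b)
    sil[i] <- if (denom == 0) 0 else (b - a) / denom
  }
  mean(sil)
}

# Cophenetic correlation of the consensus matrix: correlation between the
# consensus dissimilarities (1 - consensus) and the cophenetic distances of
# their average-linkage hierarchical clustering. A perfectly stable
# (all-ones) consensus has zero dissimilarity everywhere and is defined as 1.
consensus_cophenetic <- function(consensus) {
  d <- as.dist(1 - consensus)
  if (all(d < 1e-12)) return(1)
  hc <- hclust(d, method = "average")
  cd <- cophenetic(hc)
  if (sd(d) == 0 || sd(cd) == 0) return(1)
  cor(d, cd)
}

#' Select the NMF rank with consensus fit statistics
#'
#' Fits NMF at each candidate rank and scores clustering stability with the
#' cophenetic coefficient of the consensus matrix, the mean silhouette of
#' the best-run assignments (on consensus dissimilarities by default, raw
#' Euclidean feature distances optionally), and the relative decrease in
#' residual sum of squares. The selected rank maximizes the cophenetic
#' coefficient, with ties broken by higher mean silhouette and then by the
#' smaller rank; the RSS decrease is reported but not used for automatic
#' selection.
#'
#' @inheritParams fit_nmf
#' @param k_range Candidate ranks, each in `[2, min(S, R)]`.
#' @param silhouette_on `"consensus"` (default) or `"features"`.
#' @return A `rank_selection_report`: tibble with `k`,
#'   `cophenetic_coefficient`, `mean_silhouette`, `rss`, `delta_rss`;
#'   attributes `selected_k` and `models` (the fitted `subtype_model`s).
#' @export
rank_selection <- function(X, k_range = 2:6, n_restarts = 50, max_iter = 500,
                           tol = 1e-6, seed = 1,
                           silhouette_on = c("consensus", "features")) {
  silhouette_on <- match.arg(silhouette_on)
  if (length(k_range) == 0) abort_invalid("`k_range` is empty")
  if (any(k_range < 2) || any(k_range > min(dim(X))))
    abort_invalid("`k_range` must lie in [2, min(S, R)]")
  k_range <- sort(unique(as.integer(k_range)))
  models <- lapply(k_range, function(k)
    fit_nmf(X, k, n_restarts = n_restarts, max_iter = max_iter, tol = tol,
            seed = stream_seed(seed, sprintf("rank_k%d", k))))
  feat_d <- if (silhouette_on == "features") as.matrix(dist(X)) else NULL
  stats <- purrr::map2_dfr(models, k_range, function(m, k) {
    dmat <- 1 - m$consensus
    sil <- if (silhouette_on == "consensus")
      mean_silhouette(dmat, m$subject_assignment)
    else mean_silhouette(feat_d, m$subject_assignment)
    tibble::tibble(k = k,
                   cophenetic_coefficient = consensus_cophenetic(m$consensus),
                   mean_silhouette = sil,
                   rss = m$rss)
  })
  stats$delta_rss <- c(NA_real_, -diff(stats$rss) / head(stats$rss, -1))
  ord <- order(-stats$cophenetic_coefficient, -stats$mean_silhouette, stats$k)
  selected_k <- stats$k[ord[1]]
  structure(stats, selected_k = selected_k, models = setNames(models, k_range),
            class = c("rank_selection_report", class(stats)))
}

#' @rdname rank_selection
#' @param report A `rank_selection_report`.
#' @export
selected_rank <- function(report) attr(report, "selected_k")

#' @rdname rank_selection
#' @export
selected_model <- function(report) {
  attr(report, "models")[[as.character(attr(report, "selected_k"))]]
}
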