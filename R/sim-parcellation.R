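# Synthetic parcellation and connectivity templates.

CANONICAL_NETWORKS <- c("Visual", "Somatomotor", "DorsalAttention",
                        "VentralAttention", "Limbic", "Control", "Default")

#' Generate a synthetic cortical parcellation
#'
#' Places `n_rois` region centroids on a sphere shell of radius 70 mm with
#' Gaussian jitter, mirrored across the two hemispheres, and annotates each
#' region with one of the seven canonical resting-state networks by angular
#' sector. The geometry is a synthetic stand-in for a surface-based atlas:
#' inter-regional Euclidean distances have a realistic range without shipping
#' atlas coordinates. Real parcellation coordinates can be supplied through
#' [read_parcellation()] instead.
#'
#' @param n_rois Number of regions (>= 4; default 100).
#' @param seed Integer seed; identical seeds give identical parcellations.
#' @param radius Shell radius in mm.
#' @return A `parcellation` tibble with columns `roi_id` (0-based),
#'   `roi_name`, `network_label`, `x_mm`, `y_mm`, `z_mm`.
#' @examples
#' parc <- generate_parcellation(20, seed = 1)
#' @export
generate_parcellation <- function(n_rois = 100, seed = 1, radius = 70) {
  n_rois <- check_count(n_rois, "n_rois", min = 4)
  with_stream_seed(seed, "parcellation", {
    n_left <- n_rois %/% 2L
    n_right <- n_rois - n_left
    # base unit directions with x >= 0 (right hemisphere)
    dirs <- matrix(rnorm(3L * n_right), ncol = 3L)
    dirs[, 1] <- abs(dirs[, 1])
    dirs <- dirs / sqrt(rowSums(dirs^2))
    # network sectors from the (y, z) angle; mirror-symmetric across x
    theta <- atan2(dirs[, 3], dirs[, 2])
    sector <- pmin(floor((theta + pi) / (2 * pi) * 7), 6) + 1L
    right <- dirs
    left <- dirs[seq_len(n_left), , drop = FALSE]
    left[, 1] <- -left[, 1]
    all_dirs <- rbind(left, right)
    hemi <- c(rep("L", n_left), rep("R", n_right))
    network <- CANONICAL_NETWORKS[c(sector[seq_len(n_left)], sector)]
    r_jit <- radius + rnorm(n_rois, sd = 3)
    coords <- all_dirs * r_jit + matrix(rnorm(3L * n_rois, sd = 2), ncol = 3L)
    out <- tibble::tibble(
      roi_id = 0:(n_rois - 1L),
      roi_name = sprintf("%s_%s_%03d", hemi, network, 0:(n_rois - 1L)),
      network_label = network,
      x_mm = coords[, 1], y_mm = coords[, 2], z_mm = coords[, 3]
    )
    class(out) <- c("parcellation", class(out))
    out
  })
}

#' Pairwise Euclidean distances between region centroids
#'
#' @param parcellation A `parcellation` tibble.
#' @return A symmetric matrix (mm) with zero diagonal, dimnames `roi_<id>`.
#' @export
parcellation_distances <- function(parcellation) {
  coords <- as.matrix(parcellation[, c("x_mm", "y_mm", "z_mm")])
  if (any(!is.finite(coords))) abort_input("parcellation centroids must be finite")
  d <- as.matrix(dist(coords))
  nm <- paste0("roi_", parcellation$roi_id)
  dimnames(d) <- list(nm, nm)
  d
}

#' Construct a connectivity template
#'
#' @param weights Symmetric nonnegative matrix with zero diagonal.
#' @param distances Symmetric Euclidean distance matrix, zero diagonal.
#' @param modality One of `"functional"`, `"structural"`, `"morphometric"`.
#' @return A `connectivity_template` object.
#' @export
connectivity_template <- function(weights, distances,
                                  modality = c("functional", "structural",
                                               "morphometric")) {
  modality <- match.arg(modality)
  weights <- as.matrix(weights)
  distances <- as.matrix(distances)
  if (!isTRUE(all.equal(weights, t(weights), tolerance = 1e-9)))
    abort_input("connectivity weights must be symmetric")
  if (any(diag(weights) != 0)) abort_input("connectivity diagonal must be zero")
  if (any(!is.finite(weights)) || any(weights < 0))
    abort_input("connectivity weights must be finite and nonnegative")
  if (!all(dim(weights) == dim(distances)))
    abort_invalid("weights and distances dimensions differ")
  structure(list(weights = weights, distances = distances,
                 modality = modality),
            class = "connectivity_template")
}

#' @export
print.connectivity_template <- function(x, ...) {
  cat(sprintf("<connectivity_template> %s, %d regions, density %.2f\n",
              x$modality, nrow(x$weights),
              mean(x$weights[upper.tri(x$weights)] > 0)))
  invisible(x)
}

#' Generate three synthetic connectivity templates
#'
#' Simulated stand-ins for functional, structural and morphometric-similarity
#' connectomes. Edges occur with probability proportional to
#' `exp(-d / distance_decay)` (scaled to the requested density) and carry
#' log-normally perturbed distance-decaying weights; a minimum spanning tree
#' over Euclidean distance is always added so each template is connected. The
#' three modalities are independent realizations of the same generative
#' process, so they share geometry but not topology.
#'
#' @param parcellation A `parcellation` tibble.
#' @param density Target edge density in (0, 1].
#' @param distance_decay Decay length lambda in mm (> 0).
#' @param seed Integer seed.
#' @return Named list of three [connectivity_template()] objects.
#' @export
generate_connectomes <- function(parcellation, density = 0.2,
                                 distance_decay = 30, seed = 1) {
  density <- check_fraction(density, "density", lo = 0, hi = 1, lo_open = TRUE)
  if (!is.numeric(distance_decay) || distance_decay <= 0)
    abort_invalid("`distance_decay` must be > 0")
  d <- parcellation_distances(parcellation)
  n <- nrow(d)
  ut <- upper.tri(d)
  base <- exp(-d / distance_decay)
  # spanning tree over distance guarantees connectivity at any density
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  mst <- igraph::mst(g)
  mst_m <- igraph::as_adjacency_matrix(mst, sparse = FALSE) > 0
  templates <- lapply(c("functional", "structural", "morphometric"),
                      function(mod) {
    with_stream_seed(seed, paste0("connectome_", mod), {
      # scale edge probabilities so the expected density is met even when
      # some probabilities saturate at 1 (density = 1 -> complete graph)
      b_ut <- base[ut]
      if (density >= 1) {
        scale <- 1 / min(b_ut)
      } else {
        f <- function(lc) mean(pmin(1, exp(lc) * b_ut)) - density
        lo <- log(density / mean(b_ut))
        hi <- log(1 / min(b_ut))
        scale <- if (f(lo) >= 0) exp(lo) else exp(stats::uniroot(f, c(lo, hi))$root)
      }
      p_edge <- pmin(1, base * scale)
      keep <- matrix(FALSE, n, n)
      keep[ut] <- runif(sum(ut)) < p_edge[ut]
      keep <- keep | t(keep) | mst_m
      w <- base * exp(matrix(rnorm(n * n, sd = 0.25), n, n))
      w[upper.tri(w)] <- t(w)[upper.tri(w)]  # symmetrize the noise
      w[!keep] <- 0
      diag(w) <- 0
      dimnames(w) <- dimnames(d)
      connectivity_template(w, d, mod)
    })
  })
  names(templates) <- c("functional", "structural", "morphometric")
  templates
}
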