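# Imaging-transcriptomics: gene spatial correlations and ORA.

#' Spatial correlation of a thinning map with each gene's expression map
#'
#' @param betamap Numeric thinning map over regions (named or in the
#'   expression matrix's region order).
#' @param expr An `expression_matrix` (or bare regions x genes matrix).
#' @return Tibble `symbol`, `r` (Pearson correlation across regions);
#'   zero-variance genes get `NA` and are flagged in `zero_variance`.
#' @export
gene_spatial_correlations <- function(betamap, expr) {
  em <- if (inherits(expr, "expression_matrix")) expr$expr else expr
  if (length(betamap) != nrow(em))
    abort_input("betamap length does not match expression matrix regions")
  if (!is.null(names(betamap)) && !is.null(rownames(em))) {
    if (!all(rownames(em) %in% names(betamap)))
      abort_input("betamap names do not cover the expression regions")
    betamap <- betamap[rownames(em)]
  }
  if (anyNA(em)) abort_input("expression matrix contains missing values")
  sds <- apply(em, 2, sd)
  r <- rep(NA_real_, ncol(em))
  r[sds > 0] <- drop(cor(betamap, em[, sds > 0, drop = FALSE]))
  tibble::tibble(symbol = colnames(em) %||% paste0("gene_", seq_len(ncol(em))),
                 r = r, zero_variance = sds == 0)
}

#' Surrogate-based significance of gene-map spatial correlations
#'
#' Generates `n_surr` variogram-matched surrogates of the thinning map once
#' (the map, not the genes, is permuted), recomputes every gene's
#' correlation against each surrogate, and derives per-gene permutation
#' p-values with a +1 continuity correction. The default is two-sided on
#' |r| (both signs of spatial coupling are biologically meaningful); the
#' one-sided "greater" rule is available.
#'
#' @inheritParams gene_spatial_correlations
#' @param distances Euclidean distance matrix over regions.
#' @param n_surr Number of surrogate maps (>= 100).
#' @param alpha_threshold Significance threshold on `p_sa` (default 0.05,
#'   uncorrected; see `adjust`).
#' @param seed Integer seed.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @param adjust `"none"` (default) or `"BH"` applied to `p_sa` before
#'   thresholding.
#' @return A `gene_correlation_table` tibble: `symbol`, `source` (when
#'   known), `r`, `p_sa`, `significant`.
#' @export
gene_significance <- function(betamap, expr, distances, n_surr = 1000,
                              alpha_threshold = 0.05, seed = 1,
                              alternative = c("two.sided", "greater"),
                              adjust = c("none", "BH")) {
  alternative <- match.arg(alternative)
  adjust <- match.arg(adjust)
  n_surr <- check_count(n_surr, "n_surr", min = 100)
  em <- if (inherits(expr, "expression_matrix")) expr$expr else expr
  obs <- gene_spatial_correlations(betamap, expr)
  if (!is.null(names(betamap)) && !is.null(rownames(em)))
    betamap <- betamap[rownames(em)]
  surr <- variogram_surrogates(unname(betamap), distances, n_surr, seed = seed)
  null_r <- cor(surr, em)                    # n_surr x G
  p_sa <- vapply(seq_len(nrow(obs)), function(g) {
    if (is.na(obs$r[g])) return(NA_real_)
    if (alternative == "greater")
      (sum(null_r[, g] >= obs$r[g]) + 1) / (n_surr + 1)
    else
      (sum(abs(null_r[, g]) >= abs(obs$r[g])) + 1) / (n_surr + 1)
  }, numeric(1))
  p_use <- if (adjust == "BH") p.adjust(p_sa, "BH") else p_sa
  out <- obs
  if (inherits(expr, "expression_matrix"))
    out$source <- expr$gene_info$source[match(out$symbol, expr$gene_info$symbol)]
  out$p_sa <- p_sa
  out$significant <- !is.na(p_use) & p_use < alpha_threshold
  out <- dplyr::select(out, -"zero_variance")
  structure(out, n_surr = n_surr, alpha_threshold = alpha_threshold,
            class = c("gene_correlation_table", class(out)))
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the query list overlaps it more than
#' expected under hypergeometric sampling from the universe:
#' `p = sum_{i >= x} C(K, i) C(N - K, n - i) / C(N, n)` (upper tail
#' including the observed overlap), with Benjamini-Hochberg q-values across
#' the tested sets. Gene sets are intersected with the universe before
#' testing; sets outside `[min_size, max_size]` after intersection are
#' dropped. The intended universe is the analyzed candidate gene panel, not
#' the genome.
#'
#' @param query_genes Character vector of significant genes (subset of the
#'   universe).
#' @param universe_genes Character vector: all analyzed genes.
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param min_size,max_size Post-intersection set size bounds.
#' @return An `enrichment_table` tibble: `term`, `overlap` (x), `set_size`
#'   (K), `query_size` (n), `universe_size` (N), `p_value`, `q_value`,
#'   `genes` (overlapping genes, "/"-separated).
#' @export
ora <- function(query_genes, universe_genes, gene_sets, min_size = 3,
                max_size = Inf) {
  query_genes <- unique(as.character(query_genes))
  universe_genes <- unique(as.character(universe_genes))
  if (length(query_genes) == 0 || length(universe_genes) == 0)
    abort_input("empty query or universe")
  outside <- setdiff(query_genes, universe_genes)
  if (length(outside) > 0)
    abort_input(sprintf("query genes outside the universe: %s",
                        paste(outside, collapse = ", ")))
  if (is.null(names(gene_sets))) abort_invalid("`gene_sets` must be named")
  N <- length(universe_genes)
  n <- length(query_genes)
  sets <- lapply(gene_sets, intersect, universe_genes)
  keep <- lengths(sets) >= min_size & lengths(sets) <= max_size
  sets <- sets[keep]
  if (length(sets) == 0)
    return(structure(tibble::tibble(term = character(), overlap = integer(),
                                    set_size = integer(), query_size = integer(),
                                    universe_size = integer(), p_value = numeric(),
                                    q_value = numeric(), genes = character()),
                     class = c("enrichment_table", class(tibble::tibble()))))
  res <- purrr::imap_dfr(sets, function(genes, term) {
    K <- length(genes)
    hits <- intersect(query_genes, genes)
    x <- length(hits)
    p <- phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(term = term, overlap = x, set_size = K, query_size = n,
                   universe_size = N, p_value = p,
                   genes = paste(sort(hits), collapse = "/"))
  })
  res$q_value <- p.adjust(res$p_value, "BH")
  res <- dplyr::arrange(res, .data$p_value)
  res <- dplyr::relocate(res, "q_value", .after = "p_value")
  structure(res, class = c("enrichment_table", class(res)))
}

#' Combine per-subtype enrichment tables
#'
#' Stacks the per-subtype ORA results into one long table (every term of
#' every subtype is kept; nothing is re-tested).
#'
#' @param tables Named list of `enrichment_table`s, one per subtype.
#' @return Long tibble with a leading `subtype` column.
#' @export
compare_subtype_enrichment <- function(tables) {
  if (length(tables) == 0) abort_invalid("need at least one enrichment table")
  if (is.null(names(tables)))
    names(tables) <- paste0("subtype_", seq_along(tables))
  dplyr::bind_rows(lapply(tables, tibble::as_tibble), .id = "subtype")
}
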