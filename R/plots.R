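# ggplot2 visualizations for each result type.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_tile geom_col
#'   geom_histogram geom_vline facet_wrap labs scale_fill_viridis_c
#'   scale_fill_brewer theme_minimal geom_errorbar position_dodge
NULL

#' Plot rank-selection fit statistics
#'
#' @param object A `rank_selection_report`.
#' @param ... Unused.
#' @return A ggplot: cophenetic coefficient, mean silhouette and RSS by rank.
#' @method autoplot rank_selection_report
#' @export
autoplot.rank_selection_report <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("cophenetic_coefficient", "mean_silhouette", "rss"),
                            names_to = "statistic", values_to = "value")
  ggplot(df, aes(x = .data$k, y = .data$value)) +
    geom_line() + geom_point() +
    geom_vline(xintercept = attr(object, "selected_k"), linetype = 2) +
    facet_wrap(~statistic, scales = "free_y") +
    labs(x = "rank k", y = NULL,
         title = sprintf("NMF rank selection (selected k = %d)",
                         attr(object, "selected_k"))) +
    theme_minimal()
}

#' Plot regional subtype profiles of a fitted model
#'
#' @param object A `subtype_model`.
#' @param ... Unused.
#' @return A ggplot heatmap of H (subtypes x regions).
#' @method autoplot subtype_model
#' @export
autoplot.subtype_model <- function(object, ...) {
  df <- tibble::tibble(
    subtype = factor(rep(seq_len(object$k), each = ncol(object$H))),
    roi = rep(object$roi_names, object$k),
    score = as.vector(t(object$H)))
  ggplot(df, aes(x = .data$roi, y = .data$subtype, fill = .data$score)) +
    geom_tile() + scale_fill_viridis_c() +
    labs(x = "region", y = "subtype", fill = "NMF score (H)") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot subtype-specific thinning maps
#'
#' @param object A `beta_maps` tibble.
#' @param ... Unused.
#' @return A ggplot of per-region slopes with 95% error bars by subtype.
#' @method autoplot beta_maps
#' @export
autoplot.beta_maps <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      subtype = factor(.data$subtype),
                      roi = factor(.data$roi_name, levels = unique(.data$roi_name)))
  ggplot(df, aes(x = .data$roi, y = .data$beta, color = .data$subtype)) +
    geom_point(size = 0.8, position = position_dodge(width = 0.5)) +
    geom_errorbar(aes(ymin = .data$beta - 1.96 * .data$se,
                      ymax = .data$beta + 1.96 * .data$se),
                  width = 0, alpha = 0.5, position = position_dodge(width = 0.5)) +
    labs(x = "region", y = "thinning slope (mm/year)", color = "subtype") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot a spatial test's null distributions
#'
#' @param object A `spatial_test_result`.
#' @param ... Unused.
#' @return A ggplot with both null histograms and the observed correlation.
#' @method autoplot spatial_test_result
#' @export
autoplot.spatial_test_result <- function(object, ...) {
  df <- tibble::tibble(
    null = c(object$null_r_rewired, object$null_r_autocorr),
    model = rep(c("rewired", "autocorrelation"), each = object$n_perm))
  ggplot(df, aes(x = .data$null)) +
    geom_histogram(bins = 40, fill = "grey70") +
    geom_vline(xintercept = object$observed_r, color = "red") +
    facet_wrap(~model) +
    labs(x = "null spatial correlation", y = "count",
         title = sprintf("%s template: r = %.2f, p_rewired = %.3g, p_autocorr = %.3g",
                         object$modality, object$observed_r,
                         object$p_rewired, object$p_autocorr)) +
    theme_minimal()
}

#' Plot gene spatial correlations against surrogate significance
#'
#' @param object A `gene_correlation_table`.
#' @param ... Unused.
#' @return A ggplot of r versus -log10 surrogate p, colored by significance.
#' @method autoplot gene_correlation_table
#' @export
autoplot.gene_correlation_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot(df, aes(x = .data$r, y = -log10(.data$p_sa),
                 color = .data$significant)) +
    geom_point(alpha = 0.7) +
    labs(x = "spatial correlation r", y = expression(-log[10](p[SA])),
         color = "significant") +
    theme_minimal()
}
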