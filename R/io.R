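# Readers/writers for the package's delimited formats, configuration and
# the end-to-end pipeline. Everything is TSV/JSON/YAML: inspectable and
# diff-able; ROI identity is matched by column name, never by position.

#' Write / read a longitudinal thickness table
#'
#' TSV with columns `subject_id`, `visit_index`, `time_years`,
#' `age_baseline`, `sex`, `centiloid`, `apoe4`, `site`, then one `roi_<id>`
#' column per region (extra non-ROI columns such as outcomes are preserved).
#'
#' @param x Thickness tibble.
#' @param path File path.
#' @return `write_thickness()` the path, invisibly; `read_thickness()` a
#'   validated tibble.
#' @export
write_thickness <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_thickness
#' @param parcellation Optional `parcellation`; when given, the file must
#'   contain a `roi_<id>` column for every region.
#' @export
read_thickness <- function(path, parcellation = NULL) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("subject_id", "visit_index", "time_years", "age_baseline",
                "sex", "centiloid", "apoe4", "site")
  missing_req <- setdiff(required, names(x))
  if (length(missing_req) > 0)
    abort_input(sprintf("thickness file missing required column(s): %s",
                        paste(missing_req, collapse = ", ")))
  rois <- roi_columns(x)
  if (length(rois) == 0) abort_input("thickness file has no `roi_<id>` columns")
  if (!is.null(parcellation)) {
    expected <- paste0("roi_", parcellation$roi_id)
    miss <- setdiff(expected, rois)
    if (length(miss) > 0)
      abort_input(sprintf("thickness file missing ROI column(s): %s",
                          paste(miss, collapse = ", ")))
  }
  not_num <- rois[!vapply(x[rois], is.numeric, logical(1))]
  if (length(not_num) > 0)
    abort_input(sprintf("non-numeric thickness column(s): %s",
                        paste(not_num, collapse = ", ")))
  key <- paste(x$subject_id, x$visit_index)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    abort_input(sprintf("duplicate (subject_id, visit_index) rows, e.g. (%s) at line %d",
                        dup, which(key == dup)[2] + 1L))
  }
  no_base <- setdiff(x$subject_id, x$subject_id[x$time_years == 0])
  if (length(no_base) > 0)
    abort_input(sprintf("subject(s) without a time_years = 0 visit: %s",
                        paste(head(no_base, 10), collapse = ", ")))
  if (any(as.matrix(x[rois]) <= 0))
    abort_input("thickness values must be strictly positive")
  x
}

#' Write / read a parcellation table
#'
#' TSV with columns `roi_id`, `roi_name`, `network_label`, `x_mm`, `y_mm`,
#' `z_mm`.
#'
#' @param x A `parcellation` tibble.
#' @param path File path.
#' @export
write_parcellation <- function(x, path) {
  readr::write_tsv(as.data.frame(x), path)
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("roi_id", "roi_name", "network_label", "x_mm", "y_mm", "z_mm")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    abort_input(sprintf("parcellation file missing column(s): %s",
                        paste(miss, collapse = ", ")))
  if (!identical(sort(x$roi_id), seq_len(nrow(x)) - 1L) &&
      !identical(sort(as.integer(x$roi_id)), 0:(nrow(x) - 1L)))
    abort_input("roi_id must be 0..R-1 with no gaps")
  x <- dplyr::arrange(x, .data$roi_id)
  class(x) <- c("parcellation", class(x))
  x
}

#' Write / read a connectivity matrix
#'
#' Square TSV with a `roi` header column and one column per region.
#'
#' @param template A [connectivity_template()] or bare weight matrix.
#' @param path File path.
#' @export
write_connectome <- function(template, path) {
  w <- if (inherits(template, "connectivity_template")) template$weights else template
  df <- tibble::as_tibble(w, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(roi = rownames(w)), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_connectome
#' @param parcellation A `parcellation` supplying centroid distances.
#' @param modality Template modality tag.
#' @export
read_connectome <- function(path, parcellation, modality = "functional") {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  rois <- x$roi
  m <- as.matrix(x[, -1])
  rownames(m) <- rois
  expected <- paste0("roi_", parcellation$roi_id)
  if (!setequal(rois, expected) || !setequal(colnames(m), expected))
    abort_input("connectome regions do not match the parcellation")
  m <- m[expected, expected]
  d <- parcellation_distances(parcellation)
  connectivity_template(m, d, modality)
}

#' Write / read a regional gene-expression matrix
#'
#' TSV with a `roi` column and one column per gene; an optional side table
#' carries gene source labels.
#'
#' @param expr An `expression_matrix` or bare regions x genes matrix.
#' @param path File path.
#' @param info_path Optional path for the gene info table.
#' @export
write_expression <- function(expr, path, info_path = NULL) {
  em <- if (inherits(expr, "expression_matrix")) expr$expr else expr
  df <- dplyr::bind_cols(tibble::tibble(roi = rownames(em)),
                         tibble::as_tibble(em, .name_repair = "minimal"))
  readr::write_tsv(df, path)
  if (!is.null(info_path) && inherits(expr, "expression_matrix"))
    readr::write_tsv(expr$gene_info, info_path)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path, info_path = NULL) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  em <- as.matrix(x[, -1])
  rownames(em) <- x$roi
  if (anyNA(em)) abort_input("expression file contains missing values")
  info <- if (!is.null(info_path)) {
    readr::read_tsv(info_path, show_col_types = FALSE, progress = FALSE)
  } else {
    tibble::tibble(symbol = colnames(em), source = "other", coupled = NA)
  }
  structure(list(expr = em, gene_info = info), class = "expression_matrix")
}

#' Read a GMT gene-set file
#'
#' Standard tab-delimited GMT (term, description, genes...). Parsing is
#' delegated to `fgsea::gmtPathways()`.
#'
#' @param path GMT file path.
#' @return Named list of gene symbol vectors.
#' @export
read_gmt <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE))
    abort_input("reading GMT files requires the fgsea package")
  fgsea::gmtPathways(path)
}

#' Write a GMT gene-set file
#'
#' @param gene_sets Named list of gene symbol vectors.
#' @param path File path.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm)
    paste(c(nm, "na", gene_sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every stage parameter of [run_pipeline()]. Either `simulation`
#' is a [sim_config()] (inputs are generated) or the `*_path` fields point
#' to existing files. Unknown keys are rejected.
#'
#' @param seed Master seed; all stage substreams derive from it.
#' @param simulation A [sim_config()] or `NULL`.
#' @param thickness_path,parcellation_path,expression_path,gmt_path Input
#'   paths (used when `simulation` is `NULL`).
#' @param template_paths Named list of connectome paths by modality.
#' @param k_range Candidate NMF ranks; a single value skips rank selection.
#' @param n_restarts,n_perm,n_surr Resampling sizes.
#' @param alpha_threshold Gene significance threshold.
#' @param connectome_density,connectome_decay Simulated template parameters.
#' @param n_coupled,n_null,sa_length,coupling_r Simulated expression
#'   parameters.
#' @param normalized,alternative_network,alternative_genes,followup_space
#'   Analysis switches (see the stage functions).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1,
                            simulation = sim_config(seed = seed),
                            thickness_path = NULL,
                            parcellation_path = NULL,
                            template_paths = NULL,
                            expression_path = NULL,
                            gmt_path = NULL,
                            k_range = 2:6,
                            n_restarts = 50,
                            n_perm = 1000,
                            n_surr = 1000,
                            alpha_threshold = 0.05,
                            connectome_density = 0.2,
                            connectome_decay = 30,
                            n_coupled = 20,
                            n_null = 229,
                            sa_length = 30,
                            coupling_r = 0.8,
                            normalized = TRUE,
                            alternative_network = "greater",
                            alternative_genes = "two.sided",
                            followup_space = "inverted") {
  cfg <- as.list(environment())
  if (is.null(cfg$simulation)) {
    for (p in c("thickness_path", "parcellation_path")) {
      if (is.null(cfg[[p]]) || !file.exists(cfg[[p]]))
        abort_invalid(sprintf("`%s` must point to an existing file when not simulating", p))
    }
  }
  cfg$k_range <- sort(unique(as.integer(cfg$k_range)))
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys must match [pipeline_config()] arguments
#'   (a `simulation` block is passed to [sim_config()]).
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0)
    abort_input(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  if (!is.null(y$simulation)) {
    sim_known <- names(formals(sim_config))
    sim_unknown <- setdiff(names(y$simulation), sim_known)
    if (length(sim_unknown) > 0)
      abort_input(sprintf("unknown simulation key(s): %s",
                          paste(sim_unknown, collapse = ", ")))
    y$simulation <- do.call(sim_config, y$simulation)
  }
  do.call(pipeline_config, y)
}

# Deterministic synthetic gene sets for the simulated pipeline: one set
# concentrating the planted coupled genes plus background sets of null genes.
simulated_gene_sets <- function(expr, seed) {
  info <- expr$gene_info
  with_stream_seed(seed, "gene_sets", {
    coupled <- info$symbol[info$coupled]
    nulls <- info$symbol[!info$coupled]
    sets <- list(coupled_pathway = c(coupled, sample(nulls, min(5, length(nulls)))))
    n_bg <- 9
    for (i in seq_len(n_bg))
      sets[[sprintf("background_%02d", i)]] <-
        sample(nulls, min(15, length(nulls)))
    sets
  })
}

#' Run the full subtyping and mechanism-testing pipeline
#'
#' Orchestrates: input generation (or reading) -> thickness inversion ->
#' NMF rank selection (skipped for a single-rank `k_range`) -> model fit and
#' subject assignment -> subtype characterization -> stability -> per-region
#' thinning maps -> coordinated deformation tests per connectivity template
#' -> gene spatial correlations with surrogate significance -> ORA. Every
#' artifact is serialized into `out_dir` together with a JSON manifest
#' recording the package version, seed, configuration and file checksums;
#' rerunning with the same configuration and seed reproduces every file
#' byte-identically.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all in-memory results and `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs_dir <- file.path(out_dir, "inputs")
  dir.create(inputs_dir, showWarnings = FALSE)
  seed <- config$seed
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
            class = "cortsub_stage_error")
    })
  }

  # ---- inputs ----
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    parc <- generate_parcellation(sim$n_rois, seed = seed)
    templates <- generate_connectomes(parc, density = config$connectome_density,
                                      distance_decay = config$connectome_decay,
                                      seed = seed)
    cohort <- generate_cohort(sim, parc, templates$functional)
    thickness <- cohort$thickness
    expr <- generate_expression(parc, cohort$beta_true[1, ],
                                n_coupled = config$n_coupled,
                                n_null = config$n_null,
                                sa_length = config$sa_length,
                                coupling_r = config$coupling_r, seed = seed)
    gene_sets <- simulated_gene_sets(expr, seed)
    write_parcellation(parc, file.path(inputs_dir, "parcellation.tsv"))
    write_thickness(thickness, file.path(inputs_dir, "thickness.tsv"))
    for (m in names(templates))
      write_connectome(templates[[m]],
                       file.path(inputs_dir, paste0("connectome_", m, ".tsv")))
    write_expression(expr, file.path(inputs_dir, "expression.tsv"),
                     file.path(inputs_dir, "gene_info.tsv"))
    write_gmt(gene_sets, file.path(inputs_dir, "gene_sets.gmt"))
    jsonlite::write_json(
      list(labels = cohort$labels, beta_true = cohort$beta_true),
      file.path(inputs_dir, "truth.json"),
      auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  } else {
    parc <- read_parcellation(config$parcellation_path)
    thickness <- stage("read_thickness",
                       read_thickness(config$thickness_path, parc))
    templates <- NULL
    if (!is.null(config$template_paths))
      templates <- purrr::imap(config$template_paths, function(p, m)
        read_connectome(p, parc, modality = m))
    expr <- if (!is.null(config$expression_path))
      read_expression(config$expression_path) else NULL
    gene_sets <- if (!is.null(config$gmt_path)) read_gmt(config$gmt_path) else NULL
    cohort <- NULL
  }
  if (is.null(expr) && !is.null(config$gmt_path))
    abort("pipeline stage `genes` requires an expression matrix",
          class = "cortsub_stage_error")

  # ---- subtyping ----
  X <- stage("invert", invert_thickness(baseline_matrix(thickness)))
  if (length(config$k_range) > 1) {
    report <- stage("rank_selection",
                    rank_selection(X, k_range = config$k_range,
                                   n_restarts = config$n_restarts, seed = seed))
    model <- selected_model(report)
    readr::write_tsv(tibble::as_tibble(report),
                     file.path(out_dir, "rank_selection.tsv"))
  } else {
    report <- NULL
    model <- stage("fit", fit_nmf(X, config$k_range,
                                  n_restarts = config$n_restarts, seed = seed))
  }
  readr::write_tsv(tidy(model), file.path(out_dir, "assignments.tsv"))
  jsonlite::write_json(
    list(k = model$k, rss = model$rss, W = model$W, H = model$H,
         inversion_constant = as.list(model$inversion_constant)),
    file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA,
    matrix = "rowmajor")

  # ---- characterization and stability ----
  characterization <- if (model$k == 2)
    stage("characterize", characterize_subtypes(thickness, model)) else NULL
  if (!is.null(characterization))
    readr::write_tsv(characterization, file.path(out_dir, "characterization.tsv"))
  has_followup <- any(thickness$time_years > 0)
  stability <- if (has_followup)
    stage("stability", subtype_stability(thickness, model,
                                         space = config$followup_space)) else NULL
  if (!is.null(stability)) {
    jsonlite::write_json(
      c(as.list(glance(stability)), list(logistic = stability$logistic)),
      file.path(out_dir, "stability.json"), auto_unbox = TRUE, digits = NA)
  }

  # ---- thinning maps ----
  betamaps <- if (has_followup)
    stage("betamaps", thinning_betamaps(thickness, model)) else NULL
  if (!is.null(betamaps))
    readr::write_tsv(betamaps, file.path(out_dir, "betamaps.tsv"))

  # ---- network models ----
  cdm <- NULL
  if (!is.null(betamaps) && !is.null(templates)) {
    cdm <- stage("cdm", cdm_spatial_tests(
      betamaps, templates, n_perm = config$n_perm, seed = seed,
      alternative = config$alternative_network, normalized = config$normalized))
    readr::write_tsv(dplyr::select(cdm, -"result"), file.path(out_dir, "cdm.tsv"))
  }

  # ---- transcriptomics ----
  genes <- ora_tables <- enrichment <- NULL
  if (!is.null(betamaps) && !is.null(expr)) {
    d <- parcellation_distances(parc)
    genes <- lapply(sort(unique(betamaps$subtype)), function(j) {
      stage("genes", gene_significance(
        beta_vector(betamaps, j, roi_order = rownames(expr$expr)), expr, d,
        n_surr = config$n_surr, alpha_threshold = config$alpha_threshold,
        seed = stream_seed(seed, sprintf("genes_subtype_%d", j)),
        alternative = config$alternative_genes))
    })
    names(genes) <- paste0("subtype_", sort(unique(betamaps$subtype)))
    gene_long <- dplyr::bind_rows(lapply(genes, tibble::as_tibble), .id = "subtype")
    readr::write_tsv(gene_long, file.path(out_dir, "genes.tsv"))
    if (!is.null(gene_sets)) {
      ora_tables <- lapply(genes, function(g) {
        stage("ora", ora(g$symbol[g$significant], g$symbol, gene_sets))
      })
      enrichment <- compare_subtype_enrichment(ora_tables)
      readr::write_tsv(enrichment, file.path(out_dir, "ora.tsv"))
    }
  }

  # ---- manifest ----
  files <- sort(list.files(out_dir, recursive = TRUE, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(
    package = "cortsub",
    version = as.character(utils::packageVersion("cortsub")),
    seed = seed,
    k_selected = model$k,
    config = config_for_manifest(config),
    files = setNames(as.list(unname(sums)), files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(parcellation = parc, thickness = thickness,
                 templates = templates, cohort = cohort, model = model,
                 rank_report = report, characterization = characterization,
                 stability = stability, betamaps = betamaps, cdm = cdm,
                 genes = genes, ora = ora_tables, enrichment = enrichment,
                 manifest = manifest, out_dir = out_dir))
}

config_for_manifest <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$simulation)) cfg$simulation <- unclass(cfg$simulation)
  cfg
}
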