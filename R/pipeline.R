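#' Default pipeline configuration
#'
#' Every stage parameter of the end-to-end run, with the study-standard
#' defaults: cosine threshold 0.5, at least 5 matched fragment ions, mutual
#' top-10 edges, analog mass difference at most 500 Th, component cap 100
#' nodes, fragment tolerance 0.01 Th, presence threshold 0.01% of total
#' lipids, annotated-lipid universe for the diversity indices, alpha 0.05.
#'
#' @param ... named overrides of any default.
#' @return A named list (class `pipeline_config`).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    mgf = NULL, table = NULL, metadata = NULL, feature_meta = NULL,
    internal_standard_id = "IS_DGTS_d9",
    mz_tol = 0.01, rt_tol = 30,
    cosine_min = 0.5, min_matched = 5L, top_k = 10L,
    max_delta = 500, max_component = 100L, fragment_tol = 0.01,
    sqrt_intensity = FALSE,
    presence_threshold = 1e-4, presence_mode = "replicate_mean",
    universe = "annotated",
    alpha = 0.05,
    seed = 1L,
    out_dir = NULL
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop_validation(paste0("unknown config field(s): ",
                           paste(unknown, collapse = ", ")))
  }
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort_stage(
      sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      class = "lipidnet_stage_error",
      stage = stage, parent = e
    )
  })
}

#' Run the full lipidome pipeline
#'
#' Executes read -> recovery correction -> adduct merging -> annotation ->
#' molecular network -> composition (relative abundance, class shares,
#' presence, UpSet counts) -> information-theory indices -> multivariate
#' statistics (Hellinger + PCA, Z-score clustering), and writes CSV outputs
#' plus a reproducibility manifest when `out_dir` is set. Inputs come either
#' from the config's file paths (`mgf`, `table`, `metadata`, `feature_meta`)
#' or from in-memory objects passed directly.
#'
#' @param config a [pipeline_config()].
#' @param spectra optional in-memory `lipid_spectra` (overrides `config$mgf`).
#' @param table optional in-memory [feature_table()] (overrides the table
#'   paths).
#' @return A list with every stage result (`table`, `annotations`, `network`,
#'   `profile`, `class_shares`, `presence`, `upset`, `infotheory`, `pca`,
#'   `heatmap`, `manifest`), invisibly classed `lipidome_run`.
#' @export
run_lipidome_pipeline <- function(config = pipeline_config(),
                                  spectra = NULL, table = NULL) {
  if (is.null(spectra) && is.null(config$mgf)) {
    stop_validation("no spectra: set config$mgf or pass `spectra`")
  }
  if (is.null(table) && (is.null(config$table) || is.null(config$metadata))) {
    stop_validation("no feature table: set config$table/metadata or pass `table`")
  }
  for (f in c("mgf", "table", "metadata", "feature_meta")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      stop_validation(paste0("input file not found: ", config[[f]]))
    }
  }
  spectra <- spectra %||% run_stage("read_mgf", read_mgf(config$mgf))
  table <- table %||% run_stage(
    "read_feature_table",
    read_feature_table(config$table, config$metadata, config$feature_meta)
  )

  corrected <- run_stage("correct_recovery", {
    if (config$internal_standard_id %in% ft_features(table)) {
      correct_recovery(table, config$internal_standard_id)
    } else {
      table
    }
  })
  merged <- run_stage("merge_adducts",
                      merge_adducts(corrected, config$mz_tol, config$rt_tol))
  analytical_ids <- ft_features(merged)
  spectra_kept <- spectra[spectra$feature_id %in% analytical_ids, ]

  annotations <- run_stage("annotate",
                           annotate_spectra(spectra_kept,
                                            fragment_tol = config$fragment_tol))
  network <- run_stage("build_network", build_network(
    spectra_kept, merged,
    cosine_min = config$cosine_min, min_matched = config$min_matched,
    top_k = config$top_k, max_delta = config$max_delta,
    max_component = config$max_component, fragment_tol = config$fragment_tol,
    sqrt_intensity = config$sqrt_intensity
  ))
  profile <- run_stage("relative_abundance", relative_abundance(merged))
  class_shares <- run_stage("aggregate_classes",
                            aggregate_classes(profile, annotations))
  presence <- run_stage("call_presence", call_presence(
    profile, threshold = config$presence_threshold,
    mode = config$presence_mode
  ))
  upset <- run_stage("upset_counts", upset_counts(presence))
  info <- run_stage("infotheory", infotheory(
    profile, universe = config$universe, annotations = annotations
  ))
  pca <- run_stage("pca", {
    rel_annotated <- profile$rel[rownames(profile$rel) %in%
                                   annotated_universe(annotations), ,
                                 drop = FALSE]
    pca_ordination(hellinger(t(rel_annotated)), profile$sample_meta)
  })
  heatmap <- run_stage("zscore_cluster", zscore_cluster(class_shares))

  manifest <- list(
    package_version = as.character(utils::packageVersion("lipidnet")),
    r_version = as.character(getRversion()),
    parameters = unclass(config),
    n_spectra = nrow(spectra), n_features = nrow(table$abundance),
    n_samples = nrow(table$sample_meta),
    input_checksums = input_checksums(config)
  )
  result <- list(
    table = merged, annotations = annotations, network = network,
    profile = profile, class_shares = class_shares, presence = presence,
    upset = upset, infotheory = info, pca = pca, heatmap = heatmap,
    manifest = manifest
  )
  class(result) <- "lipidome_run"
  if (!is.null(config$out_dir)) write_run_outputs(result, config$out_dir)
  invisible(result)
}

annotated_universe <- function(annotations) {
  annotations$feature_id[annotations$lipid_class != "unknown" |
                           annotations$core != "none"]
}

input_checksums <- function(config) {
  paths <- purrr::compact(config[c("mgf", "table", "metadata", "feature_meta")])
  if (!length(paths)) return(list())
  as.list(tools::md5sum(unlist(paths)))
}

write_run_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  readr::write_csv(tidy(result$profile), p("relative_abundance.csv"))
  readr::write_csv(result$class_shares, p("class_abundance.csv"))
  pres <- tibble::as_tibble(as.data.frame(result$presence))
  pres <- tibble::add_column(pres, feature_id = rownames(result$presence),
                             .before = 1)
  readr::write_csv(pres, p("presence.csv"))
  readr::write_csv(result$upset, p("upset_counts.csv"))
  readr::write_csv(result$infotheory$samples, p("infotheory_samples.csv"))
  readr::write_csv(result$infotheory$lipids, p("infotheory_specificity.csv"))
  readr::write_csv(result$annotations, p("annotations.csv"))
  readr::write_csv(tidy(result$pca), p("pca_scores.csv"))
  readr::write_csv(glance(result$pca), p("pca_variance.csv"))
  write_edgelist(result$network, p("network_edges.tsv"))
  write_graphml(result$network, p("network.graphml"))
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' @export
print.lipidome_run <- function(x, ...) {
  cat("<lipidome_run>\n")
  print(network_summary(x$network))
  cat(sprintf("  %d features, %d annotated; %d presence patterns\n",
              nrow(x$table$abundance),
              sum(x$annotations$lipid_class != "unknown"),
              nrow(x$upset)))
  invisible(x)
}
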