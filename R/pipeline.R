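# End-to-end orchestration: activity calling -> plant enrichment ->
# drug-similarity profiling -> property/fragment characterisation ->
# plant-drug network. Every stage writes its table under the output
# directory and the run summary records the counts a screen reports.

#' Run the full screening pipeline
#'
#' Takes an in-memory dataset (the shapes produced by
#' [read_compound_library()] / [read_drug_panels()] or by the synthetic
#' generator) and executes all stages, writing TSV tables, network exports
#' and a JSON run summary under `out_dir`.
#'
#' @param compounds library compound table (`compound_id`, `smiles`).
#' @param plants plant table with `compound_ids` list-column.
#' @param panels drug table (`drug_id`, `smiles`, `stage`).
#' @param reference_actives,decoys compound tables for the activity model.
#' @param out_dir output directory, created if needed.
#' @param alpha_activity empirical-P cutoff for the activity call.
#' @param alpha_adj Bonferroni-adjusted cutoff for plant significance.
#' @param tc_threshold Tanimoto similarity threshold.
#' @param actives_only restrict network edge evidence to predicted actives.
#' @return (invisibly) the run summary list; all stage tables are attached
#'   as the `results` attribute.
#' @export
run_pipeline <- function(compounds, plants, panels, reference_actives,
                         decoys, out_dir,
                         alpha_activity = 0.05, alpha_adj = 0.05,
                         tc_threshold = 0.70, actives_only = FALSE) {
  stopifnot(alpha_activity > 0, alpha_activity <= 1,
            alpha_adj > 0, alpha_adj <= 1,
            tc_threshold > 0, tc_threshold <= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  emit <- function(table, file) {
    path <- file.path(out_dir, file)
    write_result_table(table, path)
    manifest <<- c(manifest, path)
    path
  }

  # stage 1: activity
  lib_fps <- maccs_fingerprint(compounds$smiles, compounds$compound_id)
  model <- fit_activity_model(
    maccs_fingerprint(reference_actives$smiles, reference_actives$compound_id),
    maccs_fingerprint(decoys$smiles, decoys$compound_id))
  calls <- predict_library(model, lib_fps, alpha = alpha_activity)
  emit(calls, "activity_calls.tsv")

  # stage 2: plant enrichment
  enrichment <- run_acea(plants, calls, alpha_adj = alpha_adj)
  emit(enrichment, "enrichment.tsv")

  # stage 3: drug similarity of predicted actives
  active_ids <- calls$compound_id[calls$is_active]
  active_fps <- lib_fps[rownames(lib_fps) %in% active_ids, , drop = FALSE]
  sim <- similarity_profile(active_fps, panels, threshold = tc_threshold)
  emit(sim$summary, "similarity_summary.tsv")
  emit(sim$pairs, "similarity_pairs.tsv")

  # stage 4: properties and fragments (predicted actives vs drug panel)
  active_tab <- compounds[compounds$compound_id %in% active_ids, , drop = FALSE]
  drug_tab <- panels[!duplicated(panels$drug_id), , drop = FALSE]
  props <- lipinski_flags(compute_properties(active_tab$smiles,
                                             active_tab$compound_id))
  emit(props, "properties_actives.tsv")
  drug_props <- lipinski_flags(compute_properties(drug_tab$smiles,
                                                  drug_tab$drug_id))
  emit(drug_props, "properties_drugs.tsv")
  frags <- frequency_table(active_tab$smiles, drug_tab$smiles)
  emit(frags, "fragment_frequencies.tsv")

  # stage 5: network over significant plants
  network <- build_network(enrichment, plants, lib_fps, panels,
                           calls = calls, threshold = tc_threshold,
                           actives_only = actives_only)
  net_paths <- write_network(network, file.path(out_dir, "network"))
  manifest <- c(manifest, unname(net_paths))
  comps <- connected_components(network)
  comp_table <- if (length(comps)) {
    data.frame(component = rep(seq_along(comps), lengths(comps)),
               node = unlist(comps), row.names = NULL)
  } else {
    data.frame(component = integer(0), node = character(0))
  }
  emit(comp_table, "network_components.tsv")

  summary <- list(
    N = nrow(compounds),
    n_active = sum(calls$is_active),
    active_percent = percent_of(sum(calls$is_active), nrow(compounds)),
    similarity = sim$summary,
    n_plants_tested = nrow(enrichment),
    n_significant_plants = sum(enrichment$significant),
    n_network_plants = nrow(network$plant_nodes),
    n_network_drugs = nrow(network$drug_nodes),
    n_network_edges = nrow(network$edges),
    n_components = length(comps),
    lipinski_pass_percent = percent_of(sum(props$lipinski_pass), nrow(props)),
    thresholds = list(alpha_activity = alpha_activity, alpha_adj = alpha_adj,
                      tc_threshold = tc_threshold,
                      actives_only = actives_only),
    manifest = basename(manifest))
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)

  results <- list(calls = calls, enrichment = enrichment, similarity = sim,
                  properties_actives = props, properties_drugs = drug_props,
                  fragments = frags, network = network, components = comps,
                  model = model)
  attr(summary, "results") <- results
  invisible(summary)
}

#' Run the pipeline on a generated synthetic dataset
#'
#' Convenience wrapper: generates the library, reference sets and drug
#' panels from a [generator_config()] and calls [run_pipeline()].
#'
#' @param config a [generator_config()].
#' @param out_dir output directory.
#' @param ... thresholds passed to [run_pipeline()].
#' @return the run summary (invisibly), with the generated dataset attached
#'   as attribute `dataset`.
#' @export
run_synthetic_pipeline <- function(config = generator_config(), out_dir, ...) {
  lib <- generate_library(config)
  drugs <- generate_drug_panels(config, lib$truth)
  refs <- generate_reference_sets(config)
  summary <- run_pipeline(lib$compounds, lib$plants, drugs$panels,
                          refs$actives, refs$decoys, out_dir, ...)
  attr(summary, "dataset") <- list(library = lib, drugs = drugs, refs = refs)
  invisible(summary)
}

#' Read a pipeline run configuration from YAML
#'
#' Supported keys: `library`, `annotation`, `panels` (mapping stage to
#' SMILES file), `reference_actives`, `decoys`, `out_dir`,
#' `alpha_activity`, `alpha_adj`, `tc_threshold`, `actives_only`.
#'
#' @param path YAML file.
#' @return validated list of run settings.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  needed <- c("library", "annotation", "panels", "reference_actives",
              "decoys", "out_dir")
  missing <- setdiff(needed, names(cfg))
  if (length(missing)) {
    stop("run config lacks key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (p in c(cfg$library, cfg$annotation, cfg$reference_actives, cfg$decoys,
              unlist(cfg$panels))) {
    if (!file.exists(p)) stop("configured path does not exist: ", p, call. = FALSE)
  }
  cfg$alpha_activity <- cfg$alpha_activity %||% 0.05
  cfg$alpha_adj <- cfg$alpha_adj %||% 0.05
  cfg$tc_threshold <- cfg$tc_threshold %||% 0.70
  cfg$actives_only <- isTRUE(cfg$actives_only)
  stopifnot(cfg$alpha_activity > 0, cfg$alpha_activity <= 1,
            cfg$tc_threshold > 0, cfg$tc_threshold <= 1)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the pipeline from files on disk
#'
#' @param config list from [read_run_config()], or a path to the YAML file.
#' @return the run summary, as [run_pipeline()].
#' @export
run_pipeline_files <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  lib <- read_compound_library(config$library, config$annotation)
  panels <- read_drug_panels(config$panels)
  refs_a <- read_smiles_file(config$reference_actives)
  refs_d <- read_smiles_file(config$decoys)
  run_pipeline(lib$compounds, lib$plants, panels, refs_a, refs_d,
               config$out_dir,
               alpha_activity = config$alpha_activity,
               alpha_adj = config$alpha_adj,
               tc_threshold = config$tc_threshold,
               actives_only = config$actives_only)
}
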