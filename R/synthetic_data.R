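# Synthetic benchmark generator. Emits a plant-annotated compound library,
# reference active/decoy sets and staged drug panels with known ground
# truth, so every pipeline stage can be exercised without any external
# database.
#
# Molecules come from a scaffold-decoration grammar: each scaffold is a core
# SMILES with two substitution slots filled from a fixed substituent list,
# which guarantees chemical validity and controllable MACCS similarity.
# Scaffolds are grouped into families chosen (and verified) so that
# within-family Tanimoto similarity is high while cross-family similarity
# stays below the 0.70 reporting threshold:
#   * covered active family   - six terpenoid-like saturated polycyclics;
#     drug panels decorate these cores, so these actives are drug-similar
#   * uncovered active family - thioether-terpenoid and glycoside cores with
#     no corresponding drugs; sets the drug-coverage fraction of actives
#   * isolate active family   - an N-methyl alkaloid core used only by a few
#     designated plants and two approved drugs, which yields a planned
#     isolated component in the plant-drug network
#   * inactive family         - eight flat aromatic cores (decoy chemistry)

ACTIVE_COVERED_CORES <- c(
  steroid    = "CC12CCC3C(CCC4CC(%s)CCC34C)C1CC(%s)C2O",
  drimane    = "CC1(C)CCC(%s)C2(C)C1CCC1C2CC(%s)C(=O)O1",
  guaiane    = "CC1CCC2C(C)(C)C(%s)CC3(C)CCC(%s)C1C23",
  oleanane   = "CC1(C)CCC2(C)CCC3(C)C(CC(%s)C4C3CC(%s)CC4)C2C1",
  spiroether = "O1CCC2(CC1)CC(%s)C1CCCC(%s)C1C2",
  lactone    = "O=C1OC2CC(%s)CCC2C2CC(%s)CCC12")

ACTIVE_UNCOVERED_CORES <- c(
  thioterp   = "CC1CC2SC(%s)CC3CCC(=S)C(%s)C3C2C1",
  glycoside  = "OCC1OC(OC2CC(%s)C(O)C(CO)O2)C(O)C(O)C1O%s")

ACTIVE_ISOLATE_CORE <- c(
  alkaloid   = "CN1CCC23CC(%s)N(C)C(=O)C2C1CC1C3CC(%s)CC1O")

INACTIVE_CORES <- c(
  quinoline  = "c1ccc2ncc(C(%s)=O)c(N%s)c2c1",
  indole     = "c1ccc2c(c1)cc(C%s)n2C%s",
  coumarin   = "O=c1cc(%s)c2cc(O%s)ccc2o1",
  benzofuran = "c1ccc2c(c1)oc(-c1ccc(%s)cc1%s)c2",
  azosulfa   = "O=S(=O)(N%s)c1ccc(N=Nc2ccc(%s)cc2)cc1",
  pyrimaryl  = "c1cnc(-c2ccc(C(%s)C)cc2)nc1N%s",
  acridine   = "c1ccc2nc3cc(C%s)ccc3c(N%s)c2c1",
  stilbene   = "C(=C/c1ccc(O%s)cc1)\\c1cc(OC)c(O%s)cc1")

# inactive scaffolds verified dissimilar (max Tc < 0.7) to the covered
# active cores; isolate plants take their non-active filler from these so no
# filler compound can link an isolate plant to a main-family drug
ISOLATE_SAFE_FILL <- c("quinoline", "indole", "azosulfa", "pyrimaryl",
                       "acridine", "stilbene")

SCAFFOLD_SUBSTITUENTS <- c(
  "", "C", "CC", "CCC", "C(C)C", "O", "OC", "CO", "CCO", "OCC",
  "CC(C)O", "OC(C)=O", "CC=C", "CCOC", "C(C)CO", "CC(C)C")

PLANT_FAMILIES <- c(
  "Araliaceae", "Asteraceae", "Boraginaceae", "Ranunculaceae", "Rosaceae",
  "Lamiaceae", "Apiaceae", "Fabaceae", "Apocynaceae", "Annonaceae",
  "Cucurbitaceae", "Campanulaceae", "Simaroubaceae", "Amaryllidaceae",
  "Papaveraceae")

decorate_core <- function(core, sub_a, sub_b) {
  gsub("\\(\\)", "", sprintf(core, sub_a, sub_b))
}

# n distinct decorated variants of one core, drawn from the substituent grid
sample_decorations <- function(core, n) {
  grid_n <- length(SCAFFOLD_SUBSTITUENTS)^2
  if (n > grid_n) {
    stop("scaffold capacity exceeded: ", n, " variants requested, grid has ",
         grid_n, call. = FALSE)
  }
  pick <- sample.int(grid_n, n)
  a <- SCAFFOLD_SUBSTITUENTS[((pick - 1L) %% length(SCAFFOLD_SUBSTITUENTS)) + 1L]
  b <- SCAFFOLD_SUBSTITUENTS[((pick - 1L) %/% length(SCAFFOLD_SUBSTITUENTS)) + 1L]
  mapply(decorate_core, core, a, b, USE.NAMES = FALSE)
}

# spread n molecules over several cores as evenly as possible
spread_over_cores <- function(cores, n) {
  base <- n %/% length(cores)
  counts <- rep(base, length(cores))
  extra <- n - sum(counts)
  if (extra > 0L) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  unlist(lapply(seq_along(cores), function(i) {
    stats::setNames(sample_decorations(cores[[i]], counts[i]),
                    rep(names(cores)[i], counts[i]))
  }))
}

#' Generator configuration
#'
#' Defaults emulate the shape of a large plant-compound database screen:
#' a 25% background active fraction, drug panels of 127/425/219
#' (preclinical/clinical/approved) and an approved-panel coverage target of
#' 75% of true actives, with a handful of strongly enriched plants
#' (active fraction 0.9, 30 compounds each) among ordinary plants.
#'
#' @param n_compounds distinct compounds in the library pool.
#' @param background_active_fraction fraction of pool compounds that are
#'   truly active; ordinary plants sample at this rate.
#' @param n_plants total plants.
#' @param compounds_per_plant inclusive size range for ordinary plants.
#' @param enriched_plants number of designated enriched plants.
#' @param enriched_active_fraction per-slot probability that an enriched
#'   plant draws an active compound; values <= the background fraction mean
#'   no plant is actually enriched.
#' @param enriched_plant_size compounds per enriched plant.
#' @param isolate_plants how many of the enriched plants draw their actives
#'   exclusively from the isolate scaffold family (the planned isolated
#'   network component); 0 disables the isolate cluster.
#' @param isolate_fraction fraction of actives from the isolate family.
#' @param panel_sizes named drug panel sizes per development stage.
#' @param drug_similarity_target fraction of true actives intended to reach
#'   Tc >= 0.70 against the approved panel (realised by giving
#'   `1 - target` of the actives scaffolds no drug decorates).
#' @param n_reference_actives,n_decoys sizes of the activity-model reference
#'   sets.
#' @param seed integer RNG seed; identical configs and seeds reproduce the
#'   dataset byte for byte.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_compounds = 2000L,
                             background_active_fraction = 0.25,
                             n_plants = 100L,
                             compounds_per_plant = c(8L, 30L),
                             enriched_plants = 10L,
                             enriched_active_fraction = 0.9,
                             enriched_plant_size = 30L,
                             isolate_plants = 3L,
                             isolate_fraction = 0.05,
                             panel_sizes = c(preclinical = 127L,
                                             clinical = 425L,
                                             approved = 219L),
                             drug_similarity_target = 0.75,
                             n_reference_actives = 60L,
                             n_decoys = 400L,
                             seed = 1L) {
  cfg <- list(n_compounds = as.integer(n_compounds),
              background_active_fraction = background_active_fraction,
              n_plants = as.integer(n_plants),
              compounds_per_plant = as.integer(compounds_per_plant),
              enriched_plants = as.integer(enriched_plants),
              enriched_active_fraction = enriched_active_fraction,
              enriched_plant_size = as.integer(enriched_plant_size),
              isolate_plants = as.integer(isolate_plants),
              isolate_fraction = isolate_fraction,
              panel_sizes = panel_sizes,
              drug_similarity_target = drug_similarity_target,
              n_reference_actives = as.integer(n_reference_actives),
              n_decoys = as.integer(n_decoys),
              seed = as.integer(seed))
  frac <- c(cfg$background_active_fraction, cfg$enriched_active_fraction,
            cfg$isolate_fraction, cfg$drug_similarity_target)
  if (any(frac < 0 | frac > 1)) stop("fractions must lie in [0, 1]", call. = FALSE)
  if (cfg$enriched_plants > cfg$n_plants) {
    stop("enriched_plants exceeds n_plants", call. = FALSE)
  }
  if (cfg$isolate_plants > cfg$enriched_plants) {
    stop("isolate_plants exceeds enriched_plants", call. = FALSE)
  }
  if (cfg$drug_similarity_target < cfg$isolate_fraction) {
    stop("drug_similarity_target must be >= isolate_fraction", call. = FALSE)
  }
  assert_stage(names(cfg$panel_sizes))
  structure(cfg, class = "generator_config")
}

#' Generate a plant-annotated synthetic compound library
#'
#' Builds the compound pool (actives as decorated variants of the active
#' scaffold families, inactives from disjoint aromatic scaffolds), then
#' assembles plants by sampling from the pool: ordinary plants draw
#' uniformly (so their active count is exactly hypergeometric under the
#' null), enriched plants draw each compound slot from the active pool with
#' probability `enriched_active_fraction`, and isolate plants take their
#' actives from the isolate scaffold family only. The pool's realised active
#' fraction equals the configured background fraction by construction.
#'
#' @param config a [generator_config()].
#' @return list with `compounds`, `plants`, `annotation` (the shapes
#'   [read_compound_library()] returns), and `truth`: list with
#'   `compound_truth` (`compound_id`, `active`, `scaffold`, `family_group`),
#'   `plant_truth` (`plant_id`, `enriched`, `is_isolate`) and `planned`
#'   (coverage target and component plan).
#' @export
generate_library <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, generate_library_impl(config))
}

generate_library_impl <- function(config) {
  n_act <- round(config$n_compounds * config$background_active_fraction)
  n_iso <- round(n_act * config$isolate_fraction)
  n_unc <- round(n_act * (1 - config$drug_similarity_target))
  n_cov <- n_act - n_iso - n_unc
  if (n_cov < 0L) stop("infeasible active family split", call. = FALSE)
  n_inact <- config$n_compounds - n_act

  smiles <- c(spread_over_cores(ACTIVE_COVERED_CORES, n_cov),
              spread_over_cores(ACTIVE_UNCOVERED_CORES, n_unc),
              spread_over_cores(ACTIVE_ISOLATE_CORE, n_iso),
              spread_over_cores(INACTIVE_CORES, n_inact))
  family_group <- rep(c("covered", "uncovered", "isolate", "inactive"),
                      c(n_cov, n_unc, n_iso, n_inact))
  ids <- sprintf("CMP%05d", seq_along(smiles))
  compounds <- data.frame(compound_id = ids, smiles = unname(smiles),
                          name = names(smiles), row.names = NULL)
  compound_truth <- data.frame(
    compound_id = ids, active = family_group != "inactive",
    scaffold = names(smiles), family_group = family_group, row.names = NULL)

  active_main <- ids[family_group %in% c("covered", "uncovered")]
  active_iso <- ids[family_group == "isolate"]
  inactive_ids <- ids[family_group == "inactive"]
  all_active <- c(active_main, active_iso)

  enriched <- config$enriched_active_fraction > config$background_active_fraction
  n_enr <- if (enriched) config$enriched_plants else 0L
  n_iso_plants <- if (enriched) config$isolate_plants else 0L
  plant_ids <- sprintf("PLT%03d", seq_len(config$n_plants))
  is_enriched_plant <- seq_len(config$n_plants) <= n_enr
  is_isolate_plant <- seq_len(config$n_plants) <= n_iso_plants

  rows <- vector("list", config$n_plants)
  for (i in seq_len(config$n_plants)) {
    if (is_enriched_plant[i]) {
      m <- config$enriched_plant_size
      k <- stats::rbinom(1L, m, config$enriched_active_fraction)
      source_actives <- if (is_isolate_plant[i]) active_iso else active_main
      fill_pool <- if (is_isolate_plant[i]) {
        inactive_ids[names(smiles)[match(inactive_ids, ids)] %in% ISOLATE_SAFE_FILL]
      } else inactive_ids
      k <- min(k, length(source_actives))
      comp <- c(sample(source_actives, k),
                sample(fill_pool, m - k))
    } else {
      m <- sample(seq(config$compounds_per_plant[1L],
                      config$compounds_per_plant[2L]), 1L)
      comp <- sample(ids, m)
    }
    rows[[i]] <- data.frame(compound_id = comp, plant_id = plant_ids[i],
                            row.names = NULL)
  }
  annotation <- do.call(rbind, rows)
  annotation$plant_name <- sprintf("Plant %s", sub("PLT", "", annotation$plant_id))
  annotation$family <- PLANT_FAMILIES[
    (match(annotation$plant_id, plant_ids) - 1L) %% length(PLANT_FAMILIES) + 1L]
  annotation <- annotation[, c("compound_id", "plant_id", "plant_name", "family")]

  plant_truth <- data.frame(
    plant_id = plant_ids,
    enriched = is_enriched_plant,
    is_isolate = is_isolate_plant, row.names = NULL)

  list(compounds = compounds,
       plants = build_plants(annotation),
       annotation = annotation,
       truth = list(
         compound_truth = compound_truth,
         plant_truth = plant_truth,
         planned = list(
           coverage_target = config$drug_similarity_target,
           n_active = length(all_active),
           isolate_compounds = active_iso)))
}

#' Generate stage-labelled drug panels matched to the library
#'
#' Drugs are decorated variants of the covered active scaffolds, so the
#' covered actives reach Tc >= 0.70 against them while the uncovered family
#' stays below threshold - the approved-panel coverage of true actives lands
#' near the configured target. Two approved drugs decorate the isolate
#' scaffold, completing the planned isolated network component.
#'
#' @param config a [generator_config()].
#' @param truth the `truth` element from [generate_library()].
#' @return list with `panels` (data.frame `drug_id`, `smiles`, `name`,
#'   `stage`) and `planned` (`isolate_drug_ids`, `coverage_target`).
#' @export
generate_drug_panels <- function(config, truth) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed + 1L, {
    n_isolate_drugs <- if (length(truth$planned$isolate_compounds)) 2L else 0L
    panels <- lapply(names(config$panel_sizes), function(stage) {
      size <- config$panel_sizes[[stage]]
      if (stage == "approved" && n_isolate_drugs > 0L) {
        smi <- c(spread_over_cores(ACTIVE_COVERED_CORES, size - n_isolate_drugs),
                 spread_over_cores(ACTIVE_ISOLATE_CORE, n_isolate_drugs))
      } else {
        smi <- spread_over_cores(ACTIVE_COVERED_CORES, size)
      }
      data.frame(drug_id = sprintf("%s%03d", stage, seq_along(smi)),
                 smiles = unname(smi), name = names(smi), stage = stage,
                 row.names = NULL)
    })
    panels <- do.call(rbind, panels)
    isolate_drugs <- panels$drug_id[panels$name == names(ACTIVE_ISOLATE_CORE)]
    list(panels = panels,
         planned = list(isolate_drug_ids = isolate_drugs,
                        coverage_target = config$drug_similarity_target))
  })
}

#' Generate reference active and decoy sets for the activity model
#'
#' Reference actives are fresh decorations drawn from every active scaffold
#' family (covered, uncovered and isolate, in proportion to their library
#' share); decoys decorate the inactive scaffolds. Overlap with library
#' compounds is allowed - a screening library typically contains some known
#' actives.
#'
#' @param config a [generator_config()].
#' @return list of data.frames `actives` and `decoys`
#'   (`compound_id`, `smiles`, `name`).
#' @export
generate_reference_sets <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed + 2L, {
    n_ref <- config$n_reference_actives
    n_iso <- max(1L, round(n_ref * config$isolate_fraction))
    n_unc <- max(1L, round(n_ref * (1 - config$drug_similarity_target)))
    n_cov <- n_ref - n_iso - n_unc
    act <- c(spread_over_cores(ACTIVE_COVERED_CORES, n_cov),
             spread_over_cores(ACTIVE_UNCOVERED_CORES, n_unc),
             spread_over_cores(ACTIVE_ISOLATE_CORE, n_iso))
    dec <- spread_over_cores(INACTIVE_CORES, config$n_decoys)
    list(
      actives = data.frame(compound_id = sprintf("REF%04d", seq_along(act)),
                           smiles = unname(act), name = names(act),
                           row.names = NULL),
      decoys = data.frame(compound_id = sprintf("DEC%04d", seq_along(dec)),
                          smiles = unname(dec), name = names(dec),
                          row.names = NULL))
  })
}

#' Write a synthetic dataset to disk in the pipeline's input formats
#'
#' Emits `library.smi`, `annotation.tsv`, one `drugs_<stage>.smi` per panel,
#' `reference_actives.smi`, `decoys.smi` and `truth.json`.
#'
#' @param config a [generator_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named vector of file paths.
#' @export
write_synthetic_dataset <- function(config = generator_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lib <- generate_library(config)
  drugs <- generate_drug_panels(config, lib$truth)
  refs <- generate_reference_sets(config)

  paths <- c(library = file.path(dir, "library.smi"),
             annotation = file.path(dir, "annotation.tsv"),
             reference_actives = file.path(dir, "reference_actives.smi"),
             decoys = file.path(dir, "decoys.smi"),
             truth = file.path(dir, "truth.json"))
  write_smiles_file(lib$compounds, paths["library"])
  utils::write.table(lib$annotation, paths["annotation"], sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  write_smiles_file(refs$actives, paths["reference_actives"])
  write_smiles_file(refs$decoys, paths["decoys"])
  for (stage in unique(drugs$panels$stage)) {
    p <- file.path(dir, sprintf("drugs_%s.smi", stage))
    sub <- drugs$panels[drugs$panels$stage == stage, , drop = FALSE]
    writeLines(paste(sub$smiles, sub$drug_id), p, useBytes = TRUE)
    paths[paste0("drugs_", stage)] <- p
  }
  truth <- lib$truth
  truth$planned$isolate_drug_ids <- drugs$planned$isolate_drug_ids
  jsonlite::write_json(truth, paths["truth"], dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
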