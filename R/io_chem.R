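# Reading and writing external representations: structure files, the
# compound->plant annotation table, result tables and network exports.
# All tables are UTF-8 TSV with a header row.

#' Read a SMILES structure file
#'
#' Expects one record per line, `SMILES<whitespace>id[<whitespace>name...]`.
#' Blank lines and lines starting with `#` are skipped.
#'
#' @param path file path.
#' @return data.frame with columns `compound_id`, `smiles`, `name`.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(compound_id = character(0), smiles = character(0),
                      name = character(0)))
  }
  parts <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(parts) < 2L)) {
    stop("SMILES file ", path, ": every line needs 'SMILES id'", call. = FALSE)
  }
  data.frame(
    compound_id = vapply(parts, `[[`, "", 2L),
    smiles = vapply(parts, `[[`, "", 1L),
    name = vapply(parts, function(p) paste(p[-(1:2)], collapse = " "), ""),
    row.names = NULL)
}

#' Write a SMILES structure file
#'
#' @param compounds data.frame with `compound_id` and `smiles` (optional
#'   `name` is ignored: SMILES files round-trip id and structure).
#' @param path output path.
#' @export
write_smiles_file <- function(compounds, path) {
  writeLines(paste(compounds$smiles, compounds$compound_id), path, useBytes = TRUE)
  invisible(path)
}

# read an SDF (V2000) into (compound_id, smiles, name); id = molecule title
read_sdf_file <- function(path) {
  sdf_text <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                    collapse = "\n")
  blocks <- strsplit(sdf_text, "\\$\\$\\$\\$\n?")[[1]]
  blocks <- blocks[nzchar(trimws(blocks))]
  ids <- vapply(blocks, function(b) trimws(strsplit(b, "\n")[[1]][1]), "",
                USE.NAMES = FALSE)
  smiles <- vapply(seq_along(blocks), function(i) {
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SDF", "SMILES", blocks[[i]])),
      error = function(e) "")
    strsplit(trimws(out), "[[:space:]]+")[[1]][1]
  }, "")
  smiles[is.na(smiles)] <- ""
  data.frame(compound_id = ids, smiles = smiles, name = ids, row.names = NULL)
}

#' Read a plant-annotated compound library
#'
#' Loads structures (`.smi`/`.smiles` or `.sdf`) plus a TSV annotation table
#' with columns `compound_id`, `plant_id`, `plant_name`, `family`, and
#' cross-validates the two. Unparseable structures are dropped; annotation
#' rows pointing at unknown compounds are skipped. Both events are counted in
#' the returned log rather than raised, because real plant-compound extracts
#' are noisy.
#'
#' A compound may belong to several plants; the library total `N` counts each
#' distinct compound once.
#'
#' @param structures_path SMILES or SDF file.
#' @param annotation_path TSV annotation file.
#' @return list with
#'   \describe{
#'     \item{compounds}{data.frame `compound_id`, `smiles`, `name`, sorted by id}
#'     \item{plants}{data.frame `plant_id`, `plant_name`, `family` with a
#'       list-column `compound_ids`, sorted by id}
#'     \item{annotation}{the retained long-format annotation rows}
#'     \item{log}{named counts: `n_structures`, `n_unparseable`,
#'       `n_annotation_rows`, `n_skipped_rows`, `n_compounds`, `n_plants`}
#'   }
#' @export
read_compound_library <- function(structures_path, annotation_path) {
  ext <- tolower(tools::file_ext(structures_path))
  structures <- if (ext %in% c("sdf", "mol")) read_sdf_file(structures_path)
                else read_smiles_file(structures_path)
  if (nrow(structures) == 0L) stop("empty structure file", call. = FALSE)
  if (anyDuplicated(structures$compound_id)) {
    structures <- structures[!duplicated(structures$compound_id), , drop = FALSE]
  }

  anno <- utils::read.delim(annotation_path, sep = "\t", header = TRUE,
                            colClasses = "character", fileEncoding = "UTF-8")
  required <- c("compound_id", "plant_id", "plant_name", "family")
  missing_col <- setdiff(required, names(anno))
  if (length(missing_col)) {
    stop("annotation table lacks required column(s): ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  }

  ok <- validate_smiles(structures$smiles)
  n_unparseable <- sum(!ok)
  compounds <- structures[ok, , drop = FALSE]
  if (nrow(compounds) == 0L) stop("no parseable structures in library", call. = FALSE)
  compounds <- compounds[order(compounds$compound_id), , drop = FALSE]
  rownames(compounds) <- NULL

  known <- anno$compound_id %in% compounds$compound_id
  n_skipped <- sum(!known)
  anno <- anno[known, , drop = FALSE]

  plants <- build_plants(anno)
  list(
    compounds = compounds,
    plants = plants,
    annotation = anno,
    log = c(n_structures = nrow(structures), n_unparseable = n_unparseable,
            n_annotation_rows = length(known), n_skipped_rows = n_skipped,
            n_compounds = nrow(compounds), n_plants = nrow(plants)))
}

# collapse long annotation into one row per plant with a compound id set
build_plants <- function(anno) {
  if (nrow(anno) == 0L) {
    out <- data.frame(plant_id = character(0), plant_name = character(0),
                      family = character(0))
    out$compound_ids <- list()
    return(out)
  }
  split_ids <- split(anno$compound_id, anno$plant_id)
  meta <- anno[!duplicated(anno$plant_id),
               c("plant_id", "plant_name", "family"), drop = FALSE]
  meta <- meta[order(meta$plant_id), , drop = FALSE]
  meta$compound_ids <- lapply(split_ids[meta$plant_id],
                              function(x) sort(unique(x)))
  rownames(meta) <- NULL
  meta
}

#' Read staged drug panels
#'
#' @param paths named character vector or list mapping stage
#'   (`preclinical`/`clinical`/`approved`) to a SMILES file.
#' @return data.frame with columns `drug_id`, `smiles`, `name`, `stage`;
#'   drug ids are unique within each stage.
#' @export
read_drug_panels <- function(paths) {
  assert_stage(names(paths))
  out <- do.call(rbind, lapply(names(paths), function(stage) {
    panel <- read_smiles_file(paths[[stage]])
    names(panel)[names(panel) == "compound_id"] <- "drug_id"
    panel <- panel[!duplicated(panel$drug_id), , drop = FALSE]
    panel$stage <- stage
    panel
  }))
  rownames(out) <- NULL
  out
}

#' Write a result table as TSV
#'
#' Numeric columns are written with 15 significant digits so that write/read
#' round-trips reproduce values to at least 12 significant digits. List
#' columns (e.g. per-plant compound id sets) are serialised as
#' comma-separated strings.
#'
#' @param table data.frame.
#' @param path output path.
#' @export
write_result_table <- function(table, path) {
  out <- table
  for (nm in names(out)) {
    if (is.list(out[[nm]])) {
      out[[nm]] <- vapply(out[[nm]], paste, "", collapse = ",")
    } else if (is.double(out[[nm]])) {
      out[[nm]] <- formatC(out[[nm]], digits = 15, format = "g")
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#'
#' @param path TSV path.
#' @return data.frame with numeric columns restored.
#' @export
read_result_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, fileEncoding = "UTF-8",
                    stringsAsFactors = FALSE)
}

#' Export a plant-drug network for Cytoscape
#'
#' Writes `<prefix>.sif` (one `plant similar_to drug` line per edge, sorted
#' lexicographically for bit-stable output) and `<prefix>.graphml` with node
#' attributes `node_type` (plant/drug), `stage`, `family` and `degree`.
#' An empty network still produces both files (empty SIF, GraphML holding any
#' isolated nodes) with a warning.
#'
#' @param network a `plant_drug_network` from [build_network()].
#' @param out_prefix path prefix for the two files.
#' @return invisibly, the two file paths.
#' @export
write_network <- function(network, out_prefix) {
  stopifnot(inherits(network, "plant_drug_network"))
  sif_path <- paste0(out_prefix, ".sif")
  graphml_path <- paste0(out_prefix, ".graphml")
  edges <- network$edges
  if (nrow(edges) == 0L) {
    warning("network has no edges; writing empty SIF", call. = FALSE)
    writeLines(character(0), sif_path)
  } else {
    lines <- paste(edges$plant_id, "similar_to", edges$drug_id, sep = "\t")
    writeLines(sort(lines), sif_path, useBytes = TRUE)
  }
  igraph::write_graph(network$graph, graphml_path, format = "graphml")
  invisible(c(sif = sif_path, graphml = graphml_path))
}
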