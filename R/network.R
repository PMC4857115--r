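# Bipartite plant-drug network: significant plants connect to drugs their
# compounds resemble (Tc >= threshold). igraph holds the graph; exports go
# through write_network().

#' Build the bipartite plant-drug similarity network
#'
#' Connects a significant plant to a drug when at least one of the plant's
#' compounds has Tanimoto similarity >= `threshold` to that drug. By default
#' every annotated compound of the plant can contribute an edge; set
#' `actives_only = TRUE` to restrict edge evidence to predicted actives.
#' A drug listed in several development stages is labelled with its most
#' advanced stage (approved > clinical > preclinical).
#'
#' @param enrichment result of [run_acea()]; only rows with
#'   `significant == TRUE` enter the network.
#' @param plants plant table with `plant_id`, `family`, `compound_ids`.
#' @param compound_fps fingerprint matrix of library compounds (row names =
#'   compound ids).
#' @param panels drug table (`drug_id`, `smiles`, `stage`).
#' @param calls activity calls (needed when `actives_only = TRUE`).
#' @param threshold Tanimoto cutoff, inclusive.
#' @param actives_only restrict evidence compounds to predicted actives.
#' @return a `plant_drug_network`: list with `plant_nodes`, `drug_nodes`
#'   (drugs with >= 1 edge), `edges` (plant_id, drug_id, n_evidence,
#'   max_tc), `evidence` (compound-level pairs) and `graph` (igraph object
#'   with node attributes `node_type`, `stage`, `family`, `degree`).
#' @export
build_network <- function(enrichment, plants, compound_fps, panels,
                          calls = NULL, threshold = 0.70,
                          actives_only = FALSE) {
  sig_ids <- enrichment$plant_id[enrichment$significant]
  if (length(sig_ids) == 0L) {
    warning("no significant plants; network is empty", call. = FALSE)
  }
  plants <- plants[plants$plant_id %in% sig_ids, , drop = FALSE]
  plants <- plants[order(plants$plant_id), , drop = FALSE]

  panels <- panels[order(panels$drug_id), , drop = FALSE]
  stage_rank <- stats::setNames(seq_along(DRUG_STAGES), DRUG_STAGES)
  best_stage <- tapply(panels$stage, panels$drug_id,
                       function(s) s[which.max(stage_rank[s])])
  drug_meta <- data.frame(drug_id = names(best_stage),
                          stage = as.character(best_stage), row.names = NULL)
  uniq <- panels[!duplicated(panels$drug_id), , drop = FALSE]
  drug_fps <- maccs_fingerprint(uniq$smiles, uniq$drug_id)

  allowed <- rownames(compound_fps)
  if (actives_only) {
    stopifnot(!is.null(calls))
    allowed <- intersect(allowed, calls$compound_id[calls$is_active])
  }

  evidence <- vector("list", nrow(plants))
  for (i in seq_len(nrow(plants))) {
    ids <- intersect(sort(plants$compound_ids[[i]]), allowed)
    if (length(ids) == 0L) next
    tc <- tanimoto_matrix(compound_fps[ids, , drop = FALSE], drug_fps)
    idx <- which(tc >= threshold, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    evidence[[i]] <- data.frame(
      plant_id = plants$plant_id[i],
      drug_id = colnames(tc)[idx[, 2L]],
      compound_id = rownames(tc)[idx[, 1L]],
      tc = tc[idx], row.names = NULL)
  }
  evidence <- do.call(rbind, evidence)
  if (is.null(evidence)) {
    evidence <- data.frame(plant_id = character(0), drug_id = character(0),
                           compound_id = character(0), tc = numeric(0))
  }
  evidence <- evidence[order(evidence$plant_id, evidence$drug_id,
                             evidence$compound_id), , drop = FALSE]
  rownames(evidence) <- NULL

  edges <- if (nrow(evidence)) {
    agg <- stats::aggregate(tc ~ plant_id + drug_id, data = evidence,
                            FUN = max)
    cnt <- stats::aggregate(tc ~ plant_id + drug_id, data = evidence,
                            FUN = length)
    agg$n_evidence <- cnt$tc[match(paste(agg$plant_id, agg$drug_id),
                                   paste(cnt$plant_id, cnt$drug_id))]
    names(agg)[names(agg) == "tc"] <- "max_tc"
    agg <- agg[order(agg$plant_id, agg$drug_id),
               c("plant_id", "drug_id", "n_evidence", "max_tc")]
    rownames(agg) <- NULL
    agg
  } else {
    data.frame(plant_id = character(0), drug_id = character(0),
               n_evidence = integer(0), max_tc = numeric(0))
  }

  plant_nodes <- data.frame(plant_id = plants$plant_id,
                            plant_name = plants$plant_name,
                            family = plants$family, row.names = NULL)
  drug_nodes <- drug_meta[drug_meta$drug_id %in% edges$drug_id, , drop = FALSE]
  rownames(drug_nodes) <- NULL

  vertices <- data.frame(
    name = c(plant_nodes$plant_id, drug_nodes$drug_id),
    node_type = c(rep("plant", nrow(plant_nodes)),
                  rep("drug", nrow(drug_nodes))),
    stage = c(rep(NA_character_, nrow(plant_nodes)), drug_nodes$stage),
    family = c(plant_nodes$family, rep(NA_character_, nrow(drug_nodes))))
  g <- igraph::graph_from_data_frame(
    edges[, c("plant_id", "drug_id"), drop = FALSE],
    directed = FALSE, vertices = vertices)
  igraph::V(g)$degree <- igraph::degree(g)

  structure(list(plant_nodes = plant_nodes, drug_nodes = drug_nodes,
                 edges = edges, evidence = evidence, graph = g,
                 threshold = threshold, actives_only = actives_only),
            class = "plant_drug_network")
}

#' @export
print.plant_drug_network <- function(x, ...) {
  comps <- connected_components(x)
  cat("plant-drug similarity network (Tc >= ", x$threshold, ")\n",
      "  plants: ", nrow(x$plant_nodes), "  drugs: ", nrow(x$drug_nodes),
      "  edges: ", nrow(x$edges), "  components: ", length(comps), "\n",
      sep = "")
  invisible(x)
}

#' Connected components of a plant-drug network
#'
#' Standard undirected components over the non-isolated plant and drug
#' nodes, ordered by decreasing size and then by the lexicographically
#' smallest member.
#'
#' @param network a `plant_drug_network`.
#' @return list of character vectors (sorted node names), possibly empty.
#' @export
connected_components <- function(network) {
  stopifnot(inherits(network, "plant_drug_network"))
  g <- igraph::delete_vertices(network$graph,
                               igraph::V(network$graph)[igraph::degree(network$graph) == 0])
  if (igraph::vcount(g) == 0L) return(list())
  comp <- igraph::components(g)
  members <- unname(split(igraph::V(g)$name, comp$membership))
  members <- lapply(members, sort)
  members[order(-vapply(members, length, integer(1)),
                vapply(members, `[[`, "", 1L))]
}
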