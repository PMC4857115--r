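# Drug-similarity profiling: each predicted-active compound is compared to a
# stage-labelled anti-cancer drug panel; compounds whose best MACCS Tanimoto
# reaches the threshold (default 0.70) count as drug-similar.

#' Best panel match for each query fingerprint
#'
#' @param fps query fingerprint matrix (row names = compound ids).
#' @param panel_fps drug fingerprint matrix (row names = drug ids).
#' @return data.frame `compound_id`, `best_drug_id`, `best_tc`; ties on Tc
#'   resolve to the lexicographically smallest drug id.
#' @export
max_similarity <- function(fps, panel_fps) {
  if (nrow(panel_fps) == 0L) stop("empty drug panel", call. = FALSE)
  ord <- order(rownames(panel_fps))
  panel_fps <- panel_fps[ord, , drop = FALSE]
  tc <- tanimoto_matrix(fps, panel_fps)
  best <- max.col(tc, ties.method = "first")  # panel sorted: first = smallest id
  data.frame(
    compound_id = rownames(fps),
    best_drug_id = rownames(panel_fps)[best],
    best_tc = tc[cbind(seq_len(nrow(tc)), best)],
    row.names = NULL)
}

#' Per-stage drug-similarity report
#'
#' Counts the predicted actives whose best Tanimoto coefficient against the
#' stage's drug panel reaches the threshold (inclusive: "0.70 or greater"),
#' and reports the integer percentage (halves away from zero).
#'
#' @param active_fps fingerprint matrix of predicted actives.
#' @param panel_fps fingerprint matrix of one stage's drugs.
#' @param stage stage label for the report.
#' @param threshold Tanimoto similarity cutoff, inclusive.
#' @return list with `summary` (data.frame `stage`, `n_actives`, `n_similar`,
#'   `percent_similar`) and `pairs` (all above-threshold
#'   compound/drug/Tc triples, sorted).
#' @export
stage_report <- function(active_fps, panel_fps, stage, threshold = 0.70) {
  assert_stage(stage)
  stopifnot(threshold > 0, threshold <= 1)
  tc <- tanimoto_matrix(active_fps, panel_fps)
  hit <- tc >= threshold
  n_similar <- sum(rowSums(hit) > 0L)
  idx <- which(hit, arr.ind = TRUE)
  pairs <- data.frame(
    compound_id = rownames(tc)[idx[, 1L]],
    drug_id = colnames(tc)[idx[, 2L]],
    tc = tc[idx],
    row.names = NULL)
  pairs <- pairs[order(pairs$compound_id, pairs$drug_id), , drop = FALSE]
  rownames(pairs) <- NULL
  list(
    summary = data.frame(
      stage = stage, n_actives = nrow(active_fps), n_similar = n_similar,
      percent_similar = percent_of(n_similar, max(1L, nrow(active_fps)))),
    pairs = pairs)
}

#' Drug-similarity profile across all stages
#'
#' @param active_fps fingerprint matrix of predicted actives.
#' @param panels drug table (`drug_id`, `smiles`, `stage`) from
#'   [read_drug_panels()] or [generate_drug_panels()].
#' @param threshold Tanimoto cutoff, inclusive.
#' @return list with `summary` (one row per stage) and `pairs` (pooled
#'   above-threshold pairs with a `stage` column).
#' @export
similarity_profile <- function(active_fps, panels, threshold = 0.70) {
  assert_stage(panels$stage)
  stages <- intersect(DRUG_STAGES, unique(panels$stage))
  reports <- lapply(stages, function(st) {
    sub <- panels[panels$stage == st, , drop = FALSE]
    pfps <- maccs_fingerprint(sub$smiles, sub$drug_id)
    rep <- stage_report(active_fps, pfps, st, threshold)
    if (nrow(rep$pairs)) rep$pairs$stage <- st
    rep
  })
  pairs <- do.call(rbind, lapply(reports, function(r)
    if (nrow(r$pairs)) r$pairs else NULL))
  list(
    summary = do.call(rbind, lapply(reports, `[[`, "summary")),
    pairs = if (is.null(pairs))
      data.frame(compound_id = character(0), drug_id = character(0),
                 tc = numeric(0), stage = character(0)) else pairs)
}
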