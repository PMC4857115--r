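# Ligand-based activity calling. A reference set of known actives and a
# decoy set define a frequency-weighted fingerprint model; each query gets a
# hybrid nearest-neighbour similarity score and an empirical P-value against
# the decoy score distribution. A compound is called active when P < alpha.

#' Fit a frequency-weighted fingerprint activity model
#'
#' Each MACCS bit is weighted by the log-ratio of its relative frequency in
#' the reference actives versus the decoys,
#' `w_b = ln((f_act(b) + eps) / (f_dec(b) + eps))`, clipped to
#' `[-w_max, w_max]`. The decoys are then scored under the fitted model to
#' form the null score distribution used for empirical P-values.
#'
#' @param active_fps 0/1 fingerprint matrix of reference actives (>= 10 rows).
#' @param decoy_fps 0/1 fingerprint matrix of decoys (>= `min_decoys` rows).
#' @param eps frequency smoothing constant.
#' @param w_max clip bound on the per-bit log-ratio weights.
#' @param min_decoys floor on the decoy count; bounds the smallest reportable
#'   empirical P at `1 / (min_decoys + 1)`.
#' @return an `activity_model`: list with `active_fps`, `bit_weights`,
#'   `null_scores` (sorted ascending) and the fit constants.
#' @export
fit_activity_model <- function(active_fps, decoy_fps, eps = 0.01, w_max = 5,
                               min_decoys = 200L) {
  if (nrow(active_fps) < 10L) {
    stop("need at least 10 reference actives, got ", nrow(active_fps), call. = FALSE)
  }
  if (nrow(decoy_fps) < min_decoys) {
    stop("need at least ", min_decoys, " decoys, got ", nrow(decoy_fps), call. = FALSE)
  }
  if (ncol(active_fps) != ncol(decoy_fps)) {
    stop("fingerprint length mismatch between actives and decoys", call. = FALSE)
  }
  f_act <- colMeans(active_fps)
  f_dec <- colMeans(decoy_fps)
  w <- log((f_act + eps) / (f_dec + eps))
  w <- pmin(pmax(w, -w_max), w_max)
  model <- structure(
    list(active_fps = active_fps, bit_weights = w, null_scores = NULL,
         eps = eps, w_max = w_max),
    class = "activity_model")
  model$null_scores <- sort(score_compound(model, decoy_fps))
  model
}

# weighted Tanimoto between query rows Q and reference rows A under positive
# bit weights w: sum_b w_b [q & a] / sum_b w_b [q | a]
weighted_tanimoto_matrix <- function(Q, A, w) {
  Qw <- sweep(Q, 2L, w, "*")
  inter <- Qw %*% t(A)
  uni <- outer(rowSums(Qw), as.vector(A %*% w), "+") - inter
  wtc <- inter / uni
  wtc[uni == 0] <- 0
  wtc
}

#' Score compounds under an activity model
#'
#' The hybrid score combines nearest-neighbour and neighbourhood evidence:
#' `0.5 * max_a wTc(q, a) + 0.5 * mean(top-5 wTc(q, a))`, where wTc is the
#' Tanimoto coefficient with each bit weighted by `exp(bit_weights)` (so
#' active-enriched bits count more than decoy-enriched bits). With fewer than
#' five reference actives the top-5 mean runs over all of them.
#'
#' @param model fitted `activity_model`.
#' @param fps a single fingerprint vector or a 0/1 matrix (rows = queries).
#' @return numeric score vector, one per query row.
#' @export
score_compound <- function(model, fps) {
  stopifnot(inherits(model, "activity_model"))
  if (is.null(dim(fps))) fps <- matrix(fps, nrow = 1L)
  if (nrow(model$active_fps) == 0L) stop("model has no reference actives", call. = FALSE)
  w_pos <- exp(model$bit_weights)
  wtc <- weighted_tanimoto_matrix(fps, model$active_fps, w_pos)
  k <- min(5L, ncol(wtc))
  apply(wtc, 1L, function(row) {
    top <- sort(row, decreasing = TRUE)[seq_len(k)]
    0.5 * top[1L] + 0.5 * mean(top)
  })
}

#' Empirical P-value of a score against the model's null distribution
#'
#' Add-one upper-tail estimator `p = (1 + #{null >= score}) / (1 + n_null)`;
#' ties count toward the tail (conservative) and P is never exactly zero.
#'
#' @param model fitted `activity_model` with populated `null_scores`.
#' @param score numeric vector of scores.
#' @return P-values in (0, 1\].
#' @export
empirical_pvalue <- function(model, score) {
  stopifnot(inherits(model, "activity_model"), length(model$null_scores) > 0L)
  nulls <- model$null_scores  # sorted ascending
  n <- length(nulls)
  # findInterval(x, nulls, left.open = TRUE) = #{null < x}, hence ties >= x stay in the tail
  n_ge <- n - findInterval(score, nulls, left.open = TRUE)
  (1 + n_ge) / (1 + n)
}

#' Predict activity across a compound library
#'
#' Fingerprints every parseable compound, scores it, converts the score to an
#' empirical P-value and calls it active when `p < alpha`. Unparseable
#' structures are skipped and counted.
#'
#' @param model fitted `activity_model`.
#' @param compounds data.frame with `compound_id` and `smiles`, or a
#'   pre-computed fingerprint matrix with compound ids as row names.
#' @param alpha activity call threshold on the empirical P-value.
#' @return data.frame `compound_id`, `score`, `p_value`, `is_active`, with
#'   attribute `log` = c(n_scored, n_skipped, n_active).
#' @export
predict_library <- function(model, compounds, alpha = 0.05) {
  stopifnot(alpha >= 0, alpha <= 1)
  n_skipped <- 0L
  if (is.matrix(compounds)) {
    fps <- compounds
    ids <- rownames(fps)
  } else {
    ok <- validate_smiles(compounds$smiles)
    n_skipped <- sum(!ok)
    compounds <- compounds[ok, , drop = FALSE]
    fps <- maccs_fingerprint(compounds$smiles, compounds$compound_id)
    ids <- compounds$compound_id
  }
  score <- score_compound(model, fps)
  p <- empirical_pvalue(model, score)
  calls <- data.frame(compound_id = ids, score = score, p_value = p,
                      is_active = p < alpha, row.names = NULL)
  attr(calls, "log") <- c(n_scored = nrow(calls), n_skipped = n_skipped,
                          n_active = sum(calls$is_active))
  calls
}
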