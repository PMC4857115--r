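# Small numeric helpers shared across modules.

#' Integer percentage, half rounded away from zero
#'
#' Converts a (count, total) pair into the integer percentage convention used
#' in all reports: 100 * count / total rounded to the nearest integer with
#' halves going away from zero (base `round()` rounds halves to even, which
#' does not reproduce standard report percentages such as 74.88% -> 75%).
#'
#' @param count,total non-negative numbers; `total` > 0.
#' @return integer percentage in \[0, 100\].
#' @examples
#' percent_of(3952, 5278)  # 75
#' percent_of(5278, 21334) # 25
#' @export
percent_of <- function(count, total) {
  stopifnot(total > 0, count >= 0)
  x <- 100 * count / total
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Rank-based ROC AUC
#'
#' Area under the ROC curve computed from the Wilcoxon rank-sum identity:
#' the probability that a random positive outscores a random negative, with
#' ties counted half.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels logical (or 0/1) truth labels.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), any(labels), any(!labels))
  r <- rank(scores)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# shared stage vocabulary, least to most advanced
DRUG_STAGES <- c("preclinical", "clinical", "approved")

assert_stage <- function(stage) {
  bad <- setdiff(unique(stage), DRUG_STAGES)
  if (length(bad)) {
    stop("unknown drug development stage: ", paste(bad, collapse = ", "),
         "; expected one of ", paste(DRUG_STAGES, collapse = "/"), call. = FALSE)
  }
  invisible(stage)
}
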