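# Fragment-frequency profiling: fraction of molecules in a set containing
# each dictionary fragment at least once, and the comparison table between
# two sets (typically predicted actives vs cancer drugs).

#' Built-in fragment dictionary
#'
#' Sixteen common ring and functional-group fragments, each as a SMARTS
#' substructure pattern. Aromatic patterns use aromatic atoms, so e.g.
#' cyclohexane does not match the benzene entry, while embedded rings do
#' (toluene contains benzene). User dictionaries can extend or replace this
#' set via [read_fragment_dictionary()].
#'
#' @return data.frame with columns `fragment_name`, `pattern`.
#' @export
default_fragment_dictionary <- function() {
  d <- data.frame(fragment_name = c(
    "benzene", "pyridine", "pyrimidine", "imidazole", "pyrazole", "pyrrole",
    "pyrrolidine", "piperazine", "morpholine", "trifluoroethane",
    "cyclohexane", "cyclohexene", "cyclopentane", "tetrahydropyran",
    "tetrahydrofuran", "methyl_acetate"),
    pattern = c(
      "c1ccccc1", "c1ccncc1", "c1cncnc1", "c1cncn1", "c1ccnn1", "c1ccnc1",
      "C1CCNC1", "C1CNCCN1", "C1COCCN1", "[#6][CX4](F)(F)F",
      "C1CCCCC1", "C1=CCCCC1", "C1CCCC1", "C1CCOCC1",
      "C1CCOC1", "CC(=O)OC"))
  validate_fragment_dictionary(d)
  d
}

# a dictionary is usable only if every pattern compiles as a SMARTS query
validate_fragment_dictionary <- function(dict) {
  if (!all(c("fragment_name", "pattern") %in% names(dict)) || nrow(dict) == 0L) {
    stop("fragment dictionary needs non-empty columns fragment_name, pattern",
         call. = FALSE)
  }
  if (anyDuplicated(dict$fragment_name)) {
    stop("duplicate fragment names in dictionary", call. = FALSE)
  }
  probe <- obmol_batch("CCO")
  for (i in seq_len(nrow(dict))) {
    ok <- tryCatch({
      suppressWarnings(ChemmineOB::smartsSearch_OB(probe, dict$pattern[i]))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      stop("fragment '", dict$fragment_name[i], "': unparseable pattern '",
           dict$pattern[i], "'", call. = FALSE)
    }
  }
  invisible(dict)
}

#' Read a fragment dictionary from TSV
#'
#' @param path TSV with columns `fragment_name`, `pattern`; every pattern is
#'   validated as a SMARTS query at load time.
#' @return data.frame dictionary.
#' @export
read_fragment_dictionary <- function(path) {
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         colClasses = "character", fileEncoding = "UTF-8")
  validate_fragment_dictionary(d)
  d
}

#' Does a molecule contain a fragment?
#'
#' @param smiles character vector of parseable SMILES.
#' @param pattern one SMARTS pattern.
#' @return logical vector: TRUE where the molecule has at least one embedding
#'   of the pattern.
#' @export
match_fragment <- function(smiles, pattern) {
  mols <- obmol_batch(smiles)
  as.numeric(suppressWarnings(ChemmineOB::smartsSearch_OB(mols, pattern))) > 0
}

#' Fragment-frequency comparison between two molecule sets
#'
#' For each dictionary fragment, counts the molecules in each set containing
#' the fragment at least once (molecules, not occurrences) and the
#' corresponding fraction of the set. Fragments absent from both sets keep
#' their zero row, mirroring reports of fragments present in drugs but
#' absent from a screening library.
#'
#' @param smiles_a,smiles_b SMILES vectors for the two sets (non-empty).
#' @param dict fragment dictionary (default [default_fragment_dictionary()]).
#' @return data.frame `fragment_name`, `count_a`, `freq_a`, `count_b`,
#'   `freq_b`, sorted by `freq_b` descending then fragment name.
#' @export
frequency_table <- function(smiles_a, smiles_b,
                            dict = default_fragment_dictionary()) {
  validate_fragment_dictionary(dict)
  if (length(smiles_a) == 0L || length(smiles_b) == 0L) {
    stop("both molecule sets must be non-empty", call. = FALSE)
  }
  mols_a <- obmol_batch(smiles_a)
  mols_b <- obmol_batch(smiles_b)
  count_in <- function(mols, pattern) {
    sum(as.numeric(suppressWarnings(
      ChemmineOB::smartsSearch_OB(mols, pattern))) > 0)
  }
  count_a <- vapply(dict$pattern, count_in, numeric(1), mols = mols_a)
  count_b <- vapply(dict$pattern, count_in, numeric(1), mols = mols_b)
  out <- data.frame(
    fragment_name = dict$fragment_name,
    count_a = as.integer(count_a), freq_a = count_a / length(smiles_a),
    count_b = as.integer(count_b), freq_b = count_b / length(smiles_b),
    row.names = NULL)
  out <- out[order(-out$freq_b, out$fragment_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
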