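# Structure-derived quantities: MACCS substructure-key fingerprints,
# Tanimoto similarity, molecular properties and Lipinski evaluation.
# All chemistry is delegated to Open Babel through ChemmineOB.

#' Number of public MACCS substructure keys
#'
#' The fingerprint used throughout the package is the fixed dictionary of 166
#' public MACCS keys; every similarity threshold in the pipeline (notably
#' Tc >= 0.70) is calibrated against this key set.
#' @export
MACCS_NBITS <- 166L

# Parse a batch of SMILES into Open Babel molecule references.
# Open Babel aborts the whole batch on one bad record, so failures are
# localised by recursive bisection; returns a logical validity vector.
validate_smiles <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(logical(0))
  batch_ok <- function(s) {
    !inherits(tryCatch(
      suppressWarnings(ChemmineOB::forEachMol(
        "SMILES", paste(paste(s, seq_along(s)), collapse = "\n"), identity)),
      error = function(e) e), "error")
  }
  rec <- function(idx) {
    if (batch_ok(smiles[idx])) return(rep(TRUE, length(idx)))
    if (length(idx) == 1L) return(FALSE)
    half <- length(idx) %/% 2L
    c(rec(idx[seq_len(half)]), rec(idx[-seq_len(half)]))
  }
  # blank/NA can silently collapse records in the joined input; reject upfront
  ok <- !is.na(smiles) & nzchar(trimws(smiles)) & !grepl("[[:space:]]", trimws(smiles))
  if (any(ok)) ok[ok] <- rec(which(ok))
  ok
}

# One parsed obmol batch for a vector of known-valid SMILES.
obmol_batch <- function(smiles, ids = seq_along(smiles)) {
  stopifnot(length(smiles) == length(ids))
  mols <- tryCatch(
    suppressWarnings(ChemmineOB::forEachMol(
      "SMILES", paste(paste(smiles, ids), collapse = "\n"), identity)),
    error = function(e) NULL)
  if (is.null(mols) || length(mols) != length(smiles)) {
    stop("unparseable structure in input; validate with validate_smiles() first",
         call. = FALSE)
  }
  mols
}

#' Compute MACCS fingerprints for a set of structures
#'
#' Generates the 166-bit public MACCS key fingerprint for each SMILES string.
#' Fingerprints are canonicalisation-invariant: two SMILES spellings of the
#' same molecule yield identical bit vectors.
#'
#' @param smiles character vector of SMILES strings, all parseable (use
#'   [validate_smiles()] to pre-filter noisy input).
#' @param ids optional row names for the result.
#' @return integer 0/1 matrix with `length(smiles)` rows and
#'   [MACCS_NBITS] columns.
#' @examples
#' fp <- maccs_fingerprint(c("c1ccccc1", "CCO"))
#' rowSums(fp)
#' @export
maccs_fingerprint <- function(smiles, ids = NULL) {
  if (length(smiles) == 0L) {
    return(matrix(0L, 0L, MACCS_NBITS))
  }
  mols <- obmol_batch(smiles)
  fp <- ChemmineOB::fingerprint_OB(mols, "MACCS")
  if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1L)
  fp <- fp[, seq_len(MACCS_NBITS), drop = FALSE]
  storage.mode(fp) <- "integer"
  rownames(fp) <- if (!is.null(ids)) ids else NULL
  fp
}

#' Tanimoto coefficient between two fingerprints
#'
#' Tc = |a AND b| / |a OR b| over fingerprint bit sets. Defined as 0 when
#' both fingerprints are empty (no shared evidence is never similarity).
#'
#' @param a,b 0/1 vectors of equal length.
#' @return similarity in \[0, 1\].
#' @examples
#' a <- b <- integer(8); a[1:3] <- 1L; b[2:4] <- 1L
#' tanimoto(a, b)  # 2 common / 4 union = 0.5
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    stop("fingerprint length mismatch: ", length(a), " vs ", length(b), call. = FALSE)
  }
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0L) return(0)
  sum(a & b) / u
}

#' All-pairs Tanimoto matrix between two fingerprint sets
#'
#' @param A,B 0/1 matrices with the same number of columns (rows are
#'   molecules). Row names, when present, label the result.
#' @return numeric matrix of `nrow(A)` x `nrow(B)` Tanimoto coefficients;
#'   pairs of all-zero fingerprints get 0.
#' @export
tanimoto_matrix <- function(A, B) {
  if (ncol(A) != ncol(B)) stop("fingerprint length mismatch", call. = FALSE)
  inter <- A %*% t(B)
  uni <- outer(rowSums(A), rowSums(B), "+") - inter
  tc <- inter / uni
  tc[uni == 0] <- 0
  dimnames(tc) <- list(rownames(A), rownames(B))
  tc
}

# strict rotatable-bond SMARTS: acyclic single bond between two non-terminal
# heavy atoms, triple-bond termini and amide C-N excluded
ROTATABLE_SMARTS <- paste0(
  "[!$(*#*)&!D1&!$([CX3](=O)[NX3])&!$([NX3][CX3]=O)]",
  "-&!@",
  "[!$(*#*)&!D1&!$([CX3](=O)[NX3])&!$([NX3][CX3]=O)]")

# aromatic SSSR proxy: unique aromatic 5/6/7-membered cycles
AROMATIC_RING_SMARTS <- c("a1aaaa1", "a1aaaaa1", "a1aaaaaa1")

# cyclomatic ring count (== SSSR size) from a V2000 conversion
ring_counts_sdf <- function(smiles) {
  sdf <- ChemmineOB::convertFormat(
    "SMILES", "SDF", paste(paste(smiles, seq_along(smiles)), collapse = "\n"))
  blocks <- strsplit(sdf, "\\$\\$\\$\\$\n?")[[1]]
  blocks <- blocks[nzchar(trimws(blocks))]
  if (length(blocks) != length(smiles)) {
    stop("structure conversion lost records (", length(blocks), "/",
         length(smiles), ")", call. = FALSE)
  }
  vapply(seq_along(blocks), function(i) {
    counts <- strsplit(blocks[i], "\n")[[1]][4]
    atoms <- as.integer(substr(counts, 1, 3))
    bonds <- as.integer(substr(counts, 4, 6))
    nfrag <- 1L + lengths(regmatches(smiles[i], gregexpr(".", smiles[i], fixed = TRUE)))
    bonds - atoms + nfrag
  }, integer(1))
}

#' Molecular property profile
#'
#' Computes, per molecule: ALogP (Open Babel's atom-contribution logP),
#' molecular weight (Da), hydrogen-bond donors (OH + NH), hydrogen-bond
#' acceptors (N + O count), rotatable bonds (strict definition: acyclic
#' single bonds between non-terminal heavy atoms, amides excluded), total
#' rings (smallest set of smallest rings) and aromatic rings (aromatic 5- to
#' 7-membered cycles).
#'
#' @param smiles character vector of parseable SMILES.
#' @param ids optional compound identifiers (default: the SMILES strings).
#' @return data.frame with columns `compound_id`, `smiles`, `alogp`,
#'   `mol_weight`, `hbd`, `hba`, `rotatable_bonds`, `n_rings`,
#'   `n_aromatic_rings`.
#' @examples
#' compute_properties(c("C", "C1CCCCC1", "c1ccccc1"))
#' @export
compute_properties <- function(smiles, ids = smiles) {
  if (length(smiles) == 0L) {
    return(data.frame(compound_id = character(0), smiles = character(0),
                      alogp = numeric(0), mol_weight = numeric(0),
                      hbd = integer(0), hba = integer(0),
                      rotatable_bonds = integer(0), n_rings = integer(0),
                      n_aromatic_rings = integer(0)))
  }
  mols <- obmol_batch(smiles)
  pr <- ChemmineOB::prop_OB(mols)
  rot <- as.integer(ChemmineOB::smartsSearch_OB(mols, ROTATABLE_SMARTS))
  arom <- Reduce(`+`, lapply(
    AROMATIC_RING_SMARTS,
    function(p) as.numeric(ChemmineOB::smartsSearch_OB(mols, p))))
  data.frame(
    compound_id = ids,
    smiles = smiles,
    alogp = pr$logP,
    mol_weight = pr$MW,
    hbd = as.integer(pr$HBD),
    hba = as.integer(pr$HBA2),
    rotatable_bonds = rot,
    n_rings = ring_counts_sdf(smiles),
    n_aromatic_rings = as.integer(arom),
    row.names = NULL)
}

#' Lipinski rule-of-five evaluation
#'
#' Applies the four rule-of-five criteria with strict inequalities:
#' HBD < 5, HBA < 10, molecular weight < 500 Da, ALogP < 5. A molecule
#' sitting exactly on a boundary (e.g. MW = 500) fails that criterion.
#'
#' @param properties data.frame from [compute_properties()] (or any frame
#'   with `hbd`, `hba`, `mol_weight`, `alogp`).
#' @return the input with logical columns `lip_hbd`, `lip_hba`, `lip_mw`,
#'   `lip_alogp` and `lipinski_pass` (all four) appended.
#' @export
lipinski_flags <- function(properties) {
  required <- c("hbd", "hba", "mol_weight", "alogp")
  missing <- setdiff(required, names(properties))
  if (length(missing)) {
    stop("property table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  properties$lip_hbd <- properties$hbd < 5
  properties$lip_hba <- properties$hba < 10
  properties$lip_mw <- properties$mol_weight < 500
  properties$lip_alogp <- properties$alogp < 5
  properties$lipinski_pass <- properties$lip_hbd & properties$lip_hba &
    properties$lip_mw & properties$lip_alogp
  properties
}
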