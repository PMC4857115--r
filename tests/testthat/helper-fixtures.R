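# Shared fixtures. Everything is generated in code; no stored data files.

# a desk-scale generator configuration for fast tests
small_config <- function(seed = 1L, ...) {
  generator_config(
    n_compounds = 400L, n_plants = 30L, compounds_per_plant = c(6L, 20L),
    enriched_plants = 4L, isolate_plants = 2L,
    panel_sizes = c(preclinical = 12L, clinical = 20L, approved = 30L),
    n_reference_actives = 24L, n_decoys = 200L, seed = seed, ...)
}

# random 0/1 fingerprint matrix
random_fps <- function(n, nbits = 166L, density = 0.2, seed = 1L) {
  withr::with_seed(seed, {
    m <- matrix(as.integer(stats::runif(n * nbits) < density), n, nbits)
    rownames(m) <- sprintf("FP%03d", seq_len(n))
    m
  })
}

# activity calls straight from ground-truth labels (tests the enrichment
# stage in isolation from the activity scorer)
truth_calls <- function(truth) {
  data.frame(compound_id = truth$compound_truth$compound_id,
             score = as.numeric(truth$compound_truth$active),
             p_value = ifelse(truth$compound_truth$active, 0.01, 0.5),
             is_active = truth$compound_truth$active)
}

# exact reference for the hypergeometric upper tail via binomial
# coefficients (double precision is exact here: C(25,12) << 2^53)
exact_upper_tail <- function(N, n, m, k) {
  if (k == 0) return(1)
  j <- k:min(n, m)
  sum(choose(n, j) * choose(N - n, m - j)) / choose(N, m)
}

# brute-force union-find over an edge list; returns sorted component sets
union_find_components <- function(from, to) {
  nodes <- sort(unique(c(from, to)))
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (e in seq_along(from)) {
    ri <- find(match(from[e], nodes)); rj <- find(match(to[e], nodes))
    if (ri != rj) parent[rj] <- ri
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  comps <- lapply(split(nodes, roots), sort)
  unname(comps[order(-vapply(comps, length, integer(1)),
                     vapply(comps, `[[`, "", 1L))])
}

# tiny three-plant library written to disk; returns the file paths
write_tiny_library <- function(dir,
                               smiles = c(A = "CCO", B = "c1ccccc1",
                                          C = "CC(=O)OC")) {
  smi <- file.path(dir, "lib.smi")
  writeLines(paste(smiles, names(smiles)), smi)
  anno <- file.path(dir, "anno.tsv")
  tab <- data.frame(
    compound_id = names(smiles),
    plant_id = c("P1", "P1", "P2")[seq_along(smiles)],
    plant_name = c("Plant one", "Plant one", "Plant two")[seq_along(smiles)],
    family = "Asteraceae")
  utils::write.table(tab, anno, sep = "\t", quote = FALSE, row.names = FALSE)
  list(smi = smi, anno = anno)
}
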