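#!/usr/bin/env Rscript
# Stage 6: plant-drug similarity network.
#
# Connects each significant plant to every drug that at least one of its
# compounds resembles (Tc >= 0.70); exports Cytoscape-loadable SIF/GraphML
# and the component membership table.

suppressMessages(library(herbscreen))

lib <- read_compound_library("results/data/library.smi",
                             "results/data/annotation.tsv")
calls <- read_result_table("results/activity_calls.tsv")
enrichment <- read_result_table("results/enrichment.tsv")
panels <- read_drug_panels(c(preclinical = "results/data/drugs_preclinical.smi",
                             clinical = "results/data/drugs_clinical.smi",
                             approved = "results/data/drugs_approved.smi"))

fps <- maccs_fingerprint(lib$compounds$smiles, lib$compounds$compound_id)
net <- build_network(enrichment, lib$plants, fps, panels,
                     calls = calls, threshold = 0.70)
write_network(net, "results/network")
comps <- connected_components(net)
comp_table <- data.frame(component = rep(seq_along(comps), lengths(comps)),
                         node = unlist(comps))
write_result_table(comp_table, "results/network_components.tsv")

print(net)
for (i in seq_along(comps)) {
  n_plants <- sum(comps[[i]] %in% net$plant_nodes$plant_id)
  cat(sprintf("component %d: %d nodes (%d plants, %d drugs)\n", i,
              length(comps[[i]]), n_plants, length(comps[[i]]) - n_plants))
}
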