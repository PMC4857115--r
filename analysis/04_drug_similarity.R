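#!/usr/bin/env Rscript
# Stage 4: similarity of predicted actives to staged anti-cancer drugs.
#
# For each development stage (preclinical / clinical / approved), counts the
# predicted actives whose best MACCS Tanimoto against the stage's panel
# reaches 0.70.

suppressMessages(library(herbscreen))

lib <- read_compound_library("results/data/library.smi",
                             "results/data/annotation.tsv")
calls <- read_result_table("results/activity_calls.tsv")
panels <- read_drug_panels(c(preclinical = "results/data/drugs_preclinical.smi",
                             clinical = "results/data/drugs_clinical.smi",
                             approved = "results/data/drugs_approved.smi"))

act <- lib$compounds[lib$compounds$compound_id %in%
                     calls$compound_id[calls$is_active], ]
fps <- maccs_fingerprint(act$smiles, act$compound_id)
prof <- similarity_profile(fps, panels, threshold = 0.70)
write_result_table(prof$summary, "results/similarity_summary.tsv")
write_result_table(prof$pairs, "results/similarity_pairs.tsv")

for (i in seq_len(nrow(prof$summary))) {
  cat(sprintf("%s: %d (%d%%) of %d actives are drug-similar (Tc >= 0.70)\n",
              prof$summary$stage[i], prof$summary$n_similar[i],
              prof$summary$percent_similar[i], prof$summary$n_actives[i]))
}
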