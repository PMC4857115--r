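#!/usr/bin/env Rscript
# Stage 5: structural characterisation.
#
# Lipinski-style property profiles for predicted actives and drugs, plus the
# fragment-frequency comparison between the two sets.

suppressMessages(library(herbscreen))

lib <- read_compound_library("results/data/library.smi",
                             "results/data/annotation.tsv")
calls <- read_result_table("results/activity_calls.tsv")
panels <- read_drug_panels(c(preclinical = "results/data/drugs_preclinical.smi",
                             clinical = "results/data/drugs_clinical.smi",
                             approved = "results/data/drugs_approved.smi"))
drugs <- panels[!duplicated(panels$drug_id), ]
act <- lib$compounds[lib$compounds$compound_id %in%
                     calls$compound_id[calls$is_active], ]

props_a <- lipinski_flags(compute_properties(act$smiles, act$compound_id))
props_d <- lipinski_flags(compute_properties(drugs$smiles, drugs$drug_id))
write_result_table(props_a, "results/properties_actives.tsv")
write_result_table(props_d, "results/properties_drugs.tsv")
cat(sprintf("rule-of-five pass: %d%% of actives, %d%% of drugs\n",
            percent_of(sum(props_a$lipinski_pass), nrow(props_a)),
            percent_of(sum(props_d$lipinski_pass), nrow(props_d))))
cat(sprintf("mean rings (actives vs drugs): %.1f vs %.1f; aromatic: %.1f vs %.1f\n",
            mean(props_a$n_rings), mean(props_d$n_rings),
            mean(props_a$n_aromatic_rings), mean(props_d$n_aromatic_rings)))

frags <- frequency_table(act$smiles, drugs$smiles)
write_result_table(frags, "results/fragment_frequencies.tsv")
cat("most common fragments in the drug set:\n")
print(utils::head(frags, 8), row.names = FALSE)
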