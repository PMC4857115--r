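#!/usr/bin/env Rscript
# Stage 2: ligand-based activity calling.
#
# Fits the frequency-weighted fingerprint model on the reference
# active/decoy sets and scores every library compound; a compound is called
# active when its empirical P-value beats 0.05.

suppressMessages(library(herbscreen))

lib <- read_compound_library("results/data/library.smi",
                             "results/data/annotation.tsv")
cat(sprintf("read %d compounds (%d unparseable dropped)\n",
            lib$log[["n_compounds"]], lib$log[["n_unparseable"]]))

refs_a <- read_smiles_file("results/data/reference_actives.smi")
refs_d <- read_smiles_file("results/data/decoys.smi")
model <- fit_activity_model(maccs_fingerprint(refs_a$smiles),
                            maccs_fingerprint(refs_d$smiles))
fps <- maccs_fingerprint(lib$compounds$smiles, lib$compounds$compound_id)
calls <- predict_library(model, fps, alpha = 0.05)
write_result_table(calls, "results/activity_calls.tsv")

cat(sprintf("predicted active: %d / %d compounds (%d%%)\n",
            sum(calls$is_active), nrow(calls),
            percent_of(sum(calls$is_active), nrow(calls))))
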