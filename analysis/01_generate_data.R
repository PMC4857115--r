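#!/usr/bin/env Rscript
# Stage 1: emit the synthetic screening inputs.
#
# Writes a plant-annotated SMILES library, staged drug panels, reference
# active/decoy sets and the generator's ground truth under results/data/.
# Everything downstream (02..06) reads only these files.

suppressMessages(library(herbscreen))

cfg <- generator_config(seed = 1)
paths <- write_synthetic_dataset(cfg, "results/data")

lib <- generate_library(cfg)
truth <- lib$truth$compound_truth
cat(sprintf("library: %d compounds (%d truly active, %.0f%%), %d plants\n",
            nrow(lib$compounds), sum(truth$active), 100 * mean(truth$active),
            nrow(lib$plants)))
cat(sprintf("designated enriched plants: %d (of which %d isolate-family)\n",
            sum(lib$truth$plant_truth$enriched),
            sum(lib$truth$plant_truth$is_isolate)))
cat("files:\n"); for (p in paths) cat("  ", p, "\n")
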