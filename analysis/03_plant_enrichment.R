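#!/usr/bin/env Rscript
# Stage 3: activity enrichment analysis per plant.
#
# Hypergeometric upper-tail test of each plant's predicted-active count,
# Bonferroni-adjusted across all tested plants; significant plants
# (p_adj < 0.05) are the predicted anti-cancer plants.

suppressMessages(library(herbscreen))

lib <- read_compound_library("results/data/library.smi",
                             "results/data/annotation.tsv")
calls <- read_result_table("results/activity_calls.tsv")

enrichment <- run_acea(lib$plants, calls, alpha_adj = 0.05)
write_result_table(enrichment, "results/enrichment.tsv")

sig <- enrichment[enrichment$significant, ]
cat(sprintf("tested %d plants (N = %d, n = %d); %d significant at p_adj < 0.05\n",
            nrow(enrichment), enrichment$N[1], enrichment$n[1], nrow(sig)))
cat("top plants:\n")
print(utils::head(sig[, c("plant_name", "family", "m", "k", "p_adj")], 10),
      row.names = FALSE)
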