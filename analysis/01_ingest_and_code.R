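#!/usr/bin/env Rscript
# Ingest the endemic-bird species table, code IUCN categories to integer
# risk states (EN 1, VU 2, NT 3, LC 4) and record exclusions.

suppressMessages(library(riskevo))
dir.create("results", showWarnings = FALSE)

records <- read_risk_table(risk_table_fixture())
cat("read", nrow(records), "species records\n")
print(table(records$category))

coded <- code_categories(records)
print(coded)

utils::write.table(data.frame(species = names(coded$states),
                              state = unname(coded$states)),
                   "results/states.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
utils::write.table(coded$exclusions, "results/exclusions.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("wrote results/states.tsv and results/exclusions.tsv\n")
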