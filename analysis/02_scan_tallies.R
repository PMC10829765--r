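#!/usr/bin/env Rscript
# Stage 2 — scan-results tallies: total results, selected and not selected
# per source and scan period, the numbers that define the signal total T
# feeding every novelty score downstream.

suppressMessages(library(nanoforesight))

db <- read_signals("results/signals.csv")
tl <- tally(db)
readr::write_csv(tl, "results/scan_tallies.csv")

print(tl, n = nrow(tl))
cat("\nSelected totals per source:\n")
print(selected_totals(db))
cat("\nGrand total of selected signals (T): ", sum(tl$selected), "\n", sep = "")
cat("Wrote results/scan_tallies.csv\n")
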