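#!/usr/bin/env Rscript
# Stage 5 — regulatory-gap assessment.
#
# Matches the prioritized items (trend DSCs through their signature
# families, final wild cards through their own signatures) against the
# regulatory-document table and flags categories with no applicable
# guidance. Multifunctional wild cards are flagged unless a document covers
# every code of their multivalued positions.

suppressMessages(library(nanoforesight))

db <- read_signals("results/signals.csv")
regdb <- read_regdb("results/regulatory_documents.csv")
sel <- quartile_selection(build_spectrum(db), db)
fin <- select_final_wildcards(corrected_scores(db, sel))

report <- gap_report(db, sel, fin, regdb)
readr::write_csv(report, "results/regulatory_gaps.csv")

print(report[, c("item", "kind", "query", "n_matched", "insufficient")],
      n = nrow(report))
n_gap <- sum(report$insufficient)
cat("\n", n_gap, " of ", nrow(report),
    " prioritized items have no applicable regulatory document.\n", sep = "")
cat("Wrote results/regulatory_gaps.csv\n")
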