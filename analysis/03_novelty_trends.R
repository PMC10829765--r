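#!/usr/bin/env Rscript
# Stage 3 — novelty quantification and trend selection.
#
# Builds the design-solution frequency spectrum, scores each DSC with
# S = (T - C)/T * 10, writes the cumulative table (the descending-frequency
# representation on which Q1/Q3 are read) and the trend report: every DSC
# whose cumulative interval starts before the first quartile of T.

suppressMessages(library(nanoforesight))

db <- read_signals("results/signals.csv")
spectrum <- build_spectrum(db)
ct <- cumulative_table(spectrum)
ct$score <- round_half_up(ct$score, 2)
readr::write_csv(ct, "results/cumulative_spectrum.csv")

trends <- select_weak_signals(spectrum, q1_fraction = 0.25)
dict <- read_dsc_dictionary()
report <- trends$table[, c("count", "dsc", "score")]
report$score <- round_half_up(report$score, 2)
report$descriptor <- dict$descriptor[match(report$dsc, dict$dsc_code)]
readr::write_csv(report, "results/trends.csv")

cat("Design solutions: ", nrow(spectrum), " over T = ",
    attr(spectrum, "total"), " signals\n", sep = "")
cat("\nTrends (weak signals) at Q1, covering ", trends$signal_count,
    " signals:\n", sep = "")
print(report)
for (d in trends$dscs) {
  bd <- source_breakdown(db, d)
  cat(d, ": ", paste(names(bd), bd, sep = "=", collapse = ", "), "\n", sep = "")
}
cat("\nWrote results/cumulative_spectrum.csv and results/trends.csv\n")
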