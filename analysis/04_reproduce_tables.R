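#!/usr/bin/env Rscript
# Recompute every published statistic that is recomputable from the printed
# summary tables bundled with the package: one-sample t tests of the
# dimensional asymmetries, the two between-species prevalence chi-squared
# tests (counts reconstructed from the printed percentages and cohort
# sizes), and the dimension ratios / between-species size factors.

suppressMessages(library(braintorque))

dir.create("results", showWarnings = FALSE)
tab <- reproduce_reported_statistics()
utils::write.csv(tab, "results/reported_statistics.csv", row.names = FALSE)

cat("recomputed published statistics (results/reported_statistics.csv):\n\n")
print(as.data.frame(tab), row.names = FALSE, digits = 4)
cat("\nkey checks (printed values): t length 4.77, t height -3.30,\n")
cat("chi-squared petalia 14.85, chi-squared occipital bending 22.63,\n")
cat("human length/width 1.31, human/chimp length factor 1.57\n")
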