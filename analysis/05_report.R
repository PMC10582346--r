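#!/usr/bin/env Rscript
# One-shot orchestration: the same battery as scripts 02-04, run through
# run_compare() and written as a machine-readable report.

suppressMessages(library(fixbench))

fresh <- read_count_matrix("results/sim/fresh", "mtx_triplet")
fixed <- read_count_matrix("results/sim/fixed", "mtx_triplet")
annotation <- read.delim("results/sim/annotation.tsv")

report <- run_compare(fresh, fixed, annotation = annotation, seed = 1)
write_report(report, "results/report")
print(report)
cat("\nFull report written under results/report/\n")
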