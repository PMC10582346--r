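#!/usr/bin/env Rscript
# Generate the paired fresh / MeOH-fixed SORT-seq-like experiment that the
# rest of the analysis consumes: two 384-well plates sharing cell-type
# profiles and gene lengths, with the fixation artifacts at their default
# strengths (leakage 0.2, contamination 0.05, length decay 0.2, stress
# induction 2 in fresh, 30% damaged fresh wells) and full ground truth.

suppressMessages(library(fixbench))

seed <- 20260923L
out <- "results/sim"
params <- fixation_sim_params()
run_simulate(params, out, seed = seed)

truth <- read.delim(file.path(out, "truth.tsv"))
cat("Simulated paired experiment under", out, "\n")
cat(sprintf("  %d template wells per plate; %d genes (+%d ERCC species)\n",
            nrow(truth) / 2, params$n_genes, params$n_ercc))
cat(sprintf("  fresh wells damaged by sorting stress: %d (%.0f%%)\n",
            sum(truth$damaged), 100 * mean(truth$damaged[
              truth$condition == "fresh"])))
cat(sprintf("  true contamination fraction per cell: %.2f\n",
            params$contamination))
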