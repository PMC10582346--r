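#!/usr/bin/env Rscript
# Cell taxonomy of the filtered cells: PCA, condition-mixing score,
# k-means clustering with silhouette-selected k, marker genes per
# cluster, identity assignment from the dentate-gyrus panel, composition
# shift between conditions, and per-identity concordance.

suppressMessages(library(fixbench))

dir.create("results/taxonomy", recursive = TRUE, showWarnings = FALSE)
fresh <- read_count_matrix("results/sim/fresh", "mtx_triplet")
fixed <- read_count_matrix("results/sim/fixed", "mtx_triplet")
truth <- read.delim("results/sim/truth.tsv")
rownames(truth) <- truth$barcode

merged <- count_matrix(
  cbind(fresh$counts, fixed$counts),
  data.frame(condition = rep(c("fresh", "fixed"), each = 384)))
endo <- split_spikeins(merged)
pass <- filter_barcodes(per_barcode_stats(endo))
filt <- endo$counts[, pass]
cond <- endo$meta$condition[pass]

resid <- pearson_residual_normalize(filt)
pcs <- principal_components(resid, 12)
mix <- condition_mixing_score(pcs$embeddings, cond)
cat(sprintf("Condition mixing score (k = 15 neighbours): %.3f\n", mix))
cat("  (~0.5 = conditions fully intermixed; 1 = fully separated)\n")

cl <- cluster_cells(pcs$embeddings, seed = 1)
cat(sprintf("Clustering: k = %d selected by silhouette\n", cl$k))

mk <- find_markers(resid, filt, cl$labels)
write.table(mk[mk$pass, ], "results/taxonomy/markers.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
ids <- assign_identities(resid, cl$labels)
per_cell <- unname(ids[as.character(cl$labels)])
acc <- mean(per_cell == truth[colnames(filt), "true_type"])
cat(sprintf("Identity assignment vs ground truth: %.1f%% of cells correct\n",
            100 * acc))

comp <- composition_table(per_cell, cond)
write.table(as.data.frame.matrix(comp$counts),
            "results/taxonomy/composition_counts.tsv", sep = "\t",
            quote = FALSE)
cat("\nCell-type composition (column proportions):\n")
print(round(comp$proportions, 3))
neuron <- comp$proportions["mature_neuron", ]
cat(sprintf("\nGranule-neuron share: fresh %.2f vs fixed %.2f\n",
            neuron[["fresh"]], neuron[["fixed"]]))
cat("  (damaged fresh neurons fail QC, so fixation preserves them)\n")

pid <- per_identity_concordance(resid, per_cell, cond)
write.table(pid$scores, "results/taxonomy/per_identity_mixing.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
if (length(pid$skipped))
  cat("Identities skipped (too few cells):",
      paste(pid$skipped, collapse = ", "), "\n")
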