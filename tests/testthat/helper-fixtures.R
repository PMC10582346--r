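# shared fixtures and independent oracles, all built in code

# small count matrix with spike-ins and mito genes for hand checks
toy_matrix <- function() {
  m <- rbind(
    Actb = c(5, 10, 0),
    `mt-Co1` = c(0, 10, 0),
    `ERCC-00002` = c(7, 3, 0)
  )
  colnames(m) <- c("bc1", "bc2", "bc3")
  count_matrix(m)
}

# reduced simulator parameters for fast module tests (enough genes that
# healthy cells clear the 500-genes-detected QC threshold)
small_params <- function(...) {
  fixation_sim_params(n_genes = 800, ...)
}

null_knobs <- function(...) {
  list(leakage = 0, contamination = 0, length_decay = 0,
       stress_induction = 1, damaged_frac = 0, ...)
}

# brute-force two-sided rank-sum p by exhaustive enumeration of group
# assignments; independent of stats::wilcox.test
perm_ranksum_p <- function(x, y) {
  n <- length(x)
  ranks <- rank(c(x, y))
  idx <- utils::combn(length(ranks), n)
  W <- apply(idx, 2, function(i) sum(ranks[i]))
  w_obs <- sum(ranks[seq_len(n)])
  lo <- mean(W <= w_obs)
  hi <- mean(W >= w_obs)
  min(1, 2 * min(lo, hi))
}

# brute-force exon-union length: materialize every covered position
union_length_oracle <- function(starts, ends) {
  length(unique(unlist(mapply(seq, starts, ends, SIMPLIFY = FALSE))))
}

# write a toy Ensembl-style GTF; exons = list of gene -> matrix(start, end)
write_toy_gtf <- function(exons, path = tempfile(fileext = ".gtf")) {
  lines <- unlist(lapply(names(exons), function(g) {
    apply(exons[[g]], 1, function(e) {
      sprintf(paste0("1\ttoy\texon\t%d\t%d\t.\t+\t.\t",
                     "gene_id \"%s\"; gene_name \"%s\";"),
              e[1], e[2], g, g)
    })
  }))
  writeLines(lines, path)
  path
}

# Monte-Carlo occupancy: mean distinct bins when m balls drop into K bins
mc_distinct <- function(m, K, reps) {
  vapply(seq_len(reps), function(i) {
    length(unique(sample.int(K, m, replace = TRUE)))
  }, numeric(1))
}

# split a simulated plate into filtered endogenous pieces
plate_filtered <- function(plate) {
  endo <- split_spikeins(plate$matrix)
  st <- per_barcode_stats(endo)
  pass <- filter_barcodes(st)
  list(endo = endo, stats = st, pass = pass,
       counts = endo$counts[, pass, drop = FALSE])
}
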