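#' Run the full fresh-vs-fixed comparison
#'
#' Orchestrates the whole benchmark on a pair of raw plate matrices:
#' spike-in split, optional UMI-saturation correction, per-barcode QC and
#' filtering, mitochondrial comparison (before and after filtering),
#' Pearson-residual normalization, stress-panel comparison, ambient
#' mixture EM, dropout curves, pseudo-bulk / length-bin / concordance
#' analyses, PCA with condition-mixing score, clustering, marker finding,
#' identity assignment and composition tables. Deterministic given the
#' inputs and `seed`. Sections whose inputs are missing (no annotation ->
#' length analysis) are marked `"skipped"` rather than failing the run.
#'
#' @param fresh,fixed raw `CountMatrix` objects (one plate each,
#'   spike-in rows still present).
#' @param annotation optional gene-length annotation
#'   (see [compute_exon_lengths()]); `NULL` skips the length section.
#' @param layout optional [read_plate_layout()]; empty wells are added to
#'   the ambient background set.
#' @param thresholds a [qc_thresholds()] object.
#' @param umi_correct apply [correct_matrix()] before QC and
#'   normalization? Dropout curves always use uncorrected counts.
#' @param K UMI space size.
#' @param identity_panel named list identity -> markers.
#' @param n_pcs principal components used for clustering and mixing.
#' @param k_range candidate cluster numbers.
#' @param seed integer seed (clustering restarts).
#' @return list of class `ComparisonReport`; see sections in the value.
#' @export
run_compare <- function(fresh, fixed, annotation = NULL, layout = NULL,
                        thresholds = qc_thresholds(), umi_correct = TRUE,
                        K = 4096, identity_panel = default_identity_panel(),
                        n_pcs = 12, k_range = 2:12, seed = 1) {
  decisions <- character(0)
  note <- function(x) decisions <<- c(decisions, x)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- assemble the paired dataset -------------------------------------
  shared_genes <- intersect(rownames(fresh$counts), rownames(fixed$counts))
  raw <- stage("merge", {
    m <- cbind(fresh$counts[shared_genes, , drop = FALSE],
               fixed$counts[shared_genes, , drop = FALSE])
    meta <- rbind(
      data.frame(condition = if (is.null(fresh$meta$condition)) "fresh"
                 else fresh$meta$condition,
                 row.names = colnames(fresh$counts)),
      data.frame(condition = if (is.null(fixed$meta$condition)) "fixed"
                 else fixed$meta$condition,
                 row.names = colnames(fixed$counts)))
    count_matrix(m, meta)
  })
  cond_all <- raw$meta$condition

  endo <- stage("split_spikeins", split_spikeins(raw))
  note("ERCC spike-ins moved to metadata before all QC metrics")

  raw_endo <- endo   # integer counts, kept for dropout / detection
  if (umi_correct) {
    endo <- stage("umi_correction", correct_matrix(endo, K = K))
    note(sprintf("UMI saturation correction applied (K = %d); %s", K,
                 "dropout thresholds still use uncorrected counts"))
  }

  # -- QC and filtering -------------------------------------------------
  stats_tab <- stage("per_barcode_stats", per_barcode_stats(endo))
  pass <- stage("filter_barcodes", filter_barcodes(stats_tab, thresholds))
  note("QC bounds: transcript bounds inclusive, other criteria strict")
  mito_pre <- stage("mito_comparison_prefilter",
                    mito_comparison(stats_tab, cond_all))
  mito_post <- stage("mito_comparison_postfilter", {
    if (min(table(cond_all[pass])) >= 2 &&
        length(unique(cond_all[pass])) == 2)
      mito_comparison(stats_tab[pass, ], cond_all[pass])
    else "skipped"
  })

  filt_raw <- count_matrix(raw_endo$counts[, pass, drop = FALSE],
                           raw_endo$meta[pass, , drop = FALSE])
  filt <- count_matrix(endo$counts[, pass, drop = FALSE],
                       endo$meta[pass, , drop = FALSE])
  cond <- filt$meta$condition

  # -- normalization ----------------------------------------------------
  resid <- stage("normalize", pearson_residual_normalize(filt))
  note("analytic Pearson residuals (theta = 100, clipped) used as the normalized slot; conditions pooled under one normalization, no anchor integration")

  # -- stress panel -----------------------------------------------------
  stress <- stage("stress_panel",
                  stress_panel_summary(resid, filt_raw, cond))

  # -- PCA, mixing, clustering -----------------------------------------
  pcs <- stage("pca", principal_components(resid, n_pcs = n_pcs))
  mixing <- stage("condition_mixing",
                  condition_mixing_score(pcs$embeddings, cond,
                                         k = min(15, sum(pass) - 1)))
  clust <- stage("cluster_cells",
                 cluster_cells(pcs$embeddings, k_range = k_range,
                               seed = seed))
  note("clustering: k-means on top PCs with silhouette-selected k (stand-in for graph-based community detection)")

  # -- ambient contamination (needs cluster labels) --------------------
  background <- names(pass)[!pass]
  if (!is.null(layout)) {
    # empty wells always fail the filter, so they are already in the
    # background set; the layout is used to sanity-check that
    empty_bc <- rownames(raw$meta)[!is.null(raw$meta$well) &
                                     raw$meta$well %in% layout$empty_wells]
    background <- union(background, empty_bc)
    note("layout supplied: empty wells appended to the ambient background")
  } else {
    note("ambient background = all filter-failing barcodes")
  }
  contamination <- stage("ambient_em", {
    amb <- ambient_profile(raw_endo, background)
    est <- estimate_contamination(filt_raw, clust$labels, amb)
    by_cond <- split(est$rho, cond)
    list(estimate = est, ambient = amb,
         summary = data.frame(
           condition = names(by_cond),
           mean_rho = vapply(by_cond, mean, 0),
           median_rho = vapply(by_cond, stats::median, 0),
           row.names = NULL))
  })
  note("contamination EM clustered by the expression clusters")

  # -- dropout curves ---------------------------------------------------
  dropout <- stage("dropout_curve", dropout_curve(filt_raw, cond))
  note("dropout thresholds default {1,2,3,4,5,10,25,50,100} on raw counts")

  # -- pseudo-bulk, length, concordance --------------------------------
  pb <- stage("pseudobulk", pseudobulk(filt$counts, cond))
  conds <- colnames(pb)
  concordance <- stage("concordance",
                       pseudobulk_concordance(pb[, conds[1]],
                                              pb[, conds[2]]))
  length_section <- if (is.null(annotation)) "skipped" else
    stage("length_ratio", {
      fr <- pb[, grep("fresh", conds, value = TRUE)[1]]
      fx <- pb[, grep("fixed", conds, value = TRUE)[1]]
      if (is.null(names(fr))) names(fr) <- rownames(pb)
      if (is.null(names(fx))) names(fx) <- rownames(pb)
      length_ratio_analysis(fr, fx, annotation)
    })
  if (is.null(annotation)) note("no gene annotation: length section skipped")

  # -- markers, identities, composition --------------------------------
  markers <- stage("find_markers",
                   find_markers(resid, filt_raw, clust$labels))
  identities <- stage("assign_identities",
                      assign_identities(resid, clust$labels,
                                        panel = identity_panel))
  id_per_cell <- unname(identities[as.character(clust$labels)])
  composition <- stage("composition",
                       composition_table(id_per_cell, cond))
  per_identity <- stage("per_identity_concordance",
                        per_identity_concordance(resid, id_per_cell, cond))

  structure(list(
    seed = seed,
    conditions = sort(unique(cond_all)),
    n_barcodes = table(cond_all),
    barcode_stats = stats_tab,
    filter_pass = pass,
    n_pass = table(cond),
    mito_prefilter = mito_pre,
    mito_postfilter = mito_post,
    stress = stress,
    contamination = contamination$estimate,
    contamination_summary = contamination$summary,
    contamination_rho = contamination$estimate$rho,
    dropout = dropout,
    pseudobulk = pb,
    concordance = concordance,
    length_section = length_section,
    pca_var_explained = pcs$var_explained,
    condition_mixing_score = mixing,
    clustering = clust,
    markers = markers,
    identities = identities,
    composition = composition,
    per_identity = per_identity,
    decisions = decisions
  ), class = "ComparisonReport")
}

#' @export
print.ComparisonReport <- function(x, ...) {
  cat("ComparisonReport\n")
  cat("  barcodes:", paste(names(x$n_barcodes), as.integer(x$n_barcodes),
                           sep = "=", collapse = ", "), "\n")
  cat("  passing QC:", paste(names(x$n_pass), as.integer(x$n_pass),
                             sep = "=", collapse = ", "), "\n")
  cat(sprintf("  pseudo-bulk concordance r = %.3f\n", x$concordance$r))
  cat(sprintf("  condition mixing score = %.3f\n",
              x$condition_mixing_score))
  cat(sprintf("  clusters: k = %d; identities: %s\n", x$clustering$k,
              paste(unique(x$identities), collapse = ", ")))
  invisible(x)
}

#' Write a ComparisonReport to disk
#'
#' Emits a machine-readable `report.json` (summary statistics, decisions
#' log, seed) plus one TSV per table (barcode stats, filter flags, stress
#' panel, contamination, dropout curve, length bins, markers,
#' composition). Byte-identical across runs with the same inputs and
#' seed: no timestamps enter the payload.
#'
#' @param report a [run_compare()] result.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "ComparisonReport"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE,
    row.names = is.null(ncol(x)) || !is.null(rownames(x)))
  utils::write.table(cbind(barcode = rownames(report$barcode_stats),
                           report$barcode_stats,
                           pass = report$filter_pass),
                     file.path(dir, "barcode_stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$stress, file.path(dir, "stress_panel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(barcode = names(report$contamination_rho),
                                rho = unname(report$contamination_rho)),
                     file.path(dir, "contamination.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$dropout$table,
                     file.path(dir, "dropout_curve.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!identical(report$length_section, "skipped"))
    utils::write.table(report$length_section$table,
                       file.path(dir, "length_bins.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  utils::write.table(report$markers, file.path(dir, "markers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(report$composition$counts),
                     file.path(dir, "composition_counts.tsv"), sep = "\t",
                     quote = FALSE)
  summary <- list(
    seed = report$seed,
    conditions = report$conditions,
    n_barcodes = as.list(as.integer(report$n_barcodes)),
    n_pass = as.list(report$n_pass),
    mito_prefilter = report$mito_prefilter,
    mito_postfilter = if (identical(report$mito_postfilter, "skipped"))
      "skipped" else report$mito_postfilter,
    contamination = report$contamination_summary,
    concordance_r = report$concordance$r,
    length_trend = if (identical(report$length_section, "skipped"))
      "skipped" else list(rho = report$length_section$trend_rho,
                          p = report$length_section$trend_p),
    condition_mixing_score = report$condition_mixing_score,
    k_clusters = report$clustering$k,
    identities = as.list(report$identities),
    decisions = report$decisions,
    tables = list.files(dir, pattern = "\\.tsv$")
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}

#' Simulate an experiment and write it in pipeline-ready form
#'
#' Writes the fresh and fixed raw matrices (MTX triplet directories), the
#' per-well ground truth, the simulated gene-length annotation and a
#' parameter echo, all readable back by [read_count_matrix()] /
#' [run_compare()].
#'
#' @param params a [fixation_sim_params()] object.
#' @param dir output directory.
#' @param seed integer seed.
#' @return `dir`, invisibly.
#' @export
run_simulate <- function(params, dir, seed = 1) {
  stopifnot(inherits(params, "FixationSimParams"))
  pair <- simulate_pair(params, seed = seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_matrix(pair$fresh$matrix, file.path(dir, "fresh"),
                     "mtx_triplet")
  write_count_matrix(pair$fixed$matrix, file.path(dir, "fixed"),
                     "mtx_triplet")
  truth <- rbind(pair$fresh$truth, pair$fixed$truth)
  truth$condition <- rep(c("fresh", "fixed"),
                         c(nrow(pair$fresh$truth), nrow(pair$fixed$truth)))
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(pair$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  echo <- c(unclass(params), list(seed = seed))
  echo$type_props <- as.list(echo$type_props)
  echo$damage_weights <- as.list(echo$damage_weights)
  yaml::write_yaml(echo, file.path(dir, "params.yaml"))
  invisible(dir)
}
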