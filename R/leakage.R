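#' Ambient RNA expression profile from background barcodes
#'
#' The ambient pool is estimated as the count-weighted average of
#' background barcodes — by default the barcodes failing QC filtering
#' (plus declared empty wells, when a layout is supplied by the caller).
#' Returned as a probability vector over genes.
#'
#' @param raw_matrix `CountMatrix` of raw counts (after
#'   [split_spikeins()]).
#' @param background_barcodes character vector of barcode identifiers.
#' @return named numeric vector over genes, summing to 1.
#' @export
ambient_profile <- function(raw_matrix, background_barcodes) {
  stopifnot(inherits(raw_matrix, "CountMatrix"))
  if (!length(background_barcodes)) stop("background set must be non-empty")
  missing <- setdiff(background_barcodes, colnames(raw_matrix$counts))
  if (length(missing))
    stop("unknown background barcodes: ", paste(utils::head(missing, 3),
                                                collapse = ", "))
  s <- Matrix::rowSums(raw_matrix$counts[, background_barcodes,
                                         drop = FALSE])
  tot <- sum(s)
  if (tot <= 0) stop("background barcodes have zero total counts")
  stats::setNames(as.vector(s / tot), rownames(raw_matrix$counts))
}

#' Per-cell ambient contamination by two-source multinomial mixture EM
#'
#' Estimates, for every filtered cell, the fraction `rho` of its counts
#' that came from the ambient pool rather than from its own
#' transcriptome. Cell `c` in cluster `z` is modelled as
#' `counts_c ~ Multinomial(n_c, (1 - rho_c) * phi_z + rho_c * phi_amb)`
#' with the ambient profile `phi_amb` held fixed. The E-step assigns each
#' count fractionally to the native or ambient source; the M-step updates
#' `rho_c` and the cluster profiles `phi_z`.
#'
#' A free native profile can absorb any amount of ambient signal (the
#' likelihood is flat along `(rho, phi_z)` trade-offs), so the scale of
#' `rho` is anchored by each cluster's ambient-only gene support: genes
#' whose within-cluster expression is low relative to their ambient
#' abundance — genes the cluster does not natively express, detected as
#' the lowest expression/ambient ratios accounting for
#' `support_quantile` of ambient mass. Counts on these genes can only be
#' contamination; `phi_z` is floored at 1e-12 on them (and on zero
#' native estimates), initial `rho` is the pooled expression/ambient
#' ratio over them, and the M-step keeps the constraint. The
#' log-likelihood is non-decreasing over iterations.
#'
#' @param filtered_matrix `CountMatrix` or matrix of raw counts for the
#'   filtered cells (genes x cells).
#' @param cluster_labels one label per cell (cell type / cluster).
#' @param ambient probability vector over the same genes
#'   (see [ambient_profile()]).
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood
#'   gain drops below `tol` or after `max_iter` iterations.
#' @param support_quantile fraction of ambient mass treated as each
#'   cluster's ambient-only support.
#' @return list of class `ContaminationEstimate` with `rho` (per cell),
#'   `profiles` (genes x clusters), `loglik` (trace), `converged`,
#'   `flagged_clusters` (singleton clusters).
#' @export
estimate_contamination <- function(filtered_matrix, cluster_labels, ambient,
                                   max_iter = 100, tol = 1e-3,
                                   support_quantile = 0.1) {
  X <- .as_dense(filtered_matrix)
  if (!ncol(X) || sum(X) == 0) stop("empty matrix")
  lab <- as.character(cluster_labels)
  if (length(lab) != ncol(X)) stop("one cluster label per cell required")
  amb <- pmax(as.numeric(ambient), 1e-12)
  amb <- amb / sum(amb)
  if (length(amb) != nrow(X)) stop("ambient profile length mismatch")
  clusters <- sort(unique(lab))
  singletons <- clusters[table(lab)[clusters] == 1]
  if (length(singletons))
    warning("singleton cluster(s): ", paste(singletons, collapse = ", "))
  zi <- match(lab, clusters)
  n_c <- colSums(X)

  # per-cluster ambient-only support and anchored initial rho
  off_sets <- list()
  rho0 <- stats::setNames(numeric(length(clusters)), clusters)
  pbar <- vapply(clusters, function(z) {
    s <- rowSums(X[, lab == z, drop = FALSE])
    s / sum(s)
  }, numeric(nrow(X)))
  for (i in seq_along(clusters)) {
    ratio <- pbar[, i] / amb
    ord <- order(ratio)
    cum <- cumsum(amb[ord])
    off <- ord[cum <= support_quantile]
    if (!length(off)) off <- ord[1]
    off_sets[[i]] <- off
    rho0[i] <- min(sum(pbar[off, i]) / sum(amb[off]), 0.95)
  }

  # native profiles: decontaminated cluster means, silent on the support
  phi <- vapply(seq_along(clusters), function(i) {
    w <- pmax(pbar[, i] - rho0[i] * amb, 0)
    w[off_sets[[i]]] <- 0
    w <- pmax(w, 1e-12)
    w / sum(w)
  }, numeric(nrow(X)))
  rho <- rho0[zi]
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    P_nat <- sweep(phi[, zi, drop = FALSE], 2, 1 - rho, "*")
    P_amb <- outer(amb, rho)
    mix <- P_nat + P_amb
    ll <- sum(X * log(mix))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    A <- X * (P_amb / mix)            # expected ambient-sourced counts
    rho <- colSums(A) / pmax(n_c, 1)
    rho <- pmin(pmax(rho, 0), 1)
    nat <- X - A
    phi <- vapply(seq_along(clusters), function(i) {
      w <- rowSums(nat[, lab == clusters[i], drop = FALSE])
      w[off_sets[[i]]] <- 0
      w <- pmax(w, 1e-12)
      w / sum(w)
    }, numeric(nrow(X)))
  }
  dimnames(phi) <- list(rownames(X), clusters)
  structure(list(rho = stats::setNames(rho, colnames(X)),
                 profiles = phi, loglik = ll_trace,
                 converged = converged,
                 flagged_clusters = singletons),
            class = "ContaminationEstimate")
}

#' Gene-detection (dropout) curve over expression thresholds
#'
#' For each cell and each threshold `t`, the number of genes with raw
#' count `>= t`; counts are non-increasing in `t` and at `t = 1` equal
#' the genes-detected statistic. Each threshold's fresh-vs-fixed
#' difference is tested with an unpaired rank-sum test, BH-adjusted
#' across thresholds. The default nine thresholds span the count
#' distribution.
#'
#' @param raw_matrix `CountMatrix` or matrix of raw counts.
#' @param condition_labels two-condition labels per cell.
#' @param thresholds strictly increasing positive integers.
#' @return list with `counts` (cells x thresholds matrix) and `table`
#'   (per threshold: medians per condition, `p_value`, `p_adj`).
#' @export
dropout_curve <- function(raw_matrix, condition_labels,
                          thresholds = c(1, 2, 3, 4, 5, 10, 25, 50, 100)) {
  if (!length(thresholds)) stop("thresholds must be non-empty")
  if (any(diff(thresholds) <= 0)) stop("thresholds must be strictly increasing")
  X <- .as_dense(raw_matrix)
  lab <- as.character(condition_labels)
  conds <- sort(unique(lab))
  if (length(conds) != 2) stop("exactly two conditions required")
  cnt <- vapply(thresholds, function(t) colSums(X >= t),
                numeric(ncol(X)))
  colnames(cnt) <- paste0("ge_", thresholds)
  rownames(cnt) <- colnames(X)
  p <- vapply(seq_along(thresholds), function(j) {
    rank_sum_test(cnt[lab == conds[1], j], cnt[lab == conds[2], j])$p_value
  }, numeric(1))
  med <- vapply(conds, function(cc)
    apply(cnt[lab == cc, , drop = FALSE], 2, stats::median),
    numeric(length(thresholds)))
  tab <- data.frame(threshold = thresholds,
                    med, p_value = p, p_adj = bh_fdr(p),
                    row.names = NULL, check.names = FALSE)
  colnames(tab)[2:3] <- paste0("median_", conds)
  list(counts = cnt, table = tab)
}

#' Per-condition pseudo-bulk expression
#'
#' Averages per-cell expression over all cells of each condition. The
#' expression slot is whatever matrix is passed in — normalized
#' expression by default in the pipeline, raw counts when requested.
#'
#' @param matrix `CountMatrix` or numeric matrix, genes x cells.
#' @param condition_labels label per cell.
#' @return genes x conditions matrix of mean expression.
#' @export
pseudobulk <- function(matrix, condition_labels) {
  X <- .as_dense(matrix)
  lab <- as.character(condition_labels)
  if (length(lab) != ncol(X)) stop("one label per cell required")
  conds <- sort(unique(lab))
  out <- vapply(conds, function(cc)
    rowMeans(X[, lab == cc, drop = FALSE]), numeric(nrow(X)))
  rownames(out) <- rownames(X)
  out
}

# equal-count bin ids for n ordered items into n_bins bins (sizes +/- 1)
.equal_count_bins <- function(n, n_bins) {
  sizes <- diff(round(seq(0, n, length.out = n_bins + 1)))
  rep(seq_len(n_bins), times = sizes)
}

#' Exon-length-dependent expression-loss analysis
#'
#' Genes are sorted by non-overlapping exon length into `n_bins` bins of
#' equal gene count (+/- 1). Per bin: the length range, mean pseudo-bulk
#' expression per condition, an unpaired rank-sum test of the per-gene
#' expression values between conditions (BH across bins), and the mean
#' fresh/fixed expression ratio. The length trend is tested by Spearman
#' correlation of bin index against the per-bin mean ratio; a positive
#' trend means longer transcripts are preferentially lost in the fixed
#' condition. Ratios use only genes with positive expression in both
#' conditions (the excluded count is reported); unannotated genes are
#' dropped with a warning.
#'
#' @param pb_fresh,pb_fixed named per-gene pseudo-bulk expression vectors
#'   (see [pseudobulk()]).
#' @param annotation data.frame `gene_symbol` / `exon_length_bp`
#'   (see [compute_exon_lengths()]).
#' @param n_bins number of length bins (default 20).
#' @return list with `table` (one row per bin), `trend_rho`, `trend_p`,
#'   `n_excluded_ratio` (genes without a finite ratio), `n_unannotated`.
#' @export
length_ratio_analysis <- function(pb_fresh, pb_fixed, annotation,
                                  n_bins = 20) {
  shared <- intersect(names(pb_fresh), names(pb_fixed))
  ann <- annotation[match(shared, annotation$gene_symbol), ]
  keep <- !is.na(ann$exon_length_bp)
  n_unann <- sum(!keep)
  if (n_unann)
    warning(n_unann, " expressed gene(s) without length annotation dropped")
  if (n_unann > 0.1 * length(shared))
    warning("length annotation covers < 90% of expressed genes")
  g <- shared[keep]
  len <- ann$exon_length_bp[keep]
  if (length(g) < n_bins) stop("fewer genes than bins")
  ord <- order(len)
  g <- g[ord]; len <- len[ord]
  bin <- .equal_count_bins(length(g), n_bins)
  fr <- pb_fresh[g]; fx <- pb_fixed[g]
  ok_ratio <- fr > 0 & fx > 0
  ratio <- ifelse(ok_ratio, fr / fx, NA_real_)
  rows <- lapply(seq_len(n_bins), function(b) {
    sel <- bin == b
    p <- rank_sum_test(fr[sel], fx[sel])$p_value
    data.frame(bin = b,
               length_min = min(len[sel]), length_max = max(len[sel]),
               n_genes = sum(sel),
               mean_fresh = mean(fr[sel]), mean_fixed = mean(fx[sel]),
               mean_ratio = mean(ratio[sel], na.rm = TRUE),
               p_value = p)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- bh_fdr(tab$p_value)
  if (stats::sd(tab$mean_ratio, na.rm = TRUE) == 0) {
    # perfectly flat ratios carry no trend
    tr <- list(estimate = 0, p.value = 1)
  } else {
    tr <- suppressWarnings(
      stats::cor.test(seq_len(n_bins), tab$mean_ratio, method = "spearman"))
  }
  list(table = tab,
       trend_rho = unname(tr$estimate), trend_p = tr$p.value,
       n_excluded_ratio = sum(!ok_ratio), n_unannotated = n_unann)
}

#' Pseudo-bulk transcriptome concordance between conditions
#'
#' Pearson correlation of the two conditions' pseudo-bulk expression on
#' the log1p scale — the headline similarity statistic of the benchmark.
#'
#' @param pb_a,pb_b named per-gene pseudo-bulk vectors (shared genes
#'   `>= 3`).
#' @return list with `r` and `table` (gene, log1p means).
#' @export
pseudobulk_concordance <- function(pb_a, pb_b) {
  shared <- intersect(names(pb_a), names(pb_b))
  if (length(shared) < 3) stop("need >= 3 shared genes")
  a <- log1p(pb_a[shared]); b <- log1p(pb_b[shared])
  r <- pearson_correlation(a, b)
  list(r = r, table = data.frame(gene = shared, log1p_a = unname(a),
                                 log1p_b = unname(b)))
}
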