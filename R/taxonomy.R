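#' Marker-selection criteria
#'
#' A gene is called a cluster marker when its BH-adjusted rank-sum p is
#' below `max_adj_p`, its log2 fold change (pseudocount 1) is at least
#' `min_logfc`, and the ratio of detection fractions inside vs outside
#' the cluster (pct.1/pct.2) exceeds `min_pct_ratio`.
#'
#' @param max_adj_p,min_logfc,min_pct_ratio positive thresholds.
#' @return list of class `MarkerCriteria`.
#' @export
marker_criteria <- function(max_adj_p = 0.05, min_logfc = 0.5,
                            min_pct_ratio = 2.5) {
  stopifnot(max_adj_p > 0, min_logfc > 0, min_pct_ratio > 0)
  structure(list(max_adj_p = max_adj_p, min_logfc = min_logfc,
                 min_pct_ratio = min_pct_ratio), class = "MarkerCriteria")
}

#' Cluster cells in PC space
#'
#' k-means over the principal-component embedding, with the number of
#' clusters chosen by maximal mean silhouette width over `k_range`.
#' Deterministic given `seed`.
#'
#' @param embeddings cells x PCs matrix (see [principal_components()]).
#' @param k_range candidate cluster counts, within `[2, n - 1]`.
#' @param seed integer seed for k-means starts.
#' @param nstart k-means restarts per k.
#' @return list with `labels` (integer per cell), `k`, `silhouette`
#'   (mean width per candidate k).
#' @export
cluster_cells <- function(embeddings, k_range = 2:12, seed = 1,
                          nstart = 10) {
  n <- nrow(embeddings)
  if (n < 4) stop("need >= 4 cells")
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) stop("k_range outside [2, n - 1]")
  d <- stats::dist(embeddings)
  fits <- list()
  sil <- stats::setNames(numeric(length(k_range)), k_range)
  for (i in seq_along(k_range)) {
    set.seed(seed + i)
    km <- stats::kmeans(embeddings, centers = k_range[i], nstart = nstart,
                        iter.max = 50)
    fits[[i]] <- km$cluster
    sw <- cluster::silhouette(km$cluster, d)
    sil[i] <- mean(sw[, "sil_width"])
  }
  best <- which.max(sil)
  list(labels = stats::setNames(fits[[best]], rownames(embeddings)),
       k = k_range[best], silhouette = sil)
}

#' Per-cluster marker genes
#'
#' For every gene and cluster: a rank-sum test of the cluster's cells
#' against all other cells on normalized expression (normal approximation
#' with tie correction), BH-adjusted per cluster across genes; a log2
#' fold change of raw mean counts with pseudocount 1; and the detection
#' fractions pct.1 (inside) and pct.2 (outside, floored at `1/n_out` so
#' the ratio stays finite). The `pass` column applies the
#' [marker_criteria()].
#'
#' @param normalized genes x cells matrix of normalized expression.
#' @param raw `CountMatrix` or matrix of raw counts, same cells.
#' @param cluster_labels label per cell, `>= 2` clusters.
#' @param criteria a [marker_criteria()] object.
#' @return data.frame with columns `cluster`, `gene`, `logfc`, `pct1`,
#'   `pct2`, `p_value`, `p_adj`, `pass`.
#' @export
find_markers <- function(normalized, raw, cluster_labels,
                         criteria = marker_criteria()) {
  X <- as.matrix(normalized)
  R <- .as_dense(raw)
  lab <- as.character(cluster_labels)
  clusters <- sort(unique(lab))
  if (length(clusters) < 2) stop("need >= 2 clusters")
  if (any(table(lab) == 1)) warning("singleton cluster(s) present")
  ranks <- .row_ranks(X)
  out <- lapply(clusters, function(z) {
    inz <- lab == z
    n_out <- sum(!inz)
    p <- .rowwise_ranksum(X, inz, ranks = ranks)
    mean_in <- rowMeans(R[, inz, drop = FALSE])
    mean_out <- rowMeans(R[, !inz, drop = FALSE])
    logfc <- log2((mean_in + 1) / (mean_out + 1))
    pct1 <- rowMeans(R[, inz, drop = FALSE] > 0)
    pct2 <- pmax(rowMeans(R[, !inz, drop = FALSE] > 0), 1 / n_out)
    padj <- bh_fdr(p)
    data.frame(cluster = z, gene = rownames(X), logfc = logfc,
               pct1 = pct1, pct2 = pct2, p_value = p, p_adj = padj,
               pass = padj < criteria$max_adj_p &
                 logfc >= criteria$min_logfc &
                 pct1 / pct2 > criteria$min_pct_ratio,
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Assign cell-type identities to clusters
#'
#' Each cluster receives the identity whose marker set has the highest
#' mean z-scored normalized expression in that cluster (z-scored per gene
#' across cells, so highly expressed housekeeping genes do not dominate).
#' Ties break alphabetically with a warning; identities whose marker set
#' is entirely absent from the matrix are never assigned (warning).
#'
#' @param normalized genes x cells matrix of normalized expression.
#' @param cluster_labels label per cell.
#' @param panel named list identity -> marker symbols
#'   (default [default_identity_panel()]).
#' @return named character vector: cluster -> identity.
#' @export
assign_identities <- function(normalized, cluster_labels,
                              panel = default_identity_panel()) {
  X <- as.matrix(normalized)
  lab <- as.character(cluster_labels)
  sym <- tolower(rownames(X))
  present <- lapply(panel, function(g) which(sym %in% tolower(g)))
  absent <- names(panel)[lengths(present) == 0]
  if (length(absent) == length(panel)) stop("no panel gene present")
  if (length(absent))
    warning("identities with no marker present are never assigned: ",
            paste(absent, collapse = ", "))
  present <- present[lengths(present) > 0]
  sds <- apply(X, 1, stats::sd)
  Z <- (X - rowMeans(X)) / ifelse(sds > 0, sds, 1)
  clusters <- sort(unique(lab))
  scores <- vapply(clusters, function(z) {
    vapply(present, function(rows) mean(Z[rows, lab == z]), numeric(1))
  }, numeric(length(present)))
  scores <- matrix(scores, nrow = length(present),
                   dimnames = list(names(present), clusters))
  ids <- apply(scores, 2, function(s) {
    top <- names(s)[s == max(s)]
    if (length(top) > 1) {
      warning("identity tie broken alphabetically")
      top <- sort(top)[1]
    }
    top
  })
  ids
}

#' Cell-type composition by condition
#'
#' @param identity_labels identity per cell.
#' @param condition_labels condition per cell (aligned).
#' @return list with `proportions` (identity x condition, columns sum to
#'   1) and `counts` (identity x condition cell counts).
#' @export
composition_table <- function(identity_labels, condition_labels) {
  if (length(identity_labels) != length(condition_labels))
    stop("labels must be aligned")
  counts <- table(identity = as.character(identity_labels),
                  condition = as.character(condition_labels))
  props <- sweep(counts, 2, colSums(counts), "/")
  list(proportions = as.matrix(unclass(props)),
       counts = as.matrix(unclass(counts)))
}

#' Per-identity condition concordance
#'
#' Within each identity (with at least `min_cells` cells), computes the
#' [condition_mixing_score()] from the supplied residual matrix and the
#' heat-map leaf ordering of the identity's cells
#' ([hierarchical_order()] of their pairwise correlations). Identities
#' with too few cells are skipped and listed.
#'
#' @param residual_matrix genes x cells normalized matrix.
#' @param identity_labels identity per cell.
#' @param condition_labels condition per cell.
#' @param min_cells minimum cells for scoring (default 4).
#' @param k neighbors for the mixing score (capped at n - 1).
#' @return list with `scores` (data.frame identity / n / mixing_score),
#'   `orderings` (named list of leaf orders), `skipped`.
#' @export
per_identity_concordance <- function(residual_matrix, identity_labels,
                                     condition_labels, min_cells = 4,
                                     k = 15) {
  ids <- as.character(identity_labels)
  uids <- sort(unique(ids))
  res <- list(); ords <- list(); skipped <- character(0)
  for (id in uids) {
    sel <- ids == id
    n <- sum(sel)
    if (n < min_cells || length(unique(condition_labels[sel])) < 2) {
      skipped <- c(skipped, id)
      next
    }
    sub <- residual_matrix[, sel, drop = FALSE]
    cc <- pairwise_correlation_matrix(sub)
    ords[[id]] <- hierarchical_order(cc)$order
    emb <- principal_components(sub, n_pcs = min(10, n - 1))$embeddings
    res[[id]] <- data.frame(identity = id, n = n,
                            mixing_score = condition_mixing_score(
                              emb, condition_labels[sel],
                              k = min(k, n - 1)))
  }
  list(scores = do.call(rbind, res), orderings = ords, skipped = skipped)
}
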