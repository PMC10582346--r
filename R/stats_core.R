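#' Wilcoxon rank-sum / signed-rank test
#'
#' The pipeline's test for all fresh-vs-fixed comparisons: a two-sided
#' Wilcoxon rank-sum test for unpaired samples, or the signed-rank test
#' for paired samples (zero differences dropped). The exact null
#' distribution is used for small unpaired samples (both groups <= 8, no
#' ties); otherwise the normal approximation with tie and continuity
#' correction. Degenerate inputs where every value is identical across
#' both groups return p = 1 by convention.
#'
#' @param x,y numeric samples (each `>= 2` values; equal lengths if paired).
#' @param paired logical.
#' @return list with `statistic`, `p_value`, `method`, `n` (per-group sizes).
#' @export
rank_sum_test <- function(x, y, paired = FALSE) {
  if (paired && length(x) != length(y))
    stop("paired test requires equal lengths")
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs >= 2 values")
  if (all(c(x, y) == c(x, y)[1]) || (paired && all(x == y))) {
    return(list(statistic = NA_real_, p_value = 1,
                method = if (paired) "signed-rank" else "rank-sum",
                n = c(length(x), length(y))))
  }
  exact <- !paired && length(x) <= 8 && length(y) <= 8 &&
    !anyDuplicated(c(x, y))
  res <- suppressWarnings(
    stats::wilcox.test(x, y, paired = paired, exact = exact, correct = TRUE)
  )
  list(statistic = unname(res$statistic), p_value = res$p.value,
       method = if (paired) "signed-rank" else "rank-sum",
       n = c(length(x), length(y)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment; preserves input order, never decreases a p-value,
#' caps at 1, and is idempotent.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted p-values, same order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Analytic Pearson-residual normalization
#'
#' Variance-stabilizing normalization of a count matrix against a
#' negative-binomial null with fixed overdispersion: the expected count of
#' gene g in cell c under the null that every cell expresses the same
#' proportions is `mu = rowsum_g * colsum_c / grand_total`, and the
#' residual is `(x - mu) / sqrt(mu + mu^2 / theta)`, clipped to
#' `+/- sqrt(n_cells)`. A gene expressed at an identical proportion in
#' every cell has residuals ~ 0.
#'
#' @param matrix `CountMatrix` or numeric matrix (genes x cells).
#' @param theta NB overdispersion of the null (default 100).
#' @param clip clip residuals at `+/- sqrt(n_cells)`?
#' @return dense numeric matrix of residuals, same shape and dimnames.
#' @export
pearson_residual_normalize <- function(matrix, theta = 100, clip = TRUE) {
  x <- .as_dense(matrix)
  total <- sum(x)
  if (total <= 0) stop("grand total must be > 0")
  rs <- rowSums(x)
  cs <- colSums(x)
  if (any(cs == 0))
    warning("zero-total barcode(s): residuals set to 0 for ",
            sum(cs == 0), " column(s)")
  mu <- outer(rs, cs) / total
  r <- (x - mu) / sqrt(mu + mu^2 / theta)
  r[, cs == 0] <- 0
  r[rs == 0, ] <- 0
  if (clip) {
    lim <- sqrt(ncol(x))
    r[r > lim] <- lim
    r[r < -lim] <- -lim
  }
  r
}

#' Pearson product-moment correlation
#'
#' @param a,b numeric vectors of equal length `>= 3` with non-zero variance.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson_correlation <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3)
    stop("need equal lengths >= 3")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance")
  stats::cor(a, b)
}

#' Pairwise cell-cell correlation matrix
#'
#' Correlation of every pair of cells (columns), computed either from raw
#' counts or from Pearson residuals — the matrix passed in decides.
#' Constant cells get correlation 0 against everything (with a warning);
#' the diagonal is always 1.
#'
#' @param matrix numeric matrix or `CountMatrix`, genes x cells, `>= 2` cells.
#' @return symmetric cells x cells matrix with unit diagonal.
#' @export
pairwise_correlation_matrix <- function(matrix) {
  x <- .as_dense(matrix)
  if (ncol(x) < 2) stop("need >= 2 cells")
  sds <- apply(x, 2, stats::sd)
  cc <- suppressWarnings(stats::cor(x))
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant cell(s): correlations set to 0")
    cc[sds == 0, ] <- 0
    cc[, sds == 0] <- 0
  }
  diag(cc) <- 1
  cc
}

#' Hierarchical ordering of cells from a correlation matrix
#'
#' Agglomerative clustering (complete linkage) on the Euclidean distances
#' between rows of the correlation matrix — the ordering used for
#' correlation heat maps, which keeps blocks of mutually similar cells
#' contiguous.
#'
#' @param corr_matrix square symmetric matrix (e.g. from
#'   [pairwise_correlation_matrix()]).
#' @param method linkage passed to [stats::hclust()].
#' @return list with `order` (leaf order, integer indices) and `tree`
#'   (the `hclust` object).
#' @export
hierarchical_order <- function(corr_matrix, method = "complete") {
  if (nrow(corr_matrix) < 2) stop("need >= 2 cells")
  if (nrow(corr_matrix) != ncol(corr_matrix)) stop("input must be square")
  hc <- stats::hclust(stats::dist(corr_matrix), method = method)
  list(order = hc$order, tree = hc)
}

#' Principal components of a residual matrix
#'
#' Centered PCA over cells: rows of the input are genes, columns cells;
#' cells are embedded in the top `n_pcs` components.
#'
#' @param residual_matrix numeric matrix, genes x cells.
#' @param n_pcs number of components, `1 <= n_pcs <= min(genes, cells)`.
#' @return list with `embeddings` (cells x n_pcs), `var_explained`
#'   (fraction per component, non-increasing), `sdev`.
#' @export
principal_components <- function(residual_matrix, n_pcs = 12) {
  if (n_pcs <= 0) stop("n_pcs must be positive")
  n_pcs <- min(n_pcs, nrow(residual_matrix), ncol(residual_matrix))
  pc <- stats::prcomp(t(residual_matrix), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(embeddings = pc$x[, seq_len(n_pcs), drop = FALSE],
       var_explained = ve[seq_len(n_pcs)],
       sdev = pc$sdev)
}

#' Condition-mixing score from an embedding
#'
#' Quantifies whether cells separate by condition: for each cell, the
#' fraction of its `k` nearest neighbors (Euclidean, in the embedding)
#' sharing its condition label, averaged over cells. Under perfect mixing
#' the score is about the majority condition's proportion; under complete
#' separation it approaches 1. Invariant to rotations of the embedding.
#'
#' @param embeddings cells x dims matrix (or a correlation-row matrix).
#' @param condition_labels factor/character per cell.
#' @param k number of neighbors, `k < n` cells.
#' @return score in `[0, 1]`.
#' @export
condition_mixing_score <- function(embeddings, condition_labels, k = 15) {
  n <- nrow(embeddings)
  if (k >= n) stop("k must be < number of cells")
  lab <- as.character(condition_labels)
  if (length(lab) != n) stop("one label per cell required")
  d <- as.matrix(stats::dist(embeddings))
  diag(d) <- Inf
  same <- vapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[seq_len(k)]
    mean(lab[nb] == lab[i])
  }, numeric(1))
  mean(same)
}

# Precomputed row-wise ranks and tie corrections, shared across the
# group-vs-rest tests of every cluster.
.row_ranks <- function(X) {
  R <- t(apply(X, 1, rank))
  tiecor <- apply(X, 1, function(v) {
    t <- rle(sort(v))$lengths
    sum(t^3 - t)
  })
  list(R = R, tiecor = tiecor)
}

# Row-wise rank-sum tests of group vs rest: normal approximation with tie
# and continuity correction, identical to the large-sample branch of
# rank_sum_test but vectorized over thousands of genes. `ranks` may carry
# a precomputed .row_ranks(X).
.rowwise_ranksum <- function(X, in_group, ranks = NULL) {
  n1 <- sum(in_group)
  n2 <- sum(!in_group)
  stopifnot(n1 >= 1, n2 >= 1)
  if (is.null(ranks)) ranks <- .row_ranks(X)
  W <- rowSums(ranks$R[, in_group, drop = FALSE]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - ranks$tiecor / (n * (n - 1)))
  mu <- n1 * n2 / 2
  z <- W - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  p[sigma2 == 0] <- 1
  pmin(p, 1)
}
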