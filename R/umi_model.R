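#' Expected molecule count from observed distinct UMIs
#'
#' In a plate-based protocol each molecule of a gene draws one of `K`
#' possible UMI barcodes (K = 4,096 for a 6 nt UMI), so the number of
#' distinct UMIs observed saturates as the true molecule count grows.
#' Under Poisson occupancy the expected fraction of occupied barcodes for
#' `m` molecules is `1 - exp(-m/K)`; inverting it gives the saturation
#' correction applied to counts:
#' \deqn{\hat m = -K \log(1 - k/K).}
#'
#' The estimate is 0 iff `k = 0`, always `>= k`, and strictly increasing
#' and convex in `k`. A fully saturated gene (`k = K`) has no finite
#' inverse; it is clamped to `k = K - 0.5` before inversion, with a
#' warning, so that downstream totals stay finite.
#'
#' @param k observed distinct UMI count(s), integer in `[0, K]`; vectorized.
#' @param K UMI space size (default 4096).
#' @return estimated molecule count(s), real, `>= k`.
#' @export
expected_molecules <- function(k, K = 4096) {
  if (K < 1) stop("K must be >= 1")
  if (any(k < 0) || any(k > K)) stop("k must lie in [0, K]")
  if (any(k == K)) {
    warning("fully saturated UMI count (k = K) clamped to K - 0.5")
    k[k == K] <- K - 0.5
  }
  -K * log1p(-k / K)
}

#' Expected distinct UMIs from a true molecule count
#'
#' Forward companion of [expected_molecules()]: each of `m` molecules
#' independently picks one of `K` UMI barcodes, so the expected number of
#' distinct barcodes observed is the binomial occupancy
#' `K * (1 - (1 - 1/K)^m)`, which approaches the Poisson form
#' `K * (1 - exp(-m/K))` for large `K`.
#'
#' @param m true molecule count(s), `>= 0`; vectorized.
#' @param K UMI space size.
#' @return expected distinct UMI count(s), in `[0, K)`.
#' @export
expected_distinct_umis <- function(m, K = 4096) {
  if (K < 1) stop("K must be >= 1")
  if (any(m < 0)) stop("m must be >= 0")
  K * (1 - (1 - 1 / K)^m)
}

#' UMI-saturation correction of a count matrix
#'
#' Applies [expected_molecules()] entrywise to the raw distinct-UMI counts.
#' Zeros are preserved (sparsity is untouched) and every barcode's total
#' weakly increases. The result carries real values; analyses that need
#' integer counts (dropout thresholds, detection fractions) should keep
#' using the uncorrected matrix.
#'
#' @param matrix a `CountMatrix` of raw distinct-UMI counts.
#' @param K UMI space size.
#' @return `CountMatrix` with corrected real-valued entries.
#' @export
correct_matrix <- function(matrix, K = 4096) {
  stopifnot(inherits(matrix, "CountMatrix"))
  m <- matrix$counts
  if (length(m@x) && max(m@x) > K) {
    idx <- which(as.matrix(m) > K, arr.ind = TRUE)[1, ]
    stop(sprintf("count %g exceeds UMI space K = %d at gene %s, barcode %s",
                 as.matrix(m)[idx[1], idx[2]], K,
                 rownames(m)[idx[1]], colnames(m)[idx[2]]))
  }
  m@x <- expected_molecules(m@x, K)
  out <- matrix
  out$counts <- m
  out
}
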