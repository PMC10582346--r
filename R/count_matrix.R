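#' Construct a CountMatrix
#'
#' A `CountMatrix` is the package's container for a gene x barcode count
#' matrix from one 384-well plate (or any plate-based scRNA-seq run):
#' a sparse non-negative matrix with unique gene symbols as row names,
#' unique barcode identifiers as column names, and a per-barcode metadata
#' table (condition label, well position, spike-in totals, ...).
#'
#' Counts are integers as they come off the counting pipeline, and may be
#' non-negative reals after UMI-saturation correction
#' (see [correct_matrix()]).
#'
#' @param counts matrix or [Matrix::sparseMatrix] (genes x barcodes) with
#'   unique, non-empty dimnames and no negative entries.
#' @param meta optional data.frame of per-barcode metadata, one row per
#'   barcode, in column order of `counts`.
#' @return object of class `CountMatrix`: a list with elements `counts`
#'   (a `dgCMatrix`) and `meta` (a data.frame keyed by barcode).
#' @export
count_matrix <- function(counts, meta = NULL) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts))) {
    if (nrow(counts) > 0)
      stop("counts must carry gene (row) and barcode (column) names")
    rownames(counts) <- character(0)
  }
  if (is.null(colnames(counts))) {
    if (ncol(counts) > 0)
      stop("counts must carry gene (row) and barcode (column) names")
    colnames(counts) <- character(0)
  }
  if (anyDuplicated(rownames(counts)))
    stop("gene symbols must be unique")
  if (anyDuplicated(colnames(counts)))
    stop("barcode identifiers must be unique")
  if (length(counts@x) && min(counts@x) < 0)
    stop("counts must be non-negative")
  if (is.null(meta)) {
    meta <- data.frame(row.names = colnames(counts))
  } else {
    meta <- as.data.frame(meta)
    if (nrow(meta) != ncol(counts))
      stop("meta must have one row per barcode")
    rownames(meta) <- colnames(counts)
  }
  structure(list(counts = counts, meta = meta), class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d barcodes (%.1f%% non-zero)\n",
              nrow(x$counts), ncol(x$counts),
              if (length(x$counts)) 100 * length(x$counts@x) / length(x$counts) else 0))
  if (ncol(x$meta))
    cat("meta:", paste(colnames(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Gene symbols of a CountMatrix
#' @param x a `CountMatrix`.
#' @return character vector of gene symbols.
#' @export
genes <- function(x) rownames(x$counts)

#' Barcode identifiers of a CountMatrix
#' @param x a `CountMatrix`.
#' @return character vector of barcode identifiers.
#' @export
barcodes <- function(x) colnames(x$counts)

#' Move spike-in rows into per-barcode metadata
#'
#' Removes all genes whose symbol starts with `prefix` (ERCC spike-ins by
#' convention) from the matrix and records their per-barcode totals in the
#' metadata column `ercc_count`. Spike-ins are added at a fixed amount per
#' well and act as capture-efficiency controls, so they are carried as a QC
#' covariate rather than as expression.
#'
#' Count conservation holds exactly: for every barcode, the endogenous total
#' of the returned matrix plus its `ercc_count` equals the original total.
#'
#' @param matrix a `CountMatrix`.
#' @param prefix spike-in symbol prefix; matched case-sensitively.
#' @return `CountMatrix` without spike-in rows and with `ercc_count` in
#'   `meta` (zero if no spike-in rows are present).
#' @export
split_spikeins <- function(matrix, prefix = "ERCC-") {
  stopifnot(inherits(matrix, "CountMatrix"))
  is_spike <- startsWith(rownames(matrix$counts), prefix)
  ercc <- if (any(is_spike)) {
    Matrix::colSums(matrix$counts[is_spike, , drop = FALSE])
  } else {
    stats::setNames(numeric(ncol(matrix$counts)), colnames(matrix$counts))
  }
  out <- matrix
  out$counts <- matrix$counts[!is_spike, , drop = FALSE]
  out$meta$ercc_count <- as.numeric(ercc)
  out
}

# Accept a CountMatrix or a plain (sparse) matrix; return base dense matrix.
.as_dense <- function(x) {
  if (inherits(x, "CountMatrix")) x <- x$counts
  as.matrix(x)
}
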