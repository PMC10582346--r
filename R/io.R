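#' Read a count matrix from disk
#'
#' Two dialects are supported. `"mtx_triplet"`: a directory holding
#' `matrix.mtx` (MatrixMarket coordinate, 1-based indices), `genes.tsv`
#' (one symbol per line) and `barcodes.tsv` (column `id`, optionally
#' `condition` and further metadata columns; no header needed for a single
#' column). `"dense_tsv"`: a single TSV with genes as rows, barcodes as
#' columns and a header row of barcode identifiers.
#'
#' @param path directory (`mtx_triplet`) or file (`dense_tsv`).
#' @param format `"mtx_triplet"` or `"dense_tsv"`.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path, format = c("mtx_triplet", "dense_tsv")) {
  format <- match.arg(format)
  if (format == "mtx_triplet") {
    mtx <- file.path(path, "matrix.mtx")
    gf <- file.path(path, "genes.tsv")
    bf <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, gf, bf))
      if (!file.exists(f)) stop("missing file: ", f)
    m <- Matrix::readMM(mtx)
    if (methods::is(m, "nsparseMatrix"))      # pattern matrix: no entries
      m <- methods::as(m, "dMatrix")
    if (length(m@x) && min(m@x) < 0)
      stop("parse error in ", mtx, ": negative entry")
    gene_ids <- readLines(gf)
    # header heuristic: a first line starting with "id" is a header
    first <- readLines(bf, n = 1L)
    if (grepl("^id(\t|$)", first)) {
      bc <- utils::read.delim(bf, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    } else {
      bc <- utils::read.delim(bf, header = FALSE, sep = "\t",
                              stringsAsFactors = FALSE)
      colnames(bc)[1] <- "id"
    }
    if (nrow(m) != length(gene_ids))
      stop("dimension mismatch: matrix.mtx has ", nrow(m),
           " rows but genes.tsv lists ", length(gene_ids), " genes")
    if (ncol(m) != nrow(bc))
      stop("dimension mismatch: matrix.mtx has ", ncol(m),
           " columns but barcodes.tsv lists ", nrow(bc), " barcodes")
    dimnames(m) <- list(gene_ids, bc$id)
    meta <- bc[, setdiff(colnames(bc), "id"), drop = FALSE]
    count_matrix(m, meta)
  } else {
    tab <- utils::read.delim(path, header = TRUE, row.names = 1L,
                             sep = "\t", check.names = FALSE)
    m <- as.matrix(tab)
    if (!is.numeric(m)) stop("parse error in ", path, ": non-numeric entry")
    neg <- which(m < 0, arr.ind = TRUE)
    if (nrow(neg))
      stop("parse error in ", path, ": negative entry at line ",
           neg[1, 1] + 1L, " (gene ", rownames(m)[neg[1, 1]], ")")
    count_matrix(m)
  }
}

#' Write a count matrix to disk
#'
#' Inverse of [read_count_matrix()]: integer matrices round-trip
#' bit-exactly, real-valued (UMI-corrected) matrices are written with 15
#' significant digits.
#'
#' @param matrix a `CountMatrix`.
#' @param path directory (`mtx_triplet`; created if absent) or file
#'   (`dense_tsv`).
#' @param format `"mtx_triplet"` or `"dense_tsv"`.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(matrix, path,
                               format = c("mtx_triplet", "dense_tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(matrix, "CountMatrix"))
  if (format == "mtx_triplet") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    Matrix::writeMM(matrix$counts, file.path(path, "matrix.mtx"))
    writeLines(rownames(matrix$counts), file.path(path, "genes.tsv"))
    ids <- colnames(matrix$counts)
    if (is.null(ids)) ids <- character(0)   # R drops empty dimnames
    bc <- data.frame(id = ids, stringsAsFactors = FALSE)
    if (ncol(matrix$meta)) bc <- cbind(bc, matrix$meta)
    utils::write.table(bc, file.path(path, "barcodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    m <- as.matrix(matrix$counts)
    tab <- data.frame(gene = rownames(m),
                      format(m, digits = 15, trim = TRUE, scientific = FALSE),
                      check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

.plate_wells <- function() {
  as.vector(t(outer(LETTERS[1:16], 1:24, paste0)))
}

#' Read (or default) a 384-well plate layout
#'
#' SORT-seq plates are 384-well (rows A-P, columns 1-24) with a set of
#' wells left empty as a no-template control; the default empty set is
#' O21-O24 and P21-P24. The layout file is YAML with optional keys
#' `empty_wells` (character vector of well ids) and `well_to_barcode`
#' (named mapping).
#'
#' @param config_path YAML file, or `NULL` for the default layout.
#' @return object of class `PlateLayout`: list with `wells` (384 ids,
#'   row-major A1..P24), `empty_wells`, and `well_to_barcode` (possibly
#'   `NULL`).
#' @export
read_plate_layout <- function(config_path = NULL) {
  wells <- .plate_wells()
  empty_default <- c("O21", "O22", "O23", "O24", "P21", "P22", "P23", "P24")
  if (is.null(config_path)) {
    cfg <- list()
  } else {
    cfg <- yaml::read_yaml(config_path)
  }
  empty <- if (is.null(cfg$empty_wells)) empty_default else
    as.character(unlist(cfg$empty_wells))
  bad <- setdiff(empty, wells)
  if (length(bad))
    stop("well id outside A1-P24: ", paste(bad, collapse = ", "))
  w2b <- cfg$well_to_barcode
  if (!is.null(w2b)) {
    bad <- setdiff(names(w2b), wells)
    if (length(bad))
      stop("well id outside A1-P24: ", paste(bad, collapse = ", "))
  }
  structure(list(wells = wells, empty_wells = empty, well_to_barcode = w2b),
            class = "PlateLayout")
}

#' @export
print.PlateLayout <- function(x, ...) {
  cat(sprintf("PlateLayout: %d wells, %d empty (no-template), %d template\n",
              length(x$wells), length(x$empty_wells),
              length(x$wells) - length(x$empty_wells)))
  invisible(x)
}
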