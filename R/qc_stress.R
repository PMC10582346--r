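#' Default QC filtering thresholds
#'
#' The barcode-filtering rule for SORT-seq plates: a barcode is called a
#' successfully captured healthy cell when its total transcript count lies
#' between 800 and 35,000 (inclusive), it has more than 500 genes
#' detected, a transcript-to-gene ratio greater than 1.2, and more than
#' 500 ERCC spike-in counts. Mitochondrial percentage is deliberately not
#' a criterion.
#'
#' @param min_transcripts,max_transcripts inclusive bounds on total
#'   transcripts.
#' @param min_genes strict lower bound on genes detected.
#' @param min_tg_ratio strict lower bound on transcripts/genes.
#' @param min_ercc strict lower bound on spike-in counts.
#' @return list of thresholds, class `QCThresholds`.
#' @export
qc_thresholds <- function(min_transcripts = 800, max_transcripts = 35000,
                          min_genes = 500, min_tg_ratio = 1.2,
                          min_ercc = 500) {
  stopifnot(min_transcripts <= max_transcripts,
            min_transcripts >= 0, min_genes >= 0,
            min_tg_ratio >= 0, min_ercc >= 0)
  structure(list(min_transcripts = min_transcripts,
                 max_transcripts = max_transcripts,
                 min_genes = min_genes,
                 min_tg_ratio = min_tg_ratio,
                 min_ercc = min_ercc),
            class = "QCThresholds")
}

#' Stress-response gene panel
#'
#' Immediate-early and stress genes (transcription factors, signal
#' transducers, heat-shock proteins, pro-apoptotic caspases) that are
#' rapidly induced in brain tissue by dissociation and sorting stress.
#' Matching against a matrix is case-insensitive, so "ARC"/"REM2"
#' variants map onto the mouse symbols Arc/Rem2.
#'
#' @return character vector of 17 gene symbols.
#' @export
stress_panel <- function() {
  c("Atf3", "Arc", "Casp1", "Casp9", "Egr1", "Hsp90aa1", "Hsp90ab1",
    "Hspa1a", "Hspa1b", "Hspa8", "Hspb1", "Hspe1", "Hsph1", "Ier3",
    "Junb", "Rem2", "Socs3")
}

#' Mouse mitochondrial protein-coding genes (GRCm38 symbols)
#' @return character vector of 13 gene symbols, all prefixed "mt-".
#' @export
mito_genes_mouse <- function() {
  c("mt-Nd1", "mt-Nd2", "mt-Co1", "mt-Co2", "mt-Atp8", "mt-Atp6",
    "mt-Co3", "mt-Nd3", "mt-Nd4l", "mt-Nd4", "mt-Nd5", "mt-Nd6",
    "mt-Cytb")
}

#' Per-barcode QC statistics
#'
#' Computes, for every barcode of a spike-in-free matrix (run
#' [split_spikeins()] first so `meta$ercc_count` exists): total
#' transcripts, genes detected (count > 0), transcript/gene ratio,
#' spike-in count, and mitochondrial percentage (100 x mitochondrial /
#' endogenous total). Mitochondrial genes are identified by
#' case-insensitive symbol prefix (default `"mt-"`, the GRCm38
#' convention). All-zero barcodes get ratio 0 and mito_pct 0.
#'
#' @param matrix `CountMatrix` after [split_spikeins()].
#' @param mito_prefix case-insensitive prefix identifying mitochondrial
#'   genes.
#' @return data.frame (one row per barcode, rownames = barcodes) with
#'   columns `total_transcripts`, `genes_detected`, `tg_ratio`,
#'   `ercc_count`, `mito_pct`.
#' @export
per_barcode_stats <- function(matrix, mito_prefix = "mt-") {
  stopifnot(inherits(matrix, "CountMatrix"))
  if (is.null(matrix$meta$ercc_count))
    stop("meta lacks ercc_count; run split_spikeins() first")
  m <- matrix$counts
  total <- Matrix::colSums(m)
  ngene <- Matrix::colSums(m > 0)
  ratio <- ifelse(ngene > 0, total / ngene, 0)
  is_mito <- startsWith(tolower(rownames(m)), tolower(mito_prefix))
  mito <- if (any(is_mito))
    Matrix::colSums(m[is_mito, , drop = FALSE]) else numeric(ncol(m))
  mito_pct <- ifelse(total > 0, 100 * mito / total, 0)
  data.frame(total_transcripts = as.numeric(total),
             genes_detected = as.numeric(ngene),
             tg_ratio = as.numeric(ratio),
             ercc_count = as.numeric(matrix$meta$ercc_count),
             mito_pct = as.numeric(mito_pct),
             row.names = colnames(m))
}

#' Apply the QC filtering rule
#'
#' @param stats output of [per_barcode_stats()].
#' @param thresholds a [qc_thresholds()] object.
#' @return named logical vector: `TRUE` for barcodes passing all four
#'   criteria.
#' @export
filter_barcodes <- function(stats, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "QCThresholds"))
  pass <- stats$total_transcripts >= thresholds$min_transcripts &
    stats$total_transcripts <= thresholds$max_transcripts &
    stats$genes_detected > thresholds$min_genes &
    stats$tg_ratio > thresholds$min_tg_ratio &
    stats$ercc_count > thresholds$min_ercc
  stats::setNames(pass, rownames(stats))
}

#' Compare mitochondrial percentage between conditions
#'
#' Summarizes `mito_pct` per condition (mean, median, n) and tests the
#' difference with an unpaired rank-sum test. Run before filtering to
#' assess the state of all sorted barcodes, and after filtering to see
#' whether differences persist among good-quality cells.
#'
#' @param stats output of [per_barcode_stats()] (optionally subset to
#'   filtered barcodes).
#' @param condition_labels character/factor, one label per row of `stats`;
#'   exactly two conditions, each with `>= 2` barcodes.
#' @return list with `summary` (data.frame per condition) and `p_value`.
#' @export
mito_comparison <- function(stats, condition_labels) {
  lab <- as.character(condition_labels)
  conds <- sort(unique(lab))
  if (length(conds) != 2) stop("exactly two conditions required")
  groups <- split(stats$mito_pct, lab)
  if (any(lengths(groups) < 2)) stop("each condition needs >= 2 barcodes")
  summ <- data.frame(condition = conds,
                     mean = vapply(groups, mean, 0)[conds],
                     median = vapply(groups, stats::median, 0)[conds],
                     n = as.integer(lengths(groups)[conds]),
                     row.names = NULL)
  tst <- rank_sum_test(groups[[conds[1]]], groups[[conds[2]]])
  list(summary = summ, p_value = tst$p_value)
}

#' Stress-gene panel comparison between conditions
#'
#' For each panel gene (matched case-insensitively against matrix
#' symbols): the fraction of cells with raw count > 0 per condition, the
#' mean normalized expression per condition (Pearson residuals shifted
#' per gene to be non-negative, so means are comparable dot-plot style),
#' an unpaired rank-sum p on normalized expression, and BH adjustment
#' across the matched panel genes only. Unmatched panel genes are
#' reported in the `unmatched` attribute, not fatal.
#'
#' @param normalized genes x cells matrix of normalized expression
#'   (e.g. [pearson_residual_normalize()] of the filtered matrix).
#' @param raw `CountMatrix` or matrix of raw counts, same cells.
#' @param condition_labels two-condition labels per cell.
#' @param panel character vector of panel gene symbols.
#' @return data.frame, one row per matched panel gene, with columns
#'   `gene`, `frac_pos_<cond>`, `mean_expr_<cond>`, `p_value`, `p_adj`;
#'   attribute `unmatched` lists panel genes absent from the matrix.
#' @export
stress_panel_summary <- function(normalized, raw, condition_labels,
                                 panel = stress_panel()) {
  rawm <- .as_dense(raw)
  lab <- as.character(condition_labels)
  conds <- sort(unique(lab))
  if (length(conds) != 2) stop("exactly two conditions required")
  sym <- rownames(normalized)
  hit <- match(tolower(panel), tolower(sym))
  unmatched <- panel[is.na(hit)]
  matched <- panel[!is.na(hit)]
  rows <- hit[!is.na(hit)]
  if (!length(rows)) stop("no panel gene present in the matrix")
  res <- lapply(seq_along(rows), function(i) {
    g <- rows[i]
    expr <- normalized[g, ] - min(normalized[g, ])
    by <- split(expr, lab)
    pos <- split(rawm[g, ] > 0, lab)
    p <- rank_sum_test(by[[conds[1]]], by[[conds[2]]])$p_value
    c(frac1 = mean(pos[[conds[1]]]), frac2 = mean(pos[[conds[2]]]),
      mean1 = mean(by[[conds[1]]]), mean2 = mean(by[[conds[2]]]), p = p)
  })
  res <- do.call(rbind, res)
  out <- data.frame(gene = sym[rows],
                    frac1 = res[, "frac1"], frac2 = res[, "frac2"],
                    mean1 = res[, "mean1"], mean2 = res[, "mean2"],
                    p_value = res[, "p"],
                    p_adj = bh_fdr(res[, "p"]),
                    row.names = NULL)
  colnames(out)[2:5] <- c(paste0("frac_pos_", conds),
                          paste0("mean_expr_", conds))
  attr(out, "unmatched") <- unmatched
  out
}
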