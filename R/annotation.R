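#' Non-overlapping exon length per gene from a GTF
#'
#' For every gene, the length of the union of all its exonic intervals
#' across all transcripts (so bases covered by several transcripts are
#' counted once). Coordinates are taken as 1-based inclusive, the GTF
#' convention. The union is computed per `gene_id` and reported under
#' `gene_name` where available; when several gene ids share a symbol the
#' longest union is kept, with a warning.
#'
#' @param gtf_path path to a GTF file (Ensembl dialect: attributes
#'   `gene_id` and optionally `gene_name`) with `exon` features.
#' @return data.frame with columns `gene_symbol` and `exon_length_bp`
#'   (positive integer), one row per gene.
#' @export
compute_exon_lengths <- function(gtf_path) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) {
    warning("no exon features in ", gtf_path)
    return(data.frame(gene_symbol = character(), exon_length_bp = integer()))
  }
  ids <- as.character(gr$gene_id)
  by_gene <- GenomicRanges::split(gr, ids)
  len <- vapply(by_gene,
                function(g) sum(IRanges::width(GenomicRanges::reduce(g))),
                integer(1))
  sym <- vapply(by_gene, function(g) {
    nm <- g$gene_name
    if (!is.null(nm) && length(nm) && !is.na(nm[1])) as.character(nm[1])
    else as.character(g$gene_id[1])
  }, character(1))
  out <- data.frame(gene_symbol = sym, exon_length_bp = as.integer(len),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene_symbol)) {
    warning("multiple gene ids share a symbol; keeping the longest exon union")
    out <- out[order(out$gene_symbol, -out$exon_length_bp), ]
    out <- out[!duplicated(out$gene_symbol), ]
    rownames(out) <- NULL
  }
  out
}
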