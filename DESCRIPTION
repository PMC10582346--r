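Package: fixbench
Title: Benchmarking Fixation Effects in Plate-Based Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the effect of a preservation treatment (such as
    methanol fixation) on plate-based single-cell RNA-seq data. Given a
    reference ("fresh") and a treated ("fixed") 384-well SORT-seq count
    matrix, the package runs a battery of paired comparisons: barcode-level
    quality control and filtering, mitochondrial and stress-gene signatures,
    ambient-RNA contamination estimated by a two-source multinomial mixture
    EM, dropout curves over expression thresholds, exon-length-dependent
    transcript loss, pseudo-bulk transcriptome concordance, and cell-type
    composition shifts. Includes a Poisson-occupancy model for UMI
    saturation in a finite barcode space and a synthetic SORT-seq plate
    generator with full ground truth so every comparison is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    methods,
    yaml,
    jsonlite,
    cluster,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
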