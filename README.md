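# fixbench

Benchmarking the effect of a preservation treatment — methanol fixation
in the motivating use case — on plate-based single-cell RNA-seq.

Fixation lets primary tissue be stored between dissociation and library
preparation, but it can leak cytoplasmic mRNA into the ambient pool,
preferentially lose long transcripts, and shift cell-type composition;
it can also *protect* cells from sorting-induced stress. Given a paired
design — one fresh (reference) and one fixed (treated) 384-well SORT-seq
plate — `fixbench` runs the full comparison battery:

* **QC and filtering** — per-barcode transcripts, genes,
  transcript/gene ratio, ERCC spike-ins, mitochondrial %; the
  four-criteria filtering rule (totals in [800, 35,000], >500 genes,
  ratio >1.2, >500 ERCC counts).
* **UMI saturation model** — distinct-UMI counts in a K = 4,096 barcode
  space saturate as `K(1-(1-1/K)^m)`; counts are corrected by the
  Poisson-occupancy inverse `-K log(1 - k/K)`.
* **Stress signature** — a 17-gene immediate-early/heat-shock panel,
  rank-sum tested with BH correction.
* **Ambient RNA / leakage** — per-cell contamination fraction by a
  two-source multinomial mixture EM against the ambient profile of
  filter-failing barcodes, anchored on each cluster's ambient-only gene
  support.
* **Dropout curves** — genes detected at nine increasing raw-count
  thresholds, per threshold rank-sum + FDR.
* **Transcript-length bias** — non-overlapping exon lengths from a GTF,
  20 equal-count length bins, fresh/fixed expression ratios and their
  Spearman trend over bins.
* **Concordance and taxonomy** — pseudo-bulk Pearson correlation
  (log1p), PCA, a k-nearest-neighbour condition-mixing score, k-means
  clustering with silhouette-selected k, the three-criteria marker rule,
  identity assignment from a dentate-gyrus marker panel, and
  composition-shift tables.

A synthetic SORT-seq generator (`simulate_pair()`) produces paired
plates with known ground truth — cell types, contamination fractions,
damaged wells, true molecule counts — and controllable artifact knobs
(leakage, contamination, length decay, stress induction, damage), so
the whole pipeline is testable without external data.

## Worked example

```r
library(fixbench)

params <- fixation_sim_params()          # default moderate artifacts
pair   <- simulate_pair(params, seed = 42)
report <- run_compare(pair$fresh$matrix, pair$fixed$matrix,
                      annotation = pair$annotation, seed = 7)
report
#> ComparisonReport
#>   barcodes: fixed=384, fresh=384
#>   passing QC: fixed=376, fresh=260
#>   pseudo-bulk concordance r = 0.927
#>   condition mixing score = 0.970
#>   clusters: k = 11; identities: oligodendrocyte, mature_neuron, ...
```

Reading the numbers: far fewer fresh barcodes pass QC (damaged fresh
cells fail the transcript floor — fixation preserved more healthy
cells); the two conditions' pseudo-bulk transcriptomes still correlate
at r ≈ 0.93; the mixing score near 1 reflects the condition-wide
expression shifts (stress induction in fresh, length decay in fixed)
that pooled normalization without integration leaves in PC space.
`write_report(report, "out/")` emits a deterministic `report.json` plus
one TSV per table.

The same battery is available as stepwise drivers:

```sh
Rscript analysis/01_simulate.R     # paired plates + ground truth -> results/sim
Rscript analysis/02_qc_stress.R    # QC, filtering, mito %, stress panel
Rscript analysis/03_leakage.R      # ambient EM, dropout, length bins, concordance
Rscript analysis/04_taxonomy.R     # clustering, identities, composition
Rscript analysis/05_report.R       # one-shot run_compare -> results/report
```

For example, `analysis/03_leakage.R` prints:

```
Dropout: 9 of 9 thresholds differ at FDR 0.05
Length bias: fresh/fixed ratio trend over 20 bins rho = 0.97 (p = 6.6e-06)
Pseudo-bulk concordance: Pearson r = 0.929 on log1p means
```

## Layout

```
R/                  package code (all computation lives here)
analysis/           numbered narrative drivers over the package
scripts/acceptance.R  headline-quantity recomputation
tests/testthat/     unit, property and acceptance tests
vignettes/          methods vignette (models, assumptions, choices)
```
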