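test_that("per-barcode stats match hand arithmetic", {
  m <- rbind(geneA = c(90, 0), `mt-Co1` = c(10, 0))
  colnames(m) <- c("bc1", "bc2")
  cm <- count_matrix(m, data.frame(ercc_count = c(600, 0)))
  st <- per_barcode_stats(cm)
  expect_equal(st["bc1", "total_transcripts"], 100)
  expect_equal(st["bc1", "genes_detected"], 2)
  expect_equal(st["bc1", "tg_ratio"], 50)
  expect_equal(st["bc1", "mito_pct"], 10)
  expect_equal(st["bc1", "ercc_count"], 600)
  # degenerate all-zero barcode: ratio and mito default to 0
  expect_equal(unlist(st["bc2", c("total_transcripts", "genes_detected",
                                  "tg_ratio", "mito_pct")], use.names = FALSE),
               c(0, 0, 0, 0))
  # totals equal column sums
  expect_equal(st$total_transcripts, as.numeric(colSums(m)))
  expect_error(per_barcode_stats(count_matrix(m)), "ercc_count")
})

test_that("mito percentage is invariant to spike-in handling", {
  cm <- toy_matrix()  # has an ERCC row
  st <- per_barcode_stats(split_spikeins(cm))
  # bc2: Actb 10, mt-Co1 10 -> 50% regardless of the 3 ERCC counts
  expect_equal(st["bc2", "mito_pct"], 50)
})

test_that("the filtering rule applies its boundaries as stated", {
  st <- data.frame(
    total_transcripts = c(1000, 800, 799, 35000, 35001, 1000, 1000, 1000, 1000, 0),
    genes_detected    = c(600,  600, 600,  600,   600,  500,  501,  600,  600, 0),
    tg_ratio          = c(1.67, 1.33, 1.33, 58.3, 58.3,  2.0, 1.99, 1.2,  1.3, 0),
    ercc_count        = c(600,  600,  600,  600,  600,  600,  600,  600,  500, 600),
    mito_pct          = c(10, 90, 10, 10, 10, 10, 10, 10, 10, 0),
    row.names = paste0("b", 1:10)
  )
  pass <- filter_barcodes(st, qc_thresholds())
  # hand enumeration: bounds inclusive on transcripts, strict elsewhere;
  # high mito (b2) is NOT a reason to fail
  expect_equal(unname(pass),
               c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE,
                 FALSE, FALSE))
  # idempotent / order-independent
  shuffled <- st[sample(nrow(st)), ]
  expect_equal(filter_barcodes(shuffled)[rownames(st)], pass)
})

test_that("damaged wells fail QC more often than intact wells", {
  p <- small_params(damaged_frac = 0.4)
  pl <- simulate_plate(p, "fresh", seed = 31)
  fl <- plate_filtered(pl)
  truth <- pl$truth
  pass_cells <- fl$pass[truth$barcode]
  expect_lt(mean(pass_cells[truth$damaged]),
            mean(pass_cells[!truth$damaged]))
})

test_that("mito comparison summarizes and tests between conditions", {
  st <- data.frame(mito_pct = c(1, 2, 3, 1, 2, 3),
                   row.names = paste0("b", 1:6))
  same <- mito_comparison(st, rep(c("fresh", "fixed"), each = 3))
  expect_equal(same$summary$mean[1], same$summary$mean[2])
  expect_equal(same$p_value, 1, tolerance = 0.01)
  expect_error(mito_comparison(st, rep("fresh", 6)), "two conditions")

  # damaged fresh wells push pre-filter mito up; filtering shrinks the gap
  p <- small_params(damaged_frac = 0.3)
  signs <- vapply(1:8, function(s) {
    pair <- simulate_pair(p, seed = 7000 + s)
    fr <- plate_filtered(pair$fresh)
    fx <- plate_filtered(pair$fixed)
    st <- rbind(fr$stats[!fr$endo$meta$is_empty, ],
                fx$stats[!fx$endo$meta$is_empty, ])
    cond <- rep(c("fresh", "fixed"), each = 376)
    pre <- mito_comparison(st, cond)$summary
    gap_pre <- pre$mean[pre$condition == "fresh"] -
      pre$mean[pre$condition == "fixed"]
    keep <- c(fr$pass[!fr$endo$meta$is_empty],
              fx$pass[!fx$endo$meta$is_empty])
    post <- mito_comparison(st[keep, ], cond[keep])$summary
    gap_post <- post$mean[post$condition == "fresh"] -
      post$mean[post$condition == "fixed"]
    c(gap_pre > 0, gap_post < gap_pre)
  }, logical(2))
  expect_gte(mean(signs[1, ]), 0.9)   # fresh higher before filtering
  expect_gte(mean(signs[2, ]), 0.9)   # filtering shrinks the difference
})

test_that("stress panel summary reports matched genes and flags unmatched", {
  set.seed(41)
  genes <- c("Arc", "Junb", "Other1", "Other2")
  m <- matrix(rpois(4 * 40, 5), 4, 40,
              dimnames = list(genes, paste0("c", 1:40)))
  cond <- rep(c("fresh", "fixed"), each = 20)
  resid <- pearson_residual_normalize(m)
  out <- stress_panel_summary(resid, m, cond, panel = c("ARC", "Junb", "Nope"))
  expect_equal(sort(out$gene), c("Arc", "Junb"))   # case-insensitive match
  expect_equal(attr(out, "unmatched"), "Nope")
  expect_true(all(out$p_adj >= out$p_value))
  expect_error(stress_panel_summary(resid, m, cond, panel = "Absent"),
               "no panel gene")
})
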