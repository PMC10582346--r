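test_that("silhouette-selected k-means recovers constructed blobs", {
  set.seed(61)
  centers <- rbind(c(0, 0), c(12, 0), c(0, 12))
  emb <- do.call(rbind, lapply(1:3, function(i)
    sweep(matrix(rnorm(60), 30, 2), 2, centers[i, ], "+")))
  rownames(emb) <- paste0("c", 1:90)
  cl <- cluster_cells(emb, k_range = 2:6, seed = 2)
  expect_equal(cl$k, 3)
  truth <- rep(1:3, each = 30)
  expect_equal(mclust::adjustedRandIndex(cl$labels, truth), 1)
  # duplicating every cell preserves the structure
  cl2 <- cluster_cells(rbind(emb, emb), k_range = 2:6, seed = 2)
  expect_equal(cl2$k, 3)
  expect_error(cluster_cells(emb[1:3, ], 2:3), ">= 4")
})

test_that("marker criteria behave at maximal and null contrast", {
  set.seed(62)
  n_in <- 50; n_out <- 150
  raw <- matrix(rpois((n_in + n_out) * 3, 2), 3)
  rownames(raw) <- c("specific", "uniform", "weak")
  colnames(raw) <- paste0("c", seq_len(n_in + n_out))
  raw["specific", ] <- c(rpois(n_in, 10), rep(0, n_out))
  lab <- rep(c("A", "B"), c(n_in, n_out))
  # a few cells may be all-zero across the 3 toy genes; zeroed residuals
  # are the documented behaviour there
  norm <- suppressWarnings(pearson_residual_normalize(raw))
  mk <- find_markers(norm, raw, lab)
  row_s <- mk[mk$cluster == "A" & mk$gene == "specific", ]
  expect_true(row_s$pass)
  expect_gte(row_s$pct1 / row_s$pct2, 2.5)
  row_u <- mk[mk$cluster == "A" & mk$gene == "uniform", ]
  expect_false(row_u$pass)
  expect_lt(abs(row_u$logfc), 0.5)
  # invariance to cell order
  perm <- sample(n_in + n_out)
  mk2 <- find_markers(norm[, perm], raw[, perm], lab[perm])
  expect_equal(mk2[order(mk2$cluster, mk2$gene), "p_value"],
               mk[order(mk$cluster, mk$gene), "p_value"])
  expect_error(find_markers(norm, raw, rep("A", 200)), ">= 2 clusters")
})

test_that("simulated type markers are recovered for every cluster", {
  p <- small_params()
  okay <- vapply(1:5, function(s) {
    pl <- simulate_plate(p, "fixed", seed = 70 + s)
    fl <- plate_filtered(pl)
    truth <- pl$truth; rownames(truth) <- truth$barcode
    types <- truth[colnames(fl$counts), "true_type"]
    norm <- pearson_residual_normalize(fl$counts)
    mk <- find_markers(norm, fl$counts, types)
    panel <- default_identity_panel()
    all(vapply(names(panel), function(ty) {
      hits <- mk[mk$cluster == ty & mk$gene %in% panel[[ty]], "pass"]
      any(hits)
    }, logical(1)))
  }, logical(1))
  expect_gte(mean(okay), 0.9)
})

test_that("identity assignment follows the marker panel and handles gaps", {
  set.seed(63)
  genes <- c("Csf1r", "Cx3cr1", "Mbp", "Plp1", "Filler1", "Filler2")
  n <- 40
  norm <- matrix(rnorm(length(genes) * n, sd = 0.1), length(genes), n,
                 dimnames = list(genes, paste0("c", 1:n)))
  lab <- rep(c("k1", "k2"), each = n / 2)
  norm[c("Csf1r", "Cx3cr1"), lab == "k1"] <- 3
  norm[c("Mbp", "Plp1"), lab == "k2"] <- 3
  panel <- default_identity_panel()
  expect_warning(ids <- assign_identities(norm, lab, panel),
                 "never assigned")
  expect_equal(unname(ids[c("k1", "k2")]),
               c("microglia", "oligodendrocyte"))
  expect_error(assign_identities(norm[5:6, , drop = FALSE], lab, panel),
               "no panel gene")
})

test_that("end-to-end identity recovery on simulated plates exceeds 95%", {
  p <- small_params()
  pl <- simulate_plate(p, "fixed", seed = 64)
  fl <- plate_filtered(pl)
  truth <- pl$truth; rownames(truth) <- truth$barcode
  types <- truth[colnames(fl$counts), "true_type"]
  norm <- pearson_residual_normalize(fl$counts)
  pcs <- principal_components(norm, 12)
  cl <- cluster_cells(pcs$embeddings, seed = 3)
  ids <- assign_identities(norm, cl$labels)
  per_cell <- unname(ids[as.character(cl$labels)])
  expect_gte(mean(per_cell == types), 0.95)
})

test_that("composition tables conserve counts", {
  ids <- c("a", "a", "a", "b", "a", "b", "b", "b")
  cond <- rep(c("x", "y"), each = 4)
  out <- composition_table(ids, cond)
  expect_equal(unname(out$proportions[, "x"]), c(0.75, 0.25))
  expect_equal(unname(out$proportions[, "y"]), c(0.25, 0.75))
  expect_equal(colSums(out$proportions), c(x = 1, y = 1))
  expect_equal(sum(out$counts), length(ids))
  expect_error(composition_table(ids, cond[1:3]), "aligned")
})

test_that("per-identity concordance scores identities and skips small ones", {
  set.seed(65)
  n <- 60
  resid <- matrix(rnorm(40 * n), 40, n,
                  dimnames = list(paste0("g", 1:40), paste0("c", 1:n)))
  ids <- c(rep("big", 56), rep("tiny", 4))
  cond <- rep(c("fresh", "fixed"), n / 2)
  cond[ids == "tiny"] <- "fresh"        # tiny has one condition: skipped
  out <- per_identity_concordance(resid, ids, cond)
  expect_equal(out$skipped, "tiny")
  expect_equal(out$scores$identity, "big")
  # no condition structure: score near the balanced null
  expect_lt(out$scores$mixing_score, 0.65)
  # injected condition shift raises the score above the null band
  resid2 <- resid
  resid2[1:10, cond == "fixed" & ids == "big"] <-
    resid2[1:10, cond == "fixed" & ids == "big"] + 4
  out2 <- per_identity_concordance(resid2, ids, cond)
  expect_gt(out2$scores$mixing_score, out$scores$mixing_score + 0.2)
})
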