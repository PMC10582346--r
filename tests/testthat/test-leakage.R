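test_that("ambient profile is the count-weighted background average", {
  m <- rbind(A = c(3, 1), B = c(1, 3))
  colnames(m) <- c("bg1", "bg2")
  cm <- count_matrix(m, data.frame(ercc_count = c(0, 0)))
  expect_equal(unname(ambient_profile(cm, "bg1")), c(0.75, 0.25))
  # weighting is by counts: doubling a barcode's counts doubles its weight
  m2 <- cbind(m, bg3 = 2 * m[, "bg1"])
  cm2 <- count_matrix(m2)
  p_all <- ambient_profile(cm2, c("bg1", "bg3"))
  expect_equal(unname(p_all), c(0.75, 0.25))   # same direction, triple mass
  expect_error(ambient_profile(cm, character(0)), "non-empty")
  zero <- count_matrix(matrix(0, 2, 1, dimnames = list(c("A", "B"), "z")))
  expect_error(ambient_profile(zero, "z"), "zero total")
})

test_that("EM recovers a null when ambient is orthogonal to the clusters", {
  set.seed(51)
  n_genes <- 200
  phi1 <- c(rep(1, 80), rep(0, 120)); phi1 <- phi1 / sum(phi1)
  phi2 <- c(rep(0, 80), rep(1, 80), rep(0, 40)); phi2 <- phi2 / sum(phi2)
  amb <- c(rep(0, 160), rep(1, 40)); amb <- amb / sum(amb)
  cells <- cbind(
    vapply(1:30, function(i) rmultinom(1, 2000, phi1)[, 1], numeric(n_genes)),
    vapply(1:30, function(i) rmultinom(1, 2000, phi2)[, 1], numeric(n_genes)))
  rownames(cells) <- paste0("g", 1:n_genes)
  colnames(cells) <- paste0("c", 1:60)
  est <- estimate_contamination(cells, rep(c("z1", "z2"), each = 30), amb)
  expect_lte(mean(est$rho), 0.02)
  expect_true(all(diff(est$loglik) >= -1e-6))
})

test_that("EM log-likelihood is non-decreasing on realistic mixtures", {
  p <- small_params()
  sim <- simulate_mixture_cells(p, 60, rho = 0.15, seed = 52)
  est <- estimate_contamination(sim$counts, sim$types, sim$ambient)
  expect_true(all(diff(est$loglik) >= -1e-6))
  expect_true(all(est$rho >= 0 & est$rho <= 1))
  # singleton clusters are allowed but flagged
  labs <- sim$types; labs[1] <- "lonely"
  expect_warning(
    est2 <- estimate_contamination(sim$counts, labs, sim$ambient),
    "singleton")
  expect_equal(est2$flagged_clusters, "lonely")
  expect_error(estimate_contamination(sim$counts[, 0], character(0),
                                      sim$ambient), "empty")
})

test_that("dropout curves count thresholded genes exactly", {
  m <- matrix(c(1, 5, 10, 0, 0, 0,
                2, 2, 2, 2, 0, 0), ncol = 2,
              dimnames = list(paste0("g", 1:6), c("c1", "c2")))
  m4 <- cbind(m, m)                      # two cells per condition
  colnames(m4) <- c("c1", "c2", "c3", "c4")
  cond <- c("fresh", "fixed", "fresh", "fixed")
  out <- dropout_curve(m4, cond, thresholds = c(1, 5, 10))
  expect_equal(unname(out$counts["c1", ]), c(3, 2, 1))
  expect_equal(unname(out$counts["c2", ]), c(4, 0, 0))
  expect_true(all(apply(out$counts, 1, function(r) all(diff(r) <= 0))))
  expect_error(dropout_curve(m4, cond, numeric(0)), "non-empty")
  expect_error(dropout_curve(m4, cond, c(5, 5)), "increasing")
})

test_that("threshold-1 dropout counts equal genes detected", {
  p <- small_params()
  pl <- simulate_plate(p, "fixed", seed = 53)
  fl <- plate_filtered(pl)
  cond <- rep(c("a", "b"), length.out = sum(fl$pass))
  out <- dropout_curve(fl$counts, cond)
  expect_equal(unname(out$counts[, "ge_1"]),
               fl$stats$genes_detected[fl$pass])
  # aggregation invariant to cell order
  perm <- sample(ncol(fl$counts))
  out2 <- dropout_curve(fl$counts[, perm], cond[perm])
  expect_equal(out2$table$p_value, out$table$p_value)
})

test_that("pseudobulk is the per-condition mean and is duplication-stable", {
  m <- matrix(c(1, 2, 3, 5, 4, 0), 3, 2,
              dimnames = list(paste0("g", 1:3), c("c1", "c2")))
  pb <- pseudobulk(m, c("fresh", "fixed"))
  expect_equal(unname(pb[, "fresh"]), m[, "c1"], ignore_attr = TRUE)
  expect_equal(unname(pb[, "fixed"]), m[, "c2"], ignore_attr = TRUE)
  # two identical cells average to either
  pb2 <- pseudobulk(cbind(m, c3 = m[, "c1"]),
                    c("fresh", "fixed", "fresh"))
  expect_equal(pb2[, "fresh"], pb[, "fresh"])
  # duplicating the whole cohort changes nothing
  pb3 <- pseudobulk(cbind(m, m), rep(c("fresh", "fixed"), 2))
  expect_equal(pb3, pb)
})

test_that("length bins partition genes with equal counts and flat null ratios", {
  set.seed(54)
  n <- 203
  ann <- data.frame(gene_symbol = paste0("g", 1:n),
                    exon_length_bp = sample(500:100000, n))
  pb <- setNames(runif(n, 1, 10), ann$gene_symbol)
  out <- length_ratio_analysis(pb, pb, ann, n_bins = 20)
  expect_equal(sum(out$table$n_genes), n)
  expect_true(all(abs(out$table$n_genes - n / 20) <= 1))
  expect_true(all(out$table$mean_ratio == 1))
  expect_gt(out$trend_p, 0.9)
  # ranges are ordered and non-overlapping
  expect_true(all(diff(out$table$length_min) > 0))
  expect_true(all(out$table$length_max[-20] <= out$table$length_min[-1]))
  expect_error(length_ratio_analysis(pb[1:10], pb[1:10], ann, 20), "fewer genes")
  # unannotated genes are dropped with a warning
  expect_warning(
    length_ratio_analysis(c(pb, extra = 5), c(pb, extra = 5), ann, 20),
    "without length annotation")
})

test_that("pseudobulk concordance is 1 on identical input and order-invariant", {
  set.seed(55)
  pb <- setNames(rexp(100, 0.1), paste0("g", 1:100))
  expect_equal(pseudobulk_concordance(pb, pb)$r, 1)
  pb2 <- pb * exp(rnorm(100, sd = 0.2))
  r12 <- pseudobulk_concordance(pb, pb2)$r
  perm <- sample(100)
  expect_equal(pseudobulk_concordance(pb[perm], pb2)$r, r12)
  expect_error(pseudobulk_concordance(pb[1:2], pb[1:2]), ">= 3")
})
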