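test_that("exact rank-sum equals the exhaustive permutation oracle", {
  # printed example: complete separation of 3 vs 3
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(perm_ranksum_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
  # property: all group sizes up to 6, random tie-free data
  set.seed(5)
  for (n in 2:6) for (m in 2:6) {
    x <- sample(100, n)
    y <- sample(100, m) + 0.5      # half-offset precludes ties
    expect_equal(rank_sum_test(x, y)$p_value, perm_ranksum_p(x, y),
                 info = sprintf("n=%d m=%d", n, m))
  }
})

test_that("large-sample approximation tracks the exact branch at n = 8", {
  set.seed(6)
  diffs <- vapply(1:10, function(rep) {
    x <- rnorm(8)
    y <- rnorm(8, 0.5)
    exact <- perm_ranksum_p(x, y)
    approx <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))$p.value
    abs(exact - approx)
  }, numeric(1))
  # oracle-computed bound: the continuity-corrected normal approximation
  # sits within ~0.011 of the exact distribution at this size
  expect_lt(max(diffs), 0.02)
  expect_lt(median(diffs), 0.01)
})

test_that("degenerate and paired rank-sum cases follow the conventions", {
  expect_equal(rank_sum_test(c(2, 2), c(2, 2))$p_value, 1)
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3), paired = TRUE)$p_value, 1)
  expect_error(rank_sum_test(1, c(1, 2)), ">= 2")
  expect_error(rank_sum_test(c(1, 2), c(1, 2, 3), paired = TRUE), "equal lengths")
  # paired signed-rank drops zero differences
  res <- rank_sum_test(c(5, 3, 1, 7), c(5, 1, 3, 2), paired = TRUE)
  expect_true(res$p_value > 0 && res$p_value <= 1)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(rep(0.5, 10)), rep(0.5, 10))
  p <- c(0.001, 0.2, 0.04, 0.9)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_equal(order(adj), order(p))   # monotone transform
  # re-application is stable on plateaued outputs
  expect_equal(bh_fdr(c(0.03, 0.03, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Pearson residuals vanish under the null and respect clipping", {
  profile <- c(5, 3, 2)
  m <- outer(profile, c(1, 2, 4, 8))    # every cell = scaled fixed profile
  dimnames(m) <- list(paste0("g", 1:3), paste0("c", 1:4))
  r <- pearson_residual_normalize(m, theta = Inf)
  expect_lt(max(abs(r)), 1e-6)
  # clipping bound
  set.seed(8)
  x <- matrix(rpois(300, 2), 30, 10)
  x[1, 1] <- 1000
  r2 <- pearson_residual_normalize(x, clip = TRUE)
  expect_lte(max(abs(r2)), sqrt(10))
  # zero-total barcode: residuals zeroed with warning
  x2 <- cbind(x[, 1:3], 0)
  expect_warning(r3 <- pearson_residual_normalize(x2), "zero-total")
  expect_true(all(r3[, 4] == 0))
  expect_error(pearson_residual_normalize(matrix(0, 2, 2)), "grand total")
})

test_that("residual variance is near 1 for NB counts at the modelled theta", {
  set.seed(9)
  n_genes <- 300; n_cells <- 200
  mu_g <- exp(rnorm(n_genes, 1, 1))
  m <- t(vapply(mu_g, function(mu)
    rnbinom(n_cells, mu = mu, size = 100), numeric(n_cells)))
  r <- pearson_residual_normalize(m, theta = 100, clip = FALSE)
  v <- apply(r, 1, var)
  expect_gte(mean(v > 0.5 & v < 2), 0.95)
})

test_that("correlation utilities match definitions", {
  a <- c(1, 2, 3)
  expect_equal(pearson_correlation(a, a), 1)
  expect_equal(pearson_correlation(a, -a), -1)
  expect_equal(pearson_correlation(a, c(1, 2, 4)), 0.98198, tolerance = 1e-5)
  expect_error(pearson_correlation(a, c(1, 1, 1)), "zero variance")
  expect_error(pearson_correlation(a, c(1, 2)), "equal lengths")

  set.seed(10)
  m <- matrix(rnorm(50), 10, 5, dimnames = list(NULL, paste0("c", 1:5)))
  cc <- pairwise_correlation_matrix(m)
  expect_equal(diag(cc), setNames(rep(1, 5), colnames(m)))
  expect_equal(cc, t(cc))
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(cc[i, j], pearson_correlation(m[, i], m[, j]))
  # identical cells correlate at 1; constant cells are zeroed with warning
  dup <- cbind(m[, c(1, 1)], 5)
  expect_warning(cc2 <- pairwise_correlation_matrix(dup), "constant")
  expect_equal(cc2[1, 2], 1)
  expect_equal(cc2[3, 1], 0)
})

test_that("hierarchical ordering keeps constructed blocks contiguous", {
  set.seed(12)
  base1 <- rnorm(20); base2 <- rnorm(20)
  m <- cbind(replicate(4, base1 + rnorm(20, sd = 0.1)),
             replicate(4, base2 + rnorm(20, sd = 0.1)))
  colnames(m) <- paste0("c", 1:8)
  cc <- pairwise_correlation_matrix(m)
  ord <- hierarchical_order(cc)$order
  blocks <- rep(1:2, each = 4)[ord]
  expect_equal(length(rle(blocks)$lengths), 2)   # each block contiguous
  # identical rows merge at height 0
  cc2 <- pairwise_correlation_matrix(cbind(m[, c(1, 1)], m[, 5:6]))
  expect_equal(min(hierarchical_order(cc2)$tree$height), 0)
  # permutation invariance of the tree heights
  perm <- sample(8)
  h1 <- sort(hierarchical_order(cc)$tree$height)
  h2 <- sort(hierarchical_order(cc[perm, perm])$tree$height)
  expect_equal(h1, h2)
  expect_error(hierarchical_order(matrix(1, 1, 1)), ">= 2")
})

test_that("principal components capture low-rank structure exactly", {
  set.seed(13)
  # rank-1 data: PC1 explains essentially everything
  u <- rnorm(30); v <- rnorm(12)
  m <- outer(u, v)
  pc <- principal_components(m, n_pcs = 3)
  expect_gte(pc$var_explained[1], 0.999)
  expect_true(all(diff(pc$var_explained) <= 1e-12))
  # rank-k data: k PCs reproduce pairwise cell distances
  m2 <- outer(u, v) + outer(rnorm(30), rnorm(12))
  pc2 <- principal_components(m2, n_pcs = 2)
  d_full <- dist(t(m2))
  d_emb <- dist(pc2$embeddings)
  expect_equal(as.numeric(d_emb), as.numeric(d_full), tolerance = 1e-8)
  # reconstruction error decreases with more PCs
  m3 <- matrix(rnorm(30 * 12), 30, 12)
  errs <- vapply(1:5, function(k) {
    pc <- principal_components(m3, n_pcs = k)
    sum((scale(t(m3), scale = FALSE) -
           pc$embeddings %*% t(prcomp(t(m3))$rotation[, 1:k, drop = FALSE]))^2)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_error(principal_components(m3, 0), "positive")
})

test_that("condition mixing score separates blobs and stays null on noise", {
  set.seed(14)
  blob1 <- matrix(rnorm(100 * 2), 100, 2)
  blob2 <- matrix(rnorm(100 * 2, mean = 20), 100, 2)
  lab <- rep(c("a", "b"), each = 100)
  expect_gte(condition_mixing_score(rbind(blob1, blob2), lab, k = 15), 0.95)
  # random labels on one blob: near the 0.5 null
  one <- matrix(rnorm(200 * 2), 200, 2)
  rnd <- sample(rep(c("a", "b"), each = 100))
  s <- condition_mixing_score(one, rnd, k = 15)
  expect_gt(s, 0.4); expect_lt(s, 0.62)
  # rotation invariance
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  expect_equal(condition_mixing_score(one %*% rot, rnd, k = 15), s)
  expect_error(condition_mixing_score(one, rnd, k = 200), "k must be")
})
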