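test_that("contig PCA separates duplicated genotype clusters deterministically", {
  set.seed(20)
  proto_a <- sample(0:2, 40, TRUE)
  proto_b <- sample(0:2, 40, TRUE)
  g <- rbind(matrix(proto_a, 6, 40, byrow = TRUE),
             matrix(proto_b, 6, 40, byrow = TRUE))
  ds <- toy_dataset(g)
  pca <- contig_pca(ds)
  pc1 <- pca$scores$PC1
  expect_lt(max(sd(pc1[1:6]), sd(pc1[7:12])), 1e-8)
  expect_gt(abs(mean(pc1[1:6]) - mean(pc1[7:12])), 1)
  # total variance is conserved across the spectrum
  x <- scale(g, scale = FALSE)
  expect_equal(sum(svd(x)$d^2) / (nrow(g) - 1), sum(x^2) / (nrow(g) - 1))
  # scores match a direct eigendecomposition of the covariance (up to sign)
  ev <- eigen(tcrossprod(x) / (nrow(g) - 1))
  expect_equal(abs(pc1), abs(ev$vectors[, 1] * sqrt(ev$values[1] *
                                                      (nrow(g) - 1))),
               tolerance = 1e-8)
  expect_error(contig_pca(toy_dataset(matrix(1L, 4, 3))), "monomorphic")
})

test_that("duplicated local-PCA windows sit at distance zero", {
  set.seed(21)
  block <- matrix(sample(0:2, 30 * 20, TRUE), 30, 20)
  other <- matrix(sample(0:2, 30 * 40, TRUE), 30, 40)
  g <- cbind(block, other[, 1:20], block, other[, 21:40])
  ds <- toy_dataset(g)
  lp <- local_pca(ds, "c", window_snps = 20, k = 2)
  expect_equal(lp$dist[1, 3], 0, tolerance = 1e-10)
  expect_gt(lp$dist[1, 2], 0.01)
  expect_true(isSymmetric(lp$dist))
  expect_true(all(diag(lp$dist) == 0))
})

test_that("inversion windows separate from collinear windows on MDS1", {
  sim <- fx_inv()
  lp <- local_pca(sim$dataset, "c1", window_snps = 50)
  inside <- lp$windows$start >= 1e6 & lp$windows$end <= 2.5e6
  outside <- lp$windows$end <= 1e6 | lp$windows$start >= 2.5e6
  expect_gt(min(lp$windows$mds1[inside]),
            max(lp$windows$mds1[outside]))
})

test_that("MDS outlier regions merge flagged windows by the gap rule", {
  fake <- function(flag_idx, n = 60) {
    x <- rep(c(-0.01, 0.01), length.out = n)
    x[flag_idx] <- 5
    structure(list(windows = tibble::tibble(
      contig = "c", start = (seq_len(n) - 1) * 1e4,
      end = seq_len(n) * 1e4, n_snps = 10L, mds1 = x),
      dist = NULL, k = 2, contig = "c"), class = "local_pca")
  }
  # gap of 24 unflagged windows between 5 and 30: two regions
  r <- mds_outlier_regions(fake(c(5, 30)))
  expect_equal(nrow(r), 2)
  # gap of exactly 20 (indices 5 and 26): merged
  r2 <- mds_outlier_regions(fake(c(5, 26)))
  expect_equal(nrow(r2), 1)
  expect_equal(r2$start, 4e4)
  expect_equal(r2$end, 26e4)
  expect_equal(r2$n_flagged, 2)
  # single flagged window: one single-window region
  r3 <- mds_outlier_regions(fake(7))
  expect_equal(nrow(r3), 1)
  expect_equal(r3$n_windows, 1)
  # constant scores: none
  cns <- fake(integer(0))
  cns$windows$mds1 <- 0
  expect_equal(nrow(mds_outlier_regions(cns)), 0)
})

test_that("k-means segmentation recovers clean bimodal runs", {
  x <- c(rep(0, 20), rep(10, 8), rep(0, 22))
  res <- structure(list(windows = tibble::tibble(
    contig = "c", start = (0:49) * 1e4, end = (1:50) * 1e4,
    n_snps = 10L, mds1 = x + seq(0, 0.001, length.out = 50)),
    dist = NULL, k = 2, contig = "c"), class = "local_pca")
  segs <- kmeans_mds_segmentation(res, k = 2)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start, 20e4)
  expect_equal(segs$end, 28e4)
  expect_equal(nrow(kmeans_mds_segmentation(res, k = 1)), 0)
  expect_error(kmeans_mds_segmentation(res, k = 99), "exceeds")
})

test_that("pairwise r2 matches direct correlation and the 1/n null level", {
  g <- rbind(c(0L, 0L, 2L), c(1L, 1L, 0L), c(2L, 2L, 1L), c(0L, 0L, 0L))
  ds <- toy_dataset(g, pos = c(0, 2e4, 4e4))
  ld <- ld_r2(ds)
  expect_equal(ld$r2[1, 2], 1)
  expect_equal(ld$r2[1, 3], cor(g[, 1], g[, 3])^2)
  expect_equal(diag(ld$r2), rep(1, 3), ignore_attr = TRUE)
  # independent sites: mean off-diagonal r2 near 1/(n-1)
  set.seed(22)
  n <- 200
  gi <- matrix(rbinom(n * 60, 2, 0.4), nrow = n)
  ldi <- ld_r2(toy_dataset(gi, pos = (0:59) * 2e4))
  off <- ldi$r2[upper.tri(ldi$r2)]
  expect_lt(abs(mean(off) - 1 / (n - 1)), 0.005)
})

test_that("LD block detection finds exactly the planted blocks", {
  m <- 30
  r2 <- matrix(0.05, m, m)
  r2[1:10, 1:10] <- 0.9
  r2[21:30, 21:30] <- 0.9
  diag(r2) <- 1
  ld <- structure(list(pos = (0:(m - 1)) * 1e4, r2 = r2, contig = "c"),
                  class = "ld_matrix")
  blocks <- ld_block_detect(ld)
  expect_equal(nrow(blocks), 2)
  expect_equal(blocks$start, c(0, 20e4))
  expect_equal(blocks$end, c(9e4 + 1, 29e4 + 1))
  # uniform sub-threshold LD: nothing
  ld2 <- ld
  ld2$r2 <- matrix(0.2, m, m); diag(ld2$r2) <- 1
  expect_equal(nrow(ld_block_detect(ld2)), 0)
  # min_span filters out short blocks
  expect_equal(nrow(ld_block_detect(ld, min_span = 1.5e5)), 0)
})

test_that("LD blocks recover a strongly diverged inversion interval", {
  sim <- fx_ldblock()   # near-fixed arrangements drive pairwise r2 up
  thin <- thin_for_ld(sim$dataset)
  blocks <- ld_block_detect(ld_r2(thin, "c1"), min_span = 2e5)
  expect_gte(nrow(blocks), 1)
  j <- max(vapply(seq_len(nrow(blocks)), function(i)
    jaccard_interval(blocks$start[i], blocks$end[i], 2e5, 2.6e6),
    numeric(1)))
  expect_gte(j, 0.8)
})

test_that("scan_contig is quiet on inversion-free data and finds the inversion", {
  sim <- fx_inv()
  regs <- scan_contig(sim$dataset, "c1")
  expect_gte(nrow(regs), 1)
  j <- max(vapply(seq_len(nrow(regs)), function(i)
    jaccard_interval(regs$start[i], regs$end[i], 1e6, 2.5e6), numeric(1)))
  expect_gte(j, 0.7)
  null_regs <- scan_contig(fx_null()$dataset, "c1")
  expect_lte(nrow(null_regs), 1)
})

test_that("MDS1 recovers a one-dimensional latent gradient of structure", {
  # window w carries two sample clusters whose allele-frequency contrast
  # grows linearly with w; the window ordering is a 1-D latent line that
  # MDS1 should recover monotonically
  set.seed(23)
  n <- 60; W <- 20; m <- 30
  cluster <- rep(0:1, each = n / 2)
  cols <- lapply(seq_len(W), function(w) {
    delta <- 0.9 * w / W
    p <- 0.5 + delta * (cluster - 0.5)
    matrix(rbinom(n * m, 2, rep(p, m)), nrow = n)
  })
  ds <- toy_dataset(do.call(cbind, cols))
  lp <- local_pca(ds, "c", window_snps = m, k = 1)
  expect_gt(abs(cor(lp$windows$mds1, seq_len(W), method = "spearman")),
            0.95)
})
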