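test_that("gene enrichment permutation behaves at the boundaries", {
  lens <- c(a = 1e6)
  genes <- tibble::tibble(contig = "a", pos = c(1e5, 3e5, 5e5, 7e5, 9e5))
  # an inversion covering the whole genome can only relocate onto itself:
  # every gene inside in every permutation, p = 1
  all_inv <- tibble::tibble(contig = "a", start = 0, end = 1e6)
  set.seed(60)
  res <- or_enrichment(genes, all_inv, lens, n_perm = 200)
  expect_equal(res$observed, 5)
  expect_equal(res$p, 1)
  # no inversions: observed 0, p = 1
  res0 <- or_enrichment(genes, all_inv[0, ], lens, n_perm = 200)
  expect_equal(res0$observed, 0)
  expect_equal(res0$p, 1)
  expect_error(or_enrichment(genes, tibble::tibble(contig = "a", start = 0,
                                                   end = 2e6), lens),
               "longer than every contig")
})

test_that("permutation mean matches the analytic expectation", {
  # one inversion of length L on one contig of length C with uniform genes:
  # E[genes inside] = n_genes * L / C
  set.seed(61)
  lens <- c(a = 1e6)
  genes <- tibble::tibble(contig = "a", pos = runif(200, 0, 1e6))
  inv <- tibble::tibble(contig = "a", start = 0, end = 2.5e5)
  res <- or_enrichment(genes, inv, lens, n_perm = 2000)
  expected <- 200 * 2.5e5 / 1e6
  se <- sqrt(200 * 0.25 * 0.75)
  expect_lt(abs(res$expected_perm - expected), 3 * se / sqrt(2000) * 50)
  expect_lt(abs(res$expected_perm - expected), 3)
})

test_that("divergence scan flags fixed nonsynonymous OR variants", {
  sim <- fx_dxo()   # fixed_frac 0.75: many fully diverged sites
  kt <- genotype_inversion(sim$dataset, "c1", 2e5, 2.6e6, override = TRUE)
  calls <- tibble::tibble(id = "invD", contig = "c1", start = 2e5,
                          end = 2.6e6)
  scan <- or_divergence_scan(sim$dataset, sim$annotation, calls,
                             list(invD = kt), or_only = TRUE)
  expect_gt(nrow(scan), 0)
  expect_gt(max(scan$max_dxy), 0.9)
  expect_gt(sum(scan$n_diverged), 0)
  # shared polymorphism at 0.5/0.5 is not flagged
  expect_equal(site_dxy(0.5, 0.5), 0.5)
})

test_that("dN/dS and McDonald-Kreitman arithmetic", {
  even <- or_dnds_mk(2, 2, 2, 2, 100, 100)
  expect_equal(even$dnds, 1)
  expect_equal(even$mk_p, 1)
  skewed <- or_dnds_mk(10, 1, 1, 10, 100, 100)
  expect_lt(skewed$mk_p, 0.01)
  nods <- or_dnds_mk(3, 0, 1, 1, 100, 100)
  expect_true(is.infinite(nods$dnds))
  expect_true(nods$dnds_undefined)
  # equal rates on unequal site counts still give 1
  expect_equal(or_dnds_mk(10, 5, 0, 0, 200, 100)$dnds, 1)
})

test_that("coverage contrast flags hemizygous deletions only", {
  kt <- tibble::tibble(sample = sprintf("s%02d", 1:40),
                       genotype = rep(c("AA", "BB"), each = 20))
  set.seed(62)
  equal_depth <- tibble::tibble(
    sample = rep(kt$sample, 2),
    gene_id = rep(c("g1", "g2"), each = 40),
    depth = c(rnorm(40, 20, 1),
              rep(c(20, 10), each = 20) + rnorm(40, 0, 0.5)))
  res <- or_coverage_contrast(equal_depth, kt)
  expect_false(res$flag[res$gene_id == "g1"])
  expect_true(res$flag[res$gene_id == "g2"])
  expect_gt(res$ratio[res$gene_id == "g2"], 1.6)
})

test_that("environment PCA matches closed-form cases", {
  # two perfectly correlated variables: PC1 explains everything
  env <- tibble::tibble(population = c("a", "b", "c", "d"),
                        v1 = c(1, 2, 3, 4), v2 = c(2, 4, 6, 8))
  p <- env_pca(env, n_pc = 2)
  expect_equal(p$explained[1], 1)
  # orthogonal equal-variance pair: 50/50 split
  env2 <- tibble::tibble(population = c("a", "b", "c", "d"),
                         v1 = c(1, 1, -1, -1), v2 = c(1, -1, 1, -1))
  p2 <- env_pca(env2, n_pc = 2)
  expect_equal(p2$explained, c(0.5, 0.5))
  # constant variables are dropped with a warning
  env3 <- dplyr::mutate(env, v3 = 5)
  expect_warning(env_pca(env3), "constant")
  # toy table vs direct eigendecomposition of the correlation matrix
  set.seed(63)
  env4 <- tibble::tibble(population = letters[1:8],
                         v1 = rnorm(8), v2 = rnorm(8), v3 = rnorm(8))
  p4 <- env_pca(env4, n_pc = 3)
  ev <- eigen(cor(as.matrix(env4[, -1])))$values
  expect_equal(p4$explained, ev / sum(ev), tolerance = 1e-10)
})

test_that("ridge LFMM with k = 0 equals ordinary per-locus regression", {
  set.seed(64)
  n <- 50
  Y <- matrix(rbinom(n * 30, 2, 0.4), n)
  X <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "PC1"))
  res <- lfmm_ridge(Y, X, k = 0)
  tvals <- apply(Y, 2, function(y) summary(lm(y ~ X))$coefficients[2, 3])
  expect_equal(res$z, unname(tvals), tolerance = 1e-9)
})

test_that("planted environmental effects are recovered at FDR 10%", {
  set.seed(65)
  n <- 120; m <- 300
  X <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "PC1"))
  Y <- matrix(rbinom(n * m, 2, 0.4) + 0, n)
  hits <- 1:10
  for (j in hits) Y[, j] <- Y[, j] + 0.8 * X[, 1]
  res <- lfmm_ridge(Y, X, k = 3)
  called <- as.integer(sub("locus", "", res$locus[res$q < 0.1]))
  expect_gte(length(intersect(called, hits)), 8)
  expect_lte(length(setdiff(called, hits)), 3)
  # q-values are a monotone step-up transform of p
  o <- order(res$p)
  expect_true(all(diff(res$q[o]) >= -1e-12))
  expect_true(all(res$q >= res$p - 1e-12))
})

test_that("LFMM is invariant to locus order and covariate rescaling", {
  set.seed(66)
  n <- 60; m <- 80
  Y <- matrix(rbinom(n * m, 2, 0.3), n,
              dimnames = list(NULL, paste0("L", 1:m)))
  X <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "PC1"))
  r1 <- lfmm_ridge(Y, X, k = 2)
  perm <- sample(m)
  r2 <- lfmm_ridge(Y[, perm], X, k = 2)
  expect_equal(r2$z[match(r1$locus, r2$locus)], r1$z, tolerance = 1e-9)
  r3 <- lfmm_ridge(Y, 3 * X + 1, k = 2)
  expect_equal(r3$z, r1$z, tolerance = 1e-9)
  expect_error(lfmm_ridge(Y, X, k = 60), "k must be")
})

test_that("inversion-as-locus encoding matches karyotype tables", {
  kt1 <- tibble::tibble(sample = c("a", "b", "c", "d"),
                        genotype = c("AA", "AB", "BB", "unassigned"))
  kt2 <- tibble::tibble(sample = c("a", "b", "c", "d"),
                        genotype = c("AB", "AB", "AB", "AB"))
  m <- inversion_as_locus(list(i1 = kt1, i2 = kt2))
  expect_equal(unname(m[, "i1"]), c(0, 1, 2, NA))
  expect_equal(unname(m[, "i2"]), rep(1, 4))
  expect_equal(rownames(m), kt1$sample)
})

test_that("the full GEA wrapper runs end to end on simulated data", {
  sim <- fx_inv()
  ep <- env_pca(sim$truth$env, n_pc = 2)
  kt <- genotype_inversion(sim$dataset, "c1", 1e6, 2.5e6, override = TRUE)
  excl <- tibble::tibble(contig = "c1", start = 1e6, end = 2.5e6)
  res <- run_gea(sim$dataset, ep$scores, sim$meta, k = 2,
                 covariates = c("PC1", "PC2"), exclude = excl,
                 inversion_loci = list(inv1 = kt))
  expect_s3_class(res, "gea_result")
  expect_true("inv1" %in% res$locus)
  # excluded-SNP bookkeeping: no locus name from inside the inversion
  pos <- as.numeric(sub("c1:", "", res$locus[grepl("^c1:", res$locus)]))
  expect_false(any(pos >= 1e6 & pos < 2.5e6))
  g <- glance(res)
  expect_equal(g$k, 2)
})
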