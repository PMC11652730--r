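test_that("haplotype frequencies count alleles from karyotypes", {
  kt <- tibble::tibble(sample = sprintf("s%02d", 1:20),
                       genotype = c(rep("AA", 10), rep("BB", 10)))
  f <- haplotype_frequencies(kt)
  expect_equal(f$freq_B, 0.5)
  kt2 <- tibble::tibble(sample = sprintf("s%02d", 1:5),
                        genotype = rep("AB", 5))
  f2 <- haplotype_frequencies(kt2)
  expect_equal(f2$freq_A, 0.5)
  expect_equal(f2$freq_B, 0.5)
  # hemizygous single-letter karyotypes count once
  kt3 <- tibble::tibble(sample = sprintf("s%02d", 1:4),
                        genotype = c("AA", "B", "A", "unassigned"))
  f3 <- haplotype_frequencies(kt3)
  expect_equal(f3$n_alleles, 4)
  expect_equal(f3$freq_B, 1 / 4)
})

test_that("simulated arrangement frequencies are recovered within 3 SE", {
  sim <- fx_inv()
  kt <- genotype_inversion(sim$dataset, "c1", 1e6, 2.5e6, override = TRUE)
  f <- haplotype_frequencies(kt, sim$meta, "all")
  truth <- mean(sim$truth$pop_freq$freq_B)
  se <- sqrt(truth * (1 - truth) / f$n_alleles)
  est <- min(f$freq_B, f$freq_A)  # minor arrangement, labels arbitrary
  expect_lt(abs(min(truth, 1 - truth) - est), 3 * se + 0.02)
})

test_that("age estimation is the stated closed form and scales correctly", {
  a <- estimate_age(5.8e-3, 2.9e-9)
  expect_equal(a$t_generations, 1e6)
  expect_equal(a$age_myr, 1)
  expect_equal(estimate_age(0, 1e-9)$t_generations, 0)
  expect_error(estimate_age(0.01, 0), "positive")
  # linear in dxy, inverse in mu
  grid <- expand.grid(dxy = c(1e-3, 4e-3), mu = c(1e-9, 4e-9))
  t_gen <- estimate_age(grid$dxy, grid$mu)$t_generations
  expect_equal(t_gen, grid$dxy / (2 * grid$mu))
})

test_that("age is recovered from a simulated inversion with known divergence", {
  spec <- inversion_spec("c1", 0, 1e6, base_freq = 0.5, arr_fst = 0.4,
                         fixed_frac = 0.05, id = "iv")
  cfg <- sim_config(seed = 41, contigs = c(c1 = 1e6), snp_density = 2e-2,
                    populations = tibble::tibble(
                      population = c("P1", "P2"), group = c("south", "north"),
                      lat = c(46, 62), lon = c(10, 20), alpha = c(0, 1),
                      n = c(30, 30)),
                    inversions = list(spec))
  sim <- simulate_cohort(cfg)
  kar <- sim$truth$karyotypes
  aa <- kar$sample[kar$karyotype == "AA"]
  bb <- kar$sample[kar$karyotype == "BB"]
  dxy <- mean(site_dxy(site_freq(sim$dataset, aa),
                       site_freq(sim$dataset, bb)), na.rm = TRUE)
  mu <- 2.9e-9
  t_est <- estimate_age(dxy, mu)$t_generations
  t_true <- estimate_age(expected_dxy(spec), mu)$t_generations
  expect_lt(abs(t_est / t_true - 1), 0.2)
})

test_that("exact HWE test matches canonical proportions and detects deficit", {
  p1 <- hwe_exact(25, 50, 25)
  expect_gte(p1$p_two, 0.5)
  p2 <- hwe_exact(50, 0, 50)
  expect_lt(p2$p_two, 1e-6)
  expect_equal(p2$direction, "deficit")
  p3 <- hwe_exact(0, 20, 0)
  expect_equal(p3$direction, "excess")
  expect_lt(p3$p_excess, 0.01)
})

test_that("exact HWE p equals full enumeration for n up to 30", {
  for (case in list(c(5, 10, 5), c(12, 2, 6), c(1, 9, 20), c(14, 1, 0),
                    c(10, 10, 10))) {
    nAA <- case[1]; nAB <- case[2]; nBB <- case[3]
    n <- sum(case)
    nA <- 2 * nAA + nAB
    dist <- hwe_enum_oracle(n, nA)
    p_obs <- dist[[as.character(nAB)]]
    p_two <- sum(dist[dist <= p_obs + 1e-12])
    got <- hwe_exact(nAA, nAB, nBB)
    expect_equal(got$p_two, p_two, tolerance = 1e-10)
    hets <- as.numeric(names(dist))
    expect_equal(got$p_excess, sum(dist[hets >= nAB]), tolerance = 1e-10)
    expect_equal(got$p_deficit, sum(dist[hets <= nAB]), tolerance = 1e-10)
  }
})

test_that("X-linked HWE test behaves at the extremes", {
  # balanced female genotypes with male alleles at matching frequency
  ok <- hwe_exact_x(10, 20, 10, 10, 10)
  expect_gt(ok$p_two, 0.2)
  # total female heterozygote deficit
  bad <- hwe_exact_x(20, 0, 20, 10, 10)
  expect_lt(bad$p_two, 1e-4)
  expect_equal(bad$direction, "deficit")
  # monomorphic: p = 1
  expect_equal(hwe_exact_x(10, 0, 0, 10, 0)$p_two, 1)
})

test_that("multi-haplotype karyotypes fall back to the permutation test", {
  set.seed(42)
  kt <- tibble::tibble(
    sample = sprintf("s%02d", 1:60),
    genotype = sample(c("AA", "AB", "BB", "AR", "BR", "RR"), 60, TRUE,
                      prob = c(.25, .3, .15, .12, .12, .06)))
  res <- hwe_test(kt, B = 2000)
  expect_equal(res$method, "permutation")
  expect_true(res$p > 0 && res$p <= 1)
  # hard deficit is flagged
  kt2 <- tibble::tibble(sample = sprintf("s%02d", 1:60),
                        genotype = rep(c("AA", "BB", "RR"), each = 20))
  res2 <- hwe_test(kt2, B = 2000)
  expect_lt(res2$p, 0.01)
  expect_equal(res2$direction, "deficit")
})

test_that("cline test reproduces the closed-form correlation", {
  lat <- c(44, 48, 52, 56, 60, 64)
  f <- 0.1 + 0.01 * (lat - 44)
  ct <- cline_test(f, lat)
  expect_equal(ct$r2, 1)
  f2 <- c(0.2, 0.5, 0.3, 0.6, 0.4, 0.7)
  ct2 <- cline_test(f2, lat)
  # hand closed form
  r_hand <- sum((f2 - mean(f2)) * (lat - mean(lat))) /
    sqrt(sum((f2 - mean(f2))^2) * sum((lat - mean(lat))^2))
  expect_equal(ct2$r, r_hand)
  expect_error(cline_test(rep(0.5, 6), lat), "variance")
  expect_error(cline_test(f[1:4], lat[1:4]), "5")
})

test_that("MAF-matched permutation p behaves at the boundaries and is seeded", {
  sim <- fx_null()
  excl <- tibble::tibble(contig = "c1", start = 0, end = 1)
  set.seed(7)
  # an observed r2 larger than any SNP can reach
  top <- maf_matched_permutation(sim$dataset, sim$meta, observed_r2 = 1.01,
                                 inversion_maf = 0.3, exclude = excl,
                                 n_snps = 300)
  expect_equal(top$p, 0)
  set.seed(7)
  bot <- maf_matched_permutation(sim$dataset, sim$meta, observed_r2 = 0,
                                 inversion_maf = 0.3, exclude = excl,
                                 n_snps = 300)
  expect_equal(bot$p, 1)
  # monotone in the observed r2, reproducible under the same seed
  set.seed(7)
  mid <- maf_matched_permutation(sim$dataset, sim$meta, observed_r2 = 0.2,
                                 inversion_maf = 0.3, exclude = excl,
                                 n_snps = 300)
  expect_true(mid$p >= top$p && mid$p <= bot$p)
  set.seed(7)
  mid2 <- maf_matched_permutation(sim$dataset, sim$meta, observed_r2 = 0.2,
                                  inversion_maf = 0.3, exclude = excl,
                                  n_snps = 300)
  expect_identical(mid, mid2)
  # too few matched SNPs: window widens with warnings until it saturates
  w <- testthat::capture_warnings(
    maf_matched_permutation(sim$dataset, sim$meta, observed_r2 = 0.5,
                            inversion_maf = 0.5, exclude = excl,
                            n_snps = n_variants(sim$dataset)))
  expect_true(any(grepl("widening", w)))
})

test_that("exact G-test separates associated from unassociated phenotypes", {
  set.seed(43)
  kt <- tibble::tibble(sample = sprintf("s%02d", 1:40),
                       genotype = rep(c("AA", "AB", "BB", "AB"), 10))
  # phenotype independent of genotype: large p
  ph <- tibble::tibble(sample = kt$sample,
                       phenotype = sample(c("facultative", "obligate"), 40,
                                          replace = TRUE))
  pa <- phenotype_association(kt, ph, B = 2000)
  expect_gt(pa$p, 0.05)
  # perfectly separating table, 8 vs 8
  kt2 <- tibble::tibble(sample = sprintf("s%02d", 1:16),
                        genotype = rep(c("AA", "BB"), each = 8))
  ph2 <- tibble::tibble(sample = kt2$sample,
                        phenotype = rep(c("facultative", "obligate"),
                                        each = 8))
  pa2 <- phenotype_association(kt2, ph2, B = 10000)
  expect_lte(pa2$p, 0.001)
  expect_error(phenotype_association(
    kt2, tibble::tibble(sample = kt2$sample,
                        phenotype = rep("obligate", 16))), "degenerate")
})

test_that("inversion summaries assemble per-call characterization rows", {
  sim <- fx_inv()
  kt <- genotype_inversion(sim$dataset, "c1", 1e6, 2.5e6, override = TRUE)
  calls <- tibble::tibble(id = "inv1", contig = "c1", start = 1e6,
                          end = 2.5e6)
  s <- summarize_inversions(sim$dataset, calls, list(inv1 = kt), sim$meta)
  expect_equal(nrow(s), 1)
  expect_gt(s$dxy_ab, 0.1)
  expect_equal(s$t_generations, s$dxy_ab / (2 * 2.9e-9))
  expect_true(s$hwe_p > 0 && s$hwe_p <= 1)
  expect_true(is.finite(s$cline_r2))
})
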