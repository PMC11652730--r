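make_load_fixture <- function() {
  # deterministic dataset with labelled synonymous/nonsynonymous sites
  set.seed(50)
  n <- 30; m <- 400
  g <- matrix(rbinom(n * m, 2, rep(runif(m, 0.05, 0.5), each = n)),
              nrow = n)
  ds <- toy_dataset(g, pos = sort(sample(0:(4e5 - 1), m)))
  ann <- tibble::tibble(
    contig = "c", pos = ds$sites$pos,
    inversion = NA_character_,
    coding = rep(c("nonsynonymous", "synonymous", "intergenic"),
                 length.out = m),
    gene_id = sprintf("g%02d", (ds$sites$pos %/% 5e3) %% 50),
    or_flag = FALSE)
  list(ds = ds, ann = ann)
}

test_that("piN/piS windows follow their definition on labelled sites", {
  fx <- make_load_fixture()
  w <- tibble::tibble(contig = "c", start = c(0, 2e5), end = c(2e5, 4e5))
  lw <- pin_pis_windows(fx$ds, fx$ann, rownames(fx$ds$geno), w,
                        group = "ALL", min_genes = 0, min_windows = 1,
                        min_individuals = 4)
  expect_equal(nrow(lw), 2)
  # recompute one window by hand
  pi_site <- site_pi(fx$ds)
  in_w <- fx$ds$sites$pos < 2e5
  ns <- in_w & fx$ann$coding == "nonsynonymous"
  sy <- in_w & fx$ann$coding == "synonymous"
  expect_equal(lw$pi_n[1], mean(pi_site[ns]))
  expect_equal(lw$pi_s[1], mean(pi_site[sy]))
  expect_equal(lw$ratio[1], mean(pi_site[ns]) / mean(pi_site[sy]))
  # equal diversity in the two classes gives ratio 1
  ann1 <- fx$ann
  ann1$coding <- rep(c("nonsynonymous", "synonymous"),
                     length.out = nrow(ann1))
  g1 <- matrix(rep(c(0L, 1L, 2L, 1L), 100), nrow = 4)
  ds1 <- toy_dataset(g1, pos = sort(sample(0:(4e5 - 1), 100)))
  ann1 <- tibble::tibble(contig = "c", pos = ds1$sites$pos,
                         coding = rep(c("nonsynonymous", "synonymous"), 50),
                         gene_id = "g1", or_flag = FALSE)
  lw1 <- pin_pis_windows(ds1, ann1, rownames(ds1$geno),
                         tibble::tibble(contig = "c", start = 0, end = 4e5),
                         min_genes = 0, min_windows = 1,
                         min_individuals = 3)
  expect_equal(lw1$ratio, 1)
})

test_that("group and window thresholds drop underpowered load estimates", {
  fx <- make_load_fixture()
  w <- tibble::tibble(contig = "c", start = 0, end = 4e5)
  expect_message(
    out <- pin_pis_windows(fx$ds, fx$ann, rownames(fx$ds$geno)[1:4], w),
    "dropped")
  expect_equal(nrow(out), 0)
  expect_message(
    out2 <- pin_pis_windows(fx$ds, fx$ann, rownames(fx$ds$geno), w,
                            min_windows = 4, min_genes = 0),
    "dropped")
  expect_equal(nrow(out2), 0)
})

test_that("strict collinear filtering is the stated set difference", {
  w <- tibble::tibble(contig = c("a", "a", "b", "c"), start = 0, end = 1e5)
  calls <- tibble::tibble(id = "i1", contig = "a", start = 0, end = 5e4)
  expect_equal(strict_collinear(w, calls)$contig, c("b", "c"))
  # no inversions: identity
  expect_equal(strict_collinear(w, calls[0, ]), w)
  # every contig inverted: empty
  calls_all <- tibble::tibble(id = c("i1", "i2", "i3"),
                              contig = c("a", "b", "c"),
                              start = 0, end = 1)
  expect_equal(nrow(strict_collinear(w, calls_all)), 0)
})

test_that("load contrasts detect shifted ratio distributions", {
  set.seed(51)
  base <- rgamma(50, 4, 20)
  tbl <- tibble::tibble(
    group = rep(c("COL", "invAA", "invBB"), each = 50),
    ratio = c(base, base + 0.02, base + 0.08))
  roles <- tibble::tibble(group = c("invAA", "invBB"),
                          role = c("major", "minor"))
  res <- load_contrasts(tbl, roles = roles,
                        freqs = tibble::tibble(group = c("invAA", "invBB"),
                                               freq = c(0.7, 0.3)))
  iv <- res[res$test == "inversion_vs_collinear", ]
  expect_lt(iv$wilcox_p, 0.01)
  mm <- res[res$test == "minor_vs_major", ]
  expect_lt(mm$wilcox_p, 0.01)
  expect_gt(mm$estimate, 0)
  # identical distributions: non-significant
  tbl0 <- tibble::tibble(group = rep(c("COL", "inv"), each = 50),
                         ratio = rep(base, 2))
  res0 <- load_contrasts(tbl0)
  expect_gt(res0$t_p, 0.9)
})

test_that("planted minor-arrangement load excess is recovered", {
  cfg <- sim_config(seed = 52, contigs = c(c1 = 3e6), snp_density = 2e-3,
                    gene_density = 40, gene_length = 2e4,
                    frac_nonsyn = 0.4,
                    inversions = list(inversion_spec(
                      "c1", 0, 2.4e6, base_freq = 0.3, arr_fst = 0.3,
                      load_excess_minor = 2, id = "iv")))
  sim <- simulate_cohort(cfg)
  kar <- sim$truth$karyotypes
  w <- make_windows(c(c1 = 2.4e6), size = 2e5)
  aa <- kar$sample[kar$karyotype == "AA"]  # major arrangement
  bb <- kar$sample[kar$karyotype == "BB"]  # minor, elevated load
  la <- pin_pis_windows(sim$dataset, sim$annotation, aa, w, group = "AA")
  lb <- pin_pis_windows(sim$dataset, sim$annotation, bb, w, group = "BB")
  expect_gt(median(lb$ratio), median(la$ratio))
})

test_that("neighbor joining reproduces additive distances exactly", {
  # four haplotypes over 20 sites with additive pairwise Hamming distances
  h <- rbind(
    h1 = c(rep(0, 20)),
    h2 = c(rep(1, 4), rep(0, 16)),
    h3 = c(rep(0, 4), rep(1, 10), rep(0, 6)),
    h4 = c(rep(0, 4), rep(1, 10), rep(1, 6)))
  d <- as.matrix(stats::dist(h, method = "manhattan")) / 20
  res <- nj_structuring(h, maf_min = 0)
  # a tree fitted to additive distances reproduces them as path lengths
  expect_equal(as.matrix(stats::cophenetic(res$tree))[rownames(d),
                                                      colnames(d)],
               d, tolerance = 1e-10)
})

test_that("identical haplotypes give a star tree without structuring", {
  h <- matrix(0, 6, 15)
  h[, 1] <- 1   # single shared variant keeps MAF filter sane
  res <- nj_structuring(h, maf_min = 0)
  expect_false(res$structured)
})

test_that("two diverged subhaplotype clusters are flagged as structuring", {
  set.seed(53)
  p1 <- runif(80, 0, 1) < 0.5
  flip <- runif(80) < 0.4
  mk <- function(proto, n) t(vapply(seq_len(n), function(i) {
    as.numeric(xor(proto, runif(80) < 0.03))
  }, numeric(80)))
  h <- rbind(mk(p1, 8), mk(xor(p1, flip), 8))
  res <- nj_structuring(h, maf_min = 0.05)
  expect_true(res$structured)
  expect_gt(res$ratio, 2)
  # order invariance: permuting haplotypes does not change the verdict
  perm <- sample(nrow(h))
  res2 <- nj_structuring(h[perm, ], maf_min = 0.05)
  expect_equal(res2$structured, res$structured)
  expect_equal(res2$ratio, res$ratio, tolerance = 1e-9)
  expect_error(nj_structuring(h[1:3, ]), "4 haplotypes")
})
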