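#' Arrangement (haplotype) frequencies from karyotypes
#'
#' Allele counting from assigned karyotypes (AA contributes two A alleles,
#' AB one of each, and so on; single-letter hemizygous karyotypes and
#' recombinant R labels are counted as written). Unassigned samples are
#' excluded from denominators. For X-linked inversions pass karyotypes that
#' already carry single letters for males - males then count once.
#'
#' @param kt tibble with `sample` and `genotype` (or `karyotype`) columns;
#'   genotypes are strings over the alphabet A/B/R.
#' @param meta metadata tibble with `sample` plus the grouping column.
#' @param grouping `"population"`, `"group"` or `"all"`.
#' @return tibble: grouping value, `n_ind`, `n_alleles`, `freq_A`,
#'   `freq_B`, `freq_R`.
#' @export
haplotype_frequencies <- function(kt, meta = NULL,
                                  grouping = c("all", "population",
                                               "group")) {
  grouping <- match.arg(grouping)
  gcol <- if ("genotype" %in% names(kt)) kt$genotype else kt$karyotype
  ok <- !is.na(gcol) & gcol != "unassigned"
  tbl <- tibble::tibble(sample = kt$sample[ok], geno = gcol[ok])
  if (grouping == "all") {
    tbl$grp <- "all"
  } else {
    stopifnot(!is.null(meta))
    tbl$grp <- meta[[grouping]][match(tbl$sample, meta$sample)]
  }
  if (nrow(tbl) == 0) stop("no assigned genotypes", call. = FALSE)
  count_letters <- function(genos) {
    letters_all <- unlist(strsplit(genos, ""))
    c(A = sum(letters_all == "A"), B = sum(letters_all == "B"),
      R = sum(letters_all == "R"))
  }
  out <- lapply(split(tbl$geno, tbl$grp), function(genos) {
    cnt <- count_letters(genos)
    tot <- sum(cnt)
    tibble::tibble(n_ind = length(genos), n_alleles = tot,
                   freq_A = cnt[["A"]] / tot, freq_B = cnt[["B"]] / tot,
                   freq_R = cnt[["R"]] / tot)
  })
  dplyr::bind_cols(tibble::tibble(!!grouping := names(out)),
                   dplyr::bind_rows(out))
}

#' Divergence-based inversion age
#'
#' `T = dxy / (2 mu)` generations, where `dxy` is the mean per-site
#' divergence between the two homokaryote groups over the inversion and
#' `mu` the per-site per-generation mutation rate. Ages are rough: gene
#' flux and selection are ignored.
#'
#' @param dxy_ab mean per-site dxy between arrangements.
#' @param mu mutation rate per site per generation (> 0).
#' @param generation_time years per generation.
#' @return tibble: `dxy`, `mu`, `t_generations`, `age_years`, `age_myr`.
#' @export
estimate_age <- function(dxy_ab, mu, generation_time = 1) {
  if (any(mu <= 0)) stop("mu must be positive", call. = FALSE)
  t_gen <- dxy_ab / (2 * mu)
  tibble::tibble(dxy = dxy_ab, mu = mu, t_generations = t_gen,
                 age_years = t_gen * generation_time,
                 age_myr = t_gen * generation_time / 1e6)
}

#' Hardy-Weinberg test for inversion karyotypes
#'
#' Two-arrangement inversions use the exact conditional test
#' ([hwe_exact()], or [hwe_exact_x()] for X-linked inversions where males
#' contribute single alleles); inversions with more than two haplotype
#' classes (for example a recombinant R class) use a permutation test that
#' shuffles alleles among individuals and compares the heterozygote count,
#' with `p = (1 + #extreme) / (1 + B)`.
#'
#' @param kt karyotype tibble (`sample`, `genotype`).
#' @param meta metadata (needed for grouping or X-linked tests).
#' @param grouping `"all"`, `"group"` or `"population"`.
#' @param x_linked whether males are hemizygous (single-letter karyotypes).
#' @param B permutation count.
#' @param min_n minimum assigned individuals per grouping level.
#' @return tibble: grouping value, `n`, `method`, `p`, `p_excess`,
#'   `p_deficit`, `direction`.
#' @export
hwe_test <- function(kt, meta = NULL, grouping = "all", x_linked = FALSE,
                     B = 10000, min_n = 10) {
  gcol <- kt$genotype
  ok <- !is.na(gcol) & gcol != "unassigned"
  tbl <- tibble::tibble(sample = kt$sample[ok], geno = gcol[ok])
  if (grouping == "all") tbl$grp <- "all"
  else tbl$grp <- meta[[grouping]][match(tbl$sample, meta$sample)]
  rows <- lapply(split(tbl, tbl$grp), function(d) {
    if (nrow(d) < min_n) {
      return(tibble::tibble(n = nrow(d), method = "skipped",
                            p = NA_real_, p_excess = NA_real_,
                            p_deficit = NA_real_,
                            direction = NA_character_))
    }
    haps <- unique(unlist(strsplit(d$geno, "")))
    if (x_linked) {
      sex <- meta$sex[match(d$sample, meta$sample)]
      fem <- d$geno[sex == "F"]
      mal <- d$geno[sex == "M"]
      res <- hwe_exact_x(sum(fem == "AA"), sum(fem == "AB"),
                         sum(fem == "BB"),
                         sum(mal == "A"), sum(mal == "B"))
      return(tibble::tibble(n = nrow(d), method = "exact_x", p = res$p_two,
                            p_excess = res$p_excess,
                            p_deficit = res$p_deficit,
                            direction = res$direction))
    }
    if (length(haps) <= 2) {
      res <- hwe_exact(sum(d$geno == "AA"), sum(d$geno == "AB"),
                       sum(d$geno == "BB"))
      tibble::tibble(n = nrow(d), method = "exact", p = res$p_two,
                     p_excess = res$p_excess, p_deficit = res$p_deficit,
                     direction = res$direction)
    } else {
      res <- hwe_permutation(d$geno, B = B)
      tibble::tibble(n = nrow(d), method = "permutation", p = res$p,
                     p_excess = res$p_excess, p_deficit = res$p_deficit,
                     direction = res$direction)
    }
  })
  dplyr::bind_cols(tibble::tibble(!!grouping := names(rows)),
                   dplyr::bind_rows(rows))
}

# permutation HWE test for multi-haplotype karyotypes: shuffle the pooled
# alleles among individuals and compare heterozygote counts
hwe_permutation <- function(genos, B = 10000) {
  alleles <- unlist(strsplit(genos, ""))
  n <- length(genos)
  obs <- sum(substr(genos, 1, 1) != substr(genos, 2, 2))
  perm <- vapply(seq_len(B), function(b) {
    a <- sample(alleles)
    sum(a[seq(1, 2 * n, by = 2)] != a[seq(2, 2 * n, by = 2)])
  }, numeric(1))
  mu <- mean(perm)
  tibble::tibble(
    p = (1 + sum(abs(perm - mu) >= abs(obs - mu))) / (1 + B),
    p_excess = (1 + sum(perm >= obs)) / (1 + B),
    p_deficit = (1 + sum(perm <= obs)) / (1 + B),
    direction = if (obs > mu) "excess" else if (obs < mu) "deficit" else
      "none")
}

#' Latitudinal cline test for an arrangement frequency
#'
#' Pearson correlation between per-population B-arrangement frequency and
#' latitude, with the parametric two-sided t-test p-value.
#'
#' @param freq per-population frequencies.
#' @param lat matching latitudes.
#' @return tibble: `n`, `r`, `r2`, `p`.
#' @export
cline_test <- function(freq, lat) {
  stopifnot(length(freq) == length(lat))
  if (length(freq) < 5) stop("need at least 5 populations", call. = FALSE)
  if (stats::sd(freq) == 0) stop("frequencies have zero variance",
                                 call. = FALSE)
  ct <- stats::cor.test(freq, lat)
  tibble::tibble(n = length(freq), r = unname(ct$estimate),
                 r2 = unname(ct$estimate)^2, p = ct$p.value)
}

#' MAF-matched permutation null for a cline correlation
#'
#' Samples `n_snps` collinear SNPs (outside all inversion calls) whose
#' global minor allele frequency lies within `maf_window` of the inversion's
#' minor-arrangement frequency, computes each SNP's per-population MAF vs
#' latitude r-squared, and reports the fraction of null r-squared values
#' at or above the observed one (plain count / n, matching the reported
#' permutation convention; `plus_one = TRUE` switches to (1+k)/(1+n)). If
#' too few SNPs match, the window is widened with a warning.
#'
#' @param ds a [geno_dataset()].
#' @param meta metadata with `sample`, `population`, `lat`.
#' @param observed_r2 the inversion's cline r-squared.
#' @param inversion_maf the inversion's minor-arrangement frequency.
#' @param exclude tibble `contig`, `start`, `end` of inversion intervals.
#' @param n_snps number of matched SNPs.
#' @param maf_window matching half-width.
#' @param plus_one add-one correction for the empirical p.
#' @return tibble: `p`, `n_snps`, `maf_window_used`, `n_exceeding`.
#' @export
maf_matched_permutation <- function(ds, meta, observed_r2, inversion_maf,
                                    exclude = NULL, n_snps = 1000,
                                    maf_window = 0.05, plus_one = FALSE) {
  maf <- site_maf(ds)
  eligible <- !is.na(maf)
  if (!is.null(exclude) && nrow(exclude) > 0) {
    for (i in seq_len(nrow(exclude))) {
      eligible <- eligible & !(ds$sites$contig == exclude$contig[i] &
                                 ds$sites$pos >= exclude$start[i] &
                                 ds$sites$pos < exclude$end[i])
    }
  }
  w <- maf_window
  repeat {
    pool <- which(eligible & abs(maf - inversion_maf) <= w)
    if (length(pool) >= n_snps || w >= 0.5) break
    w <- w + 0.05
    warning(sprintf("widening MAF window to %.2f (only %d eligible SNPs)",
                    w, length(pool)), call. = FALSE)
  }
  if (length(pool) < 2) stop("no eligible SNPs for the MAF-matched null",
                             call. = FALSE)
  take <- if (length(pool) > n_snps) sample(pool, n_snps) else pool
  pops <- unique(meta$population)
  lat <- meta$lat[match(pops, meta$population)]
  g_take <- ds$geno[, take, drop = FALSE]
  # per-population frequency of the globally minor allele
  pmat <- vapply(pops, function(pp) {
    gg <- g_take[meta$sample[meta$population == pp], , drop = FALSE]
    colMeans(gg, na.rm = TRUE) / 2
  }, numeric(length(take)))
  if (is.null(dim(pmat))) pmat <- matrix(pmat, nrow = 1)
  glob <- colMeans(g_take, na.rm = TRUE) / 2
  pmat[glob > 0.5, ] <- 1 - pmat[glob > 0.5, ]
  r2_null <- apply(pmat, 1, function(f) {
    if (stats::sd(f, na.rm = TRUE) == 0) return(0)
    stats::cor(f, lat, use = "complete.obs")^2
  })
  k <- sum(r2_null >= observed_r2, na.rm = TRUE)
  m <- sum(!is.na(r2_null))
  p <- if (plus_one) (1 + k) / (1 + m) else k / m
  tibble::tibble(p = p, n_snps = m, maf_window_used = w, n_exceeding = k)
}

#' Exact G-test for karyotype-phenotype association
#'
#' Log-likelihood-ratio G statistic on the genotype-by-phenotype
#' contingency table with a Monte-Carlo exact p-value over tables with the
#' observed margins.
#'
#' @param kt karyotype tibble (`sample`, `genotype`).
#' @param phenotype named character vector or tibble (`sample`,
#'   `phenotype`) with two classes.
#' @param B Monte-Carlo tables.
#' @return tibble: `G`, `df`, `p`.
#' @export
phenotype_association <- function(kt, phenotype, B = 10000) {
  if (is.data.frame(phenotype)) {
    ph <- phenotype$phenotype[match(kt$sample, phenotype$sample)]
  } else ph <- phenotype[kt$sample]
  ok <- !is.na(ph) & !is.na(kt$genotype) & kt$genotype != "unassigned"
  tab <- table(kt$genotype[ok], ph[ok])
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("degenerate genotype-phenotype table", call. = FALSE)
  }
  if (any(table(ph[ok]) < 4)) {
    stop("need at least 4 individuals per phenotype class", call. = FALSE)
  }
  gstat <- function(m) {
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    nz <- m > 0
    2 * sum(m[nz] * log(m[nz] / e[nz]))
  }
  g_obs <- gstat(tab)
  perm <- vapply(stats::r2dtable(B, rowSums(tab), colSums(tab)), gstat,
                 numeric(1))
  tibble::tibble(G = g_obs, df = (nrow(tab) - 1) * (ncol(tab) - 1),
                 p = (1 + sum(perm >= g_obs - 1e-9)) / (1 + B))
}

#' Characterize a set of called inversions
#'
#' Convenience wrapper producing one summary row per inversion: global and
#' per-group arrangement frequencies, dxy between homokaryotes, age, HWE
#' p, and the cline r-squared/p.
#'
#' @param ds a [geno_dataset()].
#' @param calls tibble `id`, `contig`, `start`, `end`.
#' @param kts named list of `inv_karyotype` tables (names matching ids).
#' @param meta metadata tibble.
#' @param mu mutation rate per site per generation.
#' @param generation_time years per generation.
#' @return tibble, one row per inversion.
#' @export
summarize_inversions <- function(ds, calls, kts, meta, mu = 2.9e-9,
                                 generation_time = 1) {
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    id <- calls$id[i]
    kt <- kts[[id]]
    fa <- haplotype_frequencies(kt, meta, "all")
    aa <- kt$sample[kt$genotype == "AA"]
    bb <- kt$sample[kt$genotype == "BB"]
    idx <- site_index(ds, calls$contig[i], calls$start[i], calls$end[i])
    dxy <- if (length(aa) >= 2 && length(bb) >= 2 && length(idx) > 0) {
      sub <- subset_dataset(ds, sites = idx)
      mean(site_dxy(site_freq(sub, aa), site_freq(sub, bb)), na.rm = TRUE)
    } else NA_real_
    age <- if (!is.na(dxy)) estimate_age(dxy, mu, generation_time) else
      tibble::tibble(t_generations = NA_real_, age_myr = NA_real_)
    hwe <- hwe_test(kt, meta, "all")
    fr_pop <- haplotype_frequencies(kt, meta, "population")
    cl <- tryCatch({
      lat <- meta$lat[match(fr_pop$population, meta$population)]
      cline_test(fr_pop$freq_B, lat)
    }, error = function(e) tibble::tibble(r2 = NA_real_, p = NA_real_))
    tibble::tibble(id = id, contig = calls$contig[i],
                   start = calls$start[i], end = calls$end[i],
                   freq_B = fa$freq_B, dxy_ab = dxy,
                   t_generations = age$t_generations,
                   age_myr = age$age_myr, hwe_p = hwe$p,
                   cline_r2 = cl$r2, cline_p = cl$p)
  })
  dplyr::bind_rows(rows)
}
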