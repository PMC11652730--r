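#' Per-site nucleotide diversity from allele counts
#'
#' Unbiased per-site heterozygosity `2 * n_ref * n_alt / (n * (n - 1))`
#' where `n` is the number of non-missing chromosomes.
#'
#' @param n_alt alternate allele count(s).
#' @param n_chr total non-missing chromosome count(s).
#' @return numeric vector of per-site pi (0 for monomorphic sites, `NA` when
#'   fewer than two chromosomes).
#' @export
pi_from_counts <- function(n_alt, n_chr) {
  out <- 2 * n_alt * (n_chr - n_alt) / (n_chr * (n_chr - 1))
  out[n_chr < 2] <- NA_real_
  out
}

#' Per-site nucleotide diversity of a dataset
#'
#' @param ds a [geno_dataset()].
#' @param samples optional sample ids.
#' @return numeric vector, one value per variant.
#' @export
site_pi <- function(ds, samples = NULL) {
  g <- if (is.null(samples)) ds$geno else ds$geno[samples, , drop = FALSE]
  n_chr <- 2 * colSums(!is.na(g))
  n_alt <- colSums(g, na.rm = TRUE)
  pi_from_counts(n_alt, n_chr)
}

#' Per-site absolute divergence between two allele frequencies
#'
#' `dxy = p_A (1 - p_B) + p_B (1 - p_A)`; 1 for a fixed difference.
#'
#' @param freq_a,freq_b alternate-allele frequencies in the two groups.
#' @return numeric vector in `[0, 1]`.
#' @export
site_dxy <- function(freq_a, freq_b) {
  freq_a * (1 - freq_b) + freq_b * (1 - freq_a)
}

# per-group per-site counts used by the Weir-Cockerham components
group_site_summary <- function(ds, samples) {
  g <- ds$geno[samples, , drop = FALSE]
  n <- colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / (2 * n)
  h <- colSums(g == 1, na.rm = TRUE) / n
  list(n = n, p = p, h = h)
}

#' Weir-Cockerham FST variance components per site
#'
#' Standard two-level variance components (a: among groups, b: among
#' individuals within groups, c: within individuals) computed from genotype
#' counts, including the heterozygosity term. Windowed FST should be formed
#' as a ratio of sums `sum(a) / sum(a + b + c)`.
#'
#' @param ds a [geno_dataset()].
#' @param groups named list of sample-id vectors (two or more groups).
#' @return tibble with `contig`, `pos`, `a`, `b`, `c` and the per-site
#'   ratio `fst` (`NA` where undefined).
#' @export
wc_fst <- function(ds, groups) {
  stopifnot(length(groups) >= 2)
  r <- length(groups)
  gs <- lapply(groups, function(s) group_site_summary(ds, s))
  n_mat <- vapply(gs, `[[`, numeric(n_variants(ds)), "n")
  p_mat <- vapply(gs, `[[`, numeric(n_variants(ds)), "p")
  h_mat <- vapply(gs, `[[`, numeric(n_variants(ds)), "h")
  if (is.null(dim(n_mat))) {
    n_mat <- matrix(n_mat, nrow = 1); p_mat <- matrix(p_mat, nrow = 1)
    h_mat <- matrix(h_mat, nrow = 1)
  }
  ok <- rowSums(n_mat >= 2) == r & !apply(p_mat, 1, anyNA)
  nbar <- rowMeans(n_mat)
  nsum <- rowSums(n_mat)
  nc <- (nsum - rowSums(n_mat^2) / nsum) / (r - 1)
  pbar <- rowSums(n_mat * p_mat) / nsum
  s2 <- rowSums(n_mat * (p_mat - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n_mat * h_mat) / nsum
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  a[!ok] <- NA_real_; b[!ok] <- NA_real_; cc[!ok] <- NA_real_
  den <- a + b + cc
  tibble::tibble(contig = ds$sites$contig, pos = ds$sites$pos,
                 a = a, b = b, c = cc,
                 fst = ifelse(!is.na(den) & den != 0, a / den, NA_real_))
}

# standard Tajima constants for n chromosomes
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

#' Tajima's D from summary quantities
#'
#' `D = (pi_total - S / a1) / sqrt(e1 S + e2 S (S - 1))` with the standard
#' constants computed from the chromosome count.
#'
#' @param S number of segregating sites.
#' @param pi_sum total (summed over sites) pairwise diversity.
#' @param n_chr number of chromosomes.
#' @return Tajima's D (`NA` when `S` is 0).
#' @export
tajimas_d_stat <- function(S, pi_sum, n_chr) {
  if (S == 0 || n_chr < 4) return(NA_real_)
  k <- tajima_constants(n_chr)
  (pi_sum - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Tajima's D for a set of samples over a region
#'
#' The chromosome count is taken as the floored mean number of non-missing
#' chromosomes across the region's segregating sites.
#'
#' @param ds a [geno_dataset()].
#' @param samples sample ids (default all).
#' @param contig,start,end region (default everything).
#' @return Tajima's D.
#' @export
tajimas_d <- function(ds, samples = NULL, contig = NULL, start = -Inf,
                      end = Inf) {
  idx <- if (is.null(contig)) seq_len(n_variants(ds)) else
    site_index(ds, contig, start, end)
  sub <- subset_dataset(ds, sites = idx, samples = samples)
  g <- sub$geno
  n_chr_site <- 2 * colSums(!is.na(g))
  n_alt <- colSums(g, na.rm = TRUE)
  seg <- n_alt > 0 & n_alt < n_chr_site
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  pi_sum <- sum(pi_from_counts(n_alt[seg], n_chr_site[seg]))
  tajimas_d_stat(S, pi_sum, floor(mean(n_chr_site[seg])))
}

#' Windowed summary statistics
#'
#' Per window: number of SNPs, segregating sites, mean per-site pi,
#' Watterson's theta per SNP, Tajima's D, and, when exactly two groups are
#' given, dxy and summed Weir-Cockerham FST components with the
#' ratio-of-sums FST. All per-site statistics are per genotyped variant
#' site; additive fields (`S`, `pi_sum`, `fst_num`, `fst_den`) are sums so
#' windows can be combined exactly.
#'
#' @param ds a [geno_dataset()].
#' @param windows tibble from [make_windows()].
#' @param groups optional named list of two sample-id vectors.
#' @param samples samples used for the single-population statistics.
#' @return tibble, one row per window.
#' @export
window_stats <- function(ds, windows, groups = NULL, samples = NULL) {
  g <- if (is.null(samples)) ds$geno else ds$geno[samples, , drop = FALSE]
  n_chr_site <- 2 * colSums(!is.na(g))
  n_alt <- colSums(g, na.rm = TRUE)
  pi_site <- pi_from_counts(n_alt, n_chr_site)
  seg <- !is.na(pi_site) & n_alt > 0 & n_alt < n_chr_site

  dxy_site <- NULL
  fst_tbl <- NULL
  if (!is.null(groups)) {
    stopifnot(length(groups) == 2)
    pa <- site_freq(ds, groups[[1]])
    pb <- site_freq(ds, groups[[2]])
    dxy_site <- site_dxy(pa, pb)
    fst_tbl <- wc_fst(ds, groups)
  }

  rows <- lapply(seq_len(nrow(windows)), function(i) {
    idx <- site_index(ds, windows$contig[i], windows$start[i],
                      windows$end[i])
    n_sites <- length(idx)
    if (n_sites == 0) {
      return(tibble::tibble(contig = windows$contig[i],
                            start = windows$start[i], end = windows$end[i],
                            n_sites = 0L, S = 0L, pi_sum = NA_real_,
                            pi = NA_real_, theta_w = NA_real_,
                            tajd = NA_real_, dxy = NA_real_,
                            fst_num = NA_real_, fst_den = NA_real_,
                            fst = NA_real_))
    }
    S <- sum(seg[idx])
    pi_sum <- sum(pi_site[idx][seg[idx]], na.rm = TRUE)
    nbar <- if (S > 0) floor(mean(n_chr_site[idx][seg[idx]])) else
      floor(mean(n_chr_site[idx]))
    theta <- if (S > 0 && nbar >= 2) {
      S / tajima_constants(max(nbar, 2))$a1 / n_sites
    } else 0
    tajd <- if (S > 0 && nbar >= 4) tajimas_d_stat(S, pi_sum, nbar) else
      NA_real_
    dxy <- if (!is.null(dxy_site)) mean(dxy_site[idx], na.rm = TRUE) else
      NA_real_
    if (!is.null(fst_tbl)) {
      fst_num <- sum(fst_tbl$a[idx], na.rm = TRUE)
      fst_den <- sum(fst_tbl$a[idx] + fst_tbl$b[idx] + fst_tbl$c[idx],
                     na.rm = TRUE)
      fst <- if (fst_den != 0) fst_num / fst_den else NA_real_
    } else {
      fst_num <- NA_real_; fst_den <- NA_real_; fst <- NA_real_
    }
    tibble::tibble(contig = windows$contig[i], start = windows$start[i],
                   end = windows$end[i], n_sites = n_sites, S = S,
                   pi_sum = pi_sum, pi = pi_sum / n_sites,
                   theta_w = theta, tajd = tajd, dxy = dxy,
                   fst_num = fst_num, fst_den = fst_den, fst = fst)
  })
  dplyr::bind_rows(rows)
}

#' Genome-wide Weir-Cockerham FST between groups (ratio of sums)
#'
#' @param ds a [geno_dataset()].
#' @param groups named list of sample-id vectors.
#' @return single FST value.
#' @export
global_fst <- function(ds, groups) {
  tbl <- wc_fst(ds, groups)
  sum(tbl$a, na.rm = TRUE) /
    sum(tbl$a + tbl$b + tbl$c, na.rm = TRUE)
}
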