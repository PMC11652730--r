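#' Per-sample heterozygosity within a region
#'
#' Proportion of heterozygous calls among non-missing SNPs in the region.
#' Samples with fewer than `min_snps` genotyped region SNPs get `NA` (they
#' are left unassigned downstream).
#'
#' @param ds a [geno_dataset()].
#' @param contig,start,end region (0-based half-open).
#' @param samples optional sample ids.
#' @param min_snps minimum genotyped SNPs per sample.
#' @return tibble `sample`, `n_snps`, `het`.
#' @export
region_heterozygosity <- function(ds, contig, start = -Inf, end = Inf,
                                  samples = NULL, min_snps = 10) {
  idx <- site_index(ds, contig, start, end)
  if (length(idx) == 0) stop("empty region", call. = FALSE)
  g <- ds$geno[, idx, drop = FALSE]
  if (!is.null(samples)) g <- g[samples, , drop = FALSE]
  n <- unname(rowSums(!is.na(g)))
  het <- unname(rowSums(g == 1, na.rm = TRUE) / n)
  het[n < min_snps] <- NA_real_
  tibble::tibble(sample = rownames(g), n_snps = n, het = het)
}

# three-cluster genotyping of one score axis with heterozygosity ordering
# and centroid-midpoint confirmation; returns genotype vector + diagnostics
three_cluster_genotype <- function(score, het, het_p = 0.05,
                                   centroid_window = c(0.35, 0.65)) {
  cl <- kmeans_1d(score, 3)$cluster
  cent <- tapply(score, cl, mean)
  ord <- order(cent)
  grp <- match(cl, ord)                  # 1 = left, 2 = middle, 3 = right
  occupied <- length(unique(grp))
  fail <- function(reason) {
    list(genotype = rep("unassigned", length(score)), status = "ambiguous",
         reason = reason, p_left = NA_real_, p_right = NA_real_,
         mid_pos = NA_real_)
  }
  if (occupied < 3) return(fail("fewer than three occupied clusters"))
  if (any(table(grp) < 2)) return(fail("cluster with a single sample"))
  h1 <- het[grp == 1]; h2 <- het[grp == 2]; h3 <- het[grp == 3]
  if (sum(!is.na(h2)) < 2 || sum(!is.na(h1)) < 2 || sum(!is.na(h3)) < 2) {
    return(fail("insufficient heterozygosity data"))
  }
  p_left <- tryCatch(stats::t.test(h2, h1, alternative = "greater")$p.value,
                     error = function(e) NA_real_)
  p_right <- tryCatch(stats::t.test(h2, h3, alternative = "greater")$p.value,
                      error = function(e) NA_real_)
  cpos <- (cent[ord][2] - cent[ord][1]) / (cent[ord][3] - cent[ord][1])
  ok_het <- !is.na(p_left) && !is.na(p_right) && p_left < het_p &&
    p_right < het_p
  ok_mid <- cpos >= centroid_window[1] && cpos <= centroid_window[2]
  if (!ok_het) return(fail("middle cluster not the most heterozygous"))
  if (!ok_mid) return(fail("middle cluster centroid off-midpoint"))
  # label homokaryote clusters by frequency: larger outer cluster = AA
  n1 <- sum(grp == 1); n3 <- sum(grp == 3)
  lab <- if (n1 >= n3) c("AA", "AB", "BB") else c("BB", "AB", "AA")
  list(genotype = lab[grp], status = "confirmed", reason = NA_character_,
       p_left = unname(p_left), p_right = unname(p_right),
       mid_pos = unname(cpos))
}

#' Genotype samples for an inversion region
#'
#' PCA on the region's SNPs, deterministic 1-D k-means (k = 3) on PC1,
#' heterozygote assignment to the middle cluster. The call is confirmed only
#' if (i) the middle cluster is significantly more heterozygous than both
#' outer clusters (one-sided Welch tests) and (ii) its centroid falls near
#' the midpoint between the outer centroids (the 50/50-ancestry analogue for
#' heterokaryotypes). The more frequent homokaryote cluster is labelled AA.
#'
#' By default genotyping refuses contigs with fewer than `min_contig_snps`
#' SNPs (such contigs give ambiguous calls); set `override = TRUE` for small
#' simulated datasets.
#'
#' @param ds a [geno_dataset()].
#' @param contig,start,end region.
#' @param min_contig_snps minimum SNPs on the contig.
#' @param override bypass the contig SNP floor.
#' @param het_p significance level for the heterozygosity ordering.
#' @param centroid_window acceptable middle-centroid position as a fraction
#'   of the outer-centroid span.
#' @param min_snps per-sample genotyped-SNP floor for heterozygosity.
#' @return tibble of class `inv_karyotype`: `sample`, `genotype` (AA / AB /
#'   BB / unassigned), `pc1`, `het`; attributes `status` (confirmed /
#'   ambiguous), `region`, `diagnostics`.
#' @export
genotype_inversion <- function(ds, contig, start = -Inf, end = Inf,
                               min_contig_snps = 1e4, override = FALSE,
                               het_p = 0.05,
                               centroid_window = c(0.35, 0.65),
                               min_snps = 10) {
  if (!override) {
    n_ct <- sum(ds$sites$contig == contig)
    if (n_ct < min_contig_snps) {
      stop(sprintf(
        "contig %s has %d SNPs (< %d); genotyping is unreliable - use override = TRUE to force",
        contig, n_ct, min_contig_snps), call. = FALSE)
    }
  }
  idx <- site_index(ds, contig, start, end)
  if (length(idx) < 3) stop("too few region SNPs", call. = FALSE)
  pca <- contig_pca(subset_dataset(ds, sites = idx), n_pc = 3)
  hets <- region_heterozygosity(ds, contig, start, end, min_snps = min_snps)
  res <- three_cluster_genotype(pca$scores$PC1, hets$het, het_p,
                                centroid_window)
  genotype <- res$genotype
  genotype[is.na(hets$het)] <- "unassigned"
  out <- tibble::tibble(sample = pca$scores$sample, genotype = genotype,
                        pc1 = pca$scores$PC1, het = hets$het)
  class(out) <- c("inv_karyotype", class(out))
  attr(out, "status") <- res$status
  attr(out, "region") <- list(contig = contig, start = start, end = end,
                              n_snps = length(idx))
  attr(out, "diagnostics") <- res[c("reason", "p_left", "p_right",
                                    "mid_pos")]
  attr(out, "pca") <- pca
  out
}

#' Contigs with too few SNPs for inversion genotyping
#'
#' @param ds a [geno_dataset()].
#' @param min_snps strict threshold; contigs with fewer SNPs are listed.
#' @return character vector of contig names to exclude.
#' @export
exclude_low_snp_contigs <- function(ds, min_snps = 1e4) {
  counts <- table(ds$sites$contig)
  names(counts)[counts < min_snps]
}

# karyotype string -> dosage of the B arrangement
karyotype_dosage <- function(genotype) {
  c(AA = 0, AB = 1, BB = 2)[genotype]
}

#' Linkage between two inversion karyotype tables
#'
#' Cosegregation check for putatively duplicated calls: dosage r-squared
#' and exact genotype concordance over jointly assigned samples, with a
#' merge recommendation when both are near 1 (the same inversion split
#' across two contigs behaves like one locus).
#'
#' @param k1,k2 [genotype_inversion()] results.
#' @param r2_merge,conc_merge merge thresholds.
#' @return one-row tibble: `n`, `r2`, `concordance`, `merge`.
#' @export
inversion_ld <- function(k1, k2, r2_merge = 0.9, conc_merge = 0.95) {
  j <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(k1), "sample", g1 = "genotype"),
    dplyr::select(tibble::as_tibble(k2), "sample", g2 = "genotype"),
    by = "sample")
  j <- j[j$g1 %in% c("AA", "AB", "BB") & j$g2 %in% c("AA", "AB", "BB"), ]
  if (nrow(j) < 10) stop("fewer than 10 jointly assigned samples",
                         call. = FALSE)
  d1 <- karyotype_dosage(j$g1)
  d2 <- karyotype_dosage(j$g2)
  r2 <- if (stats::sd(d1) == 0 || stats::sd(d2) == 0) NA_real_ else
    stats::cor(d1, d2)^2
  conc <- mean(j$g1 == j$g2)
  tibble::tibble(n = nrow(j), r2 = r2, concordance = conc,
                 merge = !is.na(r2) && r2 >= r2_merge && conc >= conc_merge)
}

#' Genotype a second, overlapping inversion
#'
#' Walks the leading axes (PC1, PC2, PC3) of the region PCA, repeats the
#' three-cluster logic on each, and accepts the first axis that passes
#' confirmation and is not collinear (dosage r-squared < `r2_max`) with an
#' existing karyotype on the region - the second inversion of an
#' overlapping pair surfaces on a later axis, or on PC1 when it dominates
#' the regional variance.
#'
#' @param ds a [geno_dataset()].
#' @param contig,start,end region of the second inversion.
#' @param existing `inv_karyotype` of the already-called inversion.
#' @param r2_max collinearity ceiling against the existing karyotype.
#' @inheritParams genotype_inversion
#' @return an `inv_karyotype` (status `ambiguous` if no axis qualifies).
#' @export
overlap_genotyping <- function(ds, contig, start = -Inf, end = Inf,
                               existing, r2_max = 0.5, het_p = 0.05,
                               centroid_window = c(0.35, 0.65),
                               min_snps = 10) {
  idx <- site_index(ds, contig, start, end)
  if (length(idx) < 4) stop("too few region SNPs", call. = FALSE)
  pca <- contig_pca(subset_dataset(ds, sites = idx), n_pc = 3)
  hets <- region_heterozygosity(ds, contig, start, end, min_snps = min_snps)
  d_old <- karyotype_dosage(existing$genotype[match(pca$scores$sample,
                                                    existing$sample)])
  pick <- NULL
  for (axis in c("PC1", "PC2", "PC3")) {
    if (!axis %in% names(pca$scores)) next
    res <- three_cluster_genotype(pca$scores[[axis]], hets$het, het_p,
                                  centroid_window)
    if (res$status != "confirmed") next
    d_new <- karyotype_dosage(res$genotype)
    ok <- !is.na(d_new) & !is.na(d_old)
    r2 <- if (sum(ok) >= 10 && stats::sd(d_new[ok]) > 0 &&
                stats::sd(d_old[ok]) > 0) {
      stats::cor(d_new[ok], d_old[ok])^2
    } else 0
    if (r2 < r2_max) {
      pick <- list(res = res, axis = axis)
      break
    }
  }
  if (is.null(pick)) {
    res <- list(genotype = rep("unassigned", nrow(pca$scores)),
                status = "ambiguous", reason = "no independent axis",
                p_left = NA_real_, p_right = NA_real_, mid_pos = NA_real_)
    pick <- list(res = res, axis = NA_character_)
  }
  genotype <- pick$res$genotype
  genotype[is.na(hets$het)] <- "unassigned"
  out <- tibble::tibble(sample = pca$scores$sample, genotype = genotype,
                        pc1 = pca$scores$PC1, het = hets$het)
  class(out) <- c("inv_karyotype", class(out))
  attr(out, "status") <- pick$res$status
  attr(out, "region") <- list(contig = contig, start = start, end = end,
                              n_snps = length(idx))
  attr(out, "diagnostics") <- c(pick$res[c("reason", "p_left", "p_right",
                                           "mid_pos")],
                                list(axis = pick$axis))
  out
}

#' Scan an inversion for double-crossover subregions
#'
#' Computes windowed Weir-Cockerham FST between the two homokaryote groups
#' and flags maximal runs of at least `min_run` consecutive windows whose
#' FST drops below `drop_frac` of the region median - the signature of a
#' historical double crossover that locally homogenized the arrangements.
#'
#' @param ds a [geno_dataset()].
#' @param contig,start,end the inversion region.
#' @param kt the inversion's `inv_karyotype`.
#' @param window window size (bp).
#' @param drop_frac FST drop threshold relative to the region median.
#' @param min_run minimum consecutive low windows.
#' @param min_hom minimum samples per homokaryote class.
#' @return tibble of flagged subintervals `contig`, `start`, `end`,
#'   `mean_fst`, `region_median_fst` (zero rows when none).
#' @export
double_crossover_scan <- function(ds, contig, start, end, kt,
                                  window = 1e5, drop_frac = 0.25,
                                  min_run = 2, min_hom = 4) {
  if (end <= start) stop("zero-length inversion region", call. = FALSE)
  aa <- kt$sample[kt$genotype == "AA"]
  bb <- kt$sample[kt$genotype == "BB"]
  if (length(aa) < min_hom || length(bb) < min_hom) {
    stop("too few homokaryotypes for a double-crossover scan",
         call. = FALSE)
  }
  starts <- seq(start, end - 1, by = window)
  wins <- tibble::tibble(contig = contig, start = starts,
                         end = pmin(starts + window, end))
  idx <- site_index(ds, contig, start, end)
  sub <- subset_dataset(ds, sites = idx)
  ws <- window_stats(sub, wins, groups = list(AA = aa, BB = bb))
  med <- stats::median(ws$fst, na.rm = TRUE)
  low <- !is.na(ws$fst) & ws$fst < drop_frac * med
  runs <- merge_flagged(which(low), 0)
  runs <- Filter(function(r) r[2] - r[1] + 1 >= min_run, runs)
  if (length(runs) == 0) {
    return(tibble::tibble(contig = character(0), start = numeric(0),
                          end = numeric(0), mean_fst = numeric(0),
                          region_median_fst = numeric(0)))
  }
  dplyr::bind_rows(lapply(runs, function(r) {
    tibble::tibble(contig = contig, start = ws$start[r[1]],
                   end = ws$end[r[2]],
                   mean_fst = mean(ws$fst[r[1]:r[2]], na.rm = TRUE),
                   region_median_fst = med)
  }))
}

#' Union span of inversion calls
#'
#' Per-contig interval union of the call coordinates (overlapping and nested
#' calls are counted once), total span, and the fraction of the analyzed
#' genome covered. `merge_pairs` lists groups of call ids that represent
#' one physical inversion split across contigs; merging affects the
#' inversion count, never the span.
#'
#' @param calls tibble with `id`, `contig`, `start`, `end` (bp).
#' @param analyzed_length total analyzed genome length (bp).
#' @param merge_pairs optional list of character vectors of ids.
#' @return one-row tibble: `span_bp`, `fraction`, `n_calls`,
#'   `n_inversions`, `n_contigs`.
#' @export
union_span <- function(calls, analyzed_length = NA_real_,
                       merge_pairs = NULL) {
  span <- 0
  if (nrow(calls) > 0) {
    for (ct in unique(calls$contig)) {
      ci <- calls[calls$contig == ct, ]
      ir <- IRanges::reduce(IRanges::IRanges(start = ci$start + 1,
                                             end = ci$end))
      span <- span + sum(IRanges::width(ir))
    }
  }
  n_inv <- nrow(calls)
  if (!is.null(merge_pairs)) {
    for (pr in merge_pairs) {
      present <- sum(calls$id %in% pr)
      if (present > 1) n_inv <- n_inv - (present - 1)
    }
  }
  tibble::tibble(span_bp = span,
                 fraction = span / analyzed_length,
                 n_calls = nrow(calls), n_inversions = n_inv,
                 n_contigs = length(unique(calls$contig)))
}
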