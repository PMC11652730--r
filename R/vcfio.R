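#' Read a multi-sample VCF and sample metadata
#'
#' Parses GT (dosage of the alternate allele) and per-site DP. Multiallelic
#' records are dropped and counted. Positions are converted to 0-based.
#'
#' @param path VCF file (plain or bgzipped).
#' @param metadata_path TSV with columns `sample`, `population`, `group`,
#'   `lat`, `lon`, `sex` and optionally `phenotype`; sample ids must match
#'   the VCF columns. `NULL` to skip.
#' @return list with `dataset` ([geno_dataset()]), `meta` (tibble or `NULL`)
#'   and `report` (tibble of dropped-record counts).
#' @export
read_vcf <- function(path, metadata_path = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  n_multi <- sum(multi)
  if (any(multi)) v <- v[!multi, ]
  fix <- fix[!multi, , drop = FALSE]
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  # dosage = number of '1' alleles; handles 0/1, 1|1 and hemizygous '1'
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  miss <- is.na(gt) | gt %in% c(".", "./.", ".|.")
  counts <- nchar(gt) - nchar(gsub("1", "", gt, fixed = TRUE))
  dos[!miss] <- counts[!miss]
  dp <- suppressWarnings(vcfR::extract.info(v, "DP", as.numeric = TRUE))
  sites <- tibble::tibble(contig = fix[, "CHROM"],
                          pos = as.integer(fix[, "POS"]) - 1L,
                          ref = fix[, "REF"], alt = fix[, "ALT"],
                          depth = if (is.null(dp)) NA_real_ else dp)
  ds <- geno_dataset(t(dos), sites)
  meta <- NULL
  if (!is.null(metadata_path)) {
    meta <- tibble::as_tibble(utils::read.delim(metadata_path))
    if (!setequal(meta$sample, rownames(ds$geno))) {
      stop("sample ids in metadata do not match the VCF", call. = FALSE)
    }
    meta <- meta[match(rownames(ds$geno), meta$sample), ]
  }
  list(dataset = ds, meta = meta,
       report = tibble::tibble(filter = "multiallelic", removed = n_multi))
}

#' Write a simulated cohort to plain-text fixture files
#'
#' Emits `cohort.vcf` (VCF 4.2 with INFO/DP and phased GT where haplotypes
#' are available), `samples.tsv`, `sites.tsv` (site annotation),
#' `truth_haplotypes.tsv`, `truth_karyotypes.tsv`, `truth_pop_freq.tsv`,
#' `genes.tsv` and `env.tsv`. Output is byte-deterministic for a fixed
#' simulation seed. Round-trips losslessly through [read_vcf()] at the
#' dosage level.
#'
#' @param sim result of [simulate_cohort()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_fixture <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- sim$dataset
  vcf_path <- file.path(out_dir, "cohort.vcf")
  contigs <- unique(ds$sites$contig)
  con <- file(vcf_path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", contigs),
               "##INFO=<ID=DP,Number=1,Type=Float,Description=\"Mean depth\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(ds$geno)),
                     collapse = "\t")), con)
  gt_chr <- gt_strings(ds)
  depth <- if ("depth" %in% names(ds$sites)) ds$sites$depth else
    rep(NA_real_, n_variants(ds))
  if (n_variants(ds) > 0) {
    body <- paste(ds$sites$contig, ds$sites$pos + 1L, ".", ds$sites$ref,
                  ds$sites$alt, ".", "PASS",
                  ifelse(is.na(depth), ".", sprintf("DP=%.2f", depth)),
                  "GT", gt_chr, sep = "\t")
    writeLines(body, con)
  }
  tsv <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(sim$meta, "samples.tsv")
  tsv(sim$annotation, "sites.tsv")
  tsv(sim$truth$hap_labels, "truth_haplotypes.tsv")
  tsv(sim$truth$karyotypes, "truth_karyotypes.tsv")
  tsv(sim$truth$pop_freq, "truth_pop_freq.tsv")
  tsv(sim$truth$genes, "genes.tsv")
  tsv(sim$truth$env, "env.tsv")
  invisible(file.path(out_dir, c("cohort.vcf", "samples.tsv", "sites.tsv",
                                 "truth_haplotypes.tsv",
                                 "truth_karyotypes.tsv",
                                 "truth_pop_freq.tsv", "genes.tsv",
                                 "env.tsv")))
}

# per-variant vector of tab-joined GT strings across samples
gt_strings <- function(ds) {
  n <- n_samples(ds); m <- n_variants(ds)
  if (m == 0) return(character(0))
  if (!is.null(ds$haplotypes)) {
    h1 <- ds$haplotypes[seq(1, 2 * n, by = 2), , drop = FALSE]
    h2 <- ds$haplotypes[seq(2, 2 * n, by = 2), , drop = FALSE]
    gt <- matrix(paste(h1, h2, sep = "|"), nrow = n)
    gt[is.na(h2) & !is.na(h1)] <- as.character(h1[is.na(h2) & !is.na(h1)])
    gt[is.na(ds$geno)] <- "./."
    hemi <- !is.na(ds$geno) & !is.na(h1) & is.na(h2)
    gt[hemi] <- as.character(h1[hemi])
  } else {
    gt <- matrix(c("0/0", "0/1", "1/1")[ds$geno + 1L], nrow = n)
    gt[is.na(ds$geno)] <- "./."
  }
  apply(gt, 2, paste, collapse = "\t")
}

#' Apply post-calling site filters
#'
#' Removes, in order: sites within +/- `indel_margin` bp of a supplied indel
#' position; sites inside masked intervals; sites whose mean depth exceeds
#' the global mean + 1 SD; sites with significant heterozygote excess
#' (one-sided exact test, p < `het_p`, a paralog/duplication guard); sites
#' genotyped in less than `min_call_rate` of individuals.
#'
#' @param ds a [geno_dataset()].
#' @param indel_positions optional tibble `contig`, `pos` (0-based).
#' @param masks optional tibble `contig`, `start`, `end` (0-based half-open).
#' @param indel_margin bp margin around indels (sites strictly within).
#' @param depth_sd_mult depth cutoff multiplier (mean + mult * SD).
#' @param depth_cutoff explicit depth cutoff; when `NULL` (default) it is
#'   estimated from the input as mean + `depth_sd_mult` * SD. The estimate
#'   is data-derived, so re-running the filter on its own output
#'   re-estimates a lower cutoff; pass the reported cutoff to re-apply a
#'   fixed rule.
#' @param het_p heterozygote-excess significance threshold.
#' @param min_call_rate minimum fraction of genotyped individuals.
#' @return list with filtered `dataset`, a `report` tibble whose removed +
#'   surviving counts sum to the input, and `depth_cutoff` used.
#' @export
filter_sites <- function(ds, indel_positions = NULL, masks = NULL,
                         indel_margin = 5, depth_sd_mult = 1,
                         depth_cutoff = NULL, het_p = 0.01,
                         min_call_rate = 0.5) {
  report <- list()
  keep <- rep(TRUE, n_variants(ds))
  note <- function(name, removed) {
    report[[length(report) + 1]] <<- tibble::tibble(filter = name,
                                                    removed = removed)
  }

  if (!is.null(indel_positions) && nrow(indel_positions) > 0) {
    bad <- rep(FALSE, n_variants(ds))
    for (ct in unique(indel_positions$contig)) {
      ip <- sort(indel_positions$pos[indel_positions$contig == ct])
      si <- which(ds$sites$contig == ct & keep)
      if (length(si) == 0) next
      # nearest indel distance via findInterval on sorted positions
      ps <- ds$sites$pos[si]
      lo <- findInterval(ps, ip)
      d1 <- ifelse(lo >= 1, ps - ip[pmax(lo, 1)], Inf)
      d2 <- ifelse(lo < length(ip), ip[pmin(lo + 1, length(ip))] - ps, Inf)
      bad[si] <- pmin(d1, d2) <= indel_margin
    }
    note("indel_proximity", sum(bad & keep))
    keep <- keep & !bad
  } else note("indel_proximity", 0L)

  if (!is.null(masks) && nrow(masks) > 0) {
    bad <- rep(FALSE, n_variants(ds))
    for (i in seq_len(nrow(masks))) {
      bad <- bad | (ds$sites$contig == masks$contig[i] &
                      ds$sites$pos >= masks$start[i] &
                      ds$sites$pos < masks$end[i])
    }
    note("masked_region", sum(bad & keep))
    keep <- keep & !bad
  } else note("masked_region", 0L)

  if ("depth" %in% names(ds$sites) && !all(is.na(ds$sites$depth))) {
    d <- ds$sites$depth
    if (is.null(depth_cutoff)) {
      depth_cutoff <- mean(d[keep], na.rm = TRUE) +
        depth_sd_mult * stats::sd(d[keep], na.rm = TRUE)
    }
    bad <- !is.na(d) & d > depth_cutoff
    note("excess_depth", sum(bad & keep))
    keep <- keep & !bad
  } else note("excess_depth", 0L)

  if (het_p < 1) {
    idx <- which(keep)
    hp <- apply(ds$geno[, idx, drop = FALSE], 2, het_excess_p)
    bad <- rep(FALSE, n_variants(ds))
    bad[idx] <- hp < het_p
    note("het_excess", sum(bad))
    keep <- keep & !bad
  } else note("het_excess", 0L)

  call_rate <- colMeans(!is.na(ds$geno))
  bad <- call_rate < min_call_rate
  note("low_call_rate", sum(bad & keep))
  keep <- keep & !bad

  out <- subset_dataset(ds, sites = keep)
  report <- dplyr::bind_rows(report)
  report <- dplyr::bind_rows(report,
                             tibble::tibble(filter = "surviving",
                                            removed = sum(keep)))
  list(dataset = out, report = report, depth_cutoff = depth_cutoff)
}

#' Drop contigs below a minimum length
#'
#' Strictly greater-than comparison: a contig of exactly `min_len` is
#' dropped.
#'
#' @param ds a [geno_dataset()].
#' @param contig_lengths named vector of contig lengths in bp; contigs absent
#'   from the dataset are ignored.
#' @param min_len minimum length (bp).
#' @return filtered [geno_dataset()].
#' @export
filter_contigs <- function(ds, contig_lengths, min_len = 1e6) {
  keep_ct <- names(contig_lengths)[contig_lengths > min_len]
  subset_dataset(ds, sites = ds$sites$contig %in% keep_ct)
}

#' Thin SNPs for LD computation
#'
#' Greedy per-contig scan: keeps the first SNP with MAF above `maf_min`,
#' then the next eligible SNP at least `spacing` bp downstream, and so on,
#' guaranteeing all inter-SNP distances are at least `spacing`.
#'
#' @param ds a [geno_dataset()].
#' @param spacing minimum spacing in bp.
#' @param maf_min strict minor-allele-frequency threshold.
#' @return thinned [geno_dataset()].
#' @export
thin_for_ld <- function(ds, spacing = 1e4, maf_min = 0.05) {
  maf <- site_maf(ds)
  keep <- logical(n_variants(ds))
  for (ct in unique(ds$sites$contig)) {
    idx <- which(ds$sites$contig == ct)
    last <- -Inf
    for (i in idx) {
      if (!is.na(maf[i]) && maf[i] > maf_min &&
            ds$sites$pos[i] >= last + spacing) {
        keep[i] <- TRUE
        last <- ds$sites$pos[i]
      }
    }
  }
  subset_dataset(ds, sites = keep)
}

#' Infer an X-like contig from sex-differential coverage
#'
#' Normalizes each sample's per-contig depth by its own median and flags a
#' contig as X-like when the male:female ratio of median relative coverage
#' falls below `male_ratio_max` while female relative coverage stays near 1.
#'
#' @param ds a [geno_dataset()] carrying `sample_contig_depth`.
#' @param meta metadata tibble with `sample` and `sex` columns.
#' @param male_ratio_max flag threshold for the male:female coverage ratio.
#' @return list with `contig` (name or `NULL`) and `coverage`, a tibble of
#'   per-contig median relative coverage by sex.
#' @export
infer_sex_contig <- function(ds, meta, male_ratio_max = 0.75) {
  depth <- ds$sample_contig_depth
  if (is.null(depth)) stop("dataset has no per-sample contig depth",
                           call. = FALSE)
  if (is.null(meta$sex) || !any(meta$sex %in% c("F", "M"))) {
    return(list(contig = NULL, coverage = NULL))
  }
  rel <- depth / apply(depth, 1, stats::median)
  sex <- meta$sex[match(rownames(depth), meta$sample)]
  cov <- tibble::tibble(
    contig = colnames(depth),
    female = apply(rel[sex == "F", , drop = FALSE], 2, stats::median),
    male = apply(rel[sex == "M", , drop = FALSE], 2, stats::median))
  cov$ratio <- cov$male / cov$female
  hit <- cov$contig[cov$ratio < male_ratio_max &
                      abs(cov$female - 1) < 0.1]
  list(contig = if (length(hit)) hit[1] else NULL, coverage = cov)
}

#' Tile contigs with (possibly overlapping) windows
#'
#' Half-open windows `[start, start + size)` every `step` bp; the trailing
#' partial window is retained, and a contig shorter than `size` yields a
#' single window.
#'
#' @param contig_lengths named vector of contig lengths (bp).
#' @param size window size (bp).
#' @param step step between window starts (bp); `step = size` tiles without
#'   overlap.
#' @return tibble `contig`, `start`, `end`.
#' @export
make_windows <- function(contig_lengths, size = 1e5, step = size) {
  stopifnot(size >= step, step > 0)
  dplyr::bind_rows(lapply(names(contig_lengths), function(ct) {
    len <- contig_lengths[[ct]]
    starts <- seq(0, max(0, len - 1), by = step)
    starts <- starts[starts < len]
    tibble::tibble(contig = ct, start = starts,
                   end = pmin(starts + size, len))
  }))
}
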