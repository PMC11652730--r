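#' Windowed piN/piS mutation-load estimates
#'
#' For a sample group (for example the AA homokaryotypes of one inversion,
#' restricted to its interval, or all samples over collinear windows),
#' computes mean per-site nucleotide diversity at nonsynonymous (piN) and
#' synonymous (piS) sites per window and their ratio. Windows with at most
#' `min_genes` distinct genes are dropped; the whole group is rejected when
#' it has at most `min_individuals` members or fewer than `min_windows`
#' surviving windows.
#'
#' @param ds a [geno_dataset()].
#' @param annotation per-site tibble with `contig`, `pos`, `coding`
#'   (synonymous / nonsynonymous / intergenic) and `gene_id`.
#' @param samples the group's sample ids.
#' @param windows tibble from [make_windows()] (200-kb windows by
#'   convention).
#' @param group label recorded in the output.
#' @param min_individuals group size floor (strictly more required).
#' @param min_windows minimum surviving windows (at least this many).
#' @param min_genes per-window gene floor (strictly more required).
#' @return tibble: `group`, `contig`, `start`, `end`, `n_genes`, `n_nonsyn`,
#'   `n_syn`, `pi_n`, `pi_s`, `ratio` (NA where piS is 0). Zero rows when
#'   the group fails its thresholds (with a message).
#' @export
pin_pis_windows <- function(ds, annotation, samples, windows,
                            group = "group", min_individuals = 4,
                            min_windows = 4, min_genes = 5) {
  if (length(samples) <= min_individuals) {
    message(sprintf("group %s has %d individuals (<= %d); dropped",
                    group, length(samples), min_individuals))
    return(empty_load_windows())
  }
  key_ds <- paste(ds$sites$contig, ds$sites$pos)
  key_an <- paste(annotation$contig, annotation$pos)
  coding <- annotation$coding[match(key_ds, key_an)]
  gene <- annotation$gene_id[match(key_ds, key_an)]
  pi_site <- site_pi(ds, samples)
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    idx <- site_index(ds, windows$contig[i], windows$start[i],
                      windows$end[i])
    ns <- idx[!is.na(coding[idx]) & coding[idx] == "nonsynonymous"]
    sy <- idx[!is.na(coding[idx]) & coding[idx] == "synonymous"]
    genes <- unique(stats::na.omit(gene[idx]))
    pi_n <- if (length(ns)) mean(pi_site[ns], na.rm = TRUE) else NA_real_
    pi_s <- if (length(sy)) mean(pi_site[sy], na.rm = TRUE) else NA_real_
    tibble::tibble(group = group, contig = windows$contig[i],
                   start = windows$start[i], end = windows$end[i],
                   n_genes = length(genes), n_nonsyn = length(ns),
                   n_syn = length(sy), pi_n = pi_n, pi_s = pi_s,
                   ratio = ifelse(!is.na(pi_s) & pi_s > 0, pi_n / pi_s,
                                  NA_real_))
  })
  out <- dplyr::bind_rows(rows)
  out <- out[out$n_genes > min_genes & !is.na(out$ratio), ]
  if (nrow(out) < min_windows) {
    message(sprintf("group %s has %d usable windows (< %d); dropped",
                    group, nrow(out), min_windows))
    return(empty_load_windows())
  }
  out
}

empty_load_windows <- function() {
  tibble::tibble(group = character(0), contig = character(0),
                 start = numeric(0), end = numeric(0),
                 n_genes = integer(0), n_nonsyn = integer(0),
                 n_syn = integer(0), pi_n = numeric(0), pi_s = numeric(0),
                 ratio = numeric(0))
}

#' Restrict collinear windows to inversion-free contigs
#'
#' Strict filtering: drops every collinear window located on a contig that
#' carries any confirmed inversion (recombination suppression can leak
#' beyond inversion boundaries).
#'
#' @param windows window tibble with a `contig` column.
#' @param calls inversion call tibble with `contig`.
#' @return the filtered window tibble.
#' @export
strict_collinear <- function(windows, calls) {
  windows[!windows$contig %in% unique(calls$contig), , drop = FALSE]
}

#' Mutation-load contrasts
#'
#' Tests on per-window piN/piS ratios: inversions vs the collinear
#' background (two-sided Welch t and Wilcoxon rank-sum), minor vs major
#' homokaryotypes (one-sided, minor greater), and the correlation between
#' per-group median ratio and arrangement frequency.
#'
#' @param load_tbl row-bound output of [pin_pis_windows()]; column `group`
#'   distinguishes inversion groups from the collinear label.
#' @param col_label the collinear group's label.
#' @param roles optional tibble `group`, `role` (major / minor) for the
#'   minor-vs-major contrast.
#' @param freqs optional tibble `group`, `freq` for the frequency
#'   correlation.
#' @return tibble: `test`, `n1`, `n2`, `estimate`, `t_p`, `wilcox_p`.
#' @export
load_contrasts <- function(load_tbl, col_label = "COL", roles = NULL,
                           freqs = NULL) {
  out <- list()
  inv <- load_tbl$ratio[load_tbl$group != col_label]
  col <- load_tbl$ratio[load_tbl$group == col_label]
  if (length(inv) >= 4 && length(col) >= 4) {
    out[[length(out) + 1]] <- tibble::tibble(
      test = "inversion_vs_collinear", n1 = length(inv), n2 = length(col),
      estimate = stats::median(inv) - stats::median(col),
      t_p = stats::t.test(inv, col)$p.value,
      wilcox_p = stats::wilcox.test(inv, col)$p.value)
  }
  if (!is.null(roles)) {
    role <- roles$role[match(load_tbl$group, roles$group)]
    mino <- load_tbl$ratio[!is.na(role) & role == "minor"]
    majo <- load_tbl$ratio[!is.na(role) & role == "major"]
    if (length(mino) >= 4 && length(majo) >= 4) {
      out[[length(out) + 1]] <- tibble::tibble(
        test = "minor_vs_major", n1 = length(mino), n2 = length(majo),
        estimate = stats::median(mino) - stats::median(majo),
        t_p = stats::t.test(mino, majo,
                            alternative = "greater")$p.value,
        wilcox_p = stats::wilcox.test(mino, majo,
                                      alternative = "greater")$p.value)
    }
  }
  if (!is.null(freqs)) {
    med <- tapply(load_tbl$ratio, load_tbl$group, stats::median)
    med <- med[names(med) != col_label]
    f <- freqs$freq[match(names(med), freqs$group)]
    ok <- !is.na(f) & !is.na(med)
    if (sum(ok) >= 3) {
      ct <- stats::cor.test(med[ok], f[ok])
      out[[length(out) + 1]] <- tibble::tibble(
        test = "median_ratio_vs_frequency", n1 = sum(ok), n2 = NA_integer_,
        estimate = unname(ct$estimate), t_p = ct$p.value,
        wilcox_p = NA_real_)
    }
  }
  if (length(out) == 0) stop("insufficient windows for any contrast",
                             call. = FALSE)
  dplyr::bind_rows(out)
}

#' Neighbor-joining haplotype structuring check
#'
#' Builds a neighbor-joining tree of phased haplotypes within one
#' homokaryotype class from normalized Hamming distances (sites with MAF
#' below `maf_min` in the class are removed first) and flags "haplotype
#' structuring": a bipartition into two clades, each with at least
#' `min_tips` tips, whose mean between-clade distance exceeds `ratio_min`
#' times the pooled mean within-clade distance. The best bipartition over
#' the tree's internal splits is reported.
#'
#' @param hap matrix of phased haplotypes (rows) by sites (0/1; `NA`
#'   allowed).
#' @param maf_min within-class MAF filter.
#' @param ratio_min between/within distance ratio to flag structuring.
#' @param min_tips minimum tips per clade.
#' @return list: `tree` (an ape `phylo`), `structured` (flag), `ratio`
#'   (best between/within ratio), `groups` (tip membership of the best
#'   split), `newick`.
#' @export
nj_structuring <- function(hap, maf_min = 0.1, ratio_min = 2,
                           min_tips = 3) {
  if (nrow(hap) < 4) stop("need at least 4 haplotypes", call. = FALSE)
  f <- colMeans(hap, na.rm = TRUE)
  keep <- !is.na(f) & pmin(f, 1 - f) >= maf_min
  h <- hap[, keep, drop = FALSE]
  n <- nrow(h)
  if (is.null(rownames(h))) rownames(h) <- paste0("h", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(rownames(h), rownames(h)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(h[i, ]) & !is.na(h[j, ])
      d[i, j] <- d[j, i] <- if (any(ok))
        mean(h[i, ok] != h[j, ok]) else 0
    }
  }
  if (all(d == 0)) {
    # identical haplotypes: star tree, nothing to structure
    tr <- ape::stree(n, tip.label = rownames(h))
    tr$edge.length <- rep(0, nrow(tr$edge))
    return(list(tree = tr, structured = FALSE, ratio = NA_real_,
                groups = NULL, newick = ape::write.tree(tr)))
  }
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  parts <- ape::prop.part(tr)
  labs <- attr(parts, "labels")
  best <- list(ratio = -Inf, groups = NULL)
  for (pp in parts) {
    if (length(pp) < min_tips || n - length(pp) < min_tips) next
    g1 <- labs[pp]
    g2 <- setdiff(rownames(h), g1)
    between <- mean(d[g1, g2])
    within <- mean(c(d[g1, g1][upper.tri(d[g1, g1])],
                     d[g2, g2][upper.tri(d[g2, g2])]))
    ratio <- if (within > 0) between / within else Inf
    if (is.finite(ratio) || between > 0) {
      if (ratio > best$ratio) best <- list(ratio = ratio,
                                           groups = list(g1, g2))
    }
  }
  structured <- is.finite(best$ratio) && best$ratio > ratio_min
  if (!is.finite(best$ratio)) best$ratio <- NA_real_
  list(tree = tr, structured = structured, ratio = best$ratio,
       groups = best$groups, newick = ape::write.tree(tr))
}
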