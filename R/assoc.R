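#' Permutation test for gene enrichment within inversions
#'
#' Keeps gene positions fixed and relocates every inversion independently in
#' each permutation: a contig is chosen with probability proportional to its
#' length among contigs the interval fits on, then a uniform start such that
#' the interval fits; permuted intervals may overlap. The statistic is the
#' number of genes (midpoints) inside the union of inversion intervals, and
#' `p` is the fraction of permutations with a count greater than or equal to
#' the observed one (plain count / n convention).
#'
#' @param gene_positions tibble `contig`, `pos` (gene midpoints, bp).
#' @param inversions tibble `contig`, `start`, `end`.
#' @param contig_lengths named vector of contig lengths (bp).
#' @param n_perm permutations.
#' @return tibble: `observed`, `n_genes`, `expected_perm`, `p`, `n_perm`.
#' @export
or_enrichment <- function(gene_positions, inversions, contig_lengths,
                          n_perm = 10000) {
  n_genes <- nrow(gene_positions)
  if (nrow(inversions) == 0) {
    return(tibble::tibble(observed = 0L, n_genes = n_genes,
                          expected_perm = 0, p = 1, n_perm = n_perm))
  }
  lens <- inversions$end - inversions$start
  if (any(vapply(lens, function(L) all(contig_lengths < L), logical(1)))) {
    stop("an inversion is longer than every contig", call. = FALSE)
  }
  count_inside <- function(ct, st, en) {
    # distinct genes covered by the union of the intervals
    inside <- rep(FALSE, n_genes)
    for (i in seq_along(ct)) {
      inside <- inside | (gene_positions$contig == ct[i] &
                            gene_positions$pos >= st[i] &
                            gene_positions$pos < en[i])
    }
    sum(inside)
  }
  observed <- count_inside(inversions$contig, inversions$start,
                           inversions$end)
  ni <- nrow(inversions)
  cts <- names(contig_lengths)
  # pre-draw placements: for each inversion, contigs ~ length among fits
  perm_counts <- rep(0L, n_perm)
  inside_mat <- matrix(FALSE, nrow = n_perm, ncol = n_genes)
  for (i in seq_len(ni)) {
    L <- lens[i]
    fits <- contig_lengths >= L
    w <- contig_lengths[fits] / sum(contig_lengths[fits])
    ct_i <- sample(cts[fits], n_perm, replace = TRUE, prob = w)
    max_start <- contig_lengths[ct_i] - L
    st_i <- floor(stats::runif(n_perm) * (max_start + 1))
    en_i <- st_i + L
    for (j in seq_len(n_genes)) {
      inside_mat[, j] <- inside_mat[, j] |
        (ct_i == gene_positions$contig[j] &
           gene_positions$pos[j] >= st_i & gene_positions$pos[j] < en_i)
    }
  }
  perm_counts <- rowSums(inside_mat)
  out <- tibble::tibble(observed = observed, n_genes = n_genes,
                        expected_perm = mean(perm_counts),
                        p = mean(perm_counts >= observed), n_perm = n_perm)
  # raw permutation counts, e.g. for tie-aware calibration diagnostics
  attr(out, "perm_counts") <- perm_counts
  out
}

#' Divergence scan over genes inside genotyped inversions
#'
#' For each nonsynonymous SNP inside a flagged gene within a genotyped
#' inversion, computes dxy between the AA and BB homokaryote groups and
#' flags fixed or nearly fixed differences (dxy above `dxy_flag`).
#'
#' @param ds a [geno_dataset()].
#' @param annotation per-site tibble (`contig`, `pos`, `coding`, `gene_id`,
#'   `or_flag`).
#' @param calls inversion call tibble (`id`, `contig`, `start`, `end`).
#' @param kts named list of `inv_karyotype` tables.
#' @param dxy_flag divergence threshold.
#' @param or_only restrict to OR-flagged genes.
#' @return tibble: `gene_id`, `inversion`, `n_nonsyn`, `max_dxy`,
#'   `n_diverged`.
#' @export
or_divergence_scan <- function(ds, annotation, calls, kts, dxy_flag = 0.9,
                               or_only = TRUE) {
  key_ds <- paste(ds$sites$contig, ds$sites$pos)
  key_an <- paste(annotation$contig, annotation$pos)
  ann <- annotation[match(key_ds, key_an), ]
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    id <- calls$id[i]
    kt <- kts[[id]]
    if (is.null(kt)) next
    aa <- kt$sample[kt$genotype == "AA"]
    bb <- kt$sample[kt$genotype == "BB"]
    if (length(aa) < 2 || length(bb) < 2) next
    idx <- site_index(ds, calls$contig[i], calls$start[i], calls$end[i])
    sel <- idx[!is.na(ann$gene_id[idx]) &
                 ann$coding[idx] == "nonsynonymous"]
    if (or_only) sel <- sel[ann$or_flag[sel]]
    if (length(sel) == 0) next
    sub <- subset_dataset(ds, sites = sel)
    dxy <- site_dxy(site_freq(sub, aa), site_freq(sub, bb))
    per_gene <- split(dxy, ann$gene_id[sel])
    for (g in names(per_gene)) {
      v <- per_gene[[g]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene_id = g, inversion = id, n_nonsyn = length(v),
        max_dxy = max(v, na.rm = TRUE),
        n_diverged = sum(v > dxy_flag, na.rm = TRUE))
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(gene_id = character(0), inversion = character(0),
                          n_nonsyn = integer(0), max_dxy = numeric(0),
                          n_diverged = integer(0)))
  }
  dplyr::bind_rows(rows)
}

#' dN/dS and McDonald-Kreitman test from substitution counts
#'
#' Counting-method dN/dS: substitutions per effective nonsynonymous site
#' over substitutions per effective synonymous site between two
#' arrangement classes; the McDonald-Kreitman test is Fisher's exact test
#' on the 2x2 table of fixed vs polymorphic, nonsynonymous vs synonymous
#' counts.
#'
#' @param fixed_n,fixed_s fixed nonsynonymous / synonymous differences.
#' @param poly_n,poly_s polymorphic nonsynonymous / synonymous sites.
#' @param sites_n,sites_s effective numbers of nonsynonymous / synonymous
#'   sites.
#' @return tibble: `dn`, `ds`, `dnds` (Inf with `dnds_undefined` flag when
#'   dS is 0), `mk_odds`, `mk_p`.
#' @export
or_dnds_mk <- function(fixed_n, fixed_s, poly_n, poly_s,
                       sites_n, sites_s) {
  dn <- fixed_n / sites_n
  dsv <- fixed_s / sites_s
  dnds <- if (dsv == 0) Inf else dn / dsv
  tab <- matrix(c(fixed_n, fixed_s, poly_n, poly_s), nrow = 2)
  ft <- stats::fisher.test(tab)
  tibble::tibble(dn = dn, ds = dsv, dnds = dnds,
                 dnds_undefined = dsv == 0,
                 mk_odds = unname(ft$estimate), mk_p = ft$p.value)
}

#' Coverage contrast between homokaryote classes per gene
#'
#' Deletion check: compares per-sample mean depth within each gene between
#' AA and BB homokaryotes; a gene is flagged as a candidate hemizygous
#' deletion when the depth ratio is outside `[ratio_lo, 1/ratio_lo]` with a
#' Wilcoxon p below `p_flag`.
#'
#' @param depth_tbl tibble `sample`, `gene_id`, `depth`.
#' @param kt the inversion's `inv_karyotype`.
#' @param ratio_lo lower ratio bound for flagging.
#' @param p_flag Wilcoxon significance for flagging.
#' @return tibble: `gene_id`, `ratio`, `p`, `flag`.
#' @export
or_coverage_contrast <- function(depth_tbl, kt, ratio_lo = 0.6,
                                 p_flag = 0.01) {
  geno <- kt$genotype[match(depth_tbl$sample, kt$sample)]
  rows <- lapply(split(seq_len(nrow(depth_tbl)), depth_tbl$gene_id),
                 function(ii) {
    da <- depth_tbl$depth[ii][geno[ii] == "AA"]
    db <- depth_tbl$depth[ii][geno[ii] == "BB"]
    da <- da[!is.na(da)]; db <- db[!is.na(db)]
    if (length(da) < 2 || length(db) < 2) {
      return(tibble::tibble(gene_id = depth_tbl$gene_id[ii][1],
                            ratio = NA_real_, p = NA_real_, flag = FALSE))
    }
    ratio <- mean(da) / mean(db)
    p <- suppressWarnings(stats::wilcox.test(da, db)$p.value)
    tibble::tibble(gene_id = depth_tbl$gene_id[ii][1], ratio = ratio,
                   p = p,
                   flag = (ratio < ratio_lo | ratio > 1 / ratio_lo) &
                     !is.na(p) & p < p_flag)
  })
  dplyr::bind_rows(rows)
}

#' PCA of per-population environmental variables
#'
#' Variables are z-scored (constant variables dropped with a warning);
#' components follow the deterministic sign convention used throughout the
#' package.
#'
#' @param env tibble with a `population` column and numeric environment
#'   columns.
#' @param n_pc components to return.
#' @return list of class `env_pca`: `scores` (tibble), `explained`,
#'   `loadings`.
#' @export
env_pca <- function(env, n_pc = 3) {
  num <- env[vapply(env, is.numeric, logical(1))]
  num <- num[setdiff(names(num), c("lat", "lon"))]
  sds <- vapply(num, stats::sd, numeric(1))
  if (any(sds == 0)) {
    warning(sprintf("dropping constant variable(s): %s",
                    paste(names(num)[sds == 0], collapse = ", ")),
            call. = FALSE)
    num <- num[sds > 0]
  }
  if (ncol(num) < 2 || nrow(num) < 2) {
    stop("need at least 2 populations and 2 variable(s)", call. = FALSE)
  }
  x <- scale(as.matrix(num))
  sv <- svd(x)
  k <- min(n_pc, length(sv$d))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)],
                                                      k, k)
  fx <- fix_signs(scores, sv$v[, seq_len(k), drop = FALSE])
  eig <- sv$d^2 / (nrow(x) - 1)
  sc <- tibble::as_tibble(fx$scores,
                          .name_repair = ~ paste0("PC", seq_len(k)))
  sc <- dplyr::bind_cols(tibble::tibble(population = env$population), sc)
  rownames(fx$loadings) <- colnames(num)
  structure(list(scores = sc, explained = eig[seq_len(k)] / sum(eig),
                 loadings = fx$loadings),
            class = "env_pca")
}

#' Ridge latent-factor genotype-environment association
#'
#' A latent-factor mixed model fitted in closed form: (1) loci are
#' regressed on the environmental covariates; (2) `k` latent factors are
#' the top left singular vectors of the residual matrix (confounding
#' structure); (3) per-locus environmental effects are re-estimated jointly
#' with the factors by ordinary least squares; (4) z-scores are calibrated
#' with a genomic-inflation factor (median chi-squared / 0.456) per
#' covariate and converted to two-sided p-values; (5) Benjamini-Hochberg
#' q-values are attached. With `k = 0` the model reduces to ordinary
#' per-locus regression.
#'
#' @param Y samples-by-loci dosage matrix (missing entries mean-imputed).
#' @param X samples-by-covariates matrix (for example per-sample values of
#'   environmental PCs).
#' @param k number of latent factors (`k < min(dim)` required).
#' @return tibble of class `gea_result`: `locus`, `covariate`, `effect`,
#'   `z`, `p`, `q`; attributes `k`, `lambda` (inflation factors).
#' @export
lfmm_ridge <- function(Y, X, k = 5) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(Y)
  stopifnot(nrow(X) == n)
  if (k >= min(n, ncol(Y))) stop("k must be below min(n_samples, n_loci)",
                                 call. = FALSE)
  # mean-impute and center
  mu <- colMeans(Y, na.rm = TRUE)
  miss <- which(is.na(Y))
  if (length(miss)) Y[miss] <- mu[(miss - 1) %/% n + 1]
  Yc <- sweep(Y, 2, colMeans(Y))
  Xc <- sweep(X, 2, colMeans(X))
  # step 1-2: latent factors from the residuals of the env regression
  if (k > 0) {
    bx <- solve(crossprod(Xc), crossprod(Xc, Yc))
    R <- Yc - Xc %*% bx
    sv <- svd(R, nu = k, nv = 0)
    Fm <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
    D <- cbind(Xc, Fm)
  } else D <- Xc
  # step 3: joint OLS, vectorized across loci
  XtX_inv <- solve(crossprod(D))
  B <- XtX_inv %*% crossprod(D, Yc)
  resid <- Yc - D %*% B
  df <- n - ncol(D) - 1
  sigma2 <- colSums(resid^2) / df
  e <- ncol(Xc)
  se <- sqrt(outer(diag(XtX_inv)[seq_len(e)], sigma2))
  zmat <- B[seq_len(e), , drop = FALSE] / se
  lambda <- apply(zmat, 1, function(z) {
    stats::median(z^2, na.rm = TRUE) / stats::qchisq(0.5, 1)
  })
  lambda[!is.finite(lambda) | lambda <= 0] <- 1
  covn <- colnames(X)
  if (is.null(covn)) covn <- paste0("X", seq_len(e))
  locn <- colnames(Y)
  if (is.null(locn)) locn <- paste0("locus", seq_len(ncol(Y)))
  rows <- lapply(seq_len(e), function(l) {
    z <- zmat[l, ]
    pz <- 2 * stats::pnorm(-abs(z) / sqrt(lambda[l]))
    tibble::tibble(locus = locn, covariate = covn[l],
                   effect = B[l, ], z = z, p = pz,
                   q = stats::p.adjust(pz, method = "BH"))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("gea_result", class(out))
  attr(out, "k") <- k
  attr(out, "lambda") <- stats::setNames(lambda, covn)
  out
}

#' Apply the GEA locus and sample filters and run the latent-factor model
#'
#' Standard pre-filters: loci with at most `max_locus_missing` missing
#' data and MAF at least `maf_min`, samples with less than
#' `max_sample_missing` missing data; SNPs inside inversion intervals can
#' be excluded and each inversion appended as a single pseudo-locus coded
#' 0/1/2.
#'
#' @param ds a [geno_dataset()].
#' @param env_scores tibble `population`, `PC1`, ... (per-population
#'   covariates, expanded to samples via `meta`).
#' @param meta metadata tibble.
#' @param k latent factors.
#' @param covariates covariate column names in `env_scores`.
#' @param maf_min,max_locus_missing,max_sample_missing filters.
#' @param exclude optional inversion intervals to drop SNPs from.
#' @param inversion_loci optional named list of `inv_karyotype` tables
#'   appended as single loci.
#' @return a `gea_result` (see [lfmm_ridge()]).
#' @export
run_gea <- function(ds, env_scores, meta, k = 5,
                    covariates = c("PC1", "PC2"),
                    maf_min = 0.1, max_locus_missing = 0.2,
                    max_sample_missing = 0.3, exclude = NULL,
                    inversion_loci = NULL) {
  keep_s <- rowMeans(is.na(ds$geno)) < max_sample_missing
  g <- ds$geno[keep_s, , drop = FALSE]
  maf <- site_maf(ds)
  keep_l <- colMeans(is.na(g)) <= max_locus_missing & !is.na(maf) &
    maf >= maf_min
  if (!is.null(exclude) && nrow(exclude) > 0) {
    for (i in seq_len(nrow(exclude))) {
      keep_l <- keep_l & !(ds$sites$contig == exclude$contig[i] &
                             ds$sites$pos >= exclude$start[i] &
                             ds$sites$pos < exclude$end[i])
    }
  }
  Y <- g[, keep_l, drop = FALSE]
  colnames(Y) <- paste(ds$sites$contig[keep_l], ds$sites$pos[keep_l],
                       sep = ":")
  if (!is.null(inversion_loci)) {
    IL <- inversion_as_locus(inversion_loci)
    Y <- cbind(Y, IL[rownames(Y), , drop = FALSE])
  }
  pop <- meta$population[match(rownames(Y), meta$sample)]
  X <- as.matrix(env_scores[match(pop, env_scores$population), covariates,
                            drop = FALSE])
  lfmm_ridge(Y, X, k = k)
}

#' Encode inversion karyotypes as single loci
#'
#' AA = 0, AB = 1, BB = 2 (B-arrangement dosage); everything else `NA`.
#'
#' @param kts named list of `inv_karyotype` tables over the same samples.
#' @return samples-by-inversions numeric matrix.
#' @export
inversion_as_locus <- function(kts) {
  stopifnot(length(kts) > 0)
  samples <- kts[[1]]$sample
  out <- vapply(kts, function(kt) {
    unname(karyotype_dosage(kt$genotype[match(samples, kt$sample)]))
  }, numeric(length(samples)))
  if (is.null(dim(out))) out <- matrix(out, nrow = length(samples))
  rownames(out) <- samples
  colnames(out) <- names(kts)
  out
}
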