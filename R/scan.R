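# mean-impute missing dosages per site and center columns
center_impute <- function(g) {
  mu <- colMeans(g, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  miss <- which(is.na(g))
  if (length(miss)) g[miss] <- mu[(miss - 1) %/% nrow(g) + 1]
  sweep(g, 2, mu)
}

# deterministic sign: flip each component so its largest-|loading| entry is
# positive
fix_signs <- function(scores, loadings) {
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, loadings = loadings)
}

#' PCA of a contig's dosage matrix
#'
#' Mean-imputed, centered dosage PCA; the first screen for inversions (an
#' inversion shows up as three sample clusters on some component). Scores
#' are deterministic: each component is oriented so its largest-magnitude
#' SNP loading is positive.
#'
#' @param ds a [geno_dataset()].
#' @param contig contig name (`NULL` for all sites).
#' @param maf_min drop sites at or below this minor allele frequency.
#' @param n_pc number of components to return.
#' @return list with `scores` (tibble: sample, PC1..), `eig` (eigenvalues,
#'   i.e. variances), `explained` (fractions), `loadings`.
#' @export
contig_pca <- function(ds, contig = NULL, maf_min = 0, n_pc = 4) {
  idx <- if (is.null(contig)) seq_len(n_variants(ds)) else
    site_index(ds, contig)
  maf <- site_maf(ds)[idx]
  idx <- idx[!is.na(maf) & maf > maf_min]
  if (length(idx) < 2 || n_samples(ds) < 2) {
    stop("need at least 2 polymorphic SNPs and 2 samples", call. = FALSE)
  }
  x <- center_impute(ds$geno[, idx, drop = FALSE])
  if (all(abs(x) < 1e-12)) stop("contig is monomorphic", call. = FALSE)
  sv <- svd(x, nu = min(n_pc, nrow(x) - 1), nv = min(n_pc, nrow(x) - 1))
  k <- min(n_pc, length(sv$d), nrow(x) - 1)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)],
                                                      k, k)
  fx <- fix_signs(scores, sv$v[, seq_len(k), drop = FALSE])
  eig <- sv$d^2 / (nrow(x) - 1)
  sc <- tibble::as_tibble(fx$scores, .name_repair = ~ paste0("PC",
                                                             seq_len(k)))
  sc <- dplyr::bind_cols(tibble::tibble(sample = rownames(ds$geno)), sc)
  list(scores = sc, eig = eig[seq_len(k)],
       explained = eig[seq_len(k)] / sum(eig), loadings = fx$loadings,
       sites = idx)
}

#' Local PCA along a contig with MDS embedding of window distances
#'
#' Windows are consecutive runs of `window_snps` SNPs (or fixed-bp windows
#' when `window_bp` is given). Each window is summarized by the rank-`k`
#' reconstruction of its sample-by-sample covariance, trace-normalized; the
#' distance between windows is the Frobenius distance between these
#' reconstructions (rotation-invariant, deterministic), and classical metric
#' MDS embeds the window distance matrix.
#'
#' @param ds a [geno_dataset()].
#' @param contig contig name.
#' @param window_snps SNPs per window (default 100).
#' @param window_bp optional window size in bp, overriding `window_snps`.
#' @param k number of principal components retained per window.
#' @param n_mds number of MDS axes.
#' @return object of class `local_pca`: list with `windows` (tibble:
#'   contig, start, end, n_snps, mds1..), `dist` (window distance matrix),
#'   `k`.
#' @export
local_pca <- function(ds, contig, window_snps = 100, window_bp = NULL,
                      k = 2, n_mds = 2) {
  idx <- site_index(ds, contig)
  if (length(idx) < 3 * (k + 1)) stop("too few SNPs for local PCA",
                                      call. = FALSE)
  if (is.null(window_bp)) {
    grp <- (seq_along(idx) - 1) %/% window_snps
    # fold a trailing stub into the last full window
    if (sum(grp == max(grp)) <= k) grp[grp == max(grp)] <- max(grp) - 1
    win_idx <- split(idx, grp)
  } else {
    b <- ds$sites$pos[idx] %/% window_bp
    win_idx <- split(idx, b)
  }
  win_idx <- win_idx[vapply(win_idx, length, integer(1)) >= k + 1]
  W <- length(win_idx)
  if (W < 3) stop("need at least 3 usable windows", call. = FALSE)
  n <- n_samples(ds)
  V <- vector("list", W)
  for (w in seq_len(W)) {
    x <- center_impute(ds$geno[, win_idx[[w]], drop = FALSE])
    sv <- svd(x, nu = k, nv = 0)
    lam <- sv$d^2
    lam_n <- lam[seq_len(k)] / sum(lam)   # trace-normalized spectrum
    V[[w]] <- sv$u[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(lam_n), k, k)
  }
  Vmat <- do.call(cbind, V)               # n x (k W)
  M <- crossprod(Vmat)                    # inner products of all factors
  tr2 <- matrix(0, W, W)
  for (i in seq_len(W)) {
    ri <- ((i - 1) * k + 1):(i * k)
    for (j in i:W) {
      rj <- ((j - 1) * k + 1):(j * k)
      tr2[i, j] <- tr2[j, i] <- sum(M[ri, rj]^2)
    }
  }
  d2 <- outer(diag(tr2), diag(tr2), "+") - 2 * tr2
  d <- sqrt(pmax(d2, 0))
  n_mds <- min(n_mds, W - 1)
  mds <- stats::cmdscale(stats::as.dist(d), k = n_mds)
  # deterministic orientation per axis
  for (j in seq_len(ncol(mds))) {
    i <- which.max(abs(mds[, j]))
    if (mds[i, j] < 0) mds[, j] <- -mds[, j]
  }
  windows <- tibble::tibble(
    contig = contig,
    start = vapply(win_idx, function(ii) min(ds$sites$pos[ii]), numeric(1)),
    end = vapply(win_idx, function(ii) max(ds$sites$pos[ii]) + 1,
                 numeric(1)),
    n_snps = vapply(win_idx, length, integer(1)))
  for (j in seq_len(ncol(mds))) windows[[paste0("mds", j)]] <- mds[, j]
  structure(list(windows = windows, dist = d, k = k, contig = contig),
            class = "local_pca")
}

#' @export
print.local_pca <- function(x, ...) {
  cat(sprintf("<local_pca> %s: %d windows, rank-%d window covariances\n",
              x$contig, nrow(x$windows), x$k))
  invisible(x)
}

# merge flagged window indices into regions, allowing gaps of up to
# max_gap unflagged windows between flagged ones
merge_flagged <- function(flagged, max_gap) {
  if (length(flagged) == 0) return(list())
  flagged <- sort(flagged)
  runs <- list()
  s <- flagged[1]; e <- flagged[1]
  for (f in flagged[-1]) {
    if (f - e - 1 <= max_gap) e <- f
    else {
      runs[[length(runs) + 1]] <- c(s, e)
      s <- f; e <- f
    }
  }
  runs[[length(runs) + 1]] <- c(s, e)
  runs
}

#' Candidate regions from MDS outlier windows
#'
#' Windows whose MDS score deviates from the mean by more than `sd_mult`
#' standard deviations are flagged (two-sided by default; MDS axes are
#' sign-indeterminate, and a one-sided greater-than rule is available via
#' `side`); flagged windows separated by at most `max_gap` unflagged windows
#' are merged into one candidate region.
#'
#' @param res a [local_pca()] result.
#' @param sd_mult outlier threshold in SD units.
#' @param max_gap maximum number of unflagged windows bridged when merging.
#' @param axis MDS axis used.
#' @param side `"two"` or `"greater"`.
#' @return tibble of candidate regions: `contig`, `start`, `end`,
#'   `n_windows`, `evidence`, `score` (max |z| inside).
#' @export
mds_outlier_regions <- function(res, sd_mult = 2, max_gap = 20, axis = 1,
                                side = c("two", "greater")) {
  side <- match.arg(side)
  x <- res$windows[[paste0("mds", axis)]]
  z <- (x - mean(x)) / stats::sd(x)
  if (!is.finite(stats::sd(x)) || stats::sd(x) == 0) {
    return(empty_regions())
  }
  flagged <- if (side == "two") which(abs(z) > sd_mult) else
    which(z > sd_mult)
  runs <- merge_flagged(flagged, max_gap)
  if (length(runs) == 0) return(empty_regions())
  dplyr::bind_rows(lapply(runs, function(r) {
    tibble::tibble(contig = res$contig,
                   start = res$windows$start[r[1]],
                   end = res$windows$end[r[2]],
                   n_windows = r[2] - r[1] + 1L,
                   n_flagged = sum(flagged >= r[1] & flagged <= r[2]),
                   evidence = "mds_outlier",
                   score = max(abs(z[r[1]:r[2]])))
  }))
}

empty_regions <- function() {
  tibble::tibble(contig = character(0), start = numeric(0),
                 end = numeric(0), n_windows = integer(0),
                 n_flagged = integer(0),
                 evidence = character(0), score = numeric(0))
}

# deterministic 1-D k-means with quantile seeding
kmeans_1d <- function(x, k) {
  if (k == 1) return(list(cluster = rep(1L, length(x)), centers = mean(x)))
  q <- stats::quantile(x, probs = seq(0.05, 0.95, length.out = k),
                       names = FALSE)
  q <- q + seq_len(k) * 1e-9        # break exact ties in seeds
  fit <- suppressWarnings(stats::kmeans(x, centers = matrix(q, ncol = 1)))
  list(cluster = fit$cluster, centers = drop(fit$centers))
}

#' Candidate regions by k-means segmentation of MDS scores
#'
#' 1-D k-means (deterministic quantile seeding) on the first MDS axis;
#' contiguous runs of windows assigned to any non-majority cluster become
#' candidate regions.
#'
#' @param res a [local_pca()] result.
#' @param k number of clusters (`k = 1` yields no regions).
#' @param axis MDS axis used.
#' @return tibble of candidate regions (`evidence = "kmeans_segment"`).
#' @export
kmeans_mds_segmentation <- function(res, k = 2, axis = 1) {
  x <- res$windows[[paste0("mds", axis)]]
  if (k > length(x)) stop("k exceeds the number of windows", call. = FALSE)
  if (k == 1) return(empty_regions())
  cl <- kmeans_1d(x, k)$cluster
  major <- as.integer(names(which.max(table(cl))))
  flagged <- which(cl != major)
  runs <- merge_flagged(flagged, 0)
  if (length(runs) == 0) return(empty_regions())
  dplyr::bind_rows(lapply(runs, function(r) {
    tibble::tibble(contig = res$contig,
                   start = res$windows$start[r[1]],
                   end = res$windows$end[r[2]],
                   n_windows = r[2] - r[1] + 1L,
                   n_flagged = r[2] - r[1] + 1L,
                   evidence = "kmeans_segment",
                   score = NA_real_)
  }))
}

#' Pairwise LD (r-squared) matrix for a thinned contig
#'
#' Squared Pearson correlation of dosage vectors over pairwise-complete
#' samples. Intended for datasets thinned with [thin_for_ld()].
#'
#' @param ds a (thinned) [geno_dataset()].
#' @param contig contig name (`NULL`: all sites, assumed one contig).
#' @return object of class `ld_matrix`: list with `pos` (bp) and `r2`.
#' @export
ld_r2 <- function(ds, contig = NULL) {
  idx <- if (is.null(contig)) seq_len(n_variants(ds)) else
    site_index(ds, contig)
  g <- ds$geno[, idx, drop = FALSE]
  r <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))
  structure(list(pos = ds$sites$pos[idx], r2 = r^2,
                 contig = if (is.null(contig))
                   ds$sites$contig[idx[1]] else contig),
            class = "ld_matrix")
}

#' Detect high-LD blocks
#'
#' Greedy, deterministic scan: starting from the leftmost adjacent pair with
#' r-squared above `r2_min`, the block is extended rightward while the
#' median of all pairwise r-squared values inside stays above `r2_min`
#' ("most SNPs in high LD"); blocks spanning at least `min_span` bp are
#' reported.
#'
#' @param ld an [ld_r2()] result.
#' @param r2_min median r-squared threshold.
#' @param min_span minimum block span in bp.
#' @param max_weak maximum run of consecutive SNPs whose own LD with the
#'   block is weak before the block is closed at the last strong SNP
#'   (tolerates interspersed low-LD sites without letting the block swallow
#'   unlinked flanks on its median majority).
#' @return tibble of candidate regions (`evidence = "ld_block"`, `score` =
#'   median r-squared inside the block).
#' @export
ld_block_detect <- function(ld, r2_min = 0.4, min_span = 0, max_weak = 5) {
  m <- length(ld$pos)
  out <- list()
  i <- 1
  while (i < m) {
    if (!is.na(ld$r2[i, i + 1]) && ld$r2[i, i + 1] > r2_min) {
      vals <- ld$r2[i, i + 1]
      b <- i + 1
      b_strong <- b
      weak_run <- 0
      while (b < m && weak_run < max_weak) {
        new <- ld$r2[i:b, b + 1]
        cand <- c(vals, new[!is.na(new)])
        if (stats::median(cand) <= r2_min) break
        vals <- cand
        b <- b + 1
        if (!is.na(stats::median(new, na.rm = TRUE)) &&
              stats::median(new, na.rm = TRUE) > r2_min) {
          b_strong <- b
          weak_run <- 0
        } else weak_run <- weak_run + 1
      }
      b <- b_strong
      span <- ld$pos[b] - ld$pos[i]
      if (span >= min_span) {
        blk <- ld$r2[i:b, i:b]
        out[[length(out) + 1]] <- tibble::tibble(
          contig = ld$contig, start = ld$pos[i], end = ld$pos[b] + 1,
          n_windows = b - i + 1L, n_flagged = b - i + 1L,
          evidence = "ld_block",
          score = stats::median(blk[upper.tri(blk)], na.rm = TRUE))
      }
      i <- b + 1
    } else i <- i + 1
  }
  if (length(out) == 0) return(empty_regions())
  dplyr::bind_rows(out)
}

#' Scan one contig for candidate inversion regions
#'
#' The standard detection pass combining both signals: local-PCA windows
#' with MDS outlier calling (one-sided, as inversions are pushed to one
#' extreme of the first MDS axis under the deterministic orientation used
#' here) and LD block detection on a thinned SNP set. MDS regions
#' supported by fewer than `min_flagged` outlier windows are discarded as
#' single-window noise.
#'
#' @param ds a [geno_dataset()].
#' @param contig contig name.
#' @param window_snps SNPs per local-PCA window.
#' @param sd_mult,max_gap,side MDS outlier parameters
#'   (see [mds_outlier_regions()]).
#' @param min_flagged minimum outlier windows per reported MDS region.
#' @param r2_min,min_span LD block parameters (see [ld_block_detect()]).
#' @param spacing,maf_min thinning parameters (see [thin_for_ld()]).
#' @return tibble of candidate regions from both evidence streams.
#' @export
scan_contig <- function(ds, contig, window_snps = 50, sd_mult = 2,
                        max_gap = 20, side = "greater", min_flagged = 2,
                        r2_min = 0.4, min_span = 2e5, spacing = 1e4,
                        maf_min = 0.05) {
  lp <- local_pca(ds, contig, window_snps = window_snps)
  mr <- mds_outlier_regions(lp, sd_mult = sd_mult, max_gap = max_gap,
                            side = side)
  mr <- mr[mr$n_flagged >= min_flagged, , drop = FALSE]
  thin <- thin_for_ld(ds, spacing = spacing, maf_min = maf_min)
  lb <- if (n_variants(thin) >= 3 &&
              sum(thin$sites$contig == contig) >= 3) {
    ld_block_detect(ld_r2(thin, contig), r2_min = r2_min,
                    min_span = min_span)
  } else empty_regions()
  dplyr::bind_rows(mr, lb)
}
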