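#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a local-PCA result
#'
#' @param x a [local_pca()] result.
#' @param ... unused.
#' @return the window tibble with MDS coordinates.
#' @method tidy local_pca
#' @export
tidy.local_pca <- function(x, ...) x$windows

#' @rdname tidy.local_pca
#' @method glance local_pca
#' @export
glance.local_pca <- function(x, ...) {
  tibble::tibble(contig = x$contig, n_windows = nrow(x$windows),
                 k = x$k,
                 mds1_sd = stats::sd(x$windows$mds1))
}

#' Tidy an inversion karyotype table
#'
#' @param x an `inv_karyotype`.
#' @param ... unused.
#' @return plain tibble of per-sample assignments.
#' @method tidy inv_karyotype
#' @export
tidy.inv_karyotype <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.inv_karyotype
#' @method glance inv_karyotype
#' @export
glance.inv_karyotype <- function(x, ...) {
  d <- attr(x, "diagnostics")
  r <- attr(x, "region")
  tibble::tibble(contig = r$contig, start = r$start, end = r$end,
                 n_snps = r$n_snps, status = attr(x, "status"),
                 n_AA = sum(x$genotype == "AA"),
                 n_AB = sum(x$genotype == "AB"),
                 n_BB = sum(x$genotype == "BB"),
                 n_unassigned = sum(x$genotype == "unassigned"),
                 het_p_left = d$p_left, het_p_right = d$p_right,
                 mid_pos = d$mid_pos)
}

#' Tidy a genotype-environment association result
#'
#' @param x a `gea_result` from [lfmm_ridge()].
#' @param ... unused.
#' @return per-locus tibble of effects, z, p and q.
#' @method tidy gea_result
#' @export
tidy.gea_result <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.gea_result
#' @method glance gea_result
#' @export
glance.gea_result <- function(x, ...) {
  lam <- attr(x, "lambda")
  tibble::tibble(k = attr(x, "k"), n_loci = length(unique(x$locus)),
                 n_covariates = length(lam),
                 lambda_mean = mean(lam),
                 n_hits_q10 = sum(x$q < 0.1, na.rm = TRUE))
}

#' Tidy an environment PCA
#'
#' @param x an [env_pca()] result.
#' @param ... unused.
#' @return score tibble.
#' @method tidy env_pca
#' @export
tidy.env_pca <- function(x, ...) x$scores

#' @rdname tidy.env_pca
#' @method glance env_pca
#' @export
glance.env_pca <- function(x, ...) {
  tibble::tibble(n_pc = length(x$explained),
                 explained_pc1 = x$explained[1],
                 explained_pc2 = if (length(x$explained) > 1)
                   x$explained[2] else NA_real_)
}
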