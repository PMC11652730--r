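#' Genotype dataset container
#'
#' A light container pairing a samples-by-variants dosage matrix with a site
#' table. Dosages are 0/1/2 copies of the alternate allele (0/1 for hemizygous
#' males on an X-like contig), `NA` for missing. Positions are 0-based
#' half-open internally and converted to 1-based only at VCF boundaries.
#'
#' @param geno integer matrix, samples x variants, values 0/1/2/NA.
#' @param sites tibble with columns `contig`, `pos` (0-based bp), `ref`,
#'   `alt`, and optionally `depth` (mean depth across samples).
#' @param haplotypes optional phased 0/1 matrix with `2 * nrow(geno)` rows
#'   (rows `<sample>_1`, `<sample>_2`); hemizygous entries may be `NA`.
#' @param sample_contig_depth optional samples x contigs matrix of relative
#'   per-sample coverage, used for sex-contig inference.
#'
#' @return An object of class `geno_dataset`.
#' @export
geno_dataset <- function(geno, sites, haplotypes = NULL,
                         sample_contig_depth = NULL) {
  stopifnot(is.matrix(geno), nrow(sites) == ncol(geno))
  if (is.null(rownames(geno))) {
    stop("`geno` must have sample ids as rownames", call. = FALSE)
  }
  sites <- tibble::as_tibble(sites)
  stopifnot(all(c("contig", "pos", "ref", "alt") %in% names(sites)))
  # positions must be strictly increasing within contig
  by_contig <- split(sites$pos, sites$contig)
  if (!all(vapply(by_contig, function(p) all(diff(p) > 0), logical(1)))) {
    stop("positions must be strictly increasing within each contig",
         call. = FALSE)
  }
  if (!is.null(haplotypes)) stopifnot(nrow(haplotypes) == 2L * nrow(geno))
  structure(
    list(geno = geno, sites = sites, haplotypes = haplotypes,
         sample_contig_depth = sample_contig_depth),
    class = "geno_dataset"
  )
}

#' @export
print.geno_dataset <- function(x, ...) {
  cat(sprintf("<geno_dataset> %d samples x %d variants on %d contig(s)\n",
              nrow(x$geno), ncol(x$geno),
              length(unique(x$sites$contig))))
  cat(sprintf("  phased haplotypes: %s\n",
              if (is.null(x$haplotypes)) "absent" else "present"))
  invisible(x)
}

#' @export
dim.geno_dataset <- function(x) dim(x$geno)

#' Number of samples / variants
#' @param ds a [geno_dataset()].
#' @return integer scalar.
#' @export
n_samples <- function(ds) nrow(ds$geno)

#' @rdname n_samples
#' @export
n_variants <- function(ds) ncol(ds$geno)

#' Subset a genotype dataset by site index or sample id
#'
#' @param ds a [geno_dataset()].
#' @param sites integer or logical index into the site table.
#' @param samples character vector of sample ids or index.
#' @return A [geno_dataset()].
#' @export
subset_dataset <- function(ds, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_len(n_variants(ds))
  if (is.logical(sites)) sites <- which(sites)
  if (is.null(samples)) samples <- seq_len(n_samples(ds))
  geno <- ds$geno[samples, sites, drop = FALSE]
  hap <- ds$haplotypes
  if (!is.null(hap)) {
    idx <- if (is.character(samples)) {
      match(samples, rownames(ds$geno))
    } else if (is.logical(samples)) which(samples) else samples
    hrows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    hap <- hap[hrows, sites, drop = FALSE]
  }
  geno_dataset(geno, ds$sites[sites, , drop = FALSE], haplotypes = hap,
               sample_contig_depth = ds$sample_contig_depth)
}

#' Per-site alternate allele frequency
#'
#' @param ds a [geno_dataset()].
#' @param samples optional subset of sample ids.
#' @return numeric vector, one frequency per variant (NA if all missing).
#' @export
site_freq <- function(ds, samples = NULL) {
  g <- if (is.null(samples)) ds$geno else ds$geno[samples, , drop = FALSE]
  colMeans(g, na.rm = TRUE) / 2
}

#' Per-site minor allele frequency
#' @inheritParams site_freq
#' @return numeric vector in `[0, 0.5]`.
#' @export
site_maf <- function(ds, samples = NULL) {
  p <- site_freq(ds, samples)
  pmin(p, 1 - p)
}

site_index <- function(ds, contig, start = -Inf, end = Inf) {
  which(ds$sites$contig == contig & ds$sites$pos >= start & ds$sites$pos < end)
}
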