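#' Published inversion coordinates for the spruce bark beetle genome
#'
#' Loads the bundled table of polymorphic inversion calls reported for the
#' *Ips typographus* (spruce bark beetle) genome: id, contig, coordinates
#' (Mb), approximate age (Myr) and the odorant-receptor (OR) genes located
#' inside each inversion. Two pairs of entries (Inv16.1/Inv23.1 and
#' Inv16.2/Inv23.2) are single physical inversions split across two
#' assembly contigs; see [inversion_bookkeeping()].
#'
#' @return tibble with columns `id`, `contig`, `start_mb`, `end_mb`,
#'   `size_mb`, `age_myr`, `ors` (semicolon-separated, may be empty).
#' @export
ips_inversion_table <- function() {
  path <- system.file("extdata", "ips_inversions.tsv", package = "invscape")
  tbl <- utils::read.delim(path, colClasses = c(ors = "character"))
  tibble::as_tibble(tbl)
}

# cosegregating entry pairs that represent one physical inversion each
ips_merge_pairs <- function() {
  list(c("Inv16.1", "Inv23.1"), c("Inv16.2", "Inv23.2"))
}

#' Genome-level bookkeeping for a published inversion table
#'
#' Computes the per-contig interval union of the inversion coordinates
#' (overlapping inversions counted once), the fraction of the analyzed
#' genome covered, and the counts of candidate entries, physical inversions
#' (after merging cross-contig cosegregating pairs) and carrier contigs.
#'
#' @param tbl table in the format of [ips_inversion_table()].
#' @param analyzed_mb analyzed genome size in Mb.
#' @param merge_pairs list of id groups that are single inversions.
#' @return one-row tibble: `span_mb`, `fraction`, `pct`, `n_candidates`,
#'   `n_inversions`, `n_contigs`.
#' @export
inversion_bookkeeping <- function(tbl = ips_inversion_table(),
                                  analyzed_mb = 170,
                                  merge_pairs = ips_merge_pairs()) {
  calls <- tibble::tibble(id = tbl$id, contig = tbl$contig,
                          start = tbl$start_mb * 1e6,
                          end = tbl$end_mb * 1e6)
  us <- union_span(calls, analyzed_length = analyzed_mb * 1e6,
                   merge_pairs = merge_pairs)
  tibble::tibble(span_mb = us$span_bp / 1e6, fraction = us$fraction,
                 pct = 100 * us$fraction, n_candidates = us$n_calls,
                 n_inversions = us$n_inversions, n_contigs = us$n_contigs)
}

#' Odorant-receptor bookkeeping for a published inversion table
#'
#' Counts the distinct OR gene identifiers located inside inversions and
#' expresses them as a percentage of all mapped ORs.
#'
#' @param tbl table in the format of [ips_inversion_table()].
#' @param n_mapped total number of ORs mapped on the analyzed contigs.
#' @return one-row tibble: `n_or_in_inversions`, `n_mapped`, `pct`.
#' @export
or_bookkeeping <- function(tbl = ips_inversion_table(), n_mapped = 71) {
  ors <- unlist(strsplit(tbl$ors[!is.na(tbl$ors) & tbl$ors != ""], ";"))
  n <- length(unique(ors))
  tibble::tibble(n_or_in_inversions = n, n_mapped = n_mapped,
                 pct = 100 * n / n_mapped)
}
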