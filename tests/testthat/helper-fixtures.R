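# cached synthetic cohorts shared across test files
.fx_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .fx_cache)) {
    assign(name, expr, envir = .fx_cache)
  }
  get(name, envir = .fx_cache)
}

# one inversion + an X-like contig, study-like cohort at desk scale
fx_inv <- function() cached("fx_inv", simulate_cohort(sim_config(
  seed = 11, contigs = c(c1 = 6e6, cX = 2e6), snp_density = 1e-3,
  x_contig = "cX",
  inversions = list(inversion_spec("c1", 1e6, 2.5e6, base_freq = 0.4,
                                   arr_fst = 0.4, fixed_frac = 0.02,
                                   id = "inv1")))))

# inversion-free cohort
fx_null <- function() cached("fx_null", simulate_cohort(sim_config(
  seed = 12, contigs = c(c1 = 3e6), snp_density = 1e-3)))

# two overlapping inversions with independent frequencies
fx_overlap <- function() cached("fx_overlap", simulate_cohort(sim_config(
  seed = 13, contigs = c(c1 = 4e6), snp_density = 1.5e-3,
  inversions = list(
    inversion_spec("c1", 5e5, 3e6, base_freq = 0.5, arr_fst = 0.45,
                   fixed_frac = 0.1, id = "invA"),
    inversion_spec("c1", 2e6, 3.9e6, base_freq = 0.3, arr_fst = 0.45,
                   fixed_frac = 0.1, id = "invB")))))

# strongly diverged inversion carrying a double-crossover recombinant
fx_dxo <- function() cached("fx_dxo", simulate_cohort(sim_config(
  seed = 14, contigs = c(c1 = 3e6), snp_density = 2e-3,
  inversions = list(inversion_spec(
    "c1", 2e5, 2.6e6, base_freq = 0.5, arr_fst = 0.5, fixed_frac = 0.75,
    double_crossover = list(sub_start = 1.2e6, sub_end = 1.6e6,
                            recombinant_freq = 0.45),
    id = "invD")))))

# near-fixed arrangements without a crossover: one clean LD block
fx_ldblock <- function() cached("fx_ldblock", simulate_cohort(sim_config(
  seed = 15, contigs = c(c1 = 3e6), snp_density = 2e-3,
  inversions = list(inversion_spec("c1", 2e5, 2.6e6, base_freq = 0.5,
                                   arr_fst = 0.5, fixed_frac = 0.75,
                                   id = "invL")))))

jaccard_interval <- function(s1, e1, s2, e2) {
  i <- max(0, min(e1, e2) - max(s1, s2))
  i / ((e1 - s1) + (e2 - s2) - i)
}

# karyotype concordance allowing the arbitrary A/B label swap
karyotype_concordance <- function(called, truth) {
  swap <- chartr("AB", "BA", truth)
  swap <- vapply(strsplit(swap, ""), function(z)
    paste(sort(z), collapse = ""), character(1))
  max(mean(called == truth), mean(called == swap))
}

# small deterministic dataset built directly from a dosage matrix
toy_dataset <- function(geno, contig = "c", pos = NULL, depth = NULL) {
  if (is.null(pos)) pos <- seq_len(ncol(geno)) * 100 - 100
  sites <- tibble::tibble(contig = contig, pos = pos,
                          ref = "A", alt = "T")
  if (!is.null(depth)) sites$depth <- depth
  if (is.null(rownames(geno)))
    rownames(geno) <- sprintf("s%02d", seq_len(nrow(geno)))
  geno_dataset(geno, sites)
}
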