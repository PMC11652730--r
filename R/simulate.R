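#' Specify a simulated polymorphic inversion
#'
#' Describes one inversion segregating in the synthetic cohort: where it sits,
#' how frequent the inverted (B) arrangement is, how strong the latitudinal
#' cline is, and how diverged the two arrangements are. Divergence has two
#' knobs: `arr_fst`, the Balding-Nichols differentiation between arrangement
#' allele frequencies, and `fixed_frac`, the fraction of inversion SNPs fully
#' fixed between arrangements (this controls dxy and therefore the apparent
#' age of the inversion).
#'
#' @param contig contig name.
#' @param start,end 0-based half-open interval in bp.
#' @param base_freq frequency of the B arrangement at the reference latitude
#'   (50 degrees N).
#' @param cline_slope change in log-odds of B per degree latitude (logistic
#'   cline; 0 for no cline).
#' @param arr_fst target differentiation between arrangements.
#' @param fixed_frac fraction of inversion SNPs fixed between arrangements.
#' @param double_crossover optional list with `sub_start`, `sub_end` (bp,
#'   nested in the inversion) and `recombinant_freq`: a recombinant haplotype
#'   class (R) derived from B that carries A-arrangement alleles inside the
#'   subinterval, emulating a historical double crossover.
#' @param load_excess_minor multiplicative excess of nonsynonymous diversity
#'   on the minor arrangement (1 = no excess). Used to plant mutation-load
#'   asymmetry between homokaryotypes.
#' @param id optional identifier; defaults to `inv_<contig>_<start>`.
#'
#' @return A list of class `inversion_spec`.
#' @export
inversion_spec <- function(contig, start, end, base_freq = 0.5,
                           cline_slope = 0, arr_fst = 0.4, fixed_frac = 0,
                           double_crossover = NULL, load_excess_minor = 1,
                           id = NULL) {
  stopifnot(start >= 0, start < end, base_freq >= 0, base_freq <= 1,
            fixed_frac >= 0, fixed_frac <= 1, arr_fst >= 0, arr_fst < 1,
            load_excess_minor >= 1)
  if (!is.null(double_crossover)) {
    stopifnot(double_crossover$sub_start >= start,
              double_crossover$sub_end <= end,
              double_crossover$sub_start < double_crossover$sub_end,
              double_crossover$recombinant_freq >= 0,
              double_crossover$recombinant_freq <= base_freq)
  }
  if (is.null(id)) id <- sprintf("inv_%s_%d", contig, as.integer(start / 1e3))
  structure(list(contig = contig, start = start, end = end,
                 base_freq = base_freq, cline_slope = cline_slope,
                 arr_fst = arr_fst, fixed_frac = fixed_frac,
                 double_crossover = double_crossover,
                 load_excess_minor = load_excess_minor, id = id),
            class = "inversion_spec")
}

# default population layout mirroring an 18-population European transect:
# 7 southern (central Europe), 3 admixed, 8 northern (Fennoscandia); 6 pops
# of 14 + 12 of 13 individuals = 240.
default_populations <- function() {
  pops <- tibble::tibble(
    population = sprintf("P%02d", 1:18),
    group = c(rep("south", 7), rep("admixed", 3), rep("north", 8)),
    lat = c(seq(45.5, 48.5, length.out = 7),
            seq(51, 53.5, length.out = 3),
            seq(59.5, 66.5, length.out = 8)),
    lon = c(seq(8, 20, length.out = 7), seq(17, 21, length.out = 3),
            seq(10, 28, length.out = 8)),
    alpha = c(rep(0, 7), c(0.35, 0.5, 0.65), rep(1, 8)),
    n = c(rep(14, 6), rep(13, 12))
  )
  pops
}

default_env_model <- function() {
  # slope per degree latitude, residual SD; loosely bioclim-like variables
  tibble::tibble(
    variable = c("mean_temp", "temp_seasonality", "min_temp_cold",
                 "annual_precip", "forest_cover", "spruce_cover"),
    intercept = c(25, 10, 10, 700, 30, 10),
    slope = c(-0.35, 0.45, -0.5, -4, 0.6, 0.45),
    sd = c(0.8, 1.0, 1.2, 40, 6, 4)
  )
}

#' Configure a synthetic multi-population cohort
#'
#' The defaults emulate a range-wide resequencing design: 18 populations in
#' two weakly differentiated groups (collinear FST ~ 0.02) bridged by admixed
#' populations, 240 diploid individuals, Mb-scale contigs, and an X-like
#' contig on which males are hemizygous. Inversions are supplied as
#' [inversion_spec()] objects.
#'
#' @param seed integer seed governing every random draw.
#' @param contigs named numeric vector of contig lengths (bp).
#' @param snp_density expected SNPs per bp.
#' @param populations tibble with columns `population`, `group` (south /
#'   admixed / north), `lat`, `lon`, `alpha` (northern ancestry fraction for
#'   admixed populations), `n` (diploid individuals).
#' @param group_fst target Balding-Nichols differentiation between the
#'   southern and northern collinear backgrounds.
#' @param inversions list of [inversion_spec()].
#' @param gene_density genes per Mb.
#' @param gene_length gene length in bp.
#' @param frac_nonsyn fraction of in-gene SNPs labelled nonsynonymous.
#' @param or_gene_count number of genes flagged as odorant receptors.
#' @param or_in_inversion_bias sampling weight multiplier for placing OR
#'   flags on genes inside inversions.
#' @param env_model tibble `variable`/`intercept`/`slope`/`sd` describing
#'   per-population environmental covariates as linear-in-latitude + noise.
#' @param missing_rate per-genotype missing probability.
#' @param depth_mean,depth_sd per-site mean depth model.
#' @param x_contig optional contig name with halved male dosage, or `NULL`.
#' @param prop_female proportion of females in the cohort.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       contigs = c(contig1 = 8e6, contig2 = 6e6),
                       snp_density = 5e-4,
                       populations = default_populations(),
                       group_fst = 0.021,
                       inversions = list(),
                       gene_density = 12,
                       gene_length = 3e4,
                       frac_nonsyn = 0.25,
                       or_gene_count = 20,
                       or_in_inversion_bias = 3,
                       env_model = default_env_model(),
                       missing_rate = 0.02,
                       depth_mean = 23, depth_sd = 6,
                       x_contig = NULL,
                       prop_female = 141 / 240) {
  stopifnot(all(contigs > 0), snp_density > 0,
            all(snp_density * contigs >= 1),
            group_fst >= 0, group_fst < 1,
            all(populations$alpha >= 0 & populations$alpha <= 1),
            missing_rate >= 0, missing_rate < 1)
  for (iv in inversions) {
    stopifnot(inherits(iv, "inversion_spec"))
    if (!iv$contig %in% names(contigs)) {
      stop(sprintf("inversion %s references unknown contig %s", iv$id,
                   iv$contig), call. = FALSE)
    }
    if (iv$end > contigs[[iv$contig]]) {
      stop(sprintf("inversion %s extends beyond contig %s", iv$id,
                   iv$contig), call. = FALSE)
    }
  }
  if (!is.null(x_contig)) stopifnot(x_contig %in% names(contigs))
  ids <- vapply(inversions, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate inversion ids", call. = FALSE)
  structure(list(seed = seed, contigs = contigs, snp_density = snp_density,
                 populations = populations, group_fst = group_fst,
                 inversions = inversions, gene_density = gene_density,
                 gene_length = gene_length, frac_nonsyn = frac_nonsyn,
                 or_gene_count = or_gene_count,
                 or_in_inversion_bias = or_in_inversion_bias,
                 env_model = env_model, missing_rate = missing_rate,
                 depth_mean = depth_mean, depth_sd = depth_sd,
                 x_contig = x_contig, prop_female = prop_female),
            class = "sim_config")
}

# ancestral allele frequency density ~ 1/p truncated to [lo, hi]
# (neutral-SFS-like rare-allele excess), sampled by inverse CDF
r_ancestral_freq <- function(n, lo = 0.01, hi = 0.99) {
  lo * (hi / lo)^stats::runif(n)
}

# Balding-Nichols draw of a subpopulation frequency around ancestral p
r_bn <- function(p, fst) {
  if (fst <= 0) return(p)
  k <- (1 - fst) / fst
  stats::rbeta(length(p), p * k, (1 - p) * k)
}

# mean per-site heterozygosity 2p(1-p) under the ancestral density
expected_ancestral_het <- function(lo = 0.01, hi = 0.99) {
  2 * ((hi - lo) - (hi^2 - lo^2) / 2) / log(hi / lo)
}

#' Expected between-arrangement dxy for a simulated inversion
#'
#' Closed form for the per-SNP absolute divergence between the two
#' arrangements implied by an [inversion_spec()]. Given the ancestral
#' frequency p of a site, the two arrangement frequencies are independent
#' Balding-Nichols draws, so E\[dxy | p\] = 2p(1 - p) regardless of
#' `arr_fst`; fully fixed sites contribute 1. Averaging over the ancestral
#' density gives
#' `fixed_frac + (1 - fixed_frac) * E[2p(1-p)]`.
#'
#' Used as the truth value in age-recovery checks against [estimate_age()].
#'
#' @param spec an [inversion_spec()].
#' @param lo,hi truncation bounds of the ancestral frequency density.
#' @return expected per-SNP dxy (dimensionless).
#' @export
expected_dxy <- function(spec, lo = 0.01, hi = 0.99) {
  stopifnot(inherits(spec, "inversion_spec"))
  spec$fixed_frac + (1 - spec$fixed_frac) * expected_ancestral_het(lo, hi)
}

# logistic cline in latitude, anchored at 50 degrees N
cline_freq <- function(base_freq, slope, lat, lat0 = 50) {
  if (base_freq <= 0) return(rep(0, length(lat)))
  if (base_freq >= 1) return(rep(1, length(lat)))
  stats::plogis(stats::qlogis(base_freq) + slope * (lat - lat0))
}

# shrink allele frequencies toward 0.5 so expected heterozygosity is
# multiplied by `load`; valid while load * E[h] < 0.5 (clamped otherwise)
inflate_het <- function(p, load, eh = expected_ancestral_het()) {
  if (load <= 1) return(p)
  s2 <- max(0, (0.5 - load * eh) / (0.5 - eh))
  0.5 + (p - 0.5) * sqrt(s2)
}

#' Simulate a multi-population diploid cohort with known inversions
#'
#' Generates genotypes under a parametric model: collinear site frequencies
#' follow a Balding-Nichols model calibrated to `group_fst` between the
#' southern and northern backgrounds (admixed populations mix the two by
#' their ancestry fraction); sites inside an inversion follow a
#' Balding-Nichols model between arrangements calibrated to `arr_fst`, with a
#' `fixed_frac` subset fully fixed; each haplotype carries one arrangement
#' label per inversion drawn from the population's cline-adjusted frequency,
#' and genotypes are the sum of two conditionally independent haplotypes.
#' Sites are conditionally independent given arrangement and group, so LD
#' inside inversions is arrangement-induced only. Males are hemizygous
#' (dosage 0/1) on the X-like contig. Missingness and per-site depth are
#' applied last. The phased truth is retained.
#'
#' @param config a [sim_config()].
#' @return A list with elements `dataset` ([geno_dataset()] with phased
#'   haplotypes), `meta` (sample metadata tibble), `annotation` (per-site
#'   class tibble: `contig`, `pos`, `inversion`, `coding`, `gene_id`,
#'   `or_flag`), `truth` (list of tibbles: `hap_labels`, `karyotypes`,
#'   `pop_freq`, `genes`, `env`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pops <- config$populations
  n_ind <- sum(pops$n)

  ## samples and metadata -----------------------------------------------
  meta <- tidyr::uncount(pops, weights = pops$n)
  meta$sample <- sprintf("%s_s%02d", meta$population,
                         unlist(lapply(pops$n, seq_len)))
  sex <- ifelse(stats::runif(n_ind) < config$prop_female, "F", "M")
  meta <- tibble::tibble(sample = meta$sample, population = meta$population,
                         group = meta$group, lat = meta$lat, lon = meta$lon,
                         sex = sex,
                         phenotype = sample(c("facultative", "obligate"),
                                            n_ind, replace = TRUE))

  ## sites ----------------------------------------------------------------
  sites_l <- lapply(names(config$contigs), function(ct) {
    len <- config$contigs[[ct]]
    m <- max(1L, stats::rpois(1, len * config$snp_density))
    tibble::tibble(contig = ct,
                   pos = sort(sample.int(len, min(m, len)) - 1L))
  })
  sites <- dplyr::bind_rows(sites_l)
  m <- nrow(sites)
  alleles <- matrix(sample(c("A", "C", "G", "T"), 2 * m, replace = TRUE),
                    ncol = 2)
  same <- alleles[, 1] == alleles[, 2]
  alleles[same, 2] <- chartr("ACGT", "CGTA", alleles[same, 1])
  sites$ref <- alleles[, 1]
  sites$alt <- alleles[, 2]

  ## site -> inversion assignment (first-listed inversion wins overlaps)
  inv_of_site <- rep(NA_character_, m)
  for (iv in config$inversions) {
    idx <- which(sites$contig == iv$contig & sites$pos >= iv$start &
                   sites$pos < iv$end & is.na(inv_of_site))
    inv_of_site[idx] <- iv$id
  }

  ## genes, coding classes, OR flags --------------------------------------
  genes_l <- lapply(names(config$contigs), function(ct) {
    len <- config$contigs[[ct]]
    ng <- stats::rpois(1, config$gene_density * len / 1e6)
    if (ng == 0) return(NULL)
    gstart <- sort(sample.int(max(1, len - config$gene_length), ng))
    tibble::tibble(contig = ct, start = gstart,
                   end = gstart + config$gene_length)
  })
  genes <- dplyr::bind_rows(genes_l)
  if (nrow(genes) > 0) {
    genes$gene_id <- sprintf("g%04d", seq_len(nrow(genes)))
    mid <- (genes$start + genes$end) / 2
    in_inv <- rep(FALSE, nrow(genes))
    for (iv in config$inversions) {
      in_inv <- in_inv | (genes$contig == iv$contig & mid >= iv$start &
                            mid < iv$end)
    }
    genes$in_inversion <- in_inv
    w <- ifelse(in_inv, config$or_in_inversion_bias, 1)
    n_or <- min(config$or_gene_count, nrow(genes))
    or_idx <- sample.int(nrow(genes), n_or, prob = w)
    genes$or_flag <- FALSE
    genes$or_flag[or_idx] <- TRUE
  } else {
    genes$gene_id <- character(0)
    genes$in_inversion <- logical(0)
    genes$or_flag <- logical(0)
  }

  gene_of_site <- rep(NA_character_, m)
  or_of_site <- rep(FALSE, m)
  if (nrow(genes) > 0) {
    for (ct in unique(genes$contig)) {
      gi <- genes[genes$contig == ct, ]
      si <- which(sites$contig == ct)
      hit <- findInterval(sites$pos[si], gi$start)
      ok <- hit > 0 & sites$pos[si] < gi$end[pmax(hit, 1)]
      gene_of_site[si[ok]] <- gi$gene_id[hit[ok]]
      or_of_site[si[ok]] <- gi$or_flag[hit[ok]]
    }
  }
  coding <- ifelse(is.na(gene_of_site), "intergenic",
                   ifelse(stats::runif(m) < config$frac_nonsyn,
                          "nonsynonymous", "synonymous"))

  annotation <- tibble::tibble(contig = sites$contig, pos = sites$pos,
                               inversion = inv_of_site, coding = coding,
                               gene_id = gene_of_site, or_flag = or_of_site)

  ## allele frequencies ---------------------------------------------------
  p_anc <- r_ancestral_freq(m)
  p_south <- r_bn(p_anc, config$group_fst)
  p_north <- r_bn(p_anc, config$group_fst)
  # per-population collinear frequency (groups share their background)
  pop_freq_mat <- vapply(seq_len(nrow(pops)), function(i) {
    a <- pops$alpha[i]
    a * p_north + (1 - a) * p_south
  }, numeric(m))
  colnames(pop_freq_mat) <- pops$population

  # per-arrangement frequencies for inversion sites
  arr_freq <- list()
  for (iv in config$inversions) {
    idx <- which(inv_of_site == iv$id)
    pA <- r_bn(p_anc[idx], iv$arr_fst)
    pB <- r_bn(p_anc[idx], iv$arr_fst)
    nfix <- round(iv$fixed_frac * length(idx))
    if (nfix > 0) {
      fix <- sample(seq_along(idx), nfix)
      pA[fix] <- 0
      pB[fix] <- 1
    }
    if (iv$load_excess_minor > 1) {
      minor <- if (iv$base_freq <= 0.5) "B" else "A"
      ns <- coding[idx] == "nonsynonymous"
      if (minor == "B") pB[ns] <- inflate_het(pB[ns], iv$load_excess_minor)
      else pA[ns] <- inflate_het(pA[ns], iv$load_excess_minor)
    }
    arr_freq[[iv$id]] <- list(idx = idx, pA = pA, pB = pB)
  }

  ## arrangement labels per haplotype -------------------------------------
  n_hap <- 2L * n_ind
  hap_sample <- rep(meta$sample, each = 2)
  hap_pop <- rep(meta$population, each = 2)
  hap_lat <- rep(meta$lat, each = 2)
  hap_labels <- list()
  pop_freq_truth <- list()
  for (iv in config$inversions) {
    f <- cline_freq(iv$base_freq, iv$cline_slope, pops$lat)
    names(f) <- pops$population
    rf <- if (is.null(iv$double_crossover)) 0 else
      iv$double_crossover$recombinant_freq
    fh <- f[hap_pop]
    u <- stats::runif(n_hap)
    lab <- ifelse(u < pmax(fh - rf, 0), "B", ifelse(u < fh, "R", "A"))
    if (rf == 0) lab[lab == "R"] <- "B"
    hap_labels[[iv$id]] <- lab
    pop_freq_truth[[iv$id]] <- tibble::tibble(
      inversion = iv$id, population = pops$population, freq_B = unname(f),
      freq_R = rf)
  }

  ## haplotype alleles -----------------------------------------------------
  H <- matrix(0L, nrow = n_hap, ncol = m)
  col_sites <- !is.na(inv_of_site)
  # collinear sites: population frequency
  for (i in seq_len(nrow(pops))) {
    rows <- which(hap_pop == pops$population[i])
    cols <- which(!col_sites)
    pr <- pop_freq_mat[cols, i]
    H[rows, cols] <- matrix(
      stats::runif(length(rows) * length(cols)) <
        rep(pr, each = length(rows)), nrow = length(rows)) + 0L
  }
  # inversion sites: arrangement frequency; R carries B alleles outside the
  # double-crossover subinterval and A alleles inside it
  for (iv in config$inversions) {
    af <- arr_freq[[iv$id]]
    lab <- hap_labels[[iv$id]]
    sub <- rep(FALSE, length(af$idx))
    if (!is.null(iv$double_crossover)) {
      ps <- sites$pos[af$idx]
      sub <- ps >= iv$double_crossover$sub_start &
        ps < iv$double_crossover$sub_end
    }
    for (cls in c("A", "B", "R")) {
      rows <- which(lab == cls)
      if (length(rows) == 0) next
      pr <- switch(cls, A = af$pA, B = af$pB,
                   R = ifelse(sub, af$pA, af$pB))
      H[rows, af$idx] <- matrix(
        stats::runif(length(rows) * length(af$idx)) <
          rep(pr, each = length(rows)), nrow = length(rows)) + 0L
    }
  }

  ## genotypes -------------------------------------------------------------
  G <- H[seq(1, n_hap, by = 2), , drop = FALSE] +
    H[seq(2, n_hap, by = 2), , drop = FALSE]
  rownames(G) <- meta$sample
  rownames(H) <- paste0(rep(meta$sample, each = 2), c("_1", "_2"))

  if (!is.null(config$x_contig)) {
    xcols <- which(sites$contig == config$x_contig)
    males <- which(meta$sex == "M")
    if (length(xcols) > 0 && length(males) > 0) {
      G[males, xcols] <- H[2L * males - 1L, xcols]
      H[2L * males, xcols] <- NA_integer_
    }
  }

  if (config$missing_rate > 0) {
    G[matrix(stats::runif(length(G)) < config$missing_rate,
             nrow = nrow(G))] <- NA_integer_
  }

  ## depth -----------------------------------------------------------------
  sites$depth <- pmax(1, stats::rnorm(m, config$depth_mean, config$depth_sd))
  samp_depth <- matrix(
    pmax(1, stats::rnorm(n_ind * length(config$contigs),
                         config$depth_mean, config$depth_sd / 2)),
    nrow = n_ind, dimnames = list(meta$sample, names(config$contigs)))
  if (!is.null(config$x_contig)) {
    males <- meta$sex == "M"
    samp_depth[males, config$x_contig] <-
      samp_depth[males, config$x_contig] * 0.5
  }

  ## truth tables -----------------------------------------------------------
  hap_truth <- dplyr::bind_rows(lapply(names(hap_labels), function(id) {
    tibble::tibble(haplotype = rownames(H), sample = hap_sample,
                   inversion = id, label = hap_labels[[id]])
  }))
  kar_truth <- dplyr::bind_rows(lapply(names(hap_labels), function(id) {
    lab <- matrix(hap_labels[[id]], ncol = 2, byrow = TRUE)
    iv <- config$inversions[[which(vapply(config$inversions, `[[`,
                                          character(1), "id") == id)]]
    kt <- apply(lab, 1, function(z) paste(sort(z), collapse = ""))
    if (!is.null(config$x_contig) && iv$contig == config$x_contig) {
      kt[meta$sex == "M"] <- lab[meta$sex == "M", 1]
    }
    tibble::tibble(sample = meta$sample, inversion = id, karyotype = kt)
  }))

  ## environment ------------------------------------------------------------
  em <- config$env_model
  env <- tibble::tibble(population = pops$population, lat = pops$lat)
  for (i in seq_len(nrow(em))) {
    env[[em$variable[i]]] <- em$intercept[i] + em$slope[i] * pops$lat +
      stats::rnorm(nrow(pops), 0, em$sd[i])
  }

  ds <- geno_dataset(G, sites, haplotypes = H,
                     sample_contig_depth = samp_depth)
  list(dataset = ds, meta = meta, annotation = annotation,
       truth = list(hap_labels = hap_truth, karyotypes = kar_truth,
                    pop_freq = dplyr::bind_rows(pop_freq_truth),
                    genes = genes, env = env))
}
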