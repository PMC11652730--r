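#' Exact Hardy-Weinberg test for biallelic genotype counts
#'
#' Levene-Haldane exact test conditioning on the observed allele counts:
#' the probability of `nAB` heterozygotes given `nA` minor alleles among `n`
#' diploids is proportional to `n! / (nAA! nAB! nBB!) * 2^nAB`. The two-sided
#' p-value sums configurations with probability less than or equal to the
#' observed one; one-sided p-values sum toward heterozygote excess or
#' deficit.
#'
#' @param nAA,nAB,nBB genotype counts.
#' @return tibble with `p_two`, `p_excess`, `p_deficit`, `direction`.
#' @export
hwe_exact <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  if (n == 0) stop("no genotypes", call. = FALSE)
  nA <- 2 * nAA + nAB
  nB <- 2 * nBB + nAB
  if (nA == 0 || nB == 0) {
    return(tibble::tibble(p_two = 1, p_excess = 1, p_deficit = 1,
                          direction = "none"))
  }
  nmin <- min(nA, nB)
  # possible heterozygote counts share the parity of nmin
  habs <- seq(nmin %% 2, nmin, by = 2)
  logp <- vapply(habs, function(h) {
    aa <- (nA - h) / 2
    bb <- (nB - h) / 2
    lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
      h * log(2)
  }, numeric(1))
  # terms constant in h cancel; normalize numerically
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- which(habs == nAB)
  if (length(obs) == 0) stop("nAB incompatible with allele counts",
                             call. = FALSE)
  p_obs <- pr[obs]
  exp_het <- sum(habs * pr)
  tibble::tibble(
    p_two = min(1, sum(pr[pr <= p_obs + 1e-12])),
    p_excess = sum(pr[habs >= nAB]),
    p_deficit = sum(pr[habs <= nAB]),
    direction = if (nAB > exp_het) "excess" else
      if (nAB < exp_het) "deficit" else "none"
  )
}

#' Exact Hardy-Weinberg test for an X-linked biallelic locus
#'
#' Females contribute genotypes, hemizygous males contribute single alleles.
#' Conditional on the total minor-allele count, the joint probability of `m`
#' minor alleles in males and `nAB` heterozygous females is proportional to
#' `choose(nm, m) * nf! / (nAA! nAB! nBB!) * 2^nAB`. Two-sided p by
#' probability ordering; one-sided p-values over the female heterozygote
#' margin.
#'
#' @param nAA,nAB,nBB female genotype counts (minor allele = A).
#' @param mA,mB male counts carrying the minor / major allele.
#' @return tibble as in [hwe_exact()].
#' @export
hwe_exact_x <- function(nAA, nAB, nBB, mA, mB) {
  nf <- nAA + nAB + nBB
  nm <- mA + mB
  t_minor <- 2 * nAA + nAB + mA
  total <- 2 * nf + nm
  if (t_minor == 0 || t_minor == total) {
    return(tibble::tibble(p_two = 1, p_excess = 1, p_deficit = 1,
                          direction = "none"))
  }
  cfg <- list()
  for (m in max(0, t_minor - 2 * nf):min(nm, t_minor)) {
    fA <- t_minor - m          # minor alleles among females
    fB <- 2 * nf - fA
    if (fB < 0) next
    hmax <- min(fA, fB)
    if (hmax < 0) next
    habs <- seq(hmax %% 2, hmax, by = 2)
    for (h in habs) {
      aa <- (fA - h) / 2
      bb <- (fB - h) / 2
      lp <- lgamma(nm + 1) - lgamma(m + 1) - lgamma(nm - m + 1) +
        lgamma(nf + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
        h * log(2)
      cfg[[length(cfg) + 1]] <- c(m = m, h = h, lp = lp)
    }
  }
  cfg <- do.call(rbind, cfg)
  pr <- exp(cfg[, "lp"] - max(cfg[, "lp"]))
  pr <- pr / sum(pr)
  obs <- which(cfg[, "m"] == mA & cfg[, "h"] == nAB)
  if (length(obs) != 1) stop("observed configuration not reachable",
                             call. = FALSE)
  p_obs <- pr[obs]
  exp_het <- sum(cfg[, "h"] * pr)
  tibble::tibble(
    p_two = min(1, sum(pr[pr <= p_obs + 1e-12])),
    p_excess = sum(pr[cfg[, "h"] >= nAB]),
    p_deficit = sum(pr[cfg[, "h"] <= nAB]),
    direction = if (nAB > exp_het) "excess" else
      if (nAB < exp_het) "deficit" else "none"
  )
}

# one-sided heterozygote-excess p from a dosage vector (used by the site
# filter); returns 1 when the test is not applicable
het_excess_p <- function(g) {
  g <- g[!is.na(g)]
  if (length(g) < 5) return(1)
  nAA <- sum(g == 0); nAB <- sum(g == 1); nBB <- sum(g == 2)
  if (nAB == 0) return(1)
  hwe_exact(nAA, nAB, nBB)$p_excess
}
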