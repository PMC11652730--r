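# Independent brute-force oracles, deliberately implemented along different
# algebraic routes than the package code.

# Weir-Cockerham components for one site via the ANOVA mean-squares
# formulation: MSG (within individuals), MSI (among individuals within
# pops), MSP (among pops); a = (MSP - MSI) / (2 nc), b = (MSI - MSG) / 2,
# c = MSG.
wc_oracle_site <- function(geno_by_group) {
  n <- vapply(geno_by_group, function(g) sum(!is.na(g)), numeric(1))
  p <- vapply(geno_by_group, function(g) mean(g, na.rm = TRUE) / 2,
              numeric(1))
  h <- vapply(geno_by_group, function(g) mean(g == 1, na.rm = TRUE),
              numeric(1))
  r <- length(n)
  nsum <- sum(n)
  pbar <- sum(n * p) / nsum
  nc <- (nsum - sum(n^2) / nsum) / (r - 1)
  MSP <- sum(2 * n * (p - pbar)^2) / (r - 1)
  MSI <- sum(2 * n * p * (1 - p) - n * h / 2) / (nsum - r)
  MSG <- sum(n * h) / (2 * nsum)
  c(a = (MSP - MSI) / (2 * nc), b = (MSI - MSG) / 2, c = MSG)
}

# textbook Tajima's D, constants written out directly
tajima_oracle <- function(S, pi_sum, n) {
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n^2 + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# exact HWE null distribution of the heterozygote count by sequential
# without-replacement assignment of alleles to individuals (dynamic
# program over remaining allele counts)
hwe_enum_oracle <- function(n, nA) {
  nB <- 2 * n - nA
  # states: remaining A alleles after assigning some individuals
  # dist[[i]][as.character(a)] = named vector over het counts
  dist <- list()
  dist[[paste(nA, 0)]] <- 1
  for (ind in seq_len(n)) {
    nxt <- list()
    rem_total <- 2 * (n - ind + 1)
    for (key in names(dist)) {
      kv <- as.numeric(strsplit(key, " ")[[1]])
      a <- kv[1]; hets <- kv[2]
      b <- rem_total - a
      pr <- dist[[key]]
      add <- function(a2, h2, p2) {
        k2 <- paste(a2, h2)
        nxt[[k2]] <<- (if (is.null(nxt[[k2]])) 0 else nxt[[k2]]) + p2
      }
      if (a >= 2) add(a - 2, hets, pr * a * (a - 1) /
                        (rem_total * (rem_total - 1)))
      if (a >= 1 && b >= 1) add(a - 1, hets + 1,
                                pr * 2 * a * b /
                                  (rem_total * (rem_total - 1)))
      if (b >= 2) add(a, hets, pr * b * (b - 1) /
                        (rem_total * (rem_total - 1)))
    }
    dist <- nxt
  }
  hets <- vapply(strsplit(names(dist), " "),
                 function(z) as.numeric(z[2]), numeric(1))
  pr <- unlist(dist, use.names = FALSE)
  stats::setNames(pr, hets)[order(hets)]
}
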