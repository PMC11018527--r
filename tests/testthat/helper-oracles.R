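# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use different computational routes (enumeration,
# pairwise counting, literal textbook formulas) from the package code.

# mean pairwise difference per site via explicit haplotype enumeration
oracle_pi_sites <- function(gt) {
  vapply(seq_len(ncol(gt)), function(s) {
    g <- gt[, s]
    g <- g[!is.na(g)]
    haps <- unlist(lapply(g, function(x) c(rep(1L, x), rep(0L, 2L - x))))
    n <- length(haps)
    if (n < 2) return(NA_real_)
    diffs <- 0L
    for (i in seq_len(n - 1L))
      for (j in (i + 1L):n)
        diffs <- diffs + (haps[i] != haps[j])
    diffs / choose(n, 2)
  }, numeric(1))
}

# Tajima (1989) D evaluated from first principles on a complete matrix
oracle_tajima_d <- function(gt) {
  n <- 2L * nrow(gt)
  p <- colMeans(gt) / 2
  seg <- p > 0 & p < 1
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  khat <- sum(oracle_pi_sites(gt[, seg, drop = FALSE]))
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (khat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Weir & Cockerham (1984) a, b, c for one site, two populations, coded as
# scalar loops straight from the published component formulas
oracle_wc_theta <- function(g1, g2) {
  pops <- list(g1[!is.na(g1)], g2[!is.na(g2)])
  r <- 2
  n_i <- vapply(pops, length, numeric(1))
  p_i <- vapply(pops, function(g) sum(g) / (2 * length(g)), numeric(1))
  h_i <- vapply(pops, function(g) mean(g == 1L), numeric(1))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# two-sided Fisher exact p by full enumeration over tables with fixed
# margins (same minimum-likelihood criterion as stats::fisher.test)
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  d <- dhyper(support, m, n, k)
  sum(d[d <= dhyper(x, m, n, k) * (1 + 1e-7)])
}

# two-sided exact binomial p by enumeration (minlik criterion)
oracle_binom_p <- function(x, n, p = 0.5) {
  d <- dbinom(0:n, n, p)
  sum(d[d <= dbinom(x, n, p) * (1 + 1e-7)])
}

# chi-squared (df = 1) upper tail through the normal integral,
# 2 * (1 - Phi(sqrt(chi2))), evaluated in the numerically stable tail form
oracle_chisq1_p <- function(chi2) 2 * pnorm(-sqrt(chi2))

# Benjamini-Hochberg step-up, written out longhand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# simple flat coverage profile constructor
make_profile <- function(cc, ee, chrom = "chr1", accession = "acc1") {
  n <- max(length(cc), length(ee))
  prof <- data.frame(pair_id = sprintf("%s_p%05d", chrom, seq_len(n)),
                     chrom = chrom, ancestral_index = seq_len(n),
                     cc_depth = rep_len(cc, n), ee_depth = rep_len(ee, n),
                     stringsAsFactors = FALSE)
  attr(prof, "accession") <- accession
  prof
}

# random small genotype_matrix for property tests
random_gmat <- function(seed, n_samples = 6, n_sites = 40,
                        missing_rate = 0) {
  set.seed(seed)
  gt <- matrix(rbinom(n_samples * n_sites, 2, runif(n_sites, 0.1, 0.9)),
               nrow = n_samples,
               dimnames = list(sprintf("s%02d", seq_len(n_samples)), NULL))
  if (missing_rate > 0)
    gt[matrix(runif(length(gt)) < missing_rate, nrow = n_samples)] <- NA
  sites <- data.frame(chrom = "chr1",
                      pos = sort(sample.int(1e6, n_sites)),
                      ref = "A", alt = "T", stringsAsFactors = FALSE)
  genotype_matrix(gt, sites)
}
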