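# Weir & Cockerham fixation index and SNP filtering.

#' Per-site Weir & Cockerham (1984) theta
#'
#' Computes the variance components a (among populations), b (among
#' individuals within populations) and c (within individuals) of the
#' two-population Weir & Cockerham estimator from genotype counts, with
#' `theta = a / (a + b + c)` per site.  Missing genotypes reduce the
#' per-population sample size; monomorphic or undersampled sites are `NA`.
#' Negative estimates are retained (not clamped).
#'
#' @param gt_a,gt_b genotype matrices (samples x sites, alternate-allele
#'   counts) for the two populations.
#' @return list `theta` (per-site), `a`, `b`, `c` (component vectors).
#' @export
wc_fst_site <- function(gt_a, gt_b) {
  stopifnot(ncol(gt_a) == ncol(gt_b))
  comp <- function(gt) {
    n <- colSums(!is.na(gt))                 # diploid individuals
    p <- colSums(gt, na.rm = TRUE) / (2 * n)
    h <- colSums(gt == 1L, na.rm = TRUE) / n # observed heterozygosity
    list(n = n, p = p, h = h)
  }
  x <- comp(gt_a); y <- comp(gt_b)
  r <- 2
  nbar <- (x$n + y$n) / 2
  pbar <- (x$n * x$p + y$n * y$p) / (r * nbar)
  s2 <- (x$n * (x$p - pbar)^2 + y$n * (y$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (x$n * x$h + y$n * y$h) / (r * nbar)
  nc <- (r * nbar - (x$n^2 + y$n^2) / (r * nbar)) / (r - 1)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r -
       hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  denom <- a + b + cc
  bad <- x$n < 2 | y$n < 2 | !is.finite(denom) | denom == 0
  theta <- ifelse(bad, NA_real_, a / denom)
  list(theta = theta, a = a, b = b, c = cc)
}

#' Genome-wide Weir & Cockerham fixation index (ratio of sums)
#'
#' The standard multi-locus Weir & Cockerham estimate
#' `sum(a) / sum(a + b + c)` over all informative sites.  Unlike the mean
#' of per-site ratios (which is biased toward zero by low-frequency
#' sites), this weighted estimator recovers the simulated Balding-Nichols
#' differentiation parameter.
#'
#' @param g a `genotype_matrix`.
#' @param pop_a,pop_b sample name vectors of the two populations.
#' @return list `fst` (scalar), `n_sites` (informative sites used).
#' @export
wc_fst_global <- function(g, pop_a, pop_b) {
  wc <- wc_fst_site(subset_gt(g, pop_a), subset_gt(g, pop_b))
  ok <- !is.na(wc$theta)
  stop_if(!any(ok), "no informative sites")
  list(fst = sum(wc$a[ok]) / sum((wc$a + wc$b + wc$c)[ok]),
       n_sites = sum(ok))
}

#' Per-gene mean fixation index between two populations
#'
#' Per-site Weir & Cockerham theta ([wc_fst_site()]) averaged over the
#' sites falling within each gene span extended by `flank_bp` on both
#' sides (arithmetic mean of site values by default, as in gene-level
#' divergence scans; `ratio_of_sums = TRUE` instead uses
#' `sum(a)/sum(a+b+c)` over the gene's sites).  Genes with no informative
#' site get `NA`.
#'
#' @param g a `genotype_matrix`.
#' @param pop_a,pop_b sample name vectors of the two populations.
#' @param genes data.frame `gene_id, chrom, start, end` (1-based
#'   inclusive).
#' @param flank_bp flank added to each side of the gene span (default
#'   2000).
#' @param ratio_of_sums use the ratio-of-sums combination instead of the
#'   mean of site values.
#' @return data.frame `gene_id, chrom, start, end, fst, n_sites`.
#' @export
gene_fst <- function(g, pop_a, pop_b, genes, flank_bp = 2000L,
                     ratio_of_sums = FALSE) {
  stop_if(length(pop_a) < 2L || length(pop_b) < 2L,
          "need >= 2 samples per population")
  wc <- wc_fst_site(subset_gt(g, pop_a), subset_gt(g, pop_b))
  res <- vapply(seq_len(nrow(genes)), function(k) {
    inw <- which(g$sites$chrom == genes$chrom[k] &
                   g$sites$pos >= genes$start[k] - flank_bp &
                   g$sites$pos <= genes$end[k] + flank_bp)
    th <- wc$theta[inw]
    ok <- !is.na(th)
    if (!any(ok)) return(c(NA_real_, 0))
    if (ratio_of_sums) {
      num <- sum(wc$a[inw][ok])
      den <- num + sum(wc$b[inw][ok]) + sum(wc$c[inw][ok])
      c(if (den == 0) NA_real_ else num / den, sum(ok))
    } else c(mean(th[ok]), sum(ok))
  }, numeric(2))
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = genes$start, end = genes$end,
             fst = res[1L, ], n_sites = res[2L, ],
             stringsAsFactors = FALSE)
}

#' Filter SNP sites by standard rules
#'
#' Applies any subset of the usual tree/structure-analysis filters and
#' logs per-rule removal counts:
#' \describe{
#'   \item{max_missing}{remove sites missing in more than this fraction of
#'     samples (e.g. 0.4).}
#'   \item{min_maf}{remove sites with minor allele frequency below this
#'     (e.g. 0.10).}
#'   \item{het_in_control}{name of a di-haploid control sample; sites
#'     called heterozygous in it are removed (cross-mapping artefacts).}
#'   \item{repeat_mask}{data.frame `chrom, start, end` (1-based inclusive)
#'     of intervals whose sites are removed.}
#'   \item{ld_prune}{list `(window, step, r2)`: within a sliding window of
#'     `window` sites advanced by `step`, greedily remove the later site of
#'     any pair whose genotype correlation r-squared exceeds `r2`
#'     (deterministic: earlier position wins).}
#' }
#' Rules are applied in the order above; LD pruning sees only sites that
#' survived the previous rules.
#'
#' @param g a `genotype_matrix`.
#' @param max_missing,min_maf,het_in_control,repeat_mask,ld_prune see
#'   above; `NULL` disables a rule.
#' @return list `genotypes` (filtered `genotype_matrix`) and `log`
#'   (data.frame `rule, removed`).
#' @export
snp_filter <- function(g, max_missing = NULL, min_maf = NULL,
                       het_in_control = NULL, repeat_mask = NULL,
                       ld_prune = NULL) {
  keep <- rep(TRUE, nrow(g$sites))
  log <- list()
  note <- function(rule, removed)
    log[[length(log) + 1L]] <<- data.frame(rule = rule, removed = removed,
                                           stringsAsFactors = FALSE)
  if (!is.null(repeat_mask)) {
    hit <- rep(FALSE, nrow(g$sites))
    for (k in seq_len(nrow(repeat_mask)))
      hit <- hit | (g$sites$chrom == repeat_mask$chrom[k] &
                      g$sites$pos >= repeat_mask$start[k] &
                      g$sites$pos <= repeat_mask$end[k])
    note("repeat_mask", sum(hit & keep)); keep <- keep & !hit
  }
  if (!is.null(het_in_control)) {
    stop_if(!het_in_control %in% g$samples,
            sprintf("control sample '%s' absent", het_in_control))
    het <- !is.na(g$gt[het_in_control, ]) & g$gt[het_in_control, ] == 1L
    note("het_in_control", sum(het & keep)); keep <- keep & !het
  }
  if (!is.null(max_missing)) {
    frac <- colMeans(is.na(g$gt))
    bad <- frac > max_missing
    note("max_missing", sum(bad & keep)); keep <- keep & !bad
  }
  if (!is.null(min_maf)) {
    f <- site_freq(g$gt)
    maf <- pmin(f$p, 1 - f$p)
    bad <- is.na(maf) | maf < min_maf
    note("min_maf", sum(bad & keep)); keep <- keep & !bad
  }
  if (!is.null(ld_prune)) {
    stopifnot(all(c("window", "step", "r2") %in% names(ld_prune)))
    idx <- which(keep)
    drop <- rep(FALSE, length(idx))
    for (chrom in unique(g$sites$chrom[idx])) {
      cix <- which(g$sites$chrom[idx] == chrom)
      starts <- seq(1L, length(cix), by = ld_prune$step)
      for (s in starts) {
        wix <- cix[s:min(s + ld_prune$window - 1L, length(cix))]
        wix <- wix[!drop[wix]]
        if (length(wix) < 2L) next
        r2 <- suppressWarnings(
          cor(g$gt[, idx[wix], drop = FALSE],
              use = "pairwise.complete.obs")^2)
        for (i in seq_len(length(wix) - 1L)) {
          if (drop[wix[i]]) next
          hits <- which(!is.na(r2[i, ]) & r2[i, ] > ld_prune$r2 &
                          seq_along(wix) > i)
          drop[wix[hits]] <- TRUE
        }
      }
    }
    note("ld_prune", sum(drop))
    keep[idx[drop]] <- FALSE
  }
  out <- genotype_matrix(g$gt[, keep, drop = FALSE],
                         g$sites[keep, , drop = FALSE], g$samples)
  list(genotypes = out,
       log = if (length(log)) do.call(rbind, log)
             else data.frame(rule = character(), removed = integer()))
}
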