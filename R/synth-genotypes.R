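#' Generate a diploid genotype matrix under two-population structure
#'
#' Simulates biallelic SNPs for two focal populations (labelled `wild` and
#' `cultivar`), optional admixed individuals (`hybrid`, each allele drawn from
#' either population with equal probability) and outgroup accessions for both
#' progenitors (`outgroup_cc`, `outgroup_ee`) that carry the ancestral allele
#' up to an error rate.
#'
#' Two frequency regimes are used so both neutrality and differentiation are
#' exact by construction:
#' \itemize{
#'   \item `pop_split_fst == 0`: the derived-allele count `j` among all focal
#'     haplotypes is drawn with probability proportional to `1/j` and the `j`
#'     derived alleles are placed uniformly at random — the expected unfolded
#'     site frequency spectrum is exactly neutral and Tajima's D is centred
#'     on zero.
#'   \item `pop_split_fst > 0`: an ancestral frequency is drawn from the
#'     neutral `1/p` density (truncated to `(1/(2M), 1 - 1/(2M))`) and each
#'     population's frequency from the Balding-Nichols beta
#'     `Beta(p(1-F)/F, (1-p)(1-F)/F)`; genotypes are binomial.
#' }
#'
#' A site is emitted with the derived allele as VCF REF with probability
#' `ancestral_flip_rate`, so ancestral polarization is non-trivial; the truth
#' records the ancestral allele of every site.  Missing genotypes are injected
#' independently per call at `missing_rate` and encoded `NA` (VCF `./.`).
#'
#' @param config a [sim_config()]; uses `n_per_pop`, `n_hybrid` via
#'   `n_outgroup`, `pop_split_fst`, `n_sites`, `missing_rate`,
#'   `outgroup_error`, `ancestral_flip_rate`.
#' @param n_hybrid number of admixed individuals (default 0).
#' @return list with `genotypes` (a `genotype_matrix`: `gt` samples x sites
#'   integer matrix of alternate-allele counts with `NA` missing; `sites`
#'   data.frame `chrom, pos, ref, alt, anc`; `samples`), `popmap`
#'   (data.frame `sample, population`), and `truth` (`ancestral_alleles`
#'   data.frame and the population labels).
#' @examples
#' g <- gen_genotypes(sim_config(seed = 1, n_sites = 100, n_per_pop = 5))
#' dim(g$genotypes$gt)
#' @export
gen_genotypes <- function(config, n_hybrid = 0L) {
  stopifnot(inherits(config, "sim_config"))
  n_hybrid <- check_count(n_hybrid, "n_hybrid", min = 0L)
  set.seed(derive_seed(config$seed, "genotypes"))
  n_pop <- config$n_per_pop
  n_out <- config$n_outgroup
  F <- config$pop_split_fst
  S <- config$n_sites

  samples <- c(sprintf("wild%02d", seq_len(n_pop)),
               sprintf("cult%02d", seq_len(n_pop)),
               if (n_hybrid) sprintf("hyb%02d", seq_len(n_hybrid)),
               sprintf("outcc%02d", seq_len(n_out)),
               sprintf("outee%02d", seq_len(n_out)))
  population <- c(rep("wild", n_pop), rep("cultivar", n_pop),
                  rep("hybrid", n_hybrid),
                  rep("outgroup_cc", n_out), rep("outgroup_ee", n_out))
  n_focal <- 2L * n_pop + n_hybrid
  k_hap <- 2L * n_focal

  # site positions spread over synthetic chromosomes
  chrom_len <- config$n_genes_per_chrom *
    (config$gene_bp + config$intergenic_bp)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  per <- diff(floor(seq(0, S, length.out = config$n_chroms + 1L)))
  site_chrom <- rep(chroms, per)
  pos <- unlist(lapply(per, function(k)
    sort(sample.int(chrom_len, k, replace = FALSE))), use.names = FALSE)

  gt <- matrix(0L, nrow = length(samples), ncol = S,
               dimnames = list(samples, NULL))
  focal <- seq_len(n_focal)
  if (F == 0) {
    # exact neutral spectrum: derived count ~ 1/j, placed uniformly
    j <- sample.int(k_hap - 1L, S, replace = TRUE,
                    prob = 1 / seq_len(k_hap - 1L))
    for (s in seq_len(S)) {
      hap <- integer(k_hap)
      hap[sample.int(k_hap, j[s])] <- 1L
      gt[focal, s] <- hap[c(TRUE, FALSE)] + hap[c(FALSE, TRUE)]
    }
  } else {
    lo <- 1 / (2 * k_hap)
    u <- runif(S)
    p0 <- lo * ((1 - lo) / lo)^u        # density proportional to 1/p
    shape <- (1 - F) / F
    p1 <- rbeta(S, p0 * shape, (1 - p0) * shape)
    p2 <- rbeta(S, p0 * shape, (1 - p0) * shape)
    idx1 <- seq_len(n_pop)
    idx2 <- n_pop + seq_len(n_pop)
    gt[idx1, ] <- matrix(rbinom(n_pop * S, 2L, rep(p1, each = n_pop)),
                         nrow = n_pop)
    gt[idx2, ] <- matrix(rbinom(n_pop * S, 2L, rep(p2, each = n_pop)),
                         nrow = n_pop)
    if (n_hybrid) {
      idxh <- 2L * n_pop + seq_len(n_hybrid)
      ph <- matrix(ifelse(runif(n_hybrid * S) < 0.5,
                          rep(p1, each = n_hybrid), rep(p2, each = n_hybrid)),
                   nrow = n_hybrid)
      ph2 <- matrix(ifelse(runif(n_hybrid * S) < 0.5,
                           rep(p1, each = n_hybrid), rep(p2, each = n_hybrid)),
                    nrow = n_hybrid)
      gt[idxh, ] <- matrix(rbinom(n_hybrid * S, 1L, ph) +
                             rbinom(n_hybrid * S, 1L, ph2),
                           nrow = n_hybrid)
    }
  }
  # outgroups: ancestral homozygote up to per-haplotype error
  out_idx <- n_focal + seq_len(2L * n_out)
  if (config$outgroup_error > 0) {
    gt[out_idx, ] <- matrix(rbinom(length(out_idx) * S, 2L,
                                   config$outgroup_error),
                            nrow = length(out_idx))
  }

  # allele letters; derived allele is ALT unless the site is flipped
  bases <- c("A", "C", "G", "T")
  anc_base <- sample(bases, S, replace = TRUE)
  der_base <- vapply(anc_base, function(b)
    sample(setdiff(bases, b), 1L), character(1))
  flip <- runif(S) < config$ancestral_flip_rate
  ref <- ifelse(flip, der_base, anc_base)
  alt <- ifelse(flip, anc_base, der_base)
  gt[, flip] <- 2L - gt[, flip, drop = FALSE]

  if (config$missing_rate > 0) {
    gt[matrix(runif(length(gt)) < config$missing_rate,
              nrow = nrow(gt))] <- NA_integer_
  }

  sites <- data.frame(chrom = site_chrom, pos = pos, ref = ref, alt = alt,
                      anc = NA_character_, stringsAsFactors = FALSE)
  g <- genotype_matrix(gt, sites, samples)
  popmap <- data.frame(sample = samples, population = population,
                       stringsAsFactors = FALSE)
  truth <- list(
    ancestral_alleles = data.frame(chrom = site_chrom, pos = pos,
                                   anc = anc_base,
                                   anc_is_ref = !flip,
                                   stringsAsFactors = FALSE),
    population_labels = popmap)
  list(genotypes = g, popmap = popmap, truth = truth)
}

#' Construct a genotype matrix object
#'
#' Container for diploid biallelic genotypes: an integer matrix of
#' alternate-allele counts (`0, 1, 2`, `NA` = missing) with samples as rows,
#' plus a per-site table (`chrom`, 1-based `pos`, `ref`, `alt`, optional
#' ancestral allele `anc`).  Positions must be strictly increasing within a
#' chromosome.
#'
#' @param gt integer matrix, samples x sites.
#' @param sites data.frame with columns `chrom, pos, ref, alt` and optional
#'   `anc`.
#' @param samples character vector of sample names (defaults to rownames).
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(gt, sites, samples = rownames(gt)) {
  stopifnot(is.matrix(gt), is.data.frame(sites),
            ncol(gt) == nrow(sites), !is.null(samples))
  stop_if(!all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
          "`sites` needs columns chrom, pos, ref, alt")
  stop_if(!all(gt %in% c(0L, 1L, 2L) | is.na(gt)),
          "genotypes must be 0, 1, 2 or NA")
  if (is.null(sites$anc)) sites$anc <- NA_character_
  ord_ok <- all(tapply(sites$pos, sites$chrom, function(p)
    all(diff(p) > 0)))
  stop_if(!isTRUE(ord_ok),
          "site positions must be strictly increasing within chromosomes")
  rownames(gt) <- samples
  structure(list(gt = gt, sites = sites, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d sites (%d chrom)\n",
              length(x$samples), nrow(x$sites),
              length(unique(x$sites$chrom))))
  invisible(x)
}
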