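#' Simulation configuration for the synthetic allotetraploid world
#'
#' Builds the validated parameter set consumed by all `gen_*()` generators.
#' The defaults describe the stated world the package is tested against: a
#' two-subgenome allotetraploid resequenced to ~40x coverage, genes deleted in
#' geometric excision runs concentrated in pericentromeres, two focal
#' populations differentiated under a Balding-Nichols model with outgroup
#' accessions of both progenitors, and syntelog expression that is globally
#' balanced unless bias is planted.
#'
#' @param seed master RNG seed; fixes all generator output bit-identically.
#' @param n_genes_per_chrom ancestral genes per chromosome.
#' @param n_chroms number of chromosomes.
#' @param n_accessions number of resequenced accessions (coverage profiles).
#' @param depth_mean mean sequencing depth (reads/base) at balanced 2:2 dosage,
#'   i.e. the per-homoeolog mean is `depth_mean` when both copies are present.
#' @param depth_dispersion negative-binomial size parameter for depth
#'   overdispersion (larger = closer to Poisson).
#' @param he_segments data.frame of planted homoeologous-exchange segments with
#'   columns `accession`, `chrom`, `start_gene`, `end_gene`, `dosage`
#'   (one of `"4:0" "3:1" "2:2" "1:3" "0:4"`, copies CC:EE). May be empty.
#' @param deletion_run_p geometric parameter for excision run length; mean run
#'   length is `1/deletion_run_p` genes.
#' @param pericentromere_span fraction of each chromosome (centred) treated as
#'   pericentromeric; must be in `[0, 1)`.
#' @param retention_base probability that a gene survives fractionation on a
#'   chromosome arm.
#' @param retention_pericentromere same, within the pericentromeric span
#'   (lower: fractionation concentrates there).
#' @param gene_bp,intergenic_bp fixed gene body and intergenic spacer lengths
#'   in bp used to lay out synthetic coordinates.
#' @param wgd_origin_p_arm,wgd_origin_p_peri probability that a gene is
#'   labelled as retained from the polyploidy event (`origin_class = "wgd"`)
#'   on arms / in the pericentromere; the remainder is split between
#'   `"tandem"` and `"other"`.
#' @param ks_mean,ks_sd location and spread of the synonymous-divergence values
#'   attached to retained pairs (truncated at zero).
#' @param pop_split_fst Balding-Nichols differentiation parameter between the
#'   two focal populations; in `[0, 1)`.
#' @param n_sites number of biallelic SNP sites to simulate.
#' @param theta_site per-site mutation parameter (reserved for density
#'   scaling; site count is fixed by `n_sites`).
#' @param n_per_pop diploid samples per focal population.
#' @param n_outgroup diploid outgroup samples per progenitor.
#' @param outgroup_error probability that an outgroup haplotype carries the
#'   derived allele (polarization noise).
#' @param missing_rate probability that any genotype call is missing.
#' @param ancestral_flip_rate probability that a site is emitted with the
#'   derived allele as VCF REF (exercises polarization).
#' @param generation_time_years generation time used for time scaling
#'   (default 21 years, typical of wild arabica coffee).
#' @param bias_fraction fraction of syntelog pairs with planted expression
#'   bias.
#' @param bias_fold fold-change of planted bias (TPM scale).
#' @param bias_direction `"both"` (random per pair), `"cc"` or `"ee"`.
#' @param n_expr_samples expression samples (tissues) per gene.
#' @param expr_noise_sd lognormal noise sd (log scale) on expression values.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1, n_genes_per_chrom = 200, n_chroms = 2)
#' cfg$depth_mean
#' @export
sim_config <- function(seed = 1L,
                       n_genes_per_chrom = 1000L,
                       n_chroms = 2L,
                       n_accessions = 10L,
                       depth_mean = 40,
                       depth_dispersion = 20,
                       he_segments = NULL,
                       deletion_run_p = 0.5,
                       pericentromere_span = 0.3,
                       retention_base = 0.95,
                       retention_pericentromere = 0.6,
                       gene_bp = 1000L,
                       intergenic_bp = 500L,
                       wgd_origin_p_arm = 0.6,
                       wgd_origin_p_peri = 0.3,
                       ks_mean = 0.05,
                       ks_sd = 0.01,
                       pop_split_fst = 0.1,
                       n_sites = 5000L,
                       theta_site = 0.005,
                       n_per_pop = 20L,
                       n_outgroup = 2L,
                       outgroup_error = 0,
                       missing_rate = 0,
                       ancestral_flip_rate = 0.5,
                       generation_time_years = 21,
                       bias_fraction = 0,
                       bias_fold = 4,
                       bias_direction = c("both", "cc", "ee"),
                       n_expr_samples = 3L,
                       expr_noise_sd = 0.2) {
  seed <- check_count(seed, "seed", min = 0L)
  n_genes_per_chrom <- check_count(n_genes_per_chrom, "n_genes_per_chrom")
  n_chroms <- check_count(n_chroms, "n_chroms")
  n_accessions <- check_count(n_accessions, "n_accessions")
  stop_if(depth_mean <= 0, "`depth_mean` must be > 0")
  stop_if(depth_dispersion <= 0, "`depth_dispersion` must be > 0")
  stop_if(deletion_run_p <= 0 || deletion_run_p > 1,
          "`deletion_run_p` must lie in (0, 1]")
  check_prob(retention_base, "retention_base")
  check_prob(retention_pericentromere, "retention_pericentromere")
  stop_if(pericentromere_span < 0 || pericentromere_span >= 1,
          "`pericentromere_span` must lie in [0, 1)")
  check_prob(wgd_origin_p_arm, "wgd_origin_p_arm")
  check_prob(wgd_origin_p_peri, "wgd_origin_p_peri")
  stop_if(pop_split_fst < 0 || pop_split_fst >= 1,
          "`pop_split_fst` must lie in [0, 1)")
  check_prob(outgroup_error, "outgroup_error")
  check_prob(missing_rate, "missing_rate")
  check_prob(ancestral_flip_rate, "ancestral_flip_rate")
  check_prob(bias_fraction, "bias_fraction")
  stop_if(bias_fold <= 0, "`bias_fold` must be > 0")
  stop_if(generation_time_years <= 0,
          "`generation_time_years` must be > 0")
  bias_direction <- match.arg(bias_direction)

  he_segments <- validate_he_segments(he_segments, n_chroms,
                                      n_genes_per_chrom, n_accessions)

  cfg <- list(seed = seed,
              n_genes_per_chrom = n_genes_per_chrom,
              n_chroms = n_chroms,
              n_accessions = n_accessions,
              depth_mean = depth_mean,
              depth_dispersion = depth_dispersion,
              he_segments = he_segments,
              deletion_run_p = deletion_run_p,
              pericentromere_span = pericentromere_span,
              retention_base = retention_base,
              retention_pericentromere = retention_pericentromere,
              gene_bp = check_count(gene_bp, "gene_bp"),
              intergenic_bp = check_count(intergenic_bp, "intergenic_bp"),
              wgd_origin_p_arm = wgd_origin_p_arm,
              wgd_origin_p_peri = wgd_origin_p_peri,
              ks_mean = ks_mean, ks_sd = ks_sd,
              pop_split_fst = pop_split_fst,
              n_sites = check_count(n_sites, "n_sites"),
              theta_site = theta_site,
              n_per_pop = check_count(n_per_pop, "n_per_pop"),
              n_outgroup = check_count(n_outgroup, "n_outgroup"),
              outgroup_error = outgroup_error,
              missing_rate = missing_rate,
              ancestral_flip_rate = ancestral_flip_rate,
              generation_time_years = generation_time_years,
              bias_fraction = bias_fraction,
              bias_fold = bias_fold,
              bias_direction = bias_direction,
              n_expr_samples = check_count(n_expr_samples, "n_expr_samples"),
              expr_noise_sd = expr_noise_sd)
  class(cfg) <- "sim_config"
  cfg
}

#' @keywords internal
#' @noRd
validate_he_segments <- function(he_segments, n_chroms, n_genes, n_acc) {
  if (is.null(he_segments) || (is.data.frame(he_segments) &&
                               nrow(he_segments) == 0L)) {
    return(data.frame(accession = character(), chrom = character(),
                      start_gene = integer(), end_gene = integer(),
                      dosage = character(), stringsAsFactors = FALSE))
  }
  stop_if(!is.data.frame(he_segments), "`he_segments` must be a data.frame")
  need <- c("accession", "chrom", "start_gene", "end_gene", "dosage")
  stop_if(!all(need %in% names(he_segments)),
          sprintf("`he_segments` needs columns: %s",
                  paste(need, collapse = ", ")))
  stop_if(!all(he_segments$dosage %in% DOSAGE_LEVELS),
          "`he_segments$dosage` must use CC:EE labels 4:0 3:1 2:2 1:3 0:4")
  stop_if(!all(he_segments$chrom %in% paste0("chr", seq_len(n_chroms))),
          "`he_segments$chrom` references unknown chromosomes")
  bad <- he_segments$start_gene < 1L | he_segments$end_gene > n_genes |
    he_segments$start_gene > he_segments$end_gene
  stop_if(any(bad), "`he_segments` gene indices out of chromosome bounds")
  stop_if(!all(he_segments$accession %in% paste0("acc", seq_len(n_acc))),
          "`he_segments$accession` must reference acc1..accN")
  he_segments
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      sprintf("%d chrom x %d genes, %d accessions, depth %gx",
              x$n_chroms, x$n_genes_per_chrom, x$n_accessions, x$depth_mean),
      sprintf("seed %d, %d planted HE segment(s)", x$seed,
              nrow(x$he_segments)), sep = "\n  ")
  invisible(x)
}
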