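#' Generate per-accession subgenome coverage profiles with planted HE
#'
#' For each accession and each retained syntelog pair, draws the mean read
#' depth of the CC-side and EE-side gene from a negative-binomial distribution
#' with mean `depth_mean * copies / 2`, where the copy numbers come from the
#' planted dosage of any homoeologous-exchange segment covering the gene in
#' that accession (`config$he_segments`); genes outside planted segments are
#' balanced 2:2.  Zero copies give exactly zero depth.  The negative binomial
#' (size `depth_dispersion`) emulates the overdispersion of real short-read
#' coverage.
#'
#' @param syntelogs syntelog table from [gen_syntelog_landscape()].
#' @param config a [sim_config()]; accessions are named `acc1..accN`.
#' @return list with `profiles` (named list of per-accession data.frames:
#'   `pair_id, chrom, ancestral_index, cc_depth, ee_depth`; one row per
#'   retained pair, in ancestral order) and `truth` (the planted HE segment
#'   table).
#' @examples
#' cfg <- sim_config(seed = 1, n_genes_per_chrom = 50, n_accessions = 2)
#' land <- gen_syntelog_landscape(cfg)
#' cov <- gen_coverage_profiles(land$syntelogs, cfg)
#' head(cov$profiles$acc1)
#' @export
gen_coverage_profiles <- function(syntelogs, config) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(syntelogs))
  stop_if(config$depth_mean <= 0, "`depth_mean` must be > 0")
  set.seed(derive_seed(config$seed, "coverage"))
  seg <- config$he_segments
  ret <- syntelogs[syntelogs$status == "retained", , drop = FALSE]
  accessions <- paste0("acc", seq_len(config$n_accessions))

  profiles <- lapply(accessions, function(acc) {
    copies_cc <- rep(2L, nrow(ret))
    copies_ee <- rep(2L, nrow(ret))
    if (nrow(seg)) {
      mine <- seg[seg$accession == acc, , drop = FALSE]
      if (nrow(mine)) {
        cp <- dosage_copies(mine$dosage)
        for (k in seq_len(nrow(mine))) {
          hit <- ret$chrom == mine$chrom[k] &
            ret$ancestral_index >= mine$start_gene[k] &
            ret$ancestral_index <= mine$end_gene[k]
          copies_cc[hit] <- cp[k, "cc"]
          copies_ee[hit] <- cp[k, "ee"]
        }
      }
    }
    draw <- function(copies) {
      mu <- config$depth_mean * copies / 2
      d <- integer(length(mu))
      pos <- mu > 0
      d[pos] <- rnbinom(sum(pos), size = config$depth_dispersion,
                        mu = mu[pos])
      d
    }
    data.frame(pair_id = ret$pair_id, chrom = ret$chrom,
               ancestral_index = ret$ancestral_index,
               cc_depth = draw(copies_cc), ee_depth = draw(copies_ee),
               stringsAsFactors = FALSE)
  })
  names(profiles) <- accessions
  list(profiles = profiles, truth = list(he_segments = seg))
}
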