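#' Generate a synthetic syntelog landscape with planted fractionation
#'
#' Lays out `n_chroms` chromosomes of `n_genes_per_chrom` ancestral genes,
#' each initially present on both subgenomes (CC and EE), then plants gene
#' deletions as excision runs: at each gene a run starts with probability
#' `(1 - retention) * deletion_run_p` on a side chosen fairly, and its length
#' is geometric with parameter `deletion_run_p` (mean `1/p` genes).  Retention
#' probability is `retention_base` on chromosome arms and
#' `retention_pericentromere` within the centred `pericentromere_span`
#' fraction, reproducing the pericentromeric fractionation gradient seen in
#' recent allopolyploids.  Coordinates follow the GFF3 convention (1-based,
#' inclusive); deletion removes the gene model but not the underlying DNA
#' span, so intergenic gaps over a run of length L span
#' `L * gene_bp + (L + 1) * intergenic_bp`.
#'
#' Runs never start immediately after a deleted gene on the same side (so
#' planted runs are also the maximal observed runs) and stop early rather than
#' deleting a gene already lost on the other side (every ancestral gene keeps
#' at least one copy).
#'
#' @param config a [sim_config()].
#' @return list with elements `syntelogs` (data.frame, one row per ancestral
#'   gene: `pair_id, chrom, block_id, ancestral_index, gene_cc, gene_ee,
#'   status, start_cc, end_cc, start_ee, end_ee, ks, origin_class,
#'   pericentromeric`) and `truth` (planted deletion runs, pericentromere
#'   spans and retention parameters).
#' @examples
#' out <- gen_syntelog_landscape(sim_config(seed = 1, n_genes_per_chrom = 100))
#' table(out$syntelogs$status)
#' @export
gen_syntelog_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "landscape"))
  n <- config$n_genes_per_chrom
  p <- config$deletion_run_p
  chroms <- paste0("chr", seq_len(config$n_chroms))

  peri_lo <- floor(n * (1 - config$pericentromere_span) / 2) + 1L
  peri_hi <- peri_lo + ceiling(n * config$pericentromere_span) - 1L
  has_peri <- config$pericentromere_span > 0

  all_rows <- vector("list", length(chroms))
  all_runs <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    chrom <- chroms[ci]
    peri <- if (has_peri) seq_len(n) >= peri_lo & seq_len(n) <= peri_hi
            else rep(FALSE, n)
    retention <- ifelse(peri, config$retention_pericentromere,
                        config$retention_base)
    del_cc <- del_ee <- rep(FALSE, n)
    runs <- list()
    i <- 1L
    while (i <= n) {
      p_start <- (1 - retention[i]) * p
      if (p_start > 0 && runif(1) < p_start) {
        side <- if (runif(1) < 0.5) "cc" else "ee"
        prev_del <- if (i > 1L) {
          if (side == "cc") del_cc[i - 1L] else del_ee[i - 1L]
        } else FALSE
        if (!prev_del) {
          len <- rgeom(1L, p) + 1L
          j <- i
          while (j <= n && j < i + len) {
            other_del <- if (side == "cc") del_ee[j] else del_cc[j]
            if (other_del) break
            if (side == "cc") del_cc[j] <- TRUE else del_ee[j] <- TRUE
            j <- j + 1L
          }
          realized <- j - i
          if (realized > 0L) {
            runs[[length(runs) + 1L]] <-
              data.frame(chrom = chrom, side = side, start_index = i,
                         length = realized, stringsAsFactors = FALSE)
            i <- j  # skip past the run; runs do not nest
            next
          }
        }
      }
      i <- i + 1L
    }
    status <- ifelse(del_cc & !del_ee, "ee_only",
                     ifelse(del_ee & !del_cc, "cc_only", "retained"))

    # ancestral layout: intergenic spacer before every gene body
    slot <- config$gene_bp + config$intergenic_bp
    start <- (seq_len(n) - 1L) * slot + config$intergenic_bp + 1L
    end <- start + config$gene_bp - 1L

    origin_p <- ifelse(peri, config$wgd_origin_p_peri,
                       config$wgd_origin_p_arm)
    u <- runif(n)
    origin <- ifelse(u < origin_p, "wgd",
                     ifelse(u < origin_p + (1 - origin_p) / 2,
                            "tandem", "other"))
    ks <- abs(rnorm(n, config$ks_mean, config$ks_sd))
    ks[status != "retained"] <- NA_real_

    rows <- data.frame(
      pair_id = sprintf("%s_p%05d", chrom, seq_len(n)),
      chrom = chrom, block_id = chrom, ancestral_index = seq_len(n),
      gene_cc = ifelse(del_cc, NA_character_,
                       sprintf("%s_cc%05d", chrom, seq_len(n))),
      gene_ee = ifelse(del_ee, NA_character_,
                       sprintf("%s_ee%05d", chrom, seq_len(n))),
      status = status,
      start_cc = ifelse(del_cc, NA_integer_, start),
      end_cc = ifelse(del_cc, NA_integer_, end),
      start_ee = ifelse(del_ee, NA_integer_, start),
      end_ee = ifelse(del_ee, NA_integer_, end),
      ks = ks, origin_class = origin, pericentromeric = peri,
      stringsAsFactors = FALSE)
    all_rows[[ci]] <- rows
    all_runs[[ci]] <- if (length(runs)) do.call(rbind, runs) else NULL
  }

  syntelogs <- do.call(rbind, all_rows)
  rownames(syntelogs) <- NULL
  runs <- do.call(rbind, all_runs)
  if (is.null(runs))
    runs <- data.frame(chrom = character(), side = character(),
                       start_index = integer(), length = integer(),
                       stringsAsFactors = FALSE)
  truth <- list(
    deleted_runs = runs,
    pericentromere = if (has_peri)
      data.frame(chrom = chroms, start_index = peri_lo, end_index = peri_hi,
                 stringsAsFactors = FALSE)
    else
      data.frame(chrom = character(), start_index = integer(),
                 end_index = integer(), stringsAsFactors = FALSE),
    retention_base = config$retention_base,
    retention_pericentromere = config$retention_pericentromere)
  list(syntelogs = syntelogs, truth = truth)
}
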