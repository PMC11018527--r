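# Fractionation and dating statistics over syntelog tables.

#' Sliding-window gene retention track
#'
#' Computes the fraction of syntelog pairs retained in sliding windows over
#' the ancestral gene order, per synteny block.  `side = "cc"` / `"ee"`
#' reports presence of that subgenome's copy (1 - fraction deleted on that
#' side); `side = "retained"` reports the fraction of pairs with both copies.
#' The trailing partial window is included with its true gene count.
#'
#' @param syntelogs syntelog table ([read_syntelogs()] or
#'   [gen_syntelog_landscape()]).
#' @param window_genes window width in genes (>= 1).
#' @param step_genes step in genes (>= 1); `step_genes = window_genes` gives
#'   non-overlapping windows.
#' @param side `"cc"`, `"ee"` or `"retained"`.
#' @return data.frame of class `retention_track`: `chrom, start_index,
#'   end_index, retention_rate, n_genes`.
#' @examples
#' land <- gen_syntelog_landscape(sim_config(seed = 1,
#'                                           n_genes_per_chrom = 200))
#' head(retention_rate_track(land$syntelogs, 50, 50))
#' @export
retention_rate_track <- function(syntelogs, window_genes, step_genes,
                                 side = c("cc", "ee", "retained")) {
  side <- match.arg(side)
  window_genes <- check_count(window_genes, "window_genes")
  step_genes <- check_count(step_genes, "step_genes")
  stop_if(!is.data.frame(syntelogs) || nrow(syntelogs) == 0L,
          "empty syntelog table")
  kept <- switch(side,
                 cc = syntelogs$status != "ee_only",
                 ee = syntelogs$status != "cc_only",
                 retained = syntelogs$status == "retained")
  out <- lapply(split(seq_len(nrow(syntelogs)), syntelogs$block_id),
                function(ix) {
    ix <- ix[order(syntelogs$ancestral_index[ix])]
    n <- length(ix)
    starts <- seq(1L, n, by = step_genes)
    full <- starts + window_genes - 1L <= n
    # full windows plus at most one trailing partial window
    if (any(!full)) starts <- c(starts[full], starts[!full][1L])
    ends <- pmin(starts + window_genes - 1L, n)
    cs <- cumsum(kept[ix])
    nret <- cs[ends] - c(0, cs)[starts]
    data.frame(chrom = syntelogs$chrom[ix[1L]],
               block_id = syntelogs$block_id[ix[1L]],
               start_index = syntelogs$ancestral_index[ix][starts],
               end_index = syntelogs$ancestral_index[ix][ends],
               retention_rate = nret / (ends - starts + 1L),
               n_genes = ends - starts + 1L,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("retention_track", "data.frame")
  attr(res, "side") <- side
  res
}

#' @keywords internal
#' @noRd
deletion_runs_by_side <- function(syntelogs) {
  del <- list(cc = syntelogs$status == "ee_only",   # CC copy lost
              ee = syntelogs$status == "cc_only")   # EE copy lost
  out <- list()
  for (side in names(del)) {
    for (blk in split(seq_len(nrow(syntelogs)), syntelogs$block_id)) {
      blk <- blk[order(syntelogs$ancestral_index[blk])]
      r <- rle(del[[side]][blk])
      if (!any(r$values)) next
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      w <- which(r$values)
      out[[length(out) + 1L]] <- data.frame(
        chrom = syntelogs$chrom[blk[1L]],
        block_id = syntelogs$block_id[blk[1L]],
        side = side,
        start_index = syntelogs$ancestral_index[blk][starts[w]],
        run_length = r$lengths[w],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), block_id = character(),
                      side = character(), start_index = integer(),
                      run_length = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Deletion run-length spectrum
#'
#' Counts maximal runs of consecutive same-side gene deletions per subgenome
#' side; runs never span synteny-block boundaries.  The conservation
#' invariant `sum(run_length * count) == deleted genes on that side` holds by
#' construction.
#'
#' @param syntelogs syntelog table.
#' @return list of class `run_length_spectrum`: `histogram` (data.frame
#'   `side, run_length, count`) and `runs` (one row per maximal run).
#' @export
deletion_run_spectrum <- function(syntelogs) {
  runs <- deletion_runs_by_side(syntelogs)
  if (nrow(runs)) {
    agg <- aggregate(list(count = runs$run_length),
                     by = list(side = runs$side,
                               run_length = runs$run_length), FUN = length)
    agg <- agg[order(agg$side, agg$run_length), c("side", "run_length",
                                                  "count")]
    rownames(agg) <- NULL
  } else {
    agg <- data.frame(side = character(), run_length = integer(),
                      count = integer(), stringsAsFactors = FALSE)
  }
  structure(list(histogram = agg, runs = runs),
            class = "run_length_spectrum")
}

#' Intergenic gap profile of fractionated runs
#'
#' For each maximal deletion run of length L, measures the bp spanned between
#' the flanking retained genes on the deleted side (the fractionated gap) and
#' the bp across the same ancestral span on the homoeologous, unfractionated
#' side.  Runs at block edges (no flanking gene on the deleted side) are
#' skipped; runs whose flanking genes are absent on the homoeologous side
#' contribute `NA` to the unfractionated mean.
#'
#' @param syntelogs syntelog table with per-side coordinate columns
#'   `start_cc, end_cc, start_ee, end_ee`.
#' @return data.frame `run_length, n_runs, gap_bp_fractionated,
#'   gap_bp_unfractionated` (means per run length).
#' @export
intergenic_gap_profile <- function(syntelogs) {
  need <- c("start_cc", "end_cc", "start_ee", "end_ee")
  stop_if(!all(need %in% names(syntelogs)),
          "syntelog table lacks per-side coordinates")
  runs <- deletion_runs_by_side(syntelogs)
  if (!nrow(runs))
    return(data.frame(run_length = integer(), n_runs = integer(),
                      gap_bp_fractionated = numeric(),
                      gap_bp_unfractionated = numeric()))
  key <- paste(syntelogs$block_id, syntelogs$ancestral_index)
  gap_del <- gap_ret <- rep(NA_real_, nrow(runs))
  for (i in seq_len(nrow(runs))) {
    blk <- syntelogs[syntelogs$block_id == runs$block_id[i], , drop = FALSE]
    blk <- blk[order(blk$ancestral_index), , drop = FALSE]
    side <- runs$side[i]
    s_col <- paste0("start_", side); e_col <- paste0("end_", side)
    o <- if (side == "cc") "ee" else "cc"
    os_col <- paste0("start_", o); oe_col <- paste0("end_", o)
    i0 <- match(runs$start_index[i], blk$ancestral_index)
    i1 <- i0 + runs$run_length[i] - 1L
    prev <- rev(which(!is.na(blk[[e_col]][seq_len(i0 - 1L)])))[1]
    nxt_rel <- which(!is.na(blk[[s_col]]) &
                       seq_len(nrow(blk)) > i1)[1]
    if (is.na(prev) || is.na(nxt_rel)) next
    gap_del[i] <- blk[[s_col]][nxt_rel] - blk[[e_col]][prev] - 1
    if (!is.na(blk[[oe_col]][prev]) && !is.na(blk[[os_col]][nxt_rel]))
      gap_ret[i] <- blk[[os_col]][nxt_rel] - blk[[oe_col]][prev] - 1
  }
  ok <- !is.na(gap_del)
  runs <- runs[ok, , drop = FALSE]
  gap_del <- gap_del[ok]; gap_ret <- gap_ret[ok]
  ls <- sort(unique(runs$run_length))
  data.frame(
    run_length = ls,
    n_runs = vapply(ls, function(L) sum(runs$run_length == L), integer(1)),
    gap_bp_fractionated = vapply(ls, function(L)
      mean(gap_del[runs$run_length == L]), numeric(1)),
    gap_bp_unfractionated = vapply(ls, function(L)
      mean(gap_ret[runs$run_length == L], na.rm = TRUE), numeric(1)))
}

#' Fisher enrichment of duplicate-origin classes by retention stratum
#'
#' Partitions genes into a high-retention stratum (window retention rate at
#' or above the `high_q` sample quantile) versus the rest and cross-tabulates
#' against duplicate origin (`wgd` vs not), testing the dosage-balance
#' expectation that highly retained regions are enriched for polyploidy-born
#' duplicates.  A second test contrasts the low-retention stratum
#' (`<= low_q` quantile) against tandem duplicates.  Odds ratios are the
#' sample cross-product ratio; p-values come from the two-sided Fisher exact
#' test.  Tables with a zero margin are flagged degenerate with `p = 1` by
#' convention.
#'
#' @param track a `retention_track` from [retention_rate_track()].
#' @param syntelogs syntelog table with an `origin_class` column
#'   (`wgd`/`tandem`/`other`).
#' @param high_q,low_q stratum quantiles (defaults 0.8 / 0.2).
#' @return list with elements `wgd` and `tandem`, each a list
#'   `(table, odds_ratio, p_value, degenerate)`.
#' @export
retention_origin_enrichment <- function(track, syntelogs, high_q = 0.8,
                                        low_q = 0.2) {
  stop_if(is.null(syntelogs$origin_class),
          "`syntelogs` lacks an origin_class column")
  # retention value of the window(s) covering each gene
  val <- rep(NA_real_, nrow(syntelogs))
  for (blk in unique(track$block_id)) {
    tw <- track[track$block_id == blk, , drop = FALSE]
    gix <- which(syntelogs$block_id == blk)
    ai <- syntelogs$ancestral_index[gix]
    m <- outer(ai, tw$start_index, ">=") & outer(ai, tw$end_index, "<=")
    val[gix] <- as.vector(m %*% tw$retention_rate) / pmax(rowSums(m), 1L)
    val[gix][rowSums(m) == 0L] <- NA_real_
  }
  ok <- !is.na(val)
  fisher2x2 <- function(in_stratum, in_class) {
    tab <- table(factor(in_stratum, c(TRUE, FALSE)),
                 factor(in_class, c(TRUE, FALSE)))
    degenerate <- any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)
    or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    p <- if (degenerate) 1 else stats::fisher.test(tab)$p.value
    list(table = tab, odds_ratio = if (degenerate) NA_real_ else or,
         p_value = p, degenerate = degenerate)
  }
  hi <- val >= stats::quantile(val[ok], high_q, na.rm = TRUE)
  lo <- val <= stats::quantile(val[ok], low_q, na.rm = TRUE)
  list(wgd = fisher2x2(hi[ok], syntelogs$origin_class[ok] == "wgd"),
       tandem = fisher2x2(lo[ok], syntelogs$origin_class[ok] == "tandem"))
}

#' Peaks of a synonymous-divergence (Ks) kernel density
#'
#' Gaussian kernel density estimate of a Ks distribution on a 512-point grid
#' over `[0, max(ks) * 1.05]`, with Silverman's rule-of-thumb bandwidth by
#' default, returning every local maximum sorted by density (the classical
#' 'peaks' approach to dating whole-genome duplications).
#'
#' @param ks numeric vector of finite nonnegative Ks values (>= 2 values).
#' @param bandwidth optional numeric bandwidth; default Silverman
#'   (`bw.nrd0`).
#' @return data.frame `peak, density`, ordered by decreasing density.
#' @examples
#' set.seed(1)
#' ks_density_peaks(abs(rnorm(500, 0.1, 0.01)))[1, ]
#' @export
ks_density_peaks <- function(ks, bandwidth = NULL) {
  ks <- ks[!is.na(ks)]
  stop_if(length(ks) < 2L, "need at least 2 Ks values")
  stop_if(any(!is.finite(ks)) || any(ks < 0),
          "Ks values must be finite and nonnegative")
  if (length(unique(ks)) == 1L)
    return(data.frame(peak = ks[1L], density = NA_real_))
  d <- stats::density(ks, bw = if (is.null(bandwidth)) "nrd0" else bandwidth,
                      n = 512L, from = 0, to = max(ks) * 1.05)
  y <- d$y
  n <- length(y)
  is_max <- c(y[1] > y[2],
              y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              y[n] > y[n - 1])
  out <- data.frame(peak = d$x[is_max], density = y[is_max])
  out[order(-out$density), , drop = FALSE]
}

#' LTR retrotransposon insertion age from divergence
#'
#' `T = d / (2 * rate)`: the two LTRs are identical at insertion and each
#' accumulates substitutions at `rate` per site per year.  An optional
#' Jukes-Cantor correction (`d' = -3/4 * log(1 - 4d/3)`) can be applied to
#' the raw divergence first; it is off by default, matching common practice
#' for young insertions.
#'
#' @param divergence substitutions/site (>= 0).
#' @param rate substitution rate per site per year (default `1.3e-8`).
#' @param jc_correct apply Jukes-Cantor correction before dating.
#' @return insertion ages in years.
#' @examples
#' ltr_age(2.6e-3, 1.3e-8)  # 100,000 years
#' @export
ltr_age <- function(divergence, rate = 1.3e-8, jc_correct = FALSE) {
  stop_if(rate <= 0, "`rate` must be > 0")
  stop_if(any(divergence < 0), "`divergence` must be >= 0")
  if (jc_correct) {
    stop_if(any(divergence >= 0.75),
            "Jukes-Cantor correction undefined for divergence >= 0.75")
    divergence <- -0.75 * log(1 - 4 * divergence / 3)
  }
  divergence / (2 * rate)
}

#' Fisher exact test of overlap between two interval sets
#'
#' Cross-classifies the units of a universe (genes or windows) by membership
#' in interval sets A and B (a unit belongs to a set when it overlaps any of
#' its intervals) and applies the two-sided Fisher exact test, as used for
#' testing whether e.g. transposon insertion polymorphisms co-occur with
#' introgressed regions.  All coordinates are 1-based inclusive in memory.
#'
#' @param set_a,set_b data.frames of intervals `chrom, start, end`.
#' @param units data.frame of universe units `chrom, start, end` (the
#'   partition in which overlap is scored).
#' @return list `(table, odds_ratio, p_value, degenerate)`; a zero-margin
#'   table is flagged degenerate with `p = 1` and `NA` odds ratio.
#' @export
interval_overlap_test <- function(set_a, set_b, units) {
  stop_if(!is.data.frame(units) || nrow(units) == 0L, "empty universe")
  as_gr <- function(df) {
    if (is.null(df) || nrow(df) == 0L)
      return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(df$chrom,
                           IRanges::IRanges(df$start, df$end))
  }
  ugr <- as_gr(units)
  in_a <- GenomicRanges::countOverlaps(ugr, as_gr(set_a)) > 0L
  in_b <- GenomicRanges::countOverlaps(ugr, as_gr(set_b)) > 0L
  tab <- table(factor(in_a, c(TRUE, FALSE)), factor(in_b, c(TRUE, FALSE)))
  degenerate <- any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)
  list(table = tab,
       odds_ratio = if (degenerate) NA_real_
                    else (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]),
       p_value = if (degenerate) 1 else stats::fisher.test(tab)$p.value,
       degenerate = degenerate)
}
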