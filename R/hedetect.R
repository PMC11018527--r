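# Homoeologous-exchange detection from subgenome read depth.

BALANCE_CLASSES <- c("EE_hom", "EE_biased", "balanced", "CC_biased",
                     "CC_hom", "no_data")

#' Per-gene coverage from a per-base depth track
#'
#' Averages a per-base depth track over each gene body and pairs the CC-side
#' and EE-side means through the syntelog table, yielding the coverage
#' profile consumed by [windowed_balance()].  Pairs missing one side keep
#' the present side's depth but are excluded from allele-balance windows
#' downstream (a deleted homoeolog cannot be distinguished from exchange).
#'
#' @param depth data.frame of depth intervals `chrom, start, end, depth` in
#'   1-based inclusive coordinates (e.g. from `bedtools genomecov` converted
#'   with [read_bed()] semantics); constant depth per interval.
#' @param genes gene models (data.frame `gene_id, chrom, start, end`, e.g.
#'   [read_gene_models()]); chromosomes are `<chrom>_cc` / `<chrom>_ee`.
#' @param syntelogs syntelog table linking `gene_cc`/`gene_ee` ids.
#' @param accession accession label stored on the profile.
#' @return coverage profile data.frame `pair_id, chrom, ancestral_index,
#'   cc_depth, ee_depth` ordered by ancestral index; one row per pair with
#'   at least one side present.
#' @export
gene_coverage_from_depth <- function(depth, genes, syntelogs,
                                     accession = "sample") {
  stop_if(!all(c("chrom", "start", "end", "depth") %in% names(depth)),
          "`depth` needs columns chrom, start, end, depth")
  stop_if(any(genes$end < genes$start), "gene with zero-length span")
  dgr <- GenomicRanges::GRanges(depth$chrom,
                                IRanges::IRanges(depth$start, depth$end),
                                depth = depth$depth)
  ggr <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$start, genes$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(ggr, dgr))
  stop_if(length(hits) == 0L,
          "depth track does not overlap the gene models (coordinate mismatch?)")
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ov_w <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(ggr)[q], IRanges::ranges(dgr)[s]))
  wsum <- tapply(ov_w * depth$depth[s], q, sum)
  mean_depth <- rep(NA_real_, nrow(genes))
  mean_depth[as.integer(names(wsum))] <-
    wsum / (genes$end - genes$start + 1)[as.integer(names(wsum))]
  names(mean_depth) <- genes$gene_id

  cc <- mean_depth[match(syntelogs$gene_cc, names(mean_depth))]
  ee <- mean_depth[match(syntelogs$gene_ee, names(mean_depth))]
  keep <- !is.na(cc) | !is.na(ee)
  prof <- data.frame(pair_id = syntelogs$pair_id[keep],
                     chrom = syntelogs$chrom[keep],
                     ancestral_index = syntelogs$ancestral_index[keep],
                     cc_depth = cc[keep], ee_depth = ee[keep],
                     stringsAsFactors = FALSE)
  prof <- prof[order(prof$chrom, prof$ancestral_index), , drop = FALSE]
  rownames(prof) <- NULL
  attr(prof, "accession") <- accession
  prof
}

#' Sliding-window allele balance
#'
#' Averages CC-side and EE-side depth in a sliding window of
#' `window_genes` genes (step 1 gene) along each chromosome and computes the
#' allele balance `A = 4 * (CC / (CC + EE) - 0.5)` on the window means.
#' `A` is 0 at balanced 2:2 dosage, +/-1 at 3:1 and +/-2 when one subgenome
#' is absent; it is invariant to uniform depth scaling.  Pairs missing one
#' side are excluded before windowing.  Windows whose total depth is zero
#' get `A = NA`.  A chromosome shorter than the window yields a single
#' partial window (flagged via `n_genes`).
#'
#' @param profile coverage profile (`pair_id, chrom, ancestral_index,
#'   cc_depth, ee_depth`).
#' @param window_genes window width in genes (default 10).
#' @return data.frame of class `balance_track`: `chrom, window_start,
#'   center_index, window_end, mean_cc, mean_ee, A, n_genes`, ordered along
#'   chromosomes.
#' @examples
#' prof <- data.frame(pair_id = paste0("p", 1:20), chrom = "chr1",
#'                    ancestral_index = 1:20, cc_depth = 30, ee_depth = 10)
#' windowed_balance(prof)$A[1]  # exactly 1: 3:1 dosage
#' @export
windowed_balance <- function(profile, window_genes = 10L) {
  window_genes <- check_count(window_genes, "window_genes")
  ok <- !is.na(profile$cc_depth) & !is.na(profile$ee_depth)
  profile <- profile[ok, , drop = FALSE]
  stop_if(nrow(profile) == 0L, "no pairs with both sides present")
  out <- lapply(split(profile, profile$chrom), function(pr) {
    pr <- pr[order(pr$ancestral_index), , drop = FALSE]
    n <- nrow(pr)
    w <- min(window_genes, n)
    starts <- seq_len(max(n - w + 1L, 1L))
    ends <- starts + w - 1L
    ccc <- cumsum(pr$cc_depth); cee <- cumsum(pr$ee_depth)
    mcc <- (ccc[ends] - c(0, ccc)[starts]) / w
    mee <- (cee[ends] - c(0, cee)[starts]) / w
    tot <- mcc + mee
    A <- ifelse(tot > 0, 4 * (mcc / tot - 0.5), NA_real_)
    data.frame(chrom = pr$chrom[1L],
               window_start = pr$ancestral_index[starts],
               center_index = pr$ancestral_index[pmin(
                 starts + (w %/% 2L), n)],
               window_end = pr$ancestral_index[ends],
               mean_cc = mcc, mean_ee = mee, A = A, n_genes = w,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("balance_track", "data.frame")
  attr(res, "window_genes") <- window_genes
  attr(res, "accession") <- attr(profile, "accession")
  res
}

#' Classify allele balance into dosage classes
#'
#' Thresholds follow the published convention: `|A| > 1.5` is homozygous for
#' one subgenome (4:0 or 0:4), `|A| < 0.5` is balanced (2:2).  The unnamed
#' bands `0.5 <= |A| <= 1.5` are labelled `CC_biased` / `EE_biased`
#' (3:1-like); undefined balances map to `no_data`.
#'
#' @param A numeric vector of allele balances (may contain `NA`).
#' @return factor with levels `EE_hom, EE_biased, balanced, CC_biased,
#'   CC_hom, no_data`.
#' @examples
#' classify_balance(c(1.8, 0.2, 1.0, -1.7, NA))
#' @export
classify_balance <- function(A) {
  cls <- rep("no_data", length(A))
  cls[!is.na(A) & A > 1.5] <- "CC_hom"
  cls[!is.na(A) & A < -1.5] <- "EE_hom"
  cls[!is.na(A) & A > -0.5 & A < 0.5] <- "balanced"
  cls[!is.na(A) & A >= 0.5 & A <= 1.5] <- "CC_biased"
  cls[!is.na(A) & A >= -1.5 & A <= -0.5] <- "EE_biased"
  factor(cls, levels = BALANCE_CLASSES)
}

#' Segment a balance track into dosage segments
#'
#' Run-length encodes the window dosage classes along each chromosome,
#' keeps maximal runs of at least `min_windows` consecutive windows sharing
#' a class as segments, and absorbs shorter runs into the flanking balanced
#' state.  Adjacent runs of equal class are merged after absorption, so the
#' procedure is idempotent.  Window runs are converted to gene-index spans
#' through the window centers (`start_gene`/`end_gene` are the centers of
#' the first and last window of the run), which makes segment boundaries
#' unbiased estimates of the true dosage breakpoints: a window straddling a
#' breakpoint changes class once about half of its genes have switched
#' dosage.
#'
#' @param track a `balance_track` from [windowed_balance()].
#' @param min_windows minimum run length in windows for a non-balanced
#'   segment (default 5).
#' @return data.frame of class `dosage_segments`: `accession, chrom,
#'   start_gene, end_gene, dosage_class, mean_A, n_windows`; segments are
#'   non-overlapping in window space and ordered.
#' @export
segment_dosage <- function(track, min_windows = 5L) {
  min_windows <- check_count(min_windows, "min_windows")
  w <- attr(track, "window_genes")
  if (is.null(w)) w <- max(track$n_genes)
  acc <- attr(track, "accession")
  if (is.null(acc)) acc <- "sample"
  out <- lapply(split(seq_len(nrow(track)), track$chrom), function(ix) {
    tr <- track[ix, , drop = FALSE]
    tr <- tr[order(tr$window_start), , drop = FALSE]
    cls <- as.character(classify_balance(tr$A))
    r <- rle(cls)
    # absorb short non-balanced runs into the balanced background
    short <- r$lengths < min_windows & !r$values %in% c("balanced")
    r$values[short] <- "balanced"
    cls2 <- inverse.rle(r)
    # windows straddling the edge of a homozygous segment ramp through the
    # biased band and show up as short spurious "biased" runs; split such
    # transition runs (length <= window width, same direction, adjacent to
    # a hom run) at their midpoint between the hom class and balanced
    r2 <- rle(cls2)
    hom_of <- c(CC_biased = "CC_hom", EE_biased = "EE_hom")
    ends2 <- cumsum(r2$lengths)
    starts2 <- ends2 - r2$lengths + 1L
    for (k in seq_along(r2$values)) {
      v <- r2$values[k]
      if (!v %in% names(hom_of) || r2$lengths[k] > w) next
      hom <- hom_of[[v]]
      before <- k > 1L && r2$values[k - 1L] == hom
      after <- k < length(r2$values) && r2$values[k + 1L] == hom
      if (!before && !after) next
      span <- starts2[k]:ends2[k]
      if (before && after) {
        cls2[span] <- hom
      } else {
        mid <- starts2[k] + (r2$lengths[k] %/% 2L)
        if (after) {           # balanced -> transition -> hom
          cls2[span[span < mid]] <- "balanced"
          cls2[span[span >= mid]] <- hom
        } else {               # hom -> transition -> balanced
          cls2[span[span <= mid]] <- hom
          cls2[span[span > mid]] <- "balanced"
        }
      }
    }
    r2 <- rle(cls2)
    ends <- cumsum(r2$lengths)
    starts <- ends - r2$lengths + 1L
    data.frame(accession = acc, chrom = tr$chrom[1L],
               start_gene = tr$center_index[starts],
               end_gene = tr$center_index[ends],
               dosage_class = r2$values,
               mean_A = vapply(seq_along(starts), function(k)
                 mean(tr$A[starts[k]:ends[k]], na.rm = TRUE), numeric(1)),
               n_windows = r2$lengths,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("dosage_segments", "data.frame")
  attr(res, "window_genes") <- w
  attr(res, "min_windows") <- min_windows
  res
}

#' Chi-squared test of a 3:1 dosage ratio
#'
#' Tests observed CC/EE read counts against an expected ratio (default 3:1
#' toward CC) with the one-degree-of-freedom chi-squared statistic
#' `sum((obs - exp)^2 / exp)` and a Bonferroni adjustment over `n_tests`
#' tests.  The published significance convention is adjusted `p < 0.0005`.
#'
#' @param cc_count,ee_count nonnegative integer read counts (CC then EE).
#' @param ratio expected CC:EE ratio as a length-2 numeric (default
#'   `c(3, 1)`).
#' @param n_tests number of tests for the Bonferroni correction.
#' @return list of class `he_test`: `cc_count, ee_count, expected, chi2, df,
#'   p_raw, p_bonferroni, n_tests, direction` (`"CC-ward"`/`"EE-ward"`
#'   relative to expectation).
#' @examples
#' test_3to1(90, 10)$chi2  # 12
#' @export
test_3to1 <- function(cc_count, ee_count, ratio = c(3, 1), n_tests = 1L) {
  stop_if(cc_count < 0 || ee_count < 0, "counts must be >= 0")
  total <- cc_count + ee_count
  stop_if(total <= 0, "zero total count")
  n_tests <- check_count(n_tests, "n_tests")
  p_exp <- ratio / sum(ratio)
  expected <- p_exp * total
  obs <- c(cc_count, ee_count)
  chi2 <- sum((obs - expected)^2 / expected)
  p_raw <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
  structure(list(cc_count = cc_count, ee_count = ee_count,
                 expected = expected, chi2 = chi2, df = 1L,
                 p_raw = p_raw,
                 p_bonferroni = min(1, p_raw * n_tests),
                 n_tests = n_tests,
                 direction = if (cc_count / total >= p_exp[1L]) "CC-ward"
                             else "EE-ward"),
            class = "he_test")
}

#' Test every non-balanced segment for the 3:1 dosage ratio
#'
#' Sums the integerized per-gene depths of each non-balanced segment into
#' CC/EE counts (depth as a read-count proxy) and applies [test_3to1()] with
#' Bonferroni correction over the number of segments tested (or a supplied
#' `n_tests`, e.g. segments x accessions for a whole run).
#'
#' @param segments `dosage_segments` for one accession.
#' @param profile the accession's coverage profile.
#' @param ratio expected CC:EE ratio.
#' @param n_tests Bonferroni denominator; default: number of tested
#'   segments.
#' @param alpha significance threshold on the adjusted p (default 0.0005).
#' @return data.frame: segment columns plus `cc_count, ee_count, chi2,
#'   p_raw, p_bonferroni, significant, direction`.
#' @export
he_test_segments <- function(segments, profile, ratio = c(3, 1),
                             n_tests = NULL, alpha = 0.0005) {
  seg <- segments[segments$dosage_class != "balanced" &
                    segments$dosage_class != "no_data", , drop = FALSE]
  if (nrow(seg) == 0L)
    return(cbind(seg, data.frame(cc_count = integer(), ee_count = integer(),
                                 chi2 = numeric(), p_raw = numeric(),
                                 p_bonferroni = numeric(),
                                 significant = logical(),
                                 direction = character())))
  if (is.null(n_tests)) n_tests <- nrow(seg)
  res <- lapply(seq_len(nrow(seg)), function(k) {
    hit <- profile$chrom == seg$chrom[k] &
      profile$ancestral_index >= seg$start_gene[k] &
      profile$ancestral_index <= seg$end_gene[k] &
      !is.na(profile$cc_depth) & !is.na(profile$ee_depth)
    tt <- test_3to1(round(sum(profile$cc_depth[hit])),
                    round(sum(profile$ee_depth[hit])),
                    ratio = ratio, n_tests = n_tests)
    data.frame(cc_count = tt$cc_count, ee_count = tt$ee_count,
               chi2 = tt$chi2, p_raw = tt$p_raw,
               p_bonferroni = tt$p_bonferroni,
               significant = tt$p_bonferroni < alpha,
               direction = tt$direction, stringsAsFactors = FALSE)
  })
  out <- cbind(as.data.frame(seg), do.call(rbind, res))
  rownames(out) <- NULL
  out
}

#' Shared and private dosage segments across accessions
#'
#' Votes per gene index and class over all accessions' segments: maximal
#' gene intervals where at least `min_share` accessions carry a segment of
#' the same non-balanced class are reported as shared; covered intervals
#' below the quorum are private (annotated with their accessions).
#'
#' @param segments_list list (or row-bound data.frame) of
#'   `dosage_segments` across >= 2 accessions.
#' @param min_share minimum number of accessions for a shared call.
#' @return list with data.frames `shared` (`chrom, start_gene, end_gene,
#'   dosage_class, n_accessions`) and `private` (same, plus `accessions`).
#' @export
shared_segments <- function(segments_list, min_share = 2L) {
  min_share <- check_count(min_share, "min_share")
  seg <- if (is.data.frame(segments_list)) segments_list
         else do.call(rbind, lapply(segments_list, as.data.frame))
  stop_if(length(unique(seg$accession)) < 2L, "need >= 2 accessions")
  seg <- seg[!seg$dosage_class %in% c("balanced", "no_data"), , drop = FALSE]
  shared <- list(); private <- list()
  for (key in unique(paste(seg$chrom, seg$dosage_class))) {
    parts <- strsplit(key, " ")[[1L]]
    sl <- seg[seg$chrom == parts[1L] & seg$dosage_class == parts[2L], ,
              drop = FALSE]
    lo <- min(sl$start_gene); hi <- max(sl$end_gene)
    cover <- matrix(FALSE, nrow = length(unique(sl$accession)),
                    ncol = hi - lo + 1L,
                    dimnames = list(unique(sl$accession), NULL))
    for (k in seq_len(nrow(sl)))
      cover[sl$accession[k], (sl$start_gene[k]:sl$end_gene[k]) - lo + 1L] <-
        TRUE
    votes <- colSums(cover)
    emit <- function(mask, n_col) {
      if (!any(mask)) return(NULL)
      r <- rle(mask)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      wix <- which(r$values)
      data.frame(chrom = parts[1L],
                 start_gene = starts[wix] + lo - 1L,
                 end_gene = ends[wix] + lo - 1L,
                 dosage_class = parts[2L],
                 n_accessions = vapply(wix, function(j)
                   max(votes[starts[j]:ends[j]]), numeric(1)),
                 stringsAsFactors = FALSE)
    }
    sh <- emit(votes >= min_share)
    pv <- emit(votes > 0L & votes < min_share)
    if (!is.null(pv))
      pv$accessions <- vapply(seq_len(nrow(pv)), function(j) {
        cols <- (pv$start_gene[j]:pv$end_gene[j]) - lo + 1L
        paste(rownames(cover)[rowSums(cover[, cols, drop = FALSE]) > 0L],
              collapse = ",")
      }, character(1))
    shared[[key]] <- sh; private[[key]] <- pv
  }
  empty <- data.frame(chrom = character(), start_gene = integer(),
                      end_gene = integer(), dosage_class = character(),
                      n_accessions = numeric(), stringsAsFactors = FALSE)
  sh <- do.call(rbind, Filter(Negate(is.null), shared))
  pv <- do.call(rbind, Filter(Negate(is.null), private))
  list(shared = if (is.null(sh)) empty else `rownames<-`(sh, NULL),
       private = if (is.null(pv)) cbind(empty, accessions = character())
                 else `rownames<-`(pv, NULL))
}

#' Remove syntelog pairs overlapping homoeologous-exchange segments
#'
#' Drops pairs whose ancestral index falls inside any non-balanced dosage
#' segment of any supplied accession — the standard pre-filter before
#' subgenome expression comparisons, where exchanged regions would mimic
#' expression bias.
#'
#' @param syntelogs syntelog table.
#' @param segments `dosage_segments` (one accession or row-bound set).
#' @return list `pairs` (filtered table) and `removed` (log of removed
#'   pairs with the segment class responsible).
#' @export
filter_he_pairs <- function(syntelogs, segments) {
  seg <- as.data.frame(segments)
  seg <- seg[!seg$dosage_class %in% c("balanced", "no_data"), , drop = FALSE]
  if (nrow(seg) == 0L)
    return(list(pairs = syntelogs,
                removed = syntelogs[0, , drop = FALSE]))
  hit <- rep(FALSE, nrow(syntelogs))
  why <- rep(NA_character_, nrow(syntelogs))
  for (k in seq_len(nrow(seg))) {
    m <- syntelogs$chrom == seg$chrom[k] &
      syntelogs$ancestral_index >= seg$start_gene[k] &
      syntelogs$ancestral_index <= seg$end_gene[k]
    why[m & !hit] <- seg$dosage_class[k]
    hit <- hit | m
  }
  removed <- syntelogs[hit, , drop = FALSE]
  if (nrow(removed)) removed$removed_class <- why[hit]
  list(pairs = syntelogs[!hit, , drop = FALSE], removed = removed)
}

#' Per-accession direction summary of HE segments
#'
#' Totals the genes lying in CC-ward (`CC_hom`/`CC_biased`) versus EE-ward
#' segments per accession; the CC/EE ratio quantifies exchange-direction
#' dominance.  An optional exact binomial test compares gene counts against
#' symmetric exchange.
#'
#' @param segments `dosage_segments` (row-bound across accessions allowed).
#' @param binomial add an exact two-sided binomial test against 0.5.
#' @return data.frame `accession, cc_ward_genes, ee_ward_genes, ratio`
#'   (`Inf` when no EE-ward genes) and optionally `p_binomial`.
#' @export
he_direction_summary <- function(segments, binomial = FALSE) {
  seg <- as.data.frame(segments)
  seg$genes <- seg$end_gene - seg$start_gene + 1L
  ccw <- seg$dosage_class %in% c("CC_hom", "CC_biased")
  eew <- seg$dosage_class %in% c("EE_hom", "EE_biased")
  accs <- unique(seg$accession)
  out <- data.frame(
    accession = accs,
    cc_ward_genes = vapply(accs, function(a)
      sum(seg$genes[ccw & seg$accession == a]), numeric(1)),
    ee_ward_genes = vapply(accs, function(a)
      sum(seg$genes[eew & seg$accession == a]), numeric(1)),
    stringsAsFactors = FALSE)
  out$ratio <- ifelse(out$ee_ward_genes > 0,
                      out$cc_ward_genes / out$ee_ward_genes, Inf)
  if (binomial)
    out$p_binomial <- vapply(seq_len(nrow(out)), function(i) {
      n <- out$cc_ward_genes[i] + out$ee_ward_genes[i]
      if (n == 0) return(NA_real_)
      stats::binom.test(out$cc_ward_genes[i], n, 0.5)$p.value
    }, numeric(1))
  rownames(out) <- NULL
  out
}
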