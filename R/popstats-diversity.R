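# Windowed diversity statistics, polarization and site frequency spectra.

#' @keywords internal
#' @noRd
subset_gt <- function(g, samples) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(samples)) return(g$gt)
  miss <- setdiff(samples, g$samples)
  stop_if(length(miss) > 0L,
          sprintf("samples not in genotype matrix: %s",
                  paste(miss, collapse = ", ")))
  g$gt[samples, , drop = FALSE]
}

#' @keywords internal
#' @noRd
site_freq <- function(gt) {
  n_hap <- 2L * colSums(!is.na(gt))
  der <- colSums(gt, na.rm = TRUE)
  list(n = n_hap, count = der,
       p = ifelse(n_hap > 0, der / n_hap, NA_real_))
}

# Per-site unbiased nucleotide diversity: 2p(1-p) * n/(n-1) with n the
# non-missing haplotype count (complete-case).
#' @keywords internal
#' @noRd
site_pi <- function(gt) {
  f <- site_freq(gt)
  ifelse(f$n >= 2, 2 * f$p * (1 - f$p) * f$n / (f$n - 1), NA_real_)
}

#' @keywords internal
#' @noRd
make_windows <- function(pos_max, window_bp, step_bp) {
  starts <- seq(1L, max(pos_max - window_bp + 1L, 1L), by = step_bp)
  if (pos_max > tail(starts, 1L) + window_bp - 1L)
    starts <- c(starts, tail(starts, 1L) + step_bp)
  data.frame(start = starts, end = starts + window_bp - 1L)
}

#' Windowed nucleotide diversity (pi)
#'
#' Per-site diversity `2 p (1 - p) n/(n - 1)` (with `n` the non-missing
#' haplotype count) summed in sliding windows and divided by the window
#' span in bp — monomorphic positions contribute zero, so the value is a
#' per-bp diversity.  Defaults follow the common resequencing convention of
#' 100-kb windows with 10-kb steps; the genome-wide value is the mean of
#' window values.
#'
#' @param g a `genotype_matrix`.
#' @param samples sample names to use (default: all).
#' @param window_bp,step_bp window and step sizes in bp.
#' @return list with `windows` (data.frame `chrom, start, end, value,
#'   n_sites, statistic`) and `mean` (genome-wide mean of window values).
#' @export
windowed_pi <- function(g, samples = NULL, window_bp = 100000L,
                        step_bp = 10000L) {
  stop_if(window_bp <= 0 || step_bp <= 0, "window/step must be > 0")
  gt <- subset_gt(g, samples)
  pi_s <- site_pi(gt)
  win <- window_apply(g$sites, pi_s, window_bp, step_bp,
                      function(v) sum(v, na.rm = TRUE) / window_bp)
  win$statistic <- "pi"
  list(windows = win, mean = mean(win$value, na.rm = TRUE))
}

#' @keywords internal
#' @noRd
window_apply <- function(sites, values, window_bp, step_bp, fun) {
  out <- lapply(split(seq_len(nrow(sites)), sites$chrom), function(ix) {
    pos <- sites$pos[ix]
    wins <- make_windows(max(pos), window_bp, step_bp)
    res <- vapply(seq_len(nrow(wins)), function(k) {
      inw <- ix[pos >= wins$start[k] & pos <= wins$end[k]]
      c(fun(values[inw]), length(inw))
    }, numeric(2))
    data.frame(chrom = sites$chrom[ix[1L]], start = wins$start,
               end = wins$end, value = res[1L, ], n_sites = res[2L, ],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @keywords internal
#' @noRd
tajima_constants <- function(n) {
  stop_if(n < 4, "Tajima's D needs >= 4 haplotypes")
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D
#'
#' Computes Tajima's (1989) D per window:
#' `D = (khat - S/a1) / sqrt(e1 S + e2 S (S - 1))`, where `khat` is the mean
#' pairwise difference (sum of per-site unbiased diversity over the window)
#' and `S` the number of segregating sites among the chosen samples.
#' Normalizing constants use the maximum haplotype count of the sample set;
#' sites with missing calls contribute their complete-case diversity.
#' Windows with `S = 0` are undefined (`NA`) and excluded from the mean.
#' Windows are non-overlapping 100 kb by default (`step_bp = window_bp`).
#'
#' @param g a `genotype_matrix`.
#' @param samples sample names (>= 2 diploids).
#' @param window_bp window size in bp.
#' @param step_bp step in bp (default: non-overlapping).
#' @return list with `windows` and `mean` as in [windowed_pi()].
#' @export
windowed_tajima_d <- function(g, samples = NULL, window_bp = 100000L,
                              step_bp = window_bp) {
  gt <- subset_gt(g, samples)
  n <- 2L * nrow(gt)
  konst <- tajima_constants(n)
  f <- site_freq(gt)
  seg <- !is.na(f$p) & f$p > 0 & f$p < 1
  pi_s <- site_pi(gt)
  stat <- function(v_pi, v_seg) {
    S <- sum(v_seg)
    if (S < 1) return(NA_real_)
    khat <- sum(v_pi[v_seg], na.rm = TRUE)
    (khat - S / konst$a1) /
      sqrt(konst$e1 * S + konst$e2 * S * (S - 1))
  }
  # carry both per-site vectors through the window machinery
  win <- window_apply(g$sites, seq_len(nrow(g$sites)), window_bp, step_bp,
                      function(ix) stat(pi_s[ix], seg[ix]))
  win$statistic <- "tajima_d"
  list(windows = win, mean = mean(win$value, na.rm = TRUE))
}

#' Tajima's D for a whole site set
#'
#' Single-value variant of [windowed_tajima_d()] over all supplied sites;
#' used mostly by tests and small fixtures.
#'
#' @param gt integer genotype matrix (samples x sites).
#' @return Tajima's D (or `NA` when no segregating sites).
#' @export
tajima_d <- function(gt) {
  n <- 2L * nrow(gt)
  konst <- tajima_constants(n)
  f <- site_freq(gt)
  seg <- !is.na(f$p) & f$p > 0 & f$p < 1
  S <- sum(seg)
  if (S < 1) return(NA_real_)
  khat <- sum(site_pi(gt)[seg], na.rm = TRUE)
  (khat - S / konst$a1) / sqrt(konst$e1 * S + konst$e2 * S * (S - 1))
}

#' Polarize sites to ancestral state by outgroup majority vote
#'
#' The ancestral allele of each site is the majority allele across all
#' non-missing outgroup haplotypes; ties and all-missing sites remain
#' unresolved (`NA`).
#'
#' @param g a `genotype_matrix`.
#' @param outgroup_samples character vector of outgroup sample names
#'   (>= 1).
#' @return `g` with `sites$anc` filled (allele letter) and an attribute
#'   `polarization` (data.frame `chrom, pos, anc, resolved`).
#' @export
polarize_ancestral <- function(g, outgroup_samples) {
  stop_if(length(outgroup_samples) < 1L, "need >= 1 outgroup sample")
  gt <- subset_gt(g, outgroup_samples)
  alt_votes <- colSums(gt, na.rm = TRUE)
  tot_votes <- 2L * colSums(!is.na(gt))
  ref_votes <- tot_votes - alt_votes
  anc <- ifelse(tot_votes == 0L | ref_votes == alt_votes, NA_character_,
                ifelse(ref_votes > alt_votes, g$sites$ref, g$sites$alt))
  g$sites$anc <- anc
  attr(g, "polarization") <- data.frame(
    chrom = g$sites$chrom, pos = g$sites$pos, anc = anc,
    resolved = !is.na(anc), stringsAsFactors = FALSE)
  g
}

#' Site frequency spectrum
#'
#' Unfolded spectrum: counts segregating sites by derived-allele count
#' `1..2N-1` among the chosen samples, using the ancestral assignment in
#' `sites$anc` (see [polarize_ancestral()]); unresolved sites are excluded
#' and logged.  Folded spectrum: counts by minor-allele count `1..N`.
#' Sites with missing calls are used at their complete-case haplotype count
#' only when it equals `2N` (complete-case projection to the full sample is
#' not performed); with no missing data every segregating site is counted.
#'
#' @param g a `genotype_matrix`.
#' @param samples sample names (default all).
#' @param polarized `TRUE` for the unfolded spectrum (requires ancestral
#'   assignments), `FALSE` for folded.
#' @return list with `spectrum` (named integer vector), `excluded`
#'   (sites dropped: unresolved ancestry or incomplete calls) and
#'   `n_segregating` (total segregating sites seen).
#' @export
sfs <- function(g, samples = NULL, polarized = TRUE) {
  gt <- subset_gt(g, samples)
  N2 <- 2L * nrow(gt)
  f <- site_freq(gt)
  seg <- !is.na(f$p) & f$p > 0 & f$p < 1
  complete <- f$n == N2
  usable <- seg & complete
  excluded <- sum(seg & !complete)
  if (polarized) {
    anc <- g$sites$anc
    stop_if(all(is.na(anc)),
            "unfolded SFS requires ancestral assignments; run polarize_ancestral()")
    resolved <- !is.na(anc)
    usable2 <- usable & resolved
    excluded <- excluded + sum(usable & !resolved)
    der <- ifelse(anc == g$sites$ref, f$count, N2 - f$count)
    counts <- tabulate(der[usable2], nbins = N2 - 1L)
    names(counts) <- seq_len(N2 - 1L)
  } else {
    minor <- pmin(f$count, N2 - f$count)
    counts <- tabulate(minor[usable], nbins = N2 %/% 2L)
    names(counts) <- seq_len(N2 %/% 2L)
  }
  list(spectrum = counts, excluded = excluded, n_segregating = sum(seg))
}

#' Fold an unfolded site frequency spectrum
#'
#' @param spectrum unfolded spectrum vector (`1..2N-1` entries).
#' @return folded spectrum (`1..N` entries, minor-allele counts).
#' @export
fold_sfs <- function(spectrum) {
  k <- length(spectrum) + 1L            # 2N
  half <- k %/% 2L
  out <- vapply(seq_len(half), function(i) {
    if (i == k - i) spectrum[i]
    else spectrum[i] + spectrum[k - i]
  }, numeric(1))
  names(out) <- seq_len(half)
  out
}

#' Convert generations to calendar years
#'
#' `years = generations * generation_time`; the default 21-year generation
#' time is standard for wild arabica coffee.  Also reports thousands of
#' years (`ka`) rounded half-away-from-zero to one decimal.
#'
#' @param generations number of generations (> 0).
#' @param generation_time generation time in years (> 0; default 21).
#' @return list `years`, `ka` (rounded to one decimal).
#' @examples
#' generations_to_years(1450)  # 30450 years, 30.5 ka
#' @export
generations_to_years <- function(generations, generation_time = 21) {
  stop_if(any(generations <= 0) || generation_time <= 0,
          "inputs must be > 0")
  years <- generations * generation_time
  ka_raw <- years / 1000
  # round half away from zero to one decimal
  ka <- sign(ka_raw) * floor(abs(ka_raw) * 10 + 0.5) / 10
  list(years = years, ka = ka)
}

#' Convert years back to generations
#'
#' @param years years (> 0).
#' @param generation_time generation time in years (default 21).
#' @return generations.
#' @export
years_to_generations <- function(years, generation_time = 21) {
  stop_if(any(years <= 0) || generation_time <= 0, "inputs must be > 0")
  years / generation_time
}
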