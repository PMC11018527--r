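# Subgenome expression-bias assessment on syntelog pairs.

#' Log-scale TPM transform
#'
#' `log10(x + 1e-4)`: the small offset keeps zero-TPM genes finite at
#' exactly -4 while leaving expressed genes essentially unchanged.
#'
#' @param x TPM values (>= 0).
#' @return log10-scaled values.
#' @examples
#' log_tpm(0)   # -4
#' log_tpm(10)  # ~1.0000043
#' @export
log_tpm <- function(x) {
  stop_if(any(x < 0, na.rm = TRUE), "TPM values must be >= 0")
  log10(x + 1e-4)
}

#' Per-pair subgenome expression bias
#'
#' For each syntelog pair surviving the homoeologous-exchange filter
#' ([filter_he_pairs()]), computes the per-sample log10 CC/EE expression
#' ratio on the log-TPM scale and its mean over samples, then classifies
#' the pair as CC- or EE-biased when the absolute mean ratio reaches
#' `log10(fold_threshold)`, else `none`.  Pairs with both members at zero
#' TPM in every sample are `undetermined`.
#'
#' @param expression expression table from [gen_expression()] /
#'   [read_fixtures()]: columns `gene_id, pair_id, subgenome` plus one
#'   numeric column per sample.
#' @param pairs syntelog table of pairs to assess (after HE filtering).
#' @param fold_threshold TPM fold-change defining bias (default 2).
#' @param families optional named assignment `pair_id -> family` label
#'   (e.g. NMT, TPS, FAD2) carried into the result.
#' @return data.frame of class `pair_bias`: `pair_id, family, log_ratio,
#'   bias_class` (`CC`/`EE`/`none`/`undetermined`), plus per-sample ratio
#'   columns `ratio_<sample>`; attribute `fold_threshold`.
#' @export
pair_bias <- function(expression, pairs, fold_threshold = 2,
                      families = NULL) {
  stop_if(fold_threshold <= 0, "`fold_threshold` must be > 0")
  samp_cols <- setdiff(names(expression),
                       c("gene_id", "pair_id", "subgenome"))
  stop_if(length(samp_cols) == 0L, "no sample columns in expression table")
  cc <- expression[expression$subgenome == "cc", , drop = FALSE]
  ee <- expression[expression$subgenome == "ee", , drop = FALSE]
  ids <- intersect(pairs$pair_id, intersect(cc$pair_id, ee$pair_id))
  cc <- cc[match(ids, cc$pair_id), samp_cols, drop = FALSE]
  ee <- ee[match(ids, ee$pair_id), samp_cols, drop = FALSE]
  ratio <- log_tpm(as.matrix(cc)) - log_tpm(as.matrix(ee))
  mean_ratio <- rowMeans(ratio)
  cut <- log10(fold_threshold)
  cls <- ifelse(mean_ratio >= cut, "CC",
                ifelse(mean_ratio <= -cut, "EE", "none"))
  all_zero <- rowSums(as.matrix(cc) > 0) == 0L &
    rowSums(as.matrix(ee) > 0) == 0L
  cls[all_zero] <- "undetermined"
  out <- data.frame(pair_id = ids,
                    family = if (is.null(families)) NA_character_
                             else unname(families[ids]),
                    log_ratio = mean_ratio,
                    bias_class = cls, stringsAsFactors = FALSE)
  colnames(ratio) <- paste0("ratio_", samp_cols)
  out <- cbind(out, as.data.frame(ratio))
  rownames(out) <- NULL
  attr(out, "fold_threshold") <- fold_threshold
  class(out) <- c("pair_bias", "data.frame")
  out
}

#' Exact binomial test of global subgenome expression dominance
#'
#' Two-sided exact binomial sign test of the number of CC-biased versus
#' EE-biased pairs against the symmetric expectation 0.5, among pairs with
#' a definite bias class.  A non-significant result is consistent with no
#' global subgenome dominance, the usual finding in harmonious
#' allopolyploids.
#'
#' @param bias a `pair_bias` result (or data.frame with `bias_class`).
#' @return list `n_cc, n_ee, p_value, estimate` (CC fraction).
#' @export
global_dominance_test <- function(bias) {
  n_cc <- sum(bias$bias_class == "CC")
  n_ee <- sum(bias$bias_class == "EE")
  stop_if(n_cc + n_ee == 0L, "no pairs with a definite bias class")
  bt <- stats::binom.test(n_cc, n_cc + n_ee, p = 0.5,
                          alternative = "two.sided")
  list(n_cc = n_cc, n_ee = n_ee, p_value = bt$p.value,
       estimate = unname(bt$estimate))
}

#' Per-family mosaic expression summary
#'
#' Tallies bias classes within gene families and flags a family as mosaic
#' when it contains at least one CC-biased and one EE-biased pair — the
#' family-wise pattern in which overall expression balance hides opposing
#' member-level biases.
#'
#' @param bias a `pair_bias` result with family labels (or supply
#'   `families` as a named vector `pair_id -> family`).
#' @param families optional named character vector overriding
#'   `bias$family`.
#' @return data.frame `family, n_cc, n_ee, n_none, mosaic`.
#' @export
family_mosaic_summary <- function(bias, families = NULL) {
  fam <- if (!is.null(families)) unname(families[bias$pair_id])
         else bias$family
  stop_if(all(is.na(fam)), "no family labels available")
  ok <- !is.na(fam)
  fam <- fam[ok]; cls <- bias$bias_class[ok]
  ufam <- sort(unique(fam))
  out <- data.frame(
    family = ufam,
    n_cc = vapply(ufam, function(f) sum(cls == "CC" & fam == f),
                  integer(1)),
    n_ee = vapply(ufam, function(f) sum(cls == "EE" & fam == f),
                  integer(1)),
    n_none = vapply(ufam, function(f) sum(cls == "none" & fam == f),
                    integer(1)),
    stringsAsFactors = FALSE)
  out$mosaic <- out$n_cc >= 1L & out$n_ee >= 1L
  rownames(out) <- NULL
  out
}
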