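#' Generate syntelog expression with optionally planted subgenome bias
#'
#' For each retained syntelog pair, draws a pair-level baseline TPM from a
#' log-normal distribution (meanlog 2, sdlog 1, i.e. median ~7 TPM) shared by
#' the CC and EE members, then multiplies per-sample log-normal noise
#' (`expr_noise_sd` on the log scale).  A fraction `bias_fraction` of pairs is
#' planted with a `bias_fold` fold-change: the favoured member is scaled by
#' `sqrt(bias_fold)` and the other by `1/sqrt(bias_fold)`, so the planted
#' CC/EE ratio is exactly `bias_fold` in expectation while the pair mean is
#' unchanged.  Direction is random per pair unless `config$bias_direction`
#' fixes it.
#'
#' @param syntelogs syntelog table from [gen_syntelog_landscape()].
#' @param config a [sim_config()].
#' @return list with `expression` (data.frame: `gene_id, pair_id, subgenome`
#'   then one TPM column per sample `s1..sK`) and `truth` (`biased_pairs`
#'   data.frame `pair_id, direction, fold`).
#' @examples
#' cfg <- sim_config(seed = 1, n_genes_per_chrom = 50, bias_fraction = 0.2)
#' land <- gen_syntelog_landscape(cfg)
#' ex <- gen_expression(land$syntelogs, cfg)
#' head(ex$expression)
#' @export
gen_expression <- function(syntelogs, config) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(syntelogs))
  check_prob(config$bias_fraction, "bias_fraction")
  stop_if(config$bias_fold <= 0, "`bias_fold` must be > 0")
  set.seed(derive_seed(config$seed, "expression"))
  ret <- syntelogs[syntelogs$status == "retained", , drop = FALSE]
  n <- nrow(ret)
  k <- config$n_expr_samples
  base <- rlnorm(n, meanlog = 2, sdlog = 1)

  biased <- runif(n) < config$bias_fraction
  direction <- rep(NA_character_, n)
  direction[biased] <- switch(config$bias_direction,
    both = ifelse(runif(sum(biased)) < 0.5, "cc", "ee"),
    cc = "cc", ee = "ee")
  mult_cc <- rep(1, n); mult_ee <- rep(1, n)
  sf <- sqrt(config$bias_fold)
  mult_cc[biased & direction == "cc"] <- sf
  mult_ee[biased & direction == "cc"] <- 1 / sf
  mult_cc[biased & direction == "ee"] <- 1 / sf
  mult_ee[biased & direction == "ee"] <- sf

  noise <- function() matrix(rlnorm(n * k, 0, config$expr_noise_sd),
                             nrow = n)
  tpm_cc <- base * mult_cc * noise()
  tpm_ee <- base * mult_ee * noise()
  samp <- sprintf("s%d", seq_len(k))
  mk <- function(genes, sub, tpm) {
    out <- data.frame(gene_id = genes, pair_id = ret$pair_id,
                      subgenome = sub, stringsAsFactors = FALSE)
    colnames(tpm) <- samp
    cbind(out, as.data.frame(tpm))
  }
  expression <- rbind(mk(ret$gene_cc, "cc", tpm_cc),
                      mk(ret$gene_ee, "ee", tpm_ee))
  rownames(expression) <- NULL
  truth <- list(biased_pairs = data.frame(
    pair_id = ret$pair_id[biased],
    direction = direction[biased],
    fold = rep(config$bias_fold, sum(biased)), stringsAsFactors = FALSE))
  list(expression = expression, truth = truth)
}

#' LTR retrotransposon divergence from insertion age
#'
#' The two long terminal repeats of a retrotransposon are identical on
#' insertion and diverge at twice the substitution rate, so the expected
#' divergence after `T` years is `d = 2 * rate * T`.  With `seq_length`
#' given, binomial sampling noise at that sequence length is added
#' (substitutions ~ `Binomial(L, d)`).
#'
#' @param ages numeric vector of insertion ages in years (>= 0).
#' @param rate substitution rate per site per year (default `1.3e-8`).
#' @param seq_length optional LTR length in bp for sampling noise; `NULL`
#'   returns noiseless expectations.
#' @return numeric vector of divergences (substitutions/site).
#' @seealso [ltr_age()] for the inverse transform.
#' @examples
#' gen_ltr_divergences(c(0, 1e5), rate = 1.3e-8)
#' @export
gen_ltr_divergences <- function(ages, rate = 1.3e-8, seq_length = NULL) {
  stop_if(any(ages < 0), "ages must be >= 0")
  stop_if(rate <= 0, "`rate` must be > 0")
  d <- 2 * rate * ages
  if (is.null(seq_length)) return(d)
  seq_length <- check_count(seq_length, "seq_length")
  stop_if(any(d > 1), "expected divergence exceeds 1; check ages/rate")
  rbinom(length(d), seq_length, d) / seq_length
}
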