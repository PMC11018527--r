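# End-to-end orchestration over fixture files.

#' Build a validated pipeline run configuration
#'
#' Bundles input paths and stage parameters.  Defaults mirror the printed
#' analysis conventions: 10-gene balance windows with dosage thresholds
#' +/-1.5 / +/-0.5, Bonferroni alpha 0.0005 for 3:1 tests, 100-kb/10-kb
#' diversity windows, 100-kb Tajima's D windows, 2-kb gene flanks for FST,
#' 20-kb scan/jackknife windows and a 21-year generation time.
#'
#' @param fixtures_dir directory of fixture files ([write_fixtures()]
#'   layout).
#' @param out_dir output directory for stage result files.
#' @param stages character subset of
#'   `c("synteny", "he", "popstats", "exprbias")`.
#' @param window_genes,min_windows,alpha HE stage parameters.
#' @param pi_window,pi_step,tajd_window,flank_bp,scan_window,block_bp
#'   population-statistics parameters (bp).
#' @param fold_threshold expression-bias fold threshold.
#' @param generation_time generation time in years.
#' @param seed seed echoed into the report (stages are deterministic).
#' @return list of class `run_config`.
#' @export
run_config <- function(fixtures_dir, out_dir,
                       stages = c("synteny", "he", "popstats", "exprbias"),
                       window_genes = 10L, min_windows = 5L,
                       alpha = 0.0005,
                       pi_window = 100000L, pi_step = 10000L,
                       tajd_window = 100000L, flank_bp = 2000L,
                       scan_window = 20000L, block_bp = 20000L,
                       fold_threshold = 2, generation_time = 21,
                       seed = 1L) {
  known <- c("synteny", "he", "popstats", "exprbias")
  stop_if(!all(stages %in% known),
          sprintf("unknown stage(s): %s",
                  paste(setdiff(stages, known), collapse = ", ")))
  structure(list(fixtures_dir = fixtures_dir, out_dir = out_dir,
                 stages = stages, window_genes = window_genes,
                 min_windows = min_windows, alpha = alpha,
                 pi_window = pi_window, pi_step = pi_step,
                 tajd_window = tajd_window, flank_bp = flank_bp,
                 scan_window = scan_window, block_bp = block_bp,
                 fold_threshold = fold_threshold,
                 generation_time = generation_time,
                 seed = check_count(seed, "seed", 0L)),
            class = "run_config")
}

#' Load a pipeline configuration from a JSON file
#'
#' @param path JSON file whose keys match the [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  stop_if(!file.exists(path), sprintf("no such file '%s'", path))
  args <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, args)
}

#' Validate pipeline inputs
#'
#' Checks fixture files for existence and format conformance (VCF header
#' and genotype codes, GFF3 readability, TSV schemas) and for agreement
#' between VCF samples and the population map.  Errors are collected, not
#' thrown.
#'
#' @param config a `run_config`.
#' @return character vector of error messages (empty when clean).
#' @export
validate_inputs <- function(config) {
  errs <- character()
  dirp <- config$fixtures_dir
  addf <- function(msg) errs <<- c(errs, msg)
  need <- c("syntelogs.tsv", "popmap.tsv", "genotypes.vcf", "genes.gff3",
            "expression.tsv")
  for (f in need)
    if (!file.exists(file.path(dirp, f)))
      addf(sprintf("missing input file: %s", f))
  if (length(errs)) return(errs)

  synt <- tryCatch(read_syntelogs(file.path(dirp, "syntelogs.tsv")),
                   error = function(e) {
                     addf(paste("syntelogs:", conditionMessage(e))); NULL
                   })
  vcf_head <- readLines(file.path(dirp, "genotypes.vcf"), n = 1L)
  if (!grepl("^##fileformat=VCF", vcf_head))
    addf("genotypes.vcf: missing ##fileformat header")
  g <- tryCatch(read_genotypes(file.path(dirp, "genotypes.vcf")),
                error = function(e) {
                  addf(paste("genotypes.vcf:", conditionMessage(e))); NULL
                })
  popmap <- tryCatch(read_tsv_df(file.path(dirp, "popmap.tsv")),
                     error = function(e) {
                       addf(paste("popmap:", conditionMessage(e))); NULL
                     })
  if (!is.null(popmap) && !all(c("sample", "population") %in% names(popmap)))
    addf("popmap.tsv: needs columns sample, population")
  if (!is.null(g) && !is.null(popmap) &&
      all(c("sample", "population") %in% names(popmap))) {
    missing <- setdiff(popmap$sample, g$samples)
    if (length(missing))
      addf(sprintf("samples in popmap but not in VCF: %s",
                   paste(missing, collapse = ", ")))
  }
  genes <- tryCatch(read_gene_models(file.path(dirp, "genes.gff3")),
                    error = function(e) {
                      addf(paste("genes.gff3:", conditionMessage(e))); NULL
                    })
  if (!is.null(synt) && !is.null(genes)) {
    known <- genes$gene_id
    ref <- c(synt$gene_cc, synt$gene_ee)
    ref <- ref[!is.na(ref)]
    if (!all(ref %in% known))
      addf("syntelogs reference gene ids absent from genes.gff3")
  }
  cov <- list.files(dirp, pattern = "^coverage_.*\\.tsv$")
  if (!length(cov)) addf("no coverage_<accession>.tsv files found")
  errs
}

#' Run all enabled pipeline stages
#'
#' Executes the enabled stages in dependency order (synteny -> HE ->
#' population statistics -> expression bias) on the fixture directory,
#' writes each stage's tables under `out_dir` and returns a structured
#' report.  The expression-bias stage requires the HE stage (its pair
#' filter); disabling HE while requesting expression bias is an error.
#' Given identical inputs the outputs are byte-identical.
#'
#' @param config a `run_config`.
#' @return list of class `run_report`: `package_version, parameters,
#'   input_checksums, stages` (per stage: output files with md5 checksums,
#'   key numbers, elapsed seconds).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  errs <- validate_inputs(config)
  stop_if(length(errs) > 0L,
          paste("invalid inputs:", paste(errs, collapse = "; ")))
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  stages <- config$stages
  if ("exprbias" %in% stages && !"he" %in% stages)
    stop("stage 'exprbias' requires stage 'he' (HE pair filter); ",
         "enable 'he' or drop 'exprbias'", call. = FALSE)

  fx <- read_fixtures(config$fixtures_dir)
  inputs <- list.files(config$fixtures_dir, full.names = TRUE)
  inputs <- inputs[!file.info(inputs)$isdir]
  report <- list(package_version = as.character(
                   utils::packageVersion("polykit")),
                 parameters = unclass(config),
                 input_checksums = as.list(tools::md5sum(inputs)),
                 stages = list())
  emit <- function(x, name) {
    path <- file.path(config$out_dir, name)
    data.table::fwrite(as.data.frame(x), path, sep = "\t", quote = FALSE,
                       na = "NA")
    path
  }
  finish <- function(stage, files, numbers, t0) {
    report$stages[[stage]] <<- list(
      outputs = as.list(tools::md5sum(files)),
      numbers = numbers,
      elapsed_s = round(as.numeric(Sys.time()) - t0, 3))
  }

  segments_all <- NULL
  if ("synteny" %in% stages) {
    t0 <- as.numeric(Sys.time())
    track <- retention_rate_track(fx$syntelogs, 50L, 50L, side = "retained")
    spec <- deletion_run_spectrum(fx$syntelogs)
    gaps <- intergenic_gap_profile(fx$syntelogs)
    files <- c(emit(track, "retention_track.tsv"),
               emit(spec$histogram, "deletion_run_spectrum.tsv"),
               emit(gaps, "intergenic_gap_profile.tsv"))
    ksp <- if (any(!is.na(fx$syntelogs$ks)))
      ks_density_peaks(fx$syntelogs$ks[!is.na(fx$syntelogs$ks)]) else NULL
    if (!is.null(ksp)) files <- c(files, emit(ksp, "ks_peaks.tsv"))
    finish("synteny", files,
           list(n_runs = nrow(spec$runs),
                top_ks_peak = if (!is.null(ksp)) ksp$peak[1L] else NA), t0)
  }
  if ("he" %in% stages) {
    t0 <- as.numeric(Sys.time())
    seg_list <- lapply(names(fx$profiles), function(acc) {
      prof <- fx$profiles[[acc]]
      attr(prof, "accession") <- acc
      tr <- windowed_balance(prof, config$window_genes)
      segment_dosage(tr, config$min_windows)
    })
    segments_all <- do.call(rbind, lapply(seg_list, as.data.frame))
    tests <- do.call(rbind, lapply(seq_along(seg_list), function(i) {
      he_test_segments(seg_list[[i]], fx$profiles[[names(fx$profiles)[i]]],
                       alpha = config$alpha)
    }))
    files <- c(emit(segments_all, "dosage_segments.tsv"),
               emit(tests, "he_tests.tsv"),
               emit(he_direction_summary(segments_all),
                    "he_direction.tsv"))
    finish("he", files,
           list(n_segments = sum(segments_all$dosage_class != "balanced"),
                n_significant = sum(tests$significant)), t0)
  }
  if ("popstats" %in% stages) {
    t0 <- as.numeric(Sys.time())
    g <- fx$genotypes
    popmap <- fx$popmap
    pops <- split(popmap$sample, popmap$population)
    wild <- pops$wild; cult <- pops$cultivar
    files <- character(); numbers <- list()
    if (!is.null(wild) && length(wild) >= 2L) {
      pw <- windowed_pi(g, wild, config$pi_window, config$pi_step)
      dw <- windowed_tajima_d(g, wild, config$tajd_window)
      files <- c(files, emit(pw$windows, "pi_wild.tsv"),
                 emit(dw$windows, "tajima_d_wild.tsv"))
      numbers$pi_wild <- pw$mean; numbers$tajima_d_wild <- dw$mean
    }
    if (!is.null(cult) && length(cult) >= 2L) {
      pc <- windowed_pi(g, cult, config$pi_window, config$pi_step)
      files <- c(files, emit(pc$windows, "pi_cultivar.tsv"))
      numbers$pi_cultivar <- pc$mean
    }
    if (!is.null(wild) && !is.null(cult) &&
        length(wild) >= 2L && length(cult) >= 2L) {
      genes <- read_gene_models(file.path(config$fixtures_dir,
                                          "genes.gff3"))
      genes_cc <- genes[grepl("_cc$", genes$chrom), , drop = FALSE]
      genes_cc$chrom <- sub("_cc$", "", genes_cc$chrom)
      fst <- gene_fst(g, wild, cult, genes_cc, config$flank_bp)
      files <- c(files, emit(fst, "gene_fst.tsv"))
      numbers$mean_gene_fst <- mean(fst$fst, na.rm = TRUE)
    }
    outg <- c(pops$outgroup_cc, pops$outgroup_ee)
    if (length(outg)) {
      g <- polarize_ancestral(g, outg)
      sp <- sfs(g, samples = c(wild, cult), polarized = TRUE)
      files <- c(files,
                 emit(data.frame(derived_count = names(sp$spectrum),
                                 sites = as.integer(sp$spectrum)),
                      "sfs_unfolded.tsv"))
      numbers$sfs_excluded <- sp$excluded
    }
    finish("popstats", files, numbers, t0)
  }
  if ("exprbias" %in% stages) {
    t0 <- as.numeric(Sys.time())
    filt <- filter_he_pairs(fx$syntelogs, segments_all)
    bias <- pair_bias(fx$expression, filt$pairs, config$fold_threshold)
    glob <- global_dominance_test(bias)
    files <- c(emit(bias, "pair_bias.tsv"))
    finish("exprbias", files,
           list(n_pairs = nrow(bias), n_removed_he = nrow(filt$removed),
                n_cc = glob$n_cc, n_ee = glob$n_ee,
                dominance_p = glob$p_value), t0)
  }
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("polykit run report (v%s): %d stage(s)\n",
              x$package_version, length(x$stages)))
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-9s %d output file(s), %.2fs\n", nm,
                length(st$outputs), st$elapsed_s))
  }
  invisible(x)
}

#' Serialize a run report to JSON
#'
#' @param report a `run_report`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
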