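# Fixture serialization: TSV via data.table, GFF3/BED via rtracklayer,
# VCF text written directly and read back through VariantAnnotation.

#' Run all generators on one configuration
#'
#' Convenience wrapper producing the complete synthetic dataset (landscape,
#' coverage profiles, genotypes, expression) with a merged ground-truth
#' record.  Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param n_hybrid admixed individuals passed to [gen_genotypes()].
#' @return object of class `polyploid_sim`: list with `config`, `syntelogs`,
#'   `profiles`, `genotypes`, `popmap`, `expression`, `truth`.
#' @examples
#' sim <- simulate_dataset(sim_config(seed = 1, n_genes_per_chrom = 50,
#'                                    n_sites = 100))
#' names(sim)
#' @export
simulate_dataset <- function(config, n_hybrid = 0L) {
  land <- gen_syntelog_landscape(config)
  cov <- gen_coverage_profiles(land$syntelogs, config)
  gen <- gen_genotypes(config, n_hybrid = n_hybrid)
  expr <- gen_expression(land$syntelogs, config)
  structure(list(config = config,
                 syntelogs = land$syntelogs,
                 profiles = cov$profiles,
                 genotypes = gen$genotypes,
                 popmap = gen$popmap,
                 expression = expr$expression,
                 truth = c(land$truth, cov$truth, gen$truth, expr$truth)),
            class = "polyploid_sim")
}

#' Write a synthetic dataset to standard-format fixture files
#'
#' Emits the full dataset as plain-text files: syntelog TSV, per-accession
#' coverage TSVs, genotypes as VCFv4.2, population map TSV, expression TSV,
#' gene models as GFF3 (1-based inclusive; CC-side and EE-side genes on
#' `<chrom>_cc` / `<chrom>_ee` sequences), planted HE segments as BED
#' (0-based half-open) and every ground-truth table as `truth_*.tsv`.
#' Re-reading with [read_fixtures()] reproduces the in-memory objects; a
#' fixed seed yields byte-identical files.
#'
#' @param sim a `polyploid_sim` from [simulate_dataset()].
#' @param dir output directory (created if absent).
#' @return invisibly, the character vector of files written.
#' @export
write_fixtures <- function(sim, dir) {
  stopifnot(inherits(sim, "polyploid_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stop_if(!dir.exists(dir), sprintf("cannot create directory '%s'", dir))
  files <- character()
  tsv <- function(x, name) {
    path <- file.path(dir, name)
    data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
    files <<- c(files, path)
    path
  }
  tsv(sim$syntelogs, "syntelogs.tsv")
  for (acc in names(sim$profiles))
    tsv(sim$profiles[[acc]], sprintf("coverage_%s.tsv", acc))
  tsv(sim$popmap, "popmap.tsv")
  tsv(sim$expression, "expression.tsv")

  vcf_path <- file.path(dir, "genotypes.vcf")
  write_vcf(sim$genotypes, vcf_path)
  files <- c(files, vcf_path)

  gff_path <- file.path(dir, "genes.gff3")
  write_gene_models(sim$syntelogs, gff_path)
  files <- c(files, gff_path)

  seg <- sim$truth$he_segments
  bed_path <- file.path(dir, "he_segments.bed")
  slot <- sim$config$gene_bp + sim$config$intergenic_bp
  bed <- data.frame(
    chrom = if (nrow(seg)) seg$chrom else character(),
    start = if (nrow(seg)) (seg$start_gene - 1L) * slot else integer(),
    end = if (nrow(seg)) seg$end_gene * slot else integer(),
    name = if (nrow(seg)) paste(seg$accession, seg$dosage, sep = "|")
           else character())
  data.table::fwrite(bed, bed_path, sep = "\t", quote = FALSE,
                     col.names = FALSE)
  files <- c(files, bed_path)

  for (nm in names(sim$truth)) {
    x <- sim$truth[[nm]]
    if (is.data.frame(x)) tsv(x, sprintf("truth_%s.tsv", nm))
  }
  invisible(files)
}

#' Read fixture files back into memory
#'
#' @param dir directory written by [write_fixtures()].
#' @return list with `syntelogs`, `profiles`, `genotypes`, `popmap`,
#'   `expression`.
#' @export
read_fixtures <- function(dir) {
  stop_if(!dir.exists(dir), sprintf("no such directory '%s'", dir))
  cov_files <- sort(list.files(dir, pattern = "^coverage_.*\\.tsv$",
                               full.names = TRUE))
  profiles <- lapply(cov_files, read_tsv_df)
  names(profiles) <- sub("^coverage_(.*)\\.tsv$", "\\1", basename(cov_files))
  list(syntelogs = read_syntelogs(file.path(dir, "syntelogs.tsv")),
       profiles = profiles,
       genotypes = read_genotypes(file.path(dir, "genotypes.vcf")),
       popmap = read_tsv_df(file.path(dir, "popmap.tsv")),
       expression = read_tsv_df(file.path(dir, "expression.tsv")))
}

#' @keywords internal
#' @noRd
read_tsv_df <- function(path) {
  stop_if(!file.exists(path), sprintf("no such file '%s'", path))
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
}

#' Read a syntelog table from TSV
#'
#' Expects at least `pair_id, chrom, block_id, ancestral_index, gene_cc,
#' gene_ee, status`; coordinate, `ks` and `origin_class` columns are kept
#' when present.
#'
#' @param path TSV file path.
#' @return syntelog data.frame ordered by chromosome and ancestral index.
#' @export
read_syntelogs <- function(path) {
  df <- read_tsv_df(path)
  need <- c("pair_id", "chrom", "ancestral_index", "status")
  stop_if(!all(need %in% names(df)),
          sprintf("syntelog table '%s' lacks columns: %s", path,
                  paste(setdiff(need, names(df)), collapse = ", ")))
  stop_if(!all(df$status %in% c("retained", "cc_only", "ee_only")),
          "syntelog status must be retained/cc_only/ee_only")
  df[order(df$chrom, df$ancestral_index), , drop = FALSE]
}

#' Write genotypes as VCFv4.2
#'
#' Minimal single-FORMAT (`GT`) diploid VCF with contig headers; missing
#' calls are `./.`.
#'
#' @param g a `genotype_matrix`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[g$gt + 1L], nrow = nrow(g$gt))
  gt_str[is.na(g$gt)] <- "./."
  chrom_max <- tapply(g$sites$pos, g$sites$chrom, max)
  header <- c("##fileformat=VCFv4.2",
              "##source=polykit",
              sprintf("##contig=<ID=%s,length=%d>", names(chrom_max),
                      as.integer(chrom_max)),
              paste0('##INFO=<ID=AA,Number=1,Type=String,',
                     'Description="Ancestral allele">'),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", g$samples), collapse = "\t"))
  body <- paste(g$sites$chrom, g$sites$pos,
                sprintf("%s_%d", g$sites$chrom, g$sites$pos),
                g$sites$ref, g$sites$alt, ".", "PASS",
                ifelse(is.na(g$sites$anc), ".",
                       paste0("AA=", g$sites$anc)),
                "GT",
                apply(gt_str, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a biallelic-SNP VCF into a genotype matrix
#'
#' Parses with `VariantAnnotation::readVcf`; multi-allelic records are
#' rejected.  An `AA=` INFO tag, if present, populates the ancestral-allele
#' column.
#'
#' @param path VCF file (plain or bgzipped).
#' @return a `genotype_matrix`.
#' @export
read_genotypes <- function(path) {
  stop_if(!file.exists(path), sprintf("no such file '%s'", path))
  vcf <- VariantAnnotation::readVcf(path, genome = "synthetic")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt_l <- VariantAnnotation::alt(vcf)
  stop_if(any(S4Vectors::elementNROWS(alt_l) != 1L),
          "only biallelic SNP records are supported")
  gt_chr <- VariantAnnotation::geno(vcf)$GT   # sites x samples
  code <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
            "1|0" = 1L, "1/1" = 2L, "1|1" = 2L, "./." = NA_integer_,
            "." = NA_integer_, ".|." = NA_integer_)
  stop_if(!all(gt_chr %in% names(code)),
          "unsupported genotype codes in VCF (diploid biallelic expected)")
  gt <- matrix(code[gt_chr], nrow = nrow(gt_chr))
  info <- VariantAnnotation::info(vcf)
  anc <- if ("AA" %in% names(info)) as.character(info$AA) else NA_character_
  sites <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(unlist(alt_l)),
    anc = anc, stringsAsFactors = FALSE)
  genotype_matrix(t(gt), sites, samples = colnames(gt_chr))
}

#' Write synthetic gene models as GFF3
#'
#' One `gene` feature per present syntelog member, on sequences named
#' `<chrom>_cc` / `<chrom>_ee`.
#'
#' @param syntelogs syntelog table with coordinate columns.
#' @param path output GFF3 path.
#' @return invisibly, `path`.
#' @export
write_gene_models <- function(syntelogs, path) {
  cc <- syntelogs[!is.na(syntelogs$gene_cc), , drop = FALSE]
  ee <- syntelogs[!is.na(syntelogs$gene_ee), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = c(paste0(cc$chrom, "_cc"), paste0(ee$chrom, "_ee")),
    ranges = IRanges::IRanges(start = c(cc$start_cc, ee$start_ee),
                              end = c(cc$end_cc, ee$end_ee)),
    strand = "+")
  gr$type <- "gene"
  gr$ID <- c(cc$gene_cc, ee$gene_ee)
  gr$Name <- gr$ID
  gr$source <- "polykit"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' @param path GFF3 file.
#' @return data.frame `gene_id, chrom, start, end` (1-based inclusive) of
#'   `gene`-type features.
#' @export
read_gene_models <- function(path) {
  stop_if(!file.exists(path), sprintf("no such file '%s'", path))
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  data.frame(gene_id = as.character(gr$ID),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Read a BED interval file
#'
#' @param path BED path (0-based half-open on disk).
#' @return data.frame `chrom, start, end` in 1-based inclusive coordinates,
#'   plus `name` when present.
#' @export
read_bed <- function(path) {
  stop_if(!file.exists(path), sprintf("no such file '%s'", path))
  gr <- rtracklayer::import(path, format = "bed")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  if (!is.null(gr$name)) out$name <- gr$name
  out
}

#' Write intervals as BED (0-based half-open)
#'
#' @param df data.frame with `chrom, start, end` in 1-based inclusive
#'   coordinates and optional `name`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bed <- function(df, path) {
  out <- data.frame(chrom = df$chrom, start = df$start - 1L, end = df$end)
  if (!is.null(df$name)) out$name <- df$name
  data.table::fwrite(out, path, sep = "\t", quote = FALSE,
                     col.names = FALSE)
  invisible(path)
}
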