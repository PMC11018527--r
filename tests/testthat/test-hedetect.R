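test_that("gene coverage averages per-base depth over gene bodies", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1_cc",
                      start = c(1, 101), end = c(100, 200))
  synt <- data.frame(pair_id = c("p1", "p2"), chrom = "chr1",
                     ancestral_index = 1:2, gene_cc = c("g1", "g2"),
                     gene_ee = c(NA, NA), status = c("cc_only", "cc_only"),
                     stringsAsFactors = FALSE)
  depth <- data.frame(chrom = "chr1_cc", start = c(1, 101, 151),
                      end = c(100, 150, 200), depth = c(40, 10, 30))
  prof <- gene_coverage_from_depth(depth, genes, synt)
  expect_equal(prof$cc_depth, c(40, 20))  # uniform 40; (10*50+30*50)/100
  expect_error(
    gene_coverage_from_depth(
      data.frame(chrom = "chrX", start = 1, end = 10, depth = 1),
      genes, synt),
    "coordinate mismatch")
})

test_that("coverage round-trips through per-base expansion", {
  cfg <- sim_config(seed = 31, n_genes_per_chrom = 40, n_chroms = 1,
                    n_accessions = 1, retention_base = 1,
                    retention_pericentromere = 1)
  land <- gen_syntelog_landscape(cfg)
  cov <- gen_coverage_profiles(land$syntelogs, cfg)
  prof0 <- cov$profiles$acc1
  # expand to constant per-gene depth intervals on both subgenome seqs
  synt <- land$syntelogs
  depth <- rbind(
    data.frame(chrom = "chr1_cc", start = synt$start_cc,
               end = synt$end_cc, depth = prof0$cc_depth),
    data.frame(chrom = "chr1_ee", start = synt$start_ee,
               end = synt$end_ee, depth = prof0$ee_depth))
  genes <- data.frame(
    gene_id = c(synt$gene_cc, synt$gene_ee),
    chrom = rep(c("chr1_cc", "chr1_ee"), each = nrow(synt)),
    start = c(synt$start_cc, synt$start_ee),
    end = c(synt$end_cc, synt$end_ee))
  prof <- gene_coverage_from_depth(depth, genes, synt)
  expect_equal(prof$cc_depth, as.numeric(prof0$cc_depth))
  expect_equal(prof$ee_depth, as.numeric(prof0$ee_depth))
})

test_that("windowed balance follows the printed formula and bounds", {
  expect_equal(windowed_balance(make_profile(30, 10))$A[1], 1)
  expect_equal(windowed_balance(make_profile(20, 20))$A[1], 0)
  expect_equal(windowed_balance(make_profile(20, 0))$A[1], 2)
  expect_equal(windowed_balance(make_profile(0, 20))$A[1], -2)
  # scaling invariance
  p1 <- make_profile(c(30, 45, 10, 70), c(10, 15, 50, 10))
  expect_equal(windowed_balance(p1, 2)$A,
               windowed_balance(transform(p1, cc_depth = cc_depth * 7,
                                          ee_depth = ee_depth * 7), 2)$A)
  # antisymmetry under cc <-> ee swap; |A| <= 2 always
  set.seed(32)
  p2 <- make_profile(rpois(60, 40), rpois(60, 25))
  swapped <- p2
  swapped$cc_depth <- p2$ee_depth; swapped$ee_depth <- p2$cc_depth
  expect_equal(windowed_balance(p2)$A, -windowed_balance(swapped)$A)
  expect_true(all(abs(windowed_balance(p2)$A) <= 2, na.rm = TRUE))
  # short chromosome -> single partial window
  tiny <- windowed_balance(make_profile(rep(10, 4), rep(10, 4)), 10)
  expect_equal(nrow(tiny), 1L)
  expect_equal(tiny$n_genes, 4L)
})

test_that("classify_balance implements the published thresholds", {
  expect_equal(as.character(classify_balance(c(1.8, 0.2, 1.0, -1.8, -1.0,
                                               0.5, -0.5, 1.5, NA))),
               c("CC_hom", "balanced", "CC_biased", "EE_hom", "EE_biased",
                 "CC_biased", "EE_biased", "CC_biased", "no_data"))
})

test_that("segmentation recovers a planted homozygous block and is idempotent", {
  A <- c(rep(0, 30), rep(1.9, 20), rep(0, 50))
  tr <- data.frame(chrom = "chr1", window_start = seq_along(A),
                   center_index = seq_along(A), window_end = seq_along(A),
                   mean_cc = 40, mean_ee = 40, A = A, n_genes = 1)
  class(tr) <- c("balance_track", "data.frame")
  attr(tr, "window_genes") <- 1L
  seg <- segment_dosage(tr, min_windows = 5)
  hom <- seg[seg$dosage_class == "CC_hom", ]
  expect_equal(nrow(hom), 1L)
  expect_equal(hom$start_gene, 31)
  expect_equal(hom$end_gene, 50)
  # all balanced -> no non-balanced segments
  tr0 <- tr; tr0$A <- 0
  expect_equal(sum(segment_dosage(tr0, 5)$dosage_class != "balanced"), 0L)
  # idempotence: re-expanding segments and re-segmenting is a fixed point
  mid_A <- c(EE_hom = -1.9, EE_biased = -1, balanced = 0, CC_biased = 1,
             CC_hom = 1.9)
  expand <- do.call(rbind, lapply(seq_len(nrow(seg)), function(k)
    data.frame(chrom = seg$chrom[k],
               window_start = seg$start_gene[k]:seg$end_gene[k],
               center_index = seg$start_gene[k]:seg$end_gene[k],
               window_end = seg$start_gene[k]:seg$end_gene[k],
               mean_cc = 40, mean_ee = 40,
               A = unname(mid_A[seg$dosage_class[k]]), n_genes = 1)))
  class(expand) <- c("balance_track", "data.frame")
  attr(expand, "window_genes") <- 1L
  seg2 <- segment_dosage(expand, min_windows = 5)
  expect_equal(seg2[, c("chrom", "start_gene", "end_gene", "dosage_class")],
               as.data.frame(seg)[, c("chrom", "start_gene", "end_gene",
                                      "dosage_class")],
               ignore_attr = TRUE)
})

test_that("test_3to1 matches hand arithmetic and the chi-squared oracle", {
  t0 <- test_3to1(75, 25)
  expect_equal(t0$chi2, 0)
  expect_equal(t0$p_raw, 1)
  t1 <- test_3to1(90, 10)
  expect_equal(t1$chi2, 12)               # 225/75 + 225/25
  expect_equal(t1$p_raw, oracle_chisq1_p(12), tolerance = 1e-10)
  expect_equal(t1$p_raw, 5.32e-4, tolerance = 1e-2)
  # reversed bias: chi2 = 2500/75 + 2500/25 = 400/3, flagged EE-ward
  t2 <- test_3to1(25, 75)
  expect_equal(t2$chi2, 400 / 3)
  expect_equal(t2$direction, "EE-ward")
  expect_lt(t2$p_bonferroni, 0.0005)
  # Bonferroni contract
  t3 <- test_3to1(90, 10, n_tests = 50)
  expect_equal(t3$p_bonferroni, min(1, t3$p_raw * 50))
  expect_error(test_3to1(0, 0), "zero total")
})

test_that("chi-squared p matches the normal-tail oracle to 6 digits", {
  for (chi2 in c(0.5, 1, 3.84, 12, 25, 50, 99))
    expect_equal(pchisq(chi2, 1, lower.tail = FALSE),
                 oracle_chisq1_p(chi2), tolerance = 1e-7)
})

test_that("shared/private segment voting matches the spec example", {
  segs <- do.call(rbind, lapply(1:5, function(i)
    data.frame(accession = paste0("acc", i), chrom = "chr1",
               start_gene = 100, end_gene = if (i == 5) 200 else 150,
               dosage_class = "CC_hom", mean_A = 1.9, n_windows = 10,
               stringsAsFactors = FALSE)))
  res <- shared_segments(segs, min_share = 2)
  expect_equal(res$shared$start_gene, 100)
  expect_equal(res$shared$end_gene, 150)
  expect_equal(res$private$start_gene, 151)
  expect_equal(res$private$end_gene, 200)
  expect_equal(res$private$accessions, "acc5")
  # identical everywhere -> all shared, none private
  segs2 <- segs; segs2$end_gene <- 150
  res2 <- shared_segments(segs2, min_share = 5)
  expect_equal(res2$shared$end_gene, 150)
  expect_equal(nrow(res2$private), 0L)
  # disjoint segments, min_share 2 -> nothing shared
  segs3 <- segs[1:2, ]
  segs3$start_gene <- c(10, 300); segs3$end_gene <- c(50, 340)
  res3 <- shared_segments(segs3, min_share = 2)
  expect_equal(nrow(res3$shared), 0L)
  expect_equal(nrow(res3$private), 2L)
})

test_that("filter_he_pairs removes exactly the overlapped pairs", {
  synt <- data.frame(pair_id = sprintf("p%02d", 1:50), chrom = "chr1",
                     ancestral_index = 1:50, status = "retained",
                     stringsAsFactors = FALSE)
  seg <- data.frame(accession = "acc1", chrom = "chr1", start_gene = 11,
                    end_gene = 20, dosage_class = "CC_hom", mean_A = 1.9,
                    n_windows = 10, stringsAsFactors = FALSE)
  out <- filter_he_pairs(synt, seg)
  expect_equal(nrow(out$removed), 10L)
  expect_true(all(out$removed$ancestral_index %in% 11:20))
  expect_equal(nrow(out$pairs), 40L)
  # brute-force overlap count oracle on random segments
  set.seed(33)
  segs <- do.call(rbind, lapply(1:6, function(i) {
    s <- sample(1:45, 1)
    data.frame(accession = sample(paste0("acc", 1:3), 1), chrom = "chr1",
               start_gene = s, end_gene = s + sample(0:5, 1),
               dosage_class = sample(c("CC_biased", "EE_hom"), 1),
               mean_A = 1, n_windows = 3, stringsAsFactors = FALSE)
  }))
  out2 <- filter_he_pairs(synt, segs)
  brute <- sum(vapply(1:50, function(i)
    any(segs$start_gene <= i & segs$end_gene >= i), logical(1)))
  expect_equal(nrow(out2$removed), brute)
  # no segments -> identity
  out3 <- filter_he_pairs(synt, seg[0, ])
  expect_equal(out3$pairs, synt)
})

test_that("he_direction_summary recovers planted direction ratios", {
  mk <- function(acc, class, len, start)
    data.frame(accession = acc, chrom = "chr1", start_gene = start,
               end_gene = start + len - 1L, dosage_class = class,
               mean_A = 0, n_windows = len, stringsAsFactors = FALSE)
  only_cc <- he_direction_summary(mk("a", "CC_hom", 40, 1))
  expect_equal(only_cc$ratio, Inf)
  expect_equal(only_cc$ee_ward_genes, 0)
  even <- he_direction_summary(rbind(mk("a", "CC_hom", 500, 1),
                                     mk("a", "EE_biased", 500, 1000)))
  expect_gte(even$ratio, 0.9); expect_lte(even$ratio, 1.1)
  three <- he_direction_summary(rbind(mk("a", "CC_hom", 900, 1),
                                      mk("a", "EE_hom", 300, 2000)))
  expect_gte(three$ratio, 2.5); expect_lte(three$ratio, 3.5)
})

test_that("end-to-end HE recovery on planted segments across accessions", {
  # stated world: 10 accessions at 40x, planted 3:1 / 4:0 (and EE-ward)
  # segments of 25-60 genes; window 10, min_windows 5
  plant <- do.call(rbind, lapply(1:10, function(i) {
    data.frame(accession = paste0("acc", i),
               chrom = c("chr1", "chr1", "chr2"),
               start_gene = c(101, 301, 201),
               end_gene = c(125, 360, 240),
               dosage = c("3:1", "4:0", if (i <= 5) "1:3" else "0:4"),
               stringsAsFactors = FALSE)
  }))
  cfg <- sim_config(seed = 34, n_genes_per_chrom = 600, n_chroms = 2,
                    n_accessions = 10, depth_mean = 40,
                    retention_base = 1, retention_pericentromere = 1,
                    he_segments = plant)
  land <- gen_syntelog_landscape(cfg)
  cov <- gen_coverage_profiles(land$syntelogs, cfg)
  class_of <- c("4:0" = "CC_hom", "3:1" = "CC_biased",
                "1:3" = "EE_biased", "0:4" = "EE_hom")
  tp <- fp <- fn <- 0; max_boundary <- 0
  for (acc in names(cov$profiles)) {
    prof <- cov$profiles[[acc]]
    attr(prof, "accession") <- acc
    seg <- segment_dosage(windowed_balance(prof, 10), 5)
    seg <- seg[seg$dosage_class != "balanced", , drop = FALSE]
    truth <- plant[plant$accession == acc, ]
    truth$class <- class_of[truth$dosage]
    for (chrom in c("chr1", "chr2")) {
      tgenes <- list(); pgenes <- list()
      for (cl in unique(class_of)) {
        tt <- truth[truth$chrom == chrom & truth$class == cl, ]
        pp <- seg[seg$chrom == chrom & seg$dosage_class == cl, ]
        tset <- unlist(lapply(seq_len(nrow(tt)), function(k)
          tt$start_gene[k]:tt$end_gene[k]))
        pset <- unlist(lapply(seq_len(nrow(pp)), function(k)
          pp$start_gene[k]:pp$end_gene[k]))
        tp <- tp + length(intersect(tset, pset))
        fp <- fp + length(setdiff(pset, tset))
        fn <- fn + length(setdiff(tset, pset))
        if (nrow(tt) == 1L && nrow(pp) == 1L)
          max_boundary <- max(max_boundary,
                              abs(pp$start_gene - tt$start_gene),
                              abs(pp$end_gene - tt$end_gene))
      }
    }
  }
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  expect_gte(precision, 0.9)
  expect_gte(recall, 0.9)
  expect_lte(max_boundary, 10)  # one window
})
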