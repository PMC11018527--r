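test_that("windowed pi: hand arithmetic and pairwise oracle", {
  # one site, p = 0.5 among 4 haplotypes, 1000-bp window
  gt <- matrix(c(1L, 1L), nrow = 2,
               dimnames = list(c("a", "b"), NULL))
  g <- genotype_matrix(gt, data.frame(chrom = "chr1", pos = 500,
                                      ref = "A", alt = "T"))
  pw <- windowed_pi(g, window_bp = 1000, step_bp = 1000)
  expect_equal(pw$windows$value, (2 * 0.25 * 4 / 3) / 1000)
  # monomorphic window -> 0
  g0 <- genotype_matrix(matrix(0L, 2, 1, dimnames = list(c("a", "b"), NULL)),
                        data.frame(chrom = "chr1", pos = 500,
                                   ref = "A", alt = "T"))
  expect_equal(windowed_pi(g0, window_bp = 1000)$windows$value, 0)
  # brute-force all-pairs oracle on random complete matrices
  for (seed in 41:43) {
    g <- random_gmat(seed, n_samples = 8, n_sites = 50)
    pw <- windowed_pi(g, window_bp = 250000, step_bp = 250000)
    span <- pw$windows$end - pw$windows$start + 1
    oracle <- sum(oracle_pi_sites(g$gt)) / sum(span)
    expect_equal(sum(pw$windows$value * span) / sum(span), oracle,
                 tolerance = 1e-12)
  }
})

test_that("Tajima's D: frozen hand value and independent oracle", {
  # n = 4 haplotypes, 3 singleton sites -> khat = 1.5, S = 3
  gt <- matrix(c(1L, 0L, 1L, 0L, 1L, 0L), nrow = 2,
               dimnames = list(c("a", "b"), NULL))
  d <- tajima_d(gt)
  # hand-evaluated: a1 = 11/6, e1 = 0.0055096..., e2 = 0.0026899...
  expect_equal(d, -0.7544, tolerance = 1e-3)
  expect_equal(d, oracle_tajima_d(gt), tolerance = 1e-12)
  # zero numerator: khat == S/a1 gives exactly 0 (engineered via oracle)
  for (seed in 44:46) {
    g <- random_gmat(seed, n_samples = 6, n_sites = 40)
    expect_equal(tajima_d(g$gt), oracle_tajima_d(g$gt), tolerance = 1e-10)
  }
  expect_error(tajima_constants(3), ">= 4")
})

test_that("windowed Tajima's D equals the whole-matrix value per window", {
  g <- random_gmat(47, n_samples = 10, n_sites = 60)
  dw <- windowed_tajima_d(g, window_bp = 1e6)
  expect_equal(dw$windows$value[1], tajima_d(g$gt), tolerance = 1e-12)
})

test_that("per-site WC theta matches the textbook oracle", {
  # fixed difference -> theta = 1
  ga <- matrix(2L, 5, 1); gb <- matrix(0L, 5, 1)
  expect_equal(wc_fst_site(ga, gb)$theta, 1)
  # identical all-heterozygote populations -> exactly 0
  g_eq <- matrix(c(1L, 1L, 1L, 1L), 4, 1)
  expect_lt(abs(wc_fst_site(g_eq, g_eq)$theta), 1e-12)
  # HWE counts at p = 0.2 / 0.8 (25 diploids each; counts 16/8/1)
  g1 <- matrix(rep(c(0L, 1L, 2L), c(16, 8, 1)), ncol = 1)
  g2 <- matrix(rep(c(0L, 1L, 2L), c(1, 8, 16)), ncol = 1)
  th <- wc_fst_site(g1, g2)$theta
  expect_equal(th, oracle_wc_theta(g1[, 1], g2[, 1]), tolerance = 1e-12)
  expect_equal(th, 0.5196, tolerance = 1e-3)   # hand-evaluated a, b, c
  # random sites, incl. missing data
  set.seed(48)
  for (rep in 1:25) {
    n1 <- sample(4:10, 1); n2 <- sample(4:10, 1)
    s1 <- rbinom(n1, 2, runif(1, 0.1, 0.9))
    s2 <- rbinom(n2, 2, runif(1, 0.1, 0.9))
    if (rep > 15) s1[sample(n1, 1)] <- NA
    got <- wc_fst_site(matrix(s1, ncol = 1), matrix(s2, ncol = 1))$theta
    want <- oracle_wc_theta(s1, s2)
    if (is.na(want)) expect_true(is.na(got)) else
      expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("gene_fst averages site theta over gene spans with flanks", {
  set.seed(49)
  n <- 30
  gt <- rbind(matrix(rbinom(8 * n, 2, 0.2), nrow = 8),
              matrix(rbinom(8 * n, 2, 0.8), nrow = 8))
  rownames(gt) <- c(paste0("a", 1:8), paste0("b", 1:8))
  sites <- data.frame(chrom = "chr1", pos = seq(1000, by = 1000,
                                                length.out = n),
                      ref = "A", alt = "T")
  g <- genotype_matrix(gt, sites)
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 5000,
                      end = 10000)
  res <- gene_fst(g, paste0("a", 1:8), paste0("b", 1:8), genes,
                  flank_bp = 2000)
  inw <- sites$pos >= 3000 & sites$pos <= 12000
  th <- wc_fst_site(gt[1:8, , drop = FALSE],
                    gt[9:16, , drop = FALSE])$theta[inw]
  expect_equal(res$fst, mean(th, na.rm = TRUE), tolerance = 1e-12)
  expect_equal(res$n_sites, sum(!is.na(th)))
  # no informative sites -> NA
  far <- data.frame(gene_id = "g2", chrom = "chr1", start = 900000,
                    end = 901000)
  expect_true(is.na(gene_fst(g, paste0("a", 1:8), paste0("b", 1:8),
                             far)$fst))
})

test_that("snp_filter applies the published thresholds and is logged", {
  gt <- matrix(0L, nrow = 10, ncol = 5,
               dimnames = list(sprintf("s%02d", 1:10), NULL))
  gt[, 2] <- c(rep(NA, 5), rep(0L, 5))          # 50% missing -> removed
  gt[2, 3] <- 1L                                # MAF 0.05 -> removed
  gt[, 4] <- rep(c(0L, 2L), 5)                  # MAF 0.5, kept
  gt[, 5] <- rep(c(0L, 2L), 5)                  # r2 = 1 with site 4
  gt[, 1] <- c(rep(1L, 2), rep(0L, 8))          # control het at site 1
  sites <- data.frame(chrom = "chr1", pos = (1:5) * 100,
                      ref = "A", alt = "T")
  g <- genotype_matrix(gt, sites)
  out <- snp_filter(g, max_missing = 0.4, min_maf = 0.10,
                    het_in_control = "s01",
                    ld_prune = list(window = 10, step = 10, r2 = 0.4))
  expect_equal(out$genotypes$sites$pos, 400)  # earlier of the r2=1 pair
  expect_equal(out$log$removed[out$log$rule == "max_missing"], 1L)
  expect_equal(out$log$removed[out$log$rule == "min_maf"], 1L)
  expect_equal(out$log$removed[out$log$rule == "het_in_control"], 1L)
  expect_equal(out$log$removed[out$log$rule == "ld_prune"], 1L)
  expect_error(snp_filter(g, het_in_control = "nope"), "absent")
})

test_that("polarize_ancestral majority vote and tie convention", {
  # outgroup haplotypes A,A,A,G -> ancestral A (one het outgroup)
  gt <- matrix(c(0L, 1L, 1L, 1L), nrow = 4,
               dimnames = list(c("o1", "o2", "x1", "x2"), NULL))
  g <- genotype_matrix(gt, data.frame(chrom = "chr1", pos = 100,
                                      ref = "A", alt = "G"))
  gp <- polarize_ancestral(g, c("o1", "o2"))
  expect_equal(gp$sites$anc, "A")
  # 2 vs 2 tie -> unresolved
  gt2 <- matrix(c(1L, 1L, 0L, 0L), nrow = 4,
                dimnames = list(c("o1", "o2", "x1", "x2"), NULL))
  g2 <- genotype_matrix(gt2, data.frame(chrom = "chr1", pos = 100,
                                        ref = "A", alt = "G"))
  expect_true(is.na(polarize_ancestral(g2, c("o1", "o2"))$sites$anc))
})

test_that("sfs counts, folds and conserves sites", {
  # 5 diploids; 3 singleton sites, 1 doubleton
  gt <- matrix(0L, nrow = 5, ncol = 4,
               dimnames = list(paste0("s", 1:5), NULL))
  gt[1, 1:3] <- 1L
  gt[2, 4] <- 1L; gt[3, 4] <- 1L
  sites <- data.frame(chrom = "chr1", pos = (1:4) * 10, ref = "A",
                      alt = "T", anc = "A")
  g <- genotype_matrix(gt, sites)
  sp <- sfs(g, polarized = TRUE)
  expect_equal(unname(sp$spectrum), c(3, 1, 0, 0, 0, 0, 0, 0, 0))
  # folding identity
  spf <- sfs(g, polarized = FALSE)
  expect_equal(fold_sfs(sp$spectrum), spf$spectrum)
  # conservation with missing data and unresolved ancestry
  g2 <- gen_genotypes(sim_config(seed = 50, n_sites = 800, n_per_pop = 6,
                                 missing_rate = 0.1,
                                 outgroup_error = 0.2))
  gg <- polarize_ancestral(g2$genotypes,
                           g2$popmap$sample[grepl("outgroup",
                                                  g2$popmap$population)])
  foc <- g2$popmap$sample[g2$popmap$population %in% c("wild", "cultivar")]
  su <- sfs(gg, foc, polarized = TRUE)
  expect_equal(sum(su$spectrum) + su$excluded, su$n_segregating)
})

test_that("neutral generator yields a 1/i spectrum (GOF)", {
  cfg <- sim_config(seed = 51, pop_split_fst = 0, n_sites = 10000,
                    n_per_pop = 10)
  gen <- gen_genotypes(cfg)
  gg <- polarize_ancestral(gen$genotypes,
                           gen$popmap$sample[grepl("outgroup",
                                                   gen$popmap$population)])
  foc <- gen$popmap$sample[gen$popmap$population %in% c("wild", "cultivar")]
  sp <- sfs(gg, foc, polarized = TRUE)
  k <- length(sp$spectrum)
  p_exp <- (1 / seq_len(k)) / sum(1 / seq_len(k))
  expected <- sum(sp$spectrum) * p_exp
  chi2 <- sum((sp$spectrum - expected)^2 / expected)
  expect_gt(pchisq(chi2, df = k - 1, lower.tail = FALSE), 0.01)
})

test_that("F3 trivial values, jackknife contract and admixture signal", {
  g <- random_gmat(52, n_samples = 9, n_sites = 50)
  s <- g$samples
  # target == source_a -> exactly 0 (raw product form)
  f0 <- f3_statistic(g, s[1:3], s[1:3], s[4:6], block_bp = 1e5,
                     het_correction = FALSE)
  expect_equal(f0$estimate, 0)
  # t = 0.5, a = 0, b = 1 everywhere -> -0.25
  gt <- rbind(t1 = rep(1L, 10), a1 = rep(0L, 10), b1 = rep(2L, 10))
  gx <- genotype_matrix(gt, data.frame(chrom = "chr1",
                                       pos = seq(1e4, 1e6, length.out = 10),
                                       ref = "A", alt = "T"))
  f1 <- f3_statistic(gx, "t1", "a1", "b1", block_bp = 2e5,
                     het_correction = FALSE)
  expect_equal(f1$estimate, -0.25)
  # identical per-block terms: SE 0, Z flagged undefined
  expect_equal(f1$se, 0)
  expect_true(is.na(f1$Z))
  expect_equal(f1$n_blocks, 5)
  # fewer than 2 blocks -> flagged, no SE
  f2 <- f3_statistic(gx, "t1", "a1", "b1", block_bp = 1e7,
                     het_correction = FALSE)
  expect_true(is.na(f2$se) && is.na(f2$Z))
  # admixed target -> strongly negative Z
  cfg <- sim_config(seed = 53, pop_split_fst = 0.5, n_sites = 5000,
                    n_per_pop = 15)
  gen <- gen_genotypes(cfg, n_hybrid = 10)
  pm <- gen$popmap
  fa <- f3_statistic(gen$genotypes,
                     pm$sample[pm$population == "hybrid"],
                     pm$sample[pm$population == "wild"],
                     pm$sample[pm$population == "cultivar"],
                     block_bp = 50000)
  expect_lt(fa$Z, -3)
  # unadmixed target (wild split) -> no admixture signal
  wi <- pm$sample[pm$population == "wild"]
  fn <- f3_statistic(gen$genotypes, wi[1:7], wi[8:15],
                     pm$sample[pm$population == "cultivar"],
                     block_bp = 50000)
  expect_gte(fn$Z, -1)
})

test_that("z_fdr_adjust matches the hand BH + normal-quantile oracle", {
  expect_equal(z_fdr_adjust(-2.5), -2.5)           # m = 1 identity
  expect_equal(z_fdr_adjust(rep(-1.7, 4)), rep(-1.7, 4))
  z <- c(-3, -2)
  za <- z_fdr_adjust(z)
  expect_equal(za, qnorm(oracle_bh(pnorm(z))), tolerance = 1e-12)
  expect_equal(za[1], qnorm(2 * pnorm(-3)), tolerance = 1e-12)
  expect_equal(za[1], -2.78, tolerance = 1e-2)
  expect_equal(za[2], -2, tolerance = 1e-12)
  # monotone: order preserved, adjusted never more extreme
  set.seed(54)
  zr <- rnorm(60, -1, 2)
  zar <- z_fdr_adjust(zr)
  expect_true(all(diff(zar[order(zr)]) >= -1e-12))  # monotone (with ties)
  expect_true(all(zar >= zr - 1e-12))
  expect_error(z_fdr_adjust(numeric(0)), "empty")
})

test_that("introgression scan: trivial D values and window behavior", {
  # p2 == p3 polymorphic, p1 == outgroup == 0 -> D = 1
  gt <- rbind(p1 = rep(0L, 20), p2 = rep(1L, 20), p3 = rep(1L, 20),
              o1 = rep(0L, 20))
  g <- genotype_matrix(gt, data.frame(chrom = "chr1",
                                      pos = seq(500, 19500, length.out = 20),
                                      ref = "A", alt = "T"))
  sc <- introgression_scan(g, "p1", "p2", "p3", "o1", window_bp = 20000)
  expect_equal(sc$windows$value, 1)
  # symmetric ABBA/BABA -> D = 0
  gt2 <- rbind(p1 = rep(c(2L, 0L), 10), p2 = rep(c(0L, 2L), 10),
               p3 = rep(1L, 20), o1 = rep(0L, 20))
  g2 <- genotype_matrix(gt2, g$sites)
  sc2 <- introgression_scan(g2, "p1", "p2", "p3", "o1", window_bp = 20000)
  expect_equal(sc2$windows$value, 0)
  expect_equal(sc2$genome$estimate, 0)
})

test_that("planted donor window is recovered by the D scan", {
  rec <- vapply(55:59, function(s) {
    cfg <- sim_config(seed = s, pop_split_fst = 0.5, n_sites = 6000,
                      n_per_pop = 24, n_genes_per_chrom = 400,
                      n_chroms = 1)
    gen <- gen_genotypes(cfg)
    wi <- paste0("wild", sprintf("%02d", 1:24))
    cu <- paste0("cult", sprintf("%02d", 1:24))
    og <- paste0("outcc", sprintf("%02d", 1:2))
    gt <- gen$genotypes$gt
    w0 <- 300001L; w1 <- 320000L
    inw <- which(gen$genotypes$sites$pos >= w0 &
                   gen$genotypes$sites$pos <= w1)
    p2 <- wi[13:24]
    gt[p2, inw] <- gt[cu[1:12], inw]   # haplotype copy = introgression
    g2 <- genotype_matrix(gt, gen$genotypes$sites)
    sc <- introgression_scan(g2, wi[1:12], p2, cu, og, window_bp = 20000)
    v <- sc$windows$value
    hit <- which(sc$windows$start == w0)
    v[hit] > quantile(v[-hit], 0.99, na.rm = TRUE)
  }, logical(1))
  expect_gte(mean(rec), 0.8)
  # f_d variant runs and is bounded in the same world
  cfg <- sim_config(seed = 60, pop_split_fst = 0.5, n_sites = 3000,
                    n_per_pop = 12, n_genes_per_chrom = 400, n_chroms = 1)
  gen <- gen_genotypes(cfg)
  wi <- paste0("wild", sprintf("%02d", 1:12))
  cu <- paste0("cult", sprintf("%02d", 1:12))
  og <- paste0("outcc", sprintf("%02d", 1:2))
  fd <- introgression_scan(gen$genotypes, wi[1:6], wi[7:12], cu, og,
                           window_bp = 20000, statistic = "f_d")
  expect_true(is.finite(fd$genome$estimate))
})

test_that("generation-time scaling matches the published arithmetic", {
  expect_equal(generations_to_years(1)$years, 21)
  out <- generations_to_years(1450)
  expect_equal(out$years, 30450)
  expect_equal(out$ka, 30.5)
  expect_equal(years_to_generations(30450), 1450)
  expect_error(generations_to_years(0), "> 0")
})
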