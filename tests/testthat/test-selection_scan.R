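# Site filters, component-frequency fitting, the likelihood-ratio scan,
# thresholds, frequency profiles, gene-context annotation and sequence
# context.

test_that("site filters enforce zero missingness and the inclusive 5% MAF", {
  G <- rbind(
    site_maf05 = c(1L, rep(0L, 9L)),            # 1/20 alleles = 0.05
    site_miss = c(NA, rep(1L, 9L)),             # one missing genotype
    site_mono = rep(0L, 10L),                   # monomorphic
    site_common = rep(1L, 10L)
  )
  geno <- sv_genotypes(G)
  kept <- site_filters(geno)
  expect_setequal(kept$sites$site, c("site_maf05", "site_common"))
  # MAF just under 5% is dropped
  G2 <- rbind(low = c(1L, rep(0L, 10L))) # 1/22 = 0.045
  expect_equal(nrow(site_filters(sv_genotypes(G2))$G), 0L)
})

test_that("component frequency fitting hits boundary MLEs and the grid oracle", {
  Q <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5))
  expect_equal(as.numeric(fit_component_frequencies(c(2, 2, 2), Q)), c(1, 1))
  expect_equal(as.numeric(fit_component_frequencies(c(0, 0, 0), Q)), c(0, 0))
  # K=2 toy: dosages (2, 0, 1) under one-hot + 50/50 rows; grid-search
  # oracle at 1e-3 resolution puts the MLE at F = (1, 0)
  f <- fit_component_frequencies(c(2, 0, 1), Q)
  expect_equal(as.numeric(f), c(1, 0), tolerance = 1e-3)
  # the fitted likelihood is within tolerance of the frozen grid optimum
  expect_equal(attr(f, "loglik"), -2 * log(2), tolerance = 1e-6)
})

test_that("the LRT is zero for nested-coinciding models and matches a grid oracle", {
  # K = 1: the two models coincide
  Q1 <- matrix(1, 20, 1)
  g <- rbinom(20, 2, 0.4)
  expect_equal(scan_statistic(g, Q1, 1)$lrt, 0, tolerance = 1e-6)
  # all individuals share one dosage
  Q <- rbind(diag(2)[rep(1:2, each = 10), ])
  expect_equal(scan_statistic(rep(1L, 20), Q, 1)$lrt, 0, tolerance = 1e-6)
  # two discrete subpopulations at frequencies 0.9 / 0.1, n = 100
  set.seed(401)
  Q2 <- diag(2)[rep(1:2, each = 50), ]
  g2 <- c(rbinom(50, 2, 0.9), rbinom(50, 2, 0.1))
  got <- scan_statistic(g2, Q2, 1)
  # 2-parameter grid-search oracle; with one-hot rows the likelihood
  # factorizes over the two subpopulations, so each frequency is optimised
  # on its own grid
  grid <- seq(1e-4, 1 - 1e-4, by = 1e-3)
  part_ll <- function(f, g) sum(g) * log(f) + sum(2 - g) * log(1 - f)
  ll_alt <- max(vapply(grid, part_ll, 1, g = g2[1:50])) +
    max(vapply(grid, part_ll, 1, g = g2[51:100]))
  f0 <- mean(g2) / 2
  ll0 <- sum(g2 * log(f0) + (2 - g2) * log(1 - f0))
  expect_equal(got$lrt, 2 * (ll_alt - ll0), tolerance = 1e-3)
  # degenerate: a component with zero total weight is reported missing
  Q0 <- cbind(rep(1, 20), 0)
  expect_true(is.na(scan_statistic(rbinom(20, 2, 0.5), Q0, 2)$lrt))
})

test_that("the LRT is invariant under relabeling of non-focal components", {
  set.seed(402)
  n <- 60
  Q <- matrix(rgamma(n * 3, 1), n, 3)
  Q <- Q / rowSums(Q)
  g <- rbinom(n, 2, pmin(pmax(Q %*% c(0.8, 0.2, 0.4), 0), 1))
  base <- scan_statistic(g, Q, 1)$lrt
  swapped <- scan_statistic(g, Q[, c(1, 3, 2)], 1)$lrt
  expect_equal(swapped, base, tolerance = 1e-6)
})

test_that("Bonferroni thresholds reproduce the printed and trivial cases", {
  expect_equal(signif(bonferroni_threshold(299115), 3), 1.67e-7)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(20), 2.5e-3)
  expect_error(bonferroni_threshold(0))
})

test_that("the scan driver flags hits at strict and relaxed thresholds", {
  cfg <- sim_config(seed = 403,
                    cohort = list(N = 150, K = 2, n_sites = 30, n_null = 25,
                                  n_selected = 5, shift = 0.5,
                                  one_hot = TRUE))
  sg <- simulate_admixed_genotypes(cfg)
  scan <- selection_scan(site_filters(sg$geno), sg$Q)
  expect_s3_class(scan, "sv_scan")
  res <- tidy(scan)
  expect_true(all(res$lrt >= 0, na.rm = TRUE))
  expect_true(all(res$p_value > 0 & res$p_value <= 1, na.rm = TRUE))
  gl <- glance(scan)
  expect_equal(gl$strict_threshold, 0.05 / gl$n_tests)
  expect_true(gl$n_relaxed >= gl$n_strict)
  # the shifted sites are the ones that light up at the relaxed threshold
  sel_sites <- sg$truth$site[sg$truth$type == "selected"]
  hit_sites <- unique(res$site[res$relaxed])
  expect_true(length(intersect(hit_sites, sel_sites)) >= 4L)
})

test_that("null p-values are approximately uniform over 10,000 sites", {
  cfg <- sim_config(seed = 409,
                    cohort = list(N = 400L, K = 3L, n_sites = 10000L,
                                  n_null = 10000L))
  sg <- simulate_admixed_genotypes(cfg)
  p <- vapply(seq_len(10000), function(s) {
    scan_statistic(sg$geno$G[s, ], sg$Q, 1L)$p_value
  }, 1)
  ks <- suppressWarnings(stats::ks.test(p, "punif")$statistic)
  expect_lt(ks, 0.02)
})

test_that("allele frequency profiles match hand tallies", {
  G <- rbind(s1 = c(2L, 2L, 1L, 1L, 0L, 0L, 0L, 1L),
             s2 = rep(0L, 8))
  labels <- c(rep("popA", 4), rep("popB", 3), "popC")
  prof <- allele_frequency_profiles(sv_genotypes(G), labels = labels)
  expect_equal(prof$alt_freq[prof$site == "s1" & prof$population == "popA"],
               0.75)
  expect_equal(prof$alt_freq[prof$site == "s1" & prof$population == "popB"],
               0)
  expect_equal(prof$alt_freq[prof$site == "s1" & prof$population == "popC"],
               0.5)
  expect_true(all(prof$alt_freq[prof$site == "s2"] == 0))
})

test_that("genotype and Q-matrix readers reproduce the written matrices", {
  cfg <- sim_config(seed = 405,
                    cohort = list(N = 12L, K = 3L, n_sites = 8L))
  sg <- simulate_admixed_genotypes(cfg)
  sim <- make_reference_and_library(sim_config(seed = 405,
                                               ref_length = 10000L))
  dir <- withr::local_tempdir()
  write_simulation(sim, cohort = sg, dir = dir)
  Q <- read_q_matrix(file.path(dir, "q_matrix.tsv"))
  expect_equal(unname(Q), unname(sg$Q), tolerance = 1e-12)
  geno <- read_dosage_tsv(file.path(dir, "dosages.tsv"))
  expect_equal(unname(geno$G), unname(sg$geno$G))
  # GT-field VCF parsing into dosages
  tf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "i1", "i2", "i3", sep = "\t"),
    paste("chr1", "100", ".", "N", "<DEL>", ".", "PASS",
          "SVTYPE=DEL;END=199", "GT", "0/1", "1|1", "./.", sep = "\t"),
    paste("chr1", "900", ".", "N", "<INS>", ".", "PASS", "SVTYPE=INS;SVLEN=60",
          "GT", "0/0", "0/1", "1/1", sep = "\t")
  ), tf)
  gv <- read_genotype_vcf(tf)
  expect_equal(unname(gv$G), rbind(c(1L, 2L, NA), c(0L, 1L, 2L)))
})

test_that("gene-context labels follow exon overlap and full ablation rules", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    paste("chr1", "toy", "gene", "1000", "5000", ".", "+", ".",
          "ID=GENE1", sep = "\t"),
    paste("chr1", "toy", "exon", "1000", "1200", ".", "+", ".",
          "Parent=GENE1", sep = "\t"),
    paste("chr1", "toy", "exon", "4800", "5000", ".", "+", ".",
          "Parent=GENE1", sep = "\t"),
    paste("chr1", "toy", "gene", "20000", "21000", ".", "-", ".",
          "ID=GENE2", sep = "\t"),
    paste("chr1", "toy", "exon", "20000", "21000", ".", "-", ".",
          "Parent=GENE2", sep = "\t")
  ), gff)
  gm <- read_gene_model(gff)
  hits <- tibble::tibble(
    chrom = "chr1",
    pos = c(2000L, 1200L, 900L, 19000L, 8000L),
    end = c(2500L, 1300L, 6000L, 22000L, 8100L)
  )
  out <- annotate_hits_genes(hits, gm)
  expect_equal(out$context,
               c("intronic", # fully inside the intron
                 "exonic",   # overlaps exon 1 by exactly 1 bp
                 "exonic",   # spans the whole gene: feature ablation
                 "exonic",   # spans GENE2 entirely
                 "intergenic"))
  expect_equal(out$genes[1], "GENE1")
})

test_that("sequence context flags low-complexity alleles and clustered insertions", {
  # a pure dinucleotide repeat is fully tandem
  ac <- strrep("AC", 100)
  expect_equal(low_complexity_fraction(ac), 1)
  ctx <- callset_context(sv_records("chr1", 100L, "INS", seq = ac))
  expect_true(ctx$lc_flag)
  # random sequence stays below the 70% flag
  set.seed(404)
  rnd <- callset_context(sv_records("chr1", 100L, "INS", seq = rand_seq(500)))
  expect_false(rnd$lc_flag)
  # neighbour flags at <= 25 bp
  near <- callset_context(sv_records("chr1", c(100L, 110L), "INS",
                                     seq = c(rand_seq(60), rand_seq(60))))
  expect_true(all(near$neighbor_flag))
  far <- callset_context(sv_records("chr1", c(100L, 130L), "INS",
                                    seq = c(rand_seq(60), rand_seq(60))))
  expect_false(any(far$neighbor_flag))
  # hand-counted toy: 20 insertions, pairs 1-10 clustered at 20 bp,
  # 11-20 spread at 1 kb
  pos <- c(as.integer(outer(c(0L, 20L), seq(0L, 4e4L, by = 1e4L), "+")) + 100L,
           seq(2e5L, by = 1000L, length.out = 10L))
  toy <- sv_records("chr1", pos, "INS", svlen = 60L)
  flags <- callset_context(toy)$neighbor_flag
  expect_equal(sum(flags), 10L)
})
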