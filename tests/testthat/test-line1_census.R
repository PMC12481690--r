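# ORF intactness scanning, poly(A)/TSD detection and the intact census.

test_that("the clean LINE consensus is intact with 100% identity in frame +1", {
  sh <- get_shared_sim()
  line <- sh$sim$library$seq[sh$sim$library$name == "L1_CF"]
  res <- scan_orfs(line, sh$sim$orf_models)
  expect_equal(res$identity, c(100, 100))
  expect_equal(res$model_coverage, c(1, 1))
  expect_equal(res$frame, c(1L, 1L))
  expect_equal(res$strand, c("+", "+"))
  expect_false(any(res$premature_stop))
  expect_true(all(res$intact))
})

test_that("intactness steps exactly at 99% amino-acid identity", {
  sh <- get_shared_sim()
  line <- sh$sim$library$seq[sh$sim$library$name == "L1_CF"]
  lay <- sh$sim$line_layout
  # 1 nonsynonymous substitution in the 300-aa ORF1: 299/300 = 99.67%
  m1 <- mutate_orf_codons(line, lay$orf1_start, 1, seed = 31)
  r1 <- scan_orfs(m1, sh$sim$orf_models)
  expect_equal(r1$identity[r1$orf == "ORF1p"], 100 * 299 / 300)
  expect_true(all(r1$intact))
  # 3 substitutions: 297/300 = 99.0%, still intact (inclusive threshold)
  m3 <- mutate_orf_codons(line, lay$orf1_start, 3, seed = 32)
  r3 <- scan_orfs(m3, sh$sim$orf_models)
  expect_equal(r3$identity[r3$orf == "ORF1p"], 99)
  expect_true(all(r3$intact))
  # 4 substitutions: 296/300 = 98.67%, no longer intact
  m4 <- mutate_orf_codons(line, lay$orf1_start, 4, seed = 33)
  r4 <- scan_orfs(m4, sh$sim$orf_models)
  expect_equal(r4$identity[r4$orf == "ORF1p"], 100 * 296 / 300)
  expect_false(all(r4$intact))
  expect_false(r4$orf_pass[r4$orf == "ORF1p"])
})

test_that("a frameshifting 1 bp deletion mid-ORF breaks intactness", {
  sh <- get_shared_sim()
  line <- sh$sim$library$seq[sh$sim$library$name == "L1_CF"]
  lay <- sh$sim$line_layout
  cut <- lay$orf2_start + 600L
  fs <- paste0(substr(line, 1, cut - 1), substr(line, cut + 1, nchar(line)))
  rfs <- scan_orfs(fs, sh$sim$orf_models)
  expect_false(all(rfs$intact))
  expect_false(rfs$orf_pass[rfs$orf == "ORF2p"])
  # degenerate input: shorter than a codon
  tiny <- scan_orfs("AC", sh$sim$orf_models)
  expect_false(any(tiny$intact))
  expect_equal(tiny$model_coverage, c(0, 0))
})

test_that("reverse-complementing the element never changes the verdict", {
  sh <- get_shared_sim()
  line <- sh$sim$library$seq[sh$sim$library$name == "L1_CF"]
  lay <- sh$sim$line_layout
  for (s in list(line, mutate_orf_codons(line, lay$orf1_start, 4, seed = 34))) {
    fwd <- scan_orfs(s, sh$sim$orf_models)
    rev <- scan_orfs(revcomp(s), sh$sim$orf_models)
    expect_equal(rev$intact, fwd$intact)
    expect_equal(rev$identity, fwd$identity)
    expect_equal(rev$strand, chartr("+-", "-+", fwd$strand))
  }
})

test_that("full-length LINE-1 selection requires family and reciprocal overlap", {
  ann <- tibble::tibble(
    sv_id = c("a", "b", "c"),
    svtype = "INS", sample = "S1",
    repeat_name = c("L1_CF", "L1_CF", "SINEC2A1"),
    family = c("LINE", "LINE", "SINE"),
    sv_coverage = c(1, 1, 1),
    consensus_coverage = c(1, 0.5, 1),
    class = c("NEAR_FULL_LENGTH", "REPEAT_DOMINATED", "NEAR_FULL_LENGTH"),
    orientation = "+"
  )
  sel <- find_full_length_line1(ann)
  expect_equal(sel$sv_id, "a") # truncated LINE and full-length SINE excluded
})

test_that("poly(A) detection applies the windowed 80% rule", {
  set.seed(35)
  body <- paste0(rand_seq(100, c("C", "G", "T")), "CC")
  expect_equal(detect_polya(paste0(body, strrep("A", 15))), 15L)
  # interrupted tail: terminal AAAAAAAAGAAA reports the full 12
  expect_equal(detect_polya(paste0(body, "AAAAAAAAGAAA")), 12L)
  # no terminal A enrichment
  expect_equal(detect_polya(body), 0L)
  # below the 8 bp minimum reports 0
  expect_equal(detect_polya(paste0(body, "AAAAA")), 0L)
  # minus orientation: tail appears as a 5' T-tract
  expect_equal(detect_polya(revcomp(paste0(body, strrep("A", 15))),
                            orientation = "-"), 15L)
})

test_that("TSD detection finds the longest <=1-mismatch duplication", {
  set.seed(36)
  tsd <- rand_seq(12)
  left <- paste0(rand_seq(30), tsd)
  right <- paste0(tsd, rand_seq(30))
  got <- detect_tsd(left, right)
  expect_equal(got$tsd_len, 12L)
  expect_equal(got$tsd, tsd)
  expect_equal(got$mismatches, 0L)
  # unrelated flanks
  none <- detect_tsd(strrep("ACGT", 10), strrep("TGCA", 10))
  expect_equal(none$tsd_len, 0L)
  # 14-mer with exactly one mismatch is still detected at length 14
  tsd14 <- rand_seq(14)
  mm <- tsd14
  substr(mm, 7, 7) <- setdiff(c("A", "C", "G", "T"), substr(mm, 7, 7))[1]
  got14 <- detect_tsd(paste0(rand_seq(25), tsd14), paste0(mm, rand_seq(25)))
  expect_equal(got14$tsd_len, 14L)
  expect_equal(got14$mismatches, 1L)
  expect_warning(short <- detect_tsd("ACG", "ACG"), "shorter")
  expect_equal(short$tsd_len, 0L)
})

test_that("the intact census splits counts by sample and SV side", {
  scans <- tibble::tibble(
    sv_id = paste0("sv", 1:9),
    sample = c(rep("A", 7), "B", "B"),
    svtype = c(rep("DEL", 3), rep("INS", 4), "DEL", "INS"),
    intact = c(rep(TRUE, 7), FALSE, FALSE)
  )
  cens <- intact_census(scans)
  expect_equal(cens$n_del[cens$sample == "A"], 3L)
  expect_equal(cens$n_ins[cens$sample == "A"], 4L)
  expect_equal(cens$total[cens$sample == "A"], 7L)
  expect_false("B" %in% cens$sample) # nothing intact in B
  expect_equal(nrow(intact_census(scans[scans$intact == FALSE, ])), 0L)
})

test_that("singleton fraction counts loci private to one sample", {
  clustered <- dplyr::bind_rows(
    sv_records("chr1", 100L, "INS", svlen = 60L, sample = c("A", "B", "C")),
    sv_records("chr1", 5000L, "INS", svlen = 60L, sample = "A"),
    sv_records("chr1", 9000L, "INS", svlen = 60L, sample = "B")
  )
  clustered$cluster <- c(1L, 1L, 1L, 2L, 3L)
  sf <- singleton_fraction(clustered)
  expect_equal(sf$n_loci, 3L)
  expect_equal(sf$n_singletons, 2L)
  expect_equal(sf$singleton_fraction, 2 / 3)
})

test_that("indel noise at increasing rates monotonically erodes intact calls", {
  sh <- get_shared_sim()
  line <- sh$sim$library$seq[sh$sim$library$name == "L1_CF"]
  recs <- sv_records("chr1", seq(1000L, by = 10000L, length.out = 6), "INS",
                     seq = rep(line, 6), genotype = "0/1")
  counts <- vapply(c(0, 5e-5, 2e-3), function(rate) {
    noised <- add_sequence_noise(recs, sub_rate = 0, indel_rate = rate,
                                 seed = 37)
    scans <- scan_orfs_callset(noised, sh$sim$orf_models)
    sum(dplyr::distinct(scans, sv_id, intact)$intact)
  }, 1)
  expect_equal(counts[1], 6) # clean elements all intact
  expect_true(all(diff(counts) <= 0)) # monotone non-increasing in the rate
  expect_lt(counts[3], counts[1]) # strictly fewer at ONT-like rates
})
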