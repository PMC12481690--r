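# Local alignment, reciprocal coverage and dimorphic-repeat classification.

test_that("aligning a sequence to itself yields a full-length perfect hit", {
  set.seed(301)
  s <- rand_seq(300)
  h <- local_align(s, s)
  expect_equal(h$q_start[1], 1L)
  expect_equal(h$q_end[1], 300L)
  expect_equal(h$t_start[1], 1L)
  expect_equal(h$t_end[1], 300L)
  expect_equal(h$pident[1], 100)
  expect_equal(h$strand[1], "+")
})

test_that("the reverse complement aligns full length on the minus strand", {
  set.seed(302)
  s <- rand_seq(250)
  h <- local_align(revcomp(s), s)
  top <- h[1, ]
  expect_equal(top$strand, "-")
  expect_equal(top$pident, 100)
  expect_equal(c(top$q_start, top$q_end), c(1L, 250L))
  expect_error(local_align("ACGU", s), "non-ACGTN")
})

test_that("a partial query with substitutions gets the expected identity and the oracle score", {
  set.seed(303)
  target <- rand_seq(200)
  q <- substr(target, 1, 100)
  # two substitutions
  x <- strsplit(q, "")[[1]]
  for (i in c(20L, 70L)) x[i] <- setdiff(c("A", "C", "G", "T"), x[i])[1]
  q <- paste(x, collapse = "")
  h <- local_align(q, target, both_strands = FALSE)
  top <- h[1, ]
  expect_equal(top$aln_len, 100L)
  expect_equal(top$pident, 98)
  expect_equal(top$score, sw_oracle_score(q, target))
})

test_that("alignment scores equal the DP oracle on random pairs", {
  set.seed(304)
  for (i in 1:15) {
    q <- rand_seq(sample(60:500, 1))
    t <- rand_seq(sample(60:500, 1))
    h <- local_align(q, t, min_score = 1, both_strands = FALSE)
    expect_equal(max(h$score, 0), sw_oracle_score(q, t))
  }
})

test_that("coverage fractions are interval unions of hits", {
  # single full-length perfect hit
  full <- tibble::tibble(q_start = 1L, q_end = 200L, t_start = 1L,
                         t_end = 200L)
  expect_equal(as.numeric(coverage_fractions(full, 200, 200)), c(1, 1))
  # SV equal to the first half of a 200 bp consensus
  half <- tibble::tibble(q_start = 1L, q_end = 100L, t_start = 1L,
                         t_end = 100L)
  cf <- coverage_fractions(half, 100, 200)
  expect_equal(cf$sv_coverage, 1)
  expect_equal(cf$consensus_coverage, 0.5)
  # two disjoint hits covering 60% and 30% of the SV
  two <- tibble::tibble(q_start = c(1L, 71L), q_end = c(60L, 100L),
                        t_start = c(1L, 71L), t_end = c(60L, 100L))
  expect_equal(coverage_fractions(two, 100, 200)$sv_coverage, 0.9)
  # overlapping hits never exceed 1 and coverage is monotone in the hit set
  set.seed(305)
  hits <- tibble::tibble(q_start = sample(1:150, 20, TRUE)) |>
    dplyr::mutate(q_end = pmin(q_start + sample(10:80, 20, TRUE), 200L),
                  t_start = q_start, t_end = q_end)
  covs <- vapply(seq_len(20), function(k) {
    coverage_fractions(hits[seq_len(k), ], 200, 200)$sv_coverage
  }, 1)
  expect_true(all(diff(covs) >= 0))
  expect_true(all(covs <= 1))
  # N positions cannot be covered
  seq_n <- paste0(strrep("A", 90), strrep("N", 10))
  cfn <- coverage_fractions(tibble::tibble(q_start = 1L, q_end = 100L,
                                           t_start = 1L, t_end = 100L),
                            100, 100, sv_seq = seq_n)
  expect_equal(cfn$sv_coverage, 0.9)
})

test_that("dimorphic classification steps exactly at 95% coverage", {
  mk <- function(sv_cov, cons_cov) {
    tibble::tibble(name = "SINEC2A1", family = "SINE", sv_coverage = sv_cov,
                   consensus_coverage = cons_cov)
  }
  expect_equal(classify_dimorphic(mk(0.95, 0.5))$class, "REPEAT_DOMINATED")
  expect_equal(classify_dimorphic(mk(0.949, 0.5))$class, "NONE")
  expect_equal(classify_dimorphic(mk(1, 1))$class, "NEAR_FULL_LENGTH")
  expect_equal(classify_dimorphic(mk(0.95, 0.95))$class, "NEAR_FULL_LENGTH")
  expect_equal(classify_dimorphic(mk(0.95, 0.949))$class, "REPEAT_DOMINATED")
  empty <- classify_dimorphic(mk(1, 1)[0, ])
  expect_equal(empty$class, "NONE")
  # best repeat maximises sv coverage, ties by consensus coverage then name
  cov <- tibble::tibble(name = c("B", "A", "C"),
                        family = "SINE",
                        sv_coverage = c(0.99, 0.99, 0.90),
                        consensus_coverage = c(0.99, 0.80, 1))
  expect_equal(classify_dimorphic(cov)$repeat_name, "B")
})

test_that("an SV identical to a consensus classifies near-full-length on either strand", {
  sh <- get_shared_sim()
  lib <- sh$sim$library
  sine <- lib$seq[lib$name == "SINEC2A1"]
  recs <- sv_records("chr1", c(100L, 5000L), "INS",
                     seq = c(sine, revcomp(sine)), genotype = "0/1")
  ann <- annotate_repeats(recs, lib)
  expect_equal(ann$class, rep("NEAR_FULL_LENGTH", 2))
  expect_equal(ann$repeat_name, rep("SINEC2A1", 2))
  expect_equal(ann$orientation, c("+", "-"))
})

test_that("the repeat census tallies the synthetic truth with shares summing to 100", {
  sh <- get_shared_sim()
  lib <- sh$sim$library
  sine <- lib$seq[lib$name == "SINEC2A1"]
  line <- lib$seq[lib$name == "L1_CF"]
  set.seed(306)
  recs <- dplyr::bind_rows(
    sv_records("chr1", seq(1000L, by = 50000L, length.out = 10), "DEL",
               seq = rep(sine, 10), genotype = "0/1"),
    sv_records("chr1", seq(600000L, by = 20000L, length.out = 5), "INS",
               seq = rep(line, 5), genotype = "0/1"),
    sv_records("chr2", seq(1000L, by = 10000L, length.out = 5), "DEL",
               seq = replicate(5, rand_seq(300)), genotype = "0/1")
  )
  ann <- annotate_repeats(recs, lib)
  cens <- repeat_census(ann, recs)
  expect_equal(cens$n[cens$repeat_name == "SINEC2A1" & cens$svtype == "DEL"],
               10L)
  expect_equal(cens$n[cens$repeat_name == "L1_CF" & cens$svtype == "INS"], 5L)
  # SINE share of repeat-annotated deletions is 100%
  expect_equal(cens$share_of_repeat_annotated[cens$svtype == "DEL"], 100)
  # shares sum to 100 within each svtype stratum
  sums <- dplyr::count(cens, svtype, wt = share_of_repeat_annotated)
  expect_equal(sums$n, rep(100, nrow(sums)))
  # share of the total callset reflects the non-repeat deletions
  expect_equal(cens$share_of_total[cens$svtype == "DEL"], 100 * 10 / 15)
  # family roll-up and combined shares
  fam <- repeat_census(ann, recs, by = "family")
  expect_setequal(fam$family, c("SINE", "LINE"))
  comb <- combined_family_share(fam, c("SINE", "LINE"))
  expect_equal(comb$combined_share[comb$svtype == "DEL"], 100 * 10 / 15)
  # empty annotations give an empty census
  expect_equal(nrow(repeat_census(ann[0, ], recs)), 0L)
})
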