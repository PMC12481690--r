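# Synthetic inputs with known truth for every pipeline stage: a toy
# reference, a repeat library whose LINE element carries two in-frame ORFs,
# implanted insertions/deletions with truncation / substitution / poly(A) /
# TSD structure, jittered multi-modality callset replicates, and admixed
# genotype matrices with known component frequencies.
#
# All generators are pure functions of (config, seed): the seed lives in
# the config and every generator runs under it without disturbing the
# caller's RNG state.

#' Simulation configuration
#'
#' Defaults describe a desk-scale cohort: a 1 Mb reference at 41% GC, three
#' samples, a 200 bp SINE (185 bp body + 15 bp A-tail, emulating SINEC2A1)
#' and a 6 kb LINE carrying a 300-aa ORF1 and a 1,275-aa ORF2 in frame +1
#' (emulating L1_CF), per-sample implant counts of 10/10 SINE DEL/INS,
#' 5/5 LINE DEL/INS and 5 non-repeat background SVs, HiFi-like
#' substitution-only noise at 0.2% confined to non-ORF element regions,
#' LINE 5'-truncation probability 0.2, poly(A) tails of 8-20 bp and TSDs of
#' 8-16 bp.
#'
#' @param seed Mandatory RNG seed.
#' @param ... Overrides for any default listed above (see the returned
#'   object's names).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    chrom = "chr1",
    ref_length = 1000000L,
    gc = 0.41,
    n_samples = 3L,
    sine_name = "SINEC2A1", sine_body_len = 185L, sine_tail_len = 15L,
    line_name = "L1_CF", line_utr5 = 489L, orf1_aa = 300L, spacer = 99L,
    orf2_aa = 1275L, line_tail_len = 15L, line_len = 6000L,
    n_sine_del = 10L, n_sine_ins = 10L, n_line_del = 5L, n_line_ins = 5L,
    n_background = 5L, n_shared = 0L,
    sub_rate = 0.002, indel_rate = 0,
    trunc_prob = 0.2, trunc_frac_range = c(0.3, 0.7),
    orf_disrupt_prob = 0,
    polya_range = c(15L, 22L), tsd_range = c(8L, 16L),
    het_prob = 0.5,
    background_len_range = c(60L, 3000L),
    jitter_sd = 5, read_len = 450L, regeno_sens = 0.9,
    cohort = list(N = 200L, K = 3L, n_sites = 200L, n_null = 0L,
                  n_selected = 0L, shift = 0.5, q_alpha = 1,
                  f_range = c(0.05, 0.95), null_f_range = c(0.1, 0.9),
                  one_hot = FALSE)
  )
  dots <- list(...)
  if ("cohort" %in% names(dots)) {
    cfg$cohort[names(dots$cohort)] <- dots$cohort
    dots$cohort <- NULL
  }
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown sim_config fields: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "sim_config")
}

NONSTOP_CODONS <- local({
  bases <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

random_orf_nt <- function(n_aa) paste(sample(NONSTOP_CODONS, n_aa,
                                             replace = TRUE), collapse = "")

#' Build the toy reference genome, repeat library and ORF peptide models
#'
#' Deterministic given the config seed. The LINE consensus translates to
#' the emitted ORF1/ORF2 peptide models exactly in frame +1; both
#' consensus elements end in a 15 bp A-tail so clean implants align
#' full length.
#'
#' @param config A [sim_config()] object.
#' @return A list: `reference` (DNA string), `chrom`, `library` (tibble as
#'   from [read_repeat_library()]), `orf_models` (tibble as from
#'   [read_orf_models()]), `line_layout` (ORF coordinates on the
#'   consensus).
#' @export
make_reference_and_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    reference <- random_dna(config$ref_length, config$gc)
    sine <- paste0(random_dna(config$sine_body_len, 0.5),
                   strrep("A", config$sine_tail_len))
    utr5 <- random_dna(config$line_utr5, 0.5)
    orf1 <- random_orf_nt(config$orf1_aa)
    spacer <- random_dna(config$spacer, 0.5)
    orf2 <- random_orf_nt(config$orf2_aa)
    used <- config$line_utr5 + 3L * config$orf1_aa + config$spacer +
      3L * config$orf2_aa
    utr3_len <- config$line_len - used - config$line_tail_len
    stopifnot(utr3_len >= 0L)
    line <- paste0(utr5, orf1, spacer, orf2, random_dna(utr3_len, 0.5),
                   strrep("A", config$line_tail_len))
    orf1_start <- config$line_utr5 + 1L
    orf1_end <- orf1_start + 3L * config$orf1_aa - 1L
    orf2_start <- orf1_end + config$spacer + 1L
    orf2_end <- orf2_start + 3L * config$orf2_aa - 1L
    models <- tibble(
      name = c("ORF1p", "ORF2p"),
      seq = c(translate_frame(orf1, 1L), translate_frame(orf2, 1L)),
      length = c(config$orf1_aa, config$orf2_aa)
    )
    list(
      reference = reference,
      chrom = config$chrom,
      library = tibble(name = c(config$sine_name, config$line_name),
                       family = c("SINE", "LINE"),
                       seq = c(sine, line),
                       length = c(nchar(sine), nchar(line))),
      orf_models = models,
      line_layout = list(orf1_start = orf1_start, orf1_end = orf1_end,
                         orf2_start = orf2_start, orf2_end = orf2_end)
    )
  })
}

# substitutions restricted to `allowed` positions (default: anywhere)
substitute_at_rate <- function(seq, rate, allowed = NULL) {
  if (rate <= 0) return(list(seq = seq, n = 0L))
  x <- strsplit(seq, "")[[1L]]
  cand <- allowed %||% seq_along(x)
  hit <- cand[runif(length(cand)) < rate]
  for (i in hit) {
    x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1L)
  }
  list(seq = paste(x, collapse = ""), n = length(hit))
}

#' Implant repeat-derived and background SVs with known truth
#'
#' Places non-overlapping loci on the toy reference and emits one callset
#' tibble per sample plus a truth table. SINE/LINE insertions carry a
#' poly(A) tail drawn from `polya_range`; their truth rows carry
#' TSD-bearing flank sequences built by duplicating the insertion-site
#' k-mer. LINE insertions are 5'-truncated with probability `trunc_prob`
#' (expected class drops from `NEAR_FULL_LENGTH` to `REPEAT_DOMINATED`);
#' with probability `orf_disrupt_prob` an otherwise intact LINE receives a
#' frameshifting 1 bp deletion inside ORF2. Substitution noise at
#' `sub_rate` avoids ORF codons so ORF intactness truth is exact by
#' construction.
#'
#' @param sim Output of [make_reference_and_library()].
#' @param config The same [sim_config()] object.
#' @return A list: `callsets` (named list of per-sample SV tibbles),
#'   `truth` (tibble with per-locus type, repeat identity, expected class,
#'   intactness, poly(A)/TSD features and flanks).
#' @export
implant_svs <- function(sim, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    samples <- paste0("S", seq_len(config$n_samples))
    kinds <- c(rep("sine_del", config$n_sine_del),
               rep("sine_ins", config$n_sine_ins),
               rep("line_del", config$n_line_del),
               rep("line_ins", config$n_line_ins),
               rep("background", config$n_background))
    plan <- tibble(
      sample_set = rep(samples, each = length(kinds)),
      kind = rep(kinds, config$n_samples)
    )
    if (config$n_shared > 0L) {
      shared_kinds <- rep(c("sine_ins", "line_ins", "sine_del", "line_del"),
                          length.out = config$n_shared)
      plan <- bind_rows(plan, tibble(sample_set = "ALL", kind = shared_kinds))
    }
    n_loci <- nrow(plan)
    plan <- plan[sample.int(n_loci), ]

    sine <- sim$library$seq[sim$library$name == config$sine_name]
    line <- sim$library$seq[sim$library$name == config$line_name]
    lay <- sim$line_layout
    orf_pos <- c(lay$orf1_start:lay$orf1_end, lay$orf2_start:lay$orf2_end)

    # reserve genome space: each locus needs its own span plus margin
    max_span <- nchar(line) + 200L
    margin <- 100L
    need <- n_loci * max_span + 2L * margin
    if (need > config$ref_length) {
      stop("cannot place ", n_loci, " loci of up to ", max_span,
           " bp on a ", config$ref_length, " bp reference")
    }
    slack <- config$ref_length - need
    gaps <- floor(slack * as.vector(rmultinom(1, 1000L, rep(1, n_loci))) / 1000)
    starts <- margin + cumsum(gaps + max_span) - max_span + 1L

    truth <- vector("list", n_loci)
    recs <- vector("list", n_loci)
    for (i in seq_len(n_loci)) {
      kind <- plan$kind[i]
      pos <- starts[i]
      carriers <- if (plan$sample_set[i] == "ALL") samples else plan$sample_set[i]
      repeat_name <- NA_character_; family <- NA_character_
      trunc <- 0; intact <- NA; polya <- NA_integer_
      tsd_len <- NA_integer_; left_flank <- NA_character_
      right_flank <- NA_character_; disrupted <- FALSE

      if (kind == "background") {
        len <- sample(config$background_len_range[1]:
                        config$background_len_range[2], 1L)
        allele <- random_dna(len, 0.5)
        svtype <- sample(c("DEL", "INS"), 1L)
        expected_class <- "NONE"
      } else {
        is_line <- grepl("^line", kind)
        svtype <- if (grepl("del$", kind)) "DEL" else "INS"
        element <- if (is_line) line else sine
        allowed <- if (is_line) {
          setdiff(seq_len(nchar(element)), orf_pos)
        } else {
          seq_len(nchar(element))
        }
        mut <- substitute_at_rate(element, config$sub_rate, allowed)
        allele <- mut$seq
        intact <- is_line
        if (is_line && svtype == "INS" && runif(1) < config$trunc_prob) {
          trunc <- runif(1, config$trunc_frac_range[1],
                         config$trunc_frac_range[2])
          allele <- substr(allele, floor(nchar(allele) * trunc) + 1L,
                           nchar(allele))
          intact <- FALSE
        }
        if (is_line && intact && runif(1) < config$orf_disrupt_prob) {
          # cut in the middle half of ORF2 so the frameshift scrambles a
          # large part of the protein (a cut in the last codons would not
          # disrupt the reading frame enough to break intactness)
          len2 <- lay$orf2_end - lay$orf2_start + 1L
          cut <- sample(seq(lay$orf2_start + len2 %/% 4L,
                            lay$orf2_start + len2 %/% 2L), 1L)
          allele <- paste0(substr(allele, 1L, cut - 1L),
                           substr(allele, cut + 1L, nchar(allele)))
          disrupted <- TRUE
          intact <- FALSE
        }
        # extend the consensus A-tail to the sampled poly(A) length
        polya <- sample(config$polya_range[1]:config$polya_range[2], 1L)
        base_tail <- if (is_line) config$line_tail_len else config$sine_tail_len
        polya <- max(polya, base_tail)
        if (polya > base_tail) {
          allele <- paste0(allele, strrep("A", polya - base_tail))
        }
        repeat_name <- if (is_line) config$line_name else config$sine_name
        family <- if (is_line) "LINE" else "SINE"
        expected_class <- if (trunc > 0) "REPEAT_DOMINATED" else "NEAR_FULL_LENGTH"
        # TSD: the insertion-site k-mer duplicated at the start of the
        # element's right flank
        tsd_len <- sample(config$tsd_range[1]:config$tsd_range[2], 1L)
        site <- substr(sim$reference, pos - tsd_len, pos - 1L)
        left_flank <- substr(sim$reference, pos - 30L, pos - 1L)
        right_flank <- paste0(site,
                              substr(sim$reference, pos, pos + 30L - tsd_len))
      }
      svlen <- nchar(allele)
      locus <- tibble(
        locus_id = sprintf("L%04d", i), chrom = sim$chrom, pos = pos,
        end = if (svtype == "INS") pos else pos + svlen - 1L,
        svtype = svtype, svlen = svlen,
        repeat_name = repeat_name, family = family,
        expected_class = expected_class, truncated_frac = trunc,
        orf_intact = intact, disrupted = disrupted,
        polya_len = polya, tsd_len = tsd_len,
        left_flank = left_flank, right_flank = right_flank,
        carriers = paste(carriers, collapse = ",")
      )
      truth[[i]] <- locus
      gts <- sample(c("0/1", "1/1"), length(carriers), replace = TRUE,
                    prob = c(config$het_prob, 1 - config$het_prob))
      recs[[i]] <- sv_records(
        chrom = sim$chrom, pos = pos, svtype = svtype, svlen = svlen,
        seq = allele, genotype = gts, sample = carriers,
        modality = "long-read"
      ) %>% mutate(locus_id = locus$locus_id)
    }
    truth <- bind_rows(truth) %>% arrange(.data$pos)
    records <- bind_rows(recs) %>% arrange(.data$sample, .data$pos)
    callsets <- split(records, records$sample)
    list(callsets = callsets, truth = truth)
  })
}

# point substitutions and 1 bp indels at given per-base rates
mutate_seq_noise <- function(seq, sub_rate, indel_rate) {
  x <- strsplit(seq, "")[[1L]]
  n <- length(x)
  u <- runif(n)
  sub_hit <- which(u < sub_rate)
  for (i in sub_hit) x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1L)
  u2 <- runif(n)
  indel_hit <- which(u2 < indel_rate)
  if (length(indel_hit)) {
    # process right-to-left so positions stay valid
    for (i in rev(indel_hit)) {
      if (runif(1) < 0.5) {
        x <- x[-i] # 1 bp deletion
      } else {
        x <- append(x, sample(c("A", "C", "G", "T"), 1L), after = i)
      }
    }
  }
  paste(x, collapse = "")
}

#' Add platform-like sequence noise to SV alleles
#'
#' Applies per-base substitutions and 1 bp indels to every
#' sequence-resolved record, emulating platform error profiles (e.g.
#' indel-dominated ONT-like noise at 3:1 indel:substitution, or
#' substitution-only HiFi-like noise). `svlen`/`end` are updated to match
#' the mutated allele.
#'
#' @param records An SV callset tibble.
#' @param sub_rate,indel_rate Per-base rates.
#' @param seed RNG seed.
#' @return The noised callset tibble.
#' @export
add_sequence_noise <- function(records, sub_rate, indel_rate, seed = 1L) {
  validate_sv_records(records)
  with_seed(seed, {
    for (i in seq_len(nrow(records))) {
      if (is.na(records$seq[i])) next
      records$seq[i] <- mutate_seq_noise(records$seq[i], sub_rate, indel_rate)
      records$svlen[i] <- nchar(records$seq[i])
      if (records$svtype[i] != "INS") {
        records$end[i] <- records$pos[i] + records$svlen[i] - 1L
      }
    }
    records
  })
}

#' Simulate per-modality callset replicates from a truth callset
#'
#' `long-read`-like calls are the truth with Gaussian breakpoint jitter;
#' `short-read`-like calls additionally drop each insertion with
#' probability `min(1, svlen / read_len)` (so insertions longer than the
#' read length are always lost); the `paragraph` (regenotyped) callset
#' restores each dropped insertion locus with probability `regeno_sens`.
#'
#' @param truth_callset A single-sample SV callset tibble (truth records).
#' @param config A [sim_config()] object (`jitter_sd`, `read_len`,
#'   `regeno_sens`, `seed`).
#' @return A named list of callset tibbles: `long_read`, `short_read`,
#'   `regenotyped`.
#' @export
simulate_callsets <- function(truth_callset, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 2L, {
    jitter <- function(df, modality) {
      if (nrow(df) == 0L) return(mutate(df, modality = modality))
      dp <- as.integer(round(rnorm(nrow(df), 0, config$jitter_sd)))
      df$pos <- pmax(1L, df$pos + dp)
      df$end <- ifelse(df$svtype == "INS", df$pos, df$pos + df$svlen - 1L)
      df$modality <- modality
      df
    }
    long_read <- jitter(truth_callset, "long-read")
    sr <- jitter(truth_callset, "short-read")
    drop_p <- ifelse(sr$svtype == "INS",
                     pmin(1, sr$svlen / config$read_len), 0)
    dropped <- runif(nrow(sr)) < drop_p
    short_read <- sr[!dropped, , drop = FALSE]
    restored <- sr[dropped & runif(nrow(sr)) < config$regeno_sens, ,
                   drop = FALSE]
    regenotyped <- bind_rows(short_read, restored) %>%
      mutate(modality = "paragraph") %>%
      arrange(.data$pos)
    list(long_read = long_read, short_read = short_read,
         regenotyped = regenotyped)
  })
}

#' Simulate an admixed cohort's genotypes with known component frequencies
#'
#' Draws ancestry proportions Q from a flat Dirichlet (or one-hot
#' population blocks), per-site component frequencies F from the
#' configured priors — `n_null` sites share one frequency across
#' components, `n_selected` sites have one component's frequency shifted by
#' `shift` (clamped to `[0.01, 0.99]`) — and dosages
#' `g ~ Binomial(2, Q F)`. Individuals are labelled by their dominant
#' component.
#'
#' @param config A [sim_config()] object (fields under `cohort`).
#' @return A list: `geno` ([sv_genotypes()]), `Q` (N x K matrix), `truth`
#'   (per-site tibble with true frequencies, site type and the selected
#'   component).
#' @export
simulate_admixed_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ch <- config$cohort
  with_seed(config$seed + 3L, {
    N <- ch$N; K <- ch$K
    Q <- if (isTRUE(ch$one_hot)) {
      comp <- rep(seq_len(K), length.out = N)
      diag(K)[comp, , drop = FALSE]
    } else {
      raw <- matrix(rgamma(N * K, shape = ch$q_alpha), N, K)
      raw / rowSums(raw)
    }
    n_free <- ch$n_sites - ch$n_null - ch$n_selected
    stopifnot(n_free >= 0)
    site_type <- c(rep("free", n_free), rep("null", ch$n_null),
                   rep("selected", ch$n_selected))
    n_sites <- ch$n_sites
    F_true <- matrix(NA_real_, n_sites, K)
    sel_comp <- rep(NA_integer_, n_sites)
    for (s in seq_len(n_sites)) {
      F_true[s, ] <- switch(
        site_type[s],
        free = runif(K, ch$f_range[1], ch$f_range[2]),
        null = rep(runif(1, ch$null_f_range[1], ch$null_f_range[2]), K),
        selected = {
          base <- runif(1, ch$null_f_range[1], ch$null_f_range[2])
          f <- rep(base, K)
          k <- sample.int(K, 1L)
          sel_comp[s] <- k
          # shift toward the feasible side so its magnitude is exact
          dir <- if (base <= 0.5) 1 else -1
          f[k] <- min(max(base + dir * ch$shift, 0.01), 0.99)
          f
        }
      )
    }
    P <- Q %*% t(F_true) # N x sites
    G <- matrix(rbinom(N * n_sites, 2L, as.vector(P)), N, n_sites)
    G <- t(G) # sites x individuals
    rownames(G) <- paste0("site", seq_len(n_sites))
    colnames(G) <- paste0("ind", seq_len(N))
    pop <- paste0("pop", max.col(Q))
    geno <- sv_genotypes(
      G,
      sites = tibble(site = rownames(G), type = site_type,
                     selected_component = sel_comp),
      samples = tibble(sample = colnames(G), population = pop)
    )
    truth <- bind_cols(geno$sites,
                       as_tibble(F_true, .name_repair = ~ paste0("F", 1:K)))
    list(geno = geno, Q = Q, truth = truth)
  })
}

#' Write simulated inputs to disk
#'
#' Emits the reference FASTA, repeat-library FASTA (RepeatMasker-style
#' `name#family` headers), ORF peptide FASTA, per-sample VCFs, the Q
#' matrix and dosage TSVs, and the truth tables — everything the pipeline
#' reads.
#'
#' @param sim Output of [make_reference_and_library()].
#' @param implants Output of [implant_svs()] (optional).
#' @param cohort Output of [simulate_admixed_genotypes()] (optional).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, implants = NULL, cohort = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- Biostrings::DNAStringSet(setNames(sim$reference, sim$chrom))
  Biostrings::writeXStringSet(ref, file.path(dir, "reference.fa"))
  lib <- Biostrings::DNAStringSet(setNames(
    sim$library$seq, paste0(sim$library$name, "#", sim$library$family)))
  Biostrings::writeXStringSet(lib, file.path(dir, "repeats.fa"))
  orf <- Biostrings::AAStringSet(setNames(sim$orf_models$seq,
                                          sim$orf_models$name))
  Biostrings::writeXStringSet(orf, file.path(dir, "orf_models.faa"))
  if (!is.null(implants)) {
    for (s in names(implants$callsets)) {
      write_sv_vcf(select(implants$callsets[[s]], -any_of("locus_id")),
                   file.path(dir, paste0(s, ".vcf")))
    }
    readr::write_tsv(implants$truth, file.path(dir, "truth_loci.tsv"))
  }
  if (!is.null(cohort)) {
    readr::write_tsv(as_tibble(cohort$Q, .name_repair = ~ paste0(
      "Q", seq_len(ncol(cohort$Q)))) %>%
        mutate(sample = cohort$geno$samples$sample, .before = 1),
      file.path(dir, "q_matrix.tsv"))
    readr::write_tsv(as_tibble(cohort$geno$G, rownames = "site"),
                     file.path(dir, "dosages.tsv"))
    readr::write_tsv(cohort$truth, file.path(dir, "truth_sites.tsv"))
  }
  invisible(dir)
}
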