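# Shared fixtures and independent oracles, all built in code.

rand_seq <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# an SV callset with random coordinates on a few chromosomes
random_callset <- function(n, sample = "S1", modality = "long-read",
                           chroms = c("chr1", "chr2"), span = 1e6) {
  svtype <- sample(c("DEL", "INS"), n, replace = TRUE)
  svlen <- sample(50:5000, n, replace = TRUE)
  pos <- sample(seq_len(span), n)
  sv_records(chrom = sample(chroms, n, replace = TRUE), pos = pos,
             svtype = svtype, svlen = svlen,
             genotype = sample(c("0/1", "1/1"), n, replace = TRUE),
             sample = sample, modality = modality)
}

# jittered copy of a callset (breakpoints moved by <= amount bp)
jittered_copy <- function(records, amount = 60, modality = "assembly") {
  records$pos <- records$pos + sample(-amount:amount, nrow(records), TRUE)
  records$end <- ifelse(records$svtype == "INS", records$pos,
                        records$pos + records$svlen - 1L)
  records$modality <- modality
  records
}

# O(n^2) single-linkage clustering oracle: evaluates the predicate on every
# pair and takes connected components via repeated label propagation
brute_cluster <- function(records, params = merge_params(),
                          predicate = pair_matches) {
  n <- nrow(records)
  lab <- seq_len(n)
  if (n >= 2L) {
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n - 1L)) {
      a <- records[rep(i, n - i), , drop = FALSE]
      b <- records[(i + 1L):n, , drop = FALSE]
      adj[i, (i + 1L):n] <- predicate(a, b, params)
    }
    repeat {
      changed <- FALSE
      for (i in seq_len(n - 1L)) {
        js <- which(adj[i, ])
        if (length(js)) {
          m <- min(lab[c(i, js)])
          if (any(lab[c(i, js)] != m)) {
            lab[c(i, js)] <- m
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
  }
  lab
}

# canonical form of a clustering: sorted list of sorted member index sets
cluster_sets <- function(labels) {
  unname(lapply(split(seq_along(labels), labels), sort))
}

same_clustering <- function(lab1, lab2) {
  s1 <- cluster_sets(lab1)
  s2 <- cluster_sets(lab2)
  setequal(vapply(s1, paste, "", collapse = ","),
           vapply(s2, paste, "", collapse = ","))
}

# full Smith-Waterman local-alignment score oracle (independent DP engine)
sw_oracle_score <- function(q, t, match = 2, mismatch = -3, gap_open = 5,
                            gap_extend = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(q, t, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend)
  max(Biostrings::score(pa), 0)
}

# a small simulation shared by several test files (computed once per run)
shared_sim_env <- new.env()
get_shared_sim <- function() {
  if (is.null(shared_sim_env$sim)) {
    cfg <- sim_config(seed = 20260927)
    shared_sim_env$cfg <- cfg
    shared_sim_env$sim <- make_reference_and_library(cfg)
  }
  list(cfg = shared_sim_env$cfg, sim = shared_sim_env$sim)
}

# substitute n codons of an ORF with codons encoding different amino acids
mutate_orf_codons <- function(line_seq, orf_start, n_sub, seed = 1) {
  withr::with_seed(seed, {
    x <- line_seq
    taken <- integer(0)
    aa_of <- function(codon) unname(Biostrings::GENETIC_CODE[codon])
    nonstop <- setdiff(
      as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            paste0), c("A", "C", "G", "T"), paste0)),
      c("TAA", "TAG", "TGA"))
    while (length(taken) < n_sub) {
      ci <- sample(setdiff(seq_len(50L), taken), 1L) # within first 50 codons
      start <- orf_start + 3L * (ci - 1L)
      old <- substr(x, start, start + 2L)
      repl <- sample(nonstop, 20L)
      repl <- repl[vapply(repl, aa_of, "") != aa_of(old)][1L]
      substr(x, start, start + 2L) <- repl
      taken <- c(taken, ci)
    }
    x
  })
}
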