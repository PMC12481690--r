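# Local alignment of SV allele sequences against a repeat consensus
# library, reciprocal-coverage computation, and dimorphic-repeat
# classification.
#
# The aligner is Smith-Waterman with affine gaps and blastn-like scoring
# (match +2, mismatch -3, gap open 5, gap extend 2; a gap of length L costs
# 5 + 2L).  Multiple hits per query/target pair are enumerated by greedily
# taking the best local alignment and re-aligning the unused query segments
# on either side.  E-value machinery is deliberately absent: score, length
# and identity thresholds substitute at this scale.

#' Read a repeat consensus library from FASTA
#'
#' Headers of the form `name#family` (RepeatMasker convention, e.g.
#' `SINEC2A1#SINE`, `L1_CF#LINE`) carry the family label; a header without
#' `#` gets family `"unknown"`.
#'
#' @param path FASTA file path.
#' @return A tibble with columns `name`, `family`, `seq`, `length`.
#' @export
read_repeat_library <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)
  name <- sub("#.*$", "", hdr)
  family <- ifelse(grepl("#", hdr), sub("^[^#]*#", "", hdr), "unknown")
  family <- sub("\\s.*$", "", family)
  tibble(name = sub("\\s.*$", "", name), family = family,
         seq = as.character(ss), length = Biostrings::width(ss))
}

# best single local alignment of two encoded sequences
sw_best <- function(q_codes, t_codes, submat, gap_open, gap_extend) {
  .sw_align_core(q_codes, t_codes, submat, gap_open, gap_extend)
}

# enumerate hits on one strand by recursive query segmentation
sw_hits_segmented <- function(q_codes, t_codes, submat, gap_open, gap_extend,
                              min_score, offset = 0L) {
  if (length(q_codes) < 10L) return(NULL)
  a <- sw_best(q_codes, t_codes, submat, gap_open, gap_extend)
  if (a$score < min_score || a$aln_len == 0L) return(NULL)
  hit <- tibble(
    q_start = a$q_start + offset, q_end = a$q_end + offset,
    t_start = a$t_start, t_end = a$t_end,
    score = a$score, n_match = a$n_match, aln_len = a$aln_len,
    pident = 100 * a$n_match / a$aln_len
  )
  left <- if (a$q_start > 1L) {
    sw_hits_segmented(q_codes[seq_len(a$q_start - 1L)], t_codes, submat,
                      gap_open, gap_extend, min_score, offset)
  }
  right <- if (a$q_end < length(q_codes)) {
    sw_hits_segmented(q_codes[(a$q_end + 1L):length(q_codes)], t_codes,
                      submat, gap_open, gap_extend, min_score,
                      offset + a$q_end)
  }
  bind_rows(left, hit, right)
}

#' Local alignment of a query against a target sequence
#'
#' Smith-Waterman with affine gaps on both strands. The minus strand is
#' searched by aligning the reverse complement of the query; minus-strand
#' hit coordinates are reported on the original (plus) query. All hits with
#' score at least `min_score` are returned, best first.
#'
#' @param query,target DNA strings over `{A,C,G,T,N}` (`N` scores as a
#'   mismatch against everything and can never be covered by a match).
#' @param match,mismatch,gap_open,gap_extend blastn-like scoring; a gap of
#'   length L costs `gap_open + L * gap_extend`.
#' @param min_score Minimum alignment score to report.
#' @param both_strands Search the reverse complement of the query too?
#' @return A tibble of hits: `q_start`, `q_end`, `t_start`, `t_end`
#'   (1-based inclusive), `strand`, `score`, `n_match`, `aln_len`,
#'   `pident` (percent identity over alignment columns).
#' @export
local_align <- function(query, target, match = 2, mismatch = -3,
                        gap_open = 5, gap_extend = 2, min_score = 40,
                        both_strands = TRUE) {
  stopifnot(nchar(query) > 0L, nchar(target) > 0L)
  submat <- dna_submat(match, mismatch)
  qc <- encode_dna(query)
  tc <- encode_dna(target)
  fwd <- sw_hits_segmented(qc, tc, submat, gap_open, gap_extend, min_score)
  if (!is.null(fwd) && nrow(fwd)) fwd$strand <- "+"
  rev <- NULL
  if (both_strands) {
    qrc <- encode_dna(revcomp(query))
    rev <- sw_hits_segmented(qrc, tc, submat, gap_open, gap_extend, min_score)
    if (!is.null(rev) && nrow(rev)) {
      n <- nchar(query)
      qs <- n - rev$q_end + 1L
      qe <- n - rev$q_start + 1L
      rev$q_start <- qs
      rev$q_end <- qe
      rev$strand <- "-"
    }
  }
  out <- bind_rows(fwd, rev)
  if (is.null(out) || nrow(out) == 0L) {
    return(tibble(q_start = integer(), q_end = integer(), t_start = integer(),
                  t_end = integer(), strand = character(), score = double(),
                  n_match = integer(), aln_len = integer(), pident = double()))
  }
  arrange(out, desc(.data$score))[, c("q_start", "q_end", "t_start", "t_end",
                                      "strand", "score", "n_match", "aln_len",
                                      "pident")]
}

#' Reciprocal coverage fractions of an SV by one repeat's hits
#'
#' `sv_coverage` is the fraction of the SV allele covered by the union of
#' the hits' query intervals (positions that are `N` in the allele can
#' never count as covered); `consensus_coverage` is the fraction of the
#' consensus covered by the union of the target intervals. Coverage is
#' monotone in the hit set and never exceeds 1.
#'
#' @param hits Hit tibble from [local_align()], all against one repeat.
#' @param sv_len SV allele length in bp.
#' @param consensus_len Repeat consensus length in bp.
#' @param sv_seq Optional SV allele sequence used to exclude `N` positions.
#' @return A tibble with one row: `sv_coverage`, `consensus_coverage`.
#' @export
coverage_fractions <- function(hits, sv_len, consensus_len, sv_seq = NULL) {
  exclude <- NULL
  if (!is.null(sv_seq)) {
    npos <- which(strsplit(toupper(sv_seq), "")[[1L]] == "N")
    if (length(npos)) exclude <- IRanges::IRanges(start = npos, width = 1L)
  }
  sv_cov <- interval_union_width(hits$q_start, hits$q_end, bound = sv_len,
                                 exclude = exclude) / sv_len
  cons_cov <- interval_union_width(hits$t_start, hits$t_end,
                                   bound = consensus_len) / consensus_len
  tibble(sv_coverage = sv_cov, consensus_coverage = cons_cov)
}

#' Classify per-repeat coverage summaries into a dimorphic-repeat class
#'
#' The best repeat maximises `sv_coverage` (ties: higher
#' `consensus_coverage`, then lexicographic name). Classes:
#' `NEAR_FULL_LENGTH` when `sv_coverage >= 0.95` and
#' `consensus_coverage >= 0.95` (95% reciprocal overlap, thresholds
#' inclusive); `REPEAT_DOMINATED` when only `sv_coverage >= 0.95`;
#' otherwise `NONE`.
#'
#' @param cov A tibble with columns `name`, `family`, `sv_coverage`,
#'   `consensus_coverage` (one row per repeat with at least one hit; may be
#'   empty).
#' @param min_sv_cov,min_recip Inclusive thresholds (default 0.95).
#' @return One-row tibble: `repeat_name`, `family`, `sv_coverage`,
#'   `consensus_coverage`, `class`.
#' @export
classify_dimorphic <- function(cov, min_sv_cov = 0.95, min_recip = 0.95) {
  if (nrow(cov) == 0L) {
    return(tibble(repeat_name = NA_character_, family = NA_character_,
                  sv_coverage = 0, consensus_coverage = 0, class = "NONE"))
  }
  best <- cov %>%
    arrange(desc(.data$sv_coverage), desc(.data$consensus_coverage),
            .data$name) %>%
    slice(1L)
  class <- if (best$sv_coverage >= min_sv_cov &&
               best$consensus_coverage >= min_recip) {
    "NEAR_FULL_LENGTH"
  } else if (best$sv_coverage >= min_sv_cov) {
    "REPEAT_DOMINATED"
  } else {
    "NONE"
  }
  tibble(repeat_name = best$name, family = best$family,
         sv_coverage = best$sv_coverage,
         consensus_coverage = best$consensus_coverage, class = class)
}

# stable per-record SV identifier
sv_id <- function(records) {
  paste(records$sample, records$chrom, records$pos, records$svtype,
        records$svlen, sep = ":")
}

#' Annotate a callset against a repeat consensus library
#'
#' Aligns every sequence-resolved record against every library consensus on
#' both strands, discards hits shorter than `min_hit_len` bp or below
#' `min_hit_identity` percent identity, computes reciprocal coverage per
#' repeat and classifies each SV with [classify_dimorphic()].
#'
#' @param records An SV callset tibble (records with `seq = NA` get class
#'   `NONE`).
#' @param library Repeat library tibble from [read_repeat_library()].
#' @param min_sv_cov,min_recip Classification thresholds (default 0.95).
#' @param min_hit_len,min_hit_identity Hit-level filters (default 30 bp,
#'   80%).
#' @return A tibble with one row per record: `sv_id`, `svtype`, `sample`,
#'   `repeat_name`, `family`, `sv_coverage`, `consensus_coverage`, `class`,
#'   `orientation`.
#' @export
annotate_repeats <- function(records, library, min_sv_cov = 0.95,
                             min_recip = 0.95, min_hit_len = 30,
                             min_hit_identity = 80) {
  validate_sv_records(records)
  ids <- sv_id(records)
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    sv_seq <- records$seq[i]
    if (is.na(sv_seq)) {
      ann <- classify_dimorphic(tibble(name = character(),
                                       family = character(),
                                       sv_coverage = double(),
                                       consensus_coverage = double()))
      ann$orientation <- NA_character_
    } else {
      cov_rows <- lapply(seq_len(nrow(library)), function(j) {
        # plus strand first; the minus strand only when the plus-strand
        # hits leave part of the query uncovered
        hits <- local_align(sv_seq, library$seq[j], both_strands = FALSE)
        plus_cov <- interval_union_width(hits$q_start, hits$q_end,
                                         bound = nchar(sv_seq))
        if (plus_cov < 0.99 * nchar(sv_seq)) {
          hits <- local_align(sv_seq, library$seq[j], both_strands = TRUE)
        }
        hits <- hits[hits$q_end - hits$q_start + 1L >= min_hit_len &
                       hits$pident >= min_hit_identity, , drop = FALSE]
        if (nrow(hits) == 0L) return(NULL)
        cf <- coverage_fractions(hits, sv_len = nchar(sv_seq),
                                 consensus_len = library$length[j],
                                 sv_seq = sv_seq)
        tibble(name = library$name[j], family = library$family[j],
               sv_coverage = cf$sv_coverage,
               consensus_coverage = cf$consensus_coverage,
               orientation = hits$strand[1L])
      })
      cov <- bind_rows(cov_rows)
      if (nrow(cov) == 0L) {
        cov <- tibble(name = character(), family = character(),
                      sv_coverage = double(), consensus_coverage = double(),
                      orientation = character())
      }
      ann <- classify_dimorphic(cov, min_sv_cov, min_recip)
      ann$orientation <- if (nrow(cov) > 0L && !is.na(ann$repeat_name)) {
        cov$orientation[match(ann$repeat_name, cov$name)]
      } else {
        NA_character_
      }
    }
    ann$sv_id <- ids[i]
    ann$svtype <- records$svtype[i]
    ann$sample <- records$sample[i]
    out[[i]] <- ann
  }
  bind_rows(out)[, c("sv_id", "svtype", "sample", "repeat_name", "family",
                     "sv_coverage", "consensus_coverage", "class",
                     "orientation")]
}

#' Census of dimorphic repeats by repeat name or family
#'
#' Counts repeat-annotated SVs (class other than `NONE`) per repeat name
#' (or family) and svtype, with each row's share of the repeat-annotated
#' subset and of the total callset within its svtype stratum.
#'
#' @param annotations Output of [annotate_repeats()].
#' @param records The callset the annotations came from (for totals).
#' @param by `"name"` (default) or `"family"` roll-up.
#' @return A tibble: `repeat_name` (or `family`), `svtype`, `n`,
#'   `share_of_repeat_annotated`, `share_of_total` (both percentages).
#' @export
repeat_census <- function(annotations, records, by = c("name", "family")) {
  by <- match.arg(by)
  key <- if (by == "name") "repeat_name" else "family"
  ann <- annotations[annotations$class != "NONE", , drop = FALSE]
  if (nrow(ann) == 0L) {
    return(tibble(!!key := character(), svtype = character(), n = integer(),
                  share_of_repeat_annotated = double(),
                  share_of_total = double()))
  }
  totals <- records %>% count(.data$svtype, name = "n_total")
  ann %>%
    count(.data[[key]], .data$svtype, name = "n") %>%
    group_by(.data$svtype) %>%
    mutate(share_of_repeat_annotated = 100 * .data$n / sum(.data$n)) %>%
    ungroup() %>%
    left_join(totals, by = "svtype") %>%
    mutate(share_of_total = 100 * .data$n / .data$n_total) %>%
    select(-"n_total")
}

#' Combined share of the total callset for a set of repeat families
#'
#' Sums `share_of_total` across census rows belonging to the given repeat
#' names or families, per svtype — e.g. the combined SINE + LINE share of
#' all deletions.
#'
#' @param census Output of [repeat_census()].
#' @param groups Character vector of repeat names/families to combine.
#' @return A tibble `svtype`, `combined_share` (percent).
#' @export
combined_family_share <- function(census, groups) {
  key <- intersect(c("repeat_name", "family"), names(census))[1L]
  census %>%
    filter(.data[[key]] %in% groups) %>%
    group_by(.data$svtype) %>%
    summarise(combined_share = sum(.data$share_of_total), .groups = "drop")
}
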