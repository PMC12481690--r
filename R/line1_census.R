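# Full-length LINE-1 identification, ORF-intactness scanning against
# ORF1p/ORF2p peptide models, poly(A)/TSD feature detection, and the
# per-sample intact-element census.

#' Read ORF peptide models from FASTA
#'
#' @param path Amino-acid FASTA (e.g. the ORF1p and ORF2p protein records).
#' @return A tibble with columns `name`, `seq`, `length` (in residues).
#' @export
read_orf_models <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  tibble(name = sub("\\s.*$", "", names(ss)), seq = as.character(ss),
         length = Biostrings::width(ss))
}

#' Select full-length LINE-1 candidates from repeat annotations
#'
#' Full-length candidates are SVs classified `NEAR_FULL_LENGTH` (95%
#' reciprocal overlap with the consensus) whose best repeat belongs to a
#' LINE family.
#'
#' @param annotations Output of [annotate_repeats()].
#' @param line_families Families counting as LINE-1 (default `"LINE"`).
#' @return The subset of annotation rows for full-length LINE-1s.
#' @export
find_full_length_line1 <- function(annotations, line_families = "LINE") {
  annotations %>%
    filter(.data$class == "NEAR_FULL_LENGTH",
           .data$family %in% line_families)
}

# translate one frame of a DNA string to a peptide (stops as '*',
# N-containing codons as 'X'); table-driven for speed
translate_frame <- function(seq, frame) {
  n <- nchar(seq)
  if (n - frame + 1L < 3L) return("")
  len <- ((n - frame + 1L) %/% 3L) * 3L
  starts <- seq.int(frame, frame + len - 1L, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

encode_aa <- function(pep, alphabet) {
  x <- strsplit(pep, "", fixed = TRUE)[[1L]]
  codes <- match(x, alphabet)
  codes[is.na(codes)] <- match("X", alphabet)
  codes
}

#' Scan an SV sequence for intact retrotransposon ORFs
#'
#' Translates all six reading frames and locally aligns each translated
#' frame against each peptide model (BLOSUM62 with affine gaps, gap open
#' 11, extend 1). Per model, the best frame is reported with identity
#' counted as exact residue matches over the model length — so a truncated
#' or frameshifted ORF fails on identity/coverage even when its aligned
#' region matches well — plus the model coverage (aligned model span /
#' model length) and a premature-stop flag (a `*` inside the aligned query
#' span). The element is `intact` when every model reaches
#' `min_identity` percent identity and `min_model_cov` coverage with no
#' internal stop.
#'
#' @param sv_seq DNA string of the SV allele.
#' @param models Peptide model tibble from [read_orf_models()].
#' @param min_identity Identity threshold in percent (default 99,
#'   inclusive).
#' @param min_model_cov Model coverage threshold (default 0.99).
#' @return A tibble with one row per model: `orf`, `identity`,
#'   `model_coverage`, `frame` (1-3), `strand`, `premature_stop`,
#'   `orf_pass`, and the overall `intact` verdict repeated on every row.
#' @export
scan_orfs <- function(sv_seq, models, min_identity = 99,
                      min_model_cov = 0.99) {
  sub <- blosum62_matrix()
  alphabet <- rownames(sub)
  empty_row <- function(orf) {
    tibble(orf = orf, identity = 0, model_coverage = 0, frame = NA_integer_,
           strand = NA_character_, premature_stop = NA)
  }
  if (is.na(sv_seq) || nchar(sv_seq) < 3L) {
    out <- bind_rows(lapply(models$name, empty_row))
    out$orf_pass <- FALSE
    out$intact <- FALSE
    return(out)
  }
  frames <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sv_seq else revcomp(sv_seq)
    for (f in 1:3) {
      pep <- translate_frame(s, f)
      if (nchar(pep) == 0L) next
      frames[[length(frames) + 1L]] <- list(strand = strand, frame = f,
                                            pep = pep,
                                            codes = encode_aa(pep, alphabet))
    }
  }
  rows <- lapply(seq_len(nrow(models)), function(m) {
    mcodes <- encode_aa(models$seq[m], alphabet)
    mlen <- models$length[m]
    best <- empty_row(models$name[m])
    best_match <- -1
    for (fr in frames) {
      a <- .sw_align_core(fr$codes, mcodes, sub, 11, 1)
      if (a$n_match > best_match) {
        best_match <- a$n_match
        span <- if (a$aln_len > 0L) {
          substr(fr$pep, a$q_start, a$q_end)
        } else {
          ""
        }
        best <- tibble(
          orf = models$name[m],
          identity = 100 * a$n_match / mlen,
          model_coverage = if (a$aln_len > 0L) {
            (a$t_end - a$t_start + 1L) / mlen
          } else {
            0
          },
          frame = fr$frame, strand = fr$strand,
          premature_stop = grepl("*", span, fixed = TRUE)
        )
      }
    }
    best
  })
  out <- bind_rows(rows)
  out$orf_pass <- out$identity >= min_identity &
    out$model_coverage >= min_model_cov &
    !is.na(out$premature_stop) & !out$premature_stop
  out$intact <- all(out$orf_pass)
  out
}

#' Scan every record of a callset for intact ORFs
#'
#' @param records An SV callset tibble (typically the full-length LINE-1
#'   subset).
#' @param models Peptide model tibble from [read_orf_models()].
#' @param ... Passed to [scan_orfs()].
#' @return A tibble with one row per record x model; `sv_id` keys back to
#'   the callset and `intact` gives the per-record verdict.
#' @export
scan_orfs_callset <- function(records, models, ...) {
  validate_sv_records(records)
  ids <- sv_id(records)
  out <- lapply(seq_len(nrow(records)), function(i) {
    res <- scan_orfs(records$seq[i], models, ...)
    res$sv_id <- ids[i]
    res$sample <- records$sample[i]
    res$svtype <- records$svtype[i]
    res
  })
  bind_rows(out)
}

#' Length of the terminal poly(A) tract of an element
#'
#' Scans inward from the element's 3' terminus with a sliding window
#' (default 12 bp): the tail extends while every window is at least
#' `min_frac` adenine, then the inner boundary is trimmed to the first A.
#' For minus-orientation elements the sequence is reverse-complemented
#' first (a 5' T-tract on the given strand). Tails shorter than `min_len`
#' report 0; the rule tolerates single interruptions (e.g. a terminal
#' `AAAAAAAAGAAA` reports 12).
#'
#' @param sv_seq DNA string of the element allele.
#' @param orientation `"+"` or `"-"` relative to the consensus.
#' @param window Window size in bp (default 12).
#' @param min_frac Minimum A fraction per window (default 0.8).
#' @param min_len Minimum reportable tail length in bp (default 8).
#' @return Integer tail length in bp (0 when below `min_len`).
#' @export
detect_polya <- function(sv_seq, orientation = "+", window = 12L,
                         min_frac = 0.8, min_len = 8L) {
  if (is.na(sv_seq) || nchar(sv_seq) == 0L) return(0L)
  s <- if (orientation == "-") revcomp(sv_seq) else toupper(sv_seq)
  x <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(x)
  w <- min(window, n)
  is_a <- x == "A"
  k <- 0L
  repeat {
    start <- n - w + 1L - k
    if (start < 1L) break
    if (mean(is_a[start:(start + w - 1L)]) < min_frac) break
    k <- k + 1L
  }
  if (k == 0L) return(0L)
  left <- n - w + 1L - (k - 1L)
  while (left <= n && !is_a[left]) left <- left + 1L
  tail_len <- n - left + 1L
  if (tail_len >= min_len) as.integer(tail_len) else 0L
}

#' Detect a target-site duplication from insertion flanks
#'
#' Finds the longest suffix of the left flank (length `min_len` to
#' `max_len`) matching a prefix of the right flank with at most
#' `max_mismatch` mismatches; the longest match wins.
#'
#' @param left_flank,right_flank Reference sequence immediately left/right
#'   of the insertion point (at least `min_len` bp each).
#' @param max_len Maximum TSD length searched (default 30).
#' @param min_len Minimum TSD length (default 5).
#' @param max_mismatch Mismatch tolerance (default 1).
#' @return A one-row tibble `tsd`, `tsd_len`, `mismatches`; `tsd_len = 0`
#'   with `tsd = NA` when no duplication qualifies.
#' @export
detect_tsd <- function(left_flank, right_flank, max_len = 30L, min_len = 5L,
                       max_mismatch = 1L) {
  none <- tibble(tsd = NA_character_, tsd_len = 0L, mismatches = NA_integer_)
  if (nchar(left_flank) < min_len || nchar(right_flank) < min_len) {
    warning("flanks shorter than ", min_len, " bp; no TSD search performed")
    return(none)
  }
  lmax <- min(max_len, nchar(left_flank), nchar(right_flank))
  lchars <- strsplit(toupper(left_flank), "")[[1L]]
  rchars <- strsplit(toupper(right_flank), "")[[1L]]
  nl <- length(lchars)
  for (L in seq(lmax, min_len)) {
    suf <- lchars[(nl - L + 1L):nl]
    pre <- rchars[1:L]
    mm <- sum(suf != pre)
    if (mm <= max_mismatch) {
      return(tibble(tsd = paste(pre, collapse = ""), tsd_len = L,
                    mismatches = as.integer(mm)))
    }
  }
  none
}

#' Per-sample census of intact elements
#'
#' Counts elements with intact ORFs per sample, split by deletion and
#' insertion side.
#'
#' @param orf_scans Output of [scan_orfs_callset()].
#' @param records The scanned callset (unused columns ignored; present for
#'   symmetry and future per-record joins).
#' @return A tibble `sample`, `n_del`, `n_ins`, `total`.
#' @export
intact_census <- function(orf_scans, records = NULL) {
  per_sv <- orf_scans %>%
    distinct(.data$sv_id, .data$sample, .data$svtype, .data$intact)
  per_sv %>%
    filter(.data$intact) %>%
    group_by(.data$sample) %>%
    summarise(n_del = sum(.data$svtype == "DEL"),
              n_ins = sum(.data$svtype == "INS"),
              .groups = "drop") %>%
    mutate(total = .data$n_del + .data$n_ins)
}

#' Fraction of merged loci present in exactly one sample
#'
#' @param clustered A callset tibble with a `cluster` column (e.g. from
#'   [cluster_callsets()] across samples), restricted to the elements of
#'   interest.
#' @return A one-row tibble `n_loci`, `n_singletons`,
#'   `singleton_fraction`.
#' @export
singleton_fraction <- function(clustered) {
  stopifnot("cluster" %in% names(clustered))
  per_locus <- clustered %>%
    group_by(.data$cluster) %>%
    summarise(n_samples = n_distinct(.data$sample), .groups = "drop")
  tibble(n_loci = nrow(per_locus),
         n_singletons = sum(per_locus$n_samples == 1L),
         singleton_fraction = if (nrow(per_locus)) {
           mean(per_locus$n_samples == 1L)
         } else {
           NA_real_
         })
}
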