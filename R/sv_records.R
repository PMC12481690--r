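# Callset data model, VCF I/O, and callset-level filters and summaries.
#
# An SV callset is an ordinary tibble with one row per call:
#   chrom     chromosome name
#   pos       1-based start (VCF convention)
#   end       1-based inclusive end; equals pos for INS and BND
#   svtype    one of DEL, INS, DUP, INV, BND
#   svlen     positive length in bp (NA for BND)
#   seq       allele sequence over {A,C,G,T,N}: deleted sequence for DEL,
#             inserted sequence for INS; NA for symbolic records
#   genotype  "0/0", "0/1", "1/1" or "./."
#   sample    sample identifier
#   modality  one of assembly, long-read, short-read, paragraph
#   filter    free-text filter status
#
# Coordinates are 1-based inclusive [pos, end] throughout; a DEL with seq
# present satisfies nchar(seq) == svlen == end - pos + 1.

SVTYPES <- c("DEL", "INS", "DUP", "INV", "BND")
MODALITIES <- c("assembly", "long-read", "short-read", "paragraph")

#' Construct an SV callset tibble
#'
#' Builds and validates the standard callset tibble used throughout the
#' package. All arguments are recycled to a common length.
#'
#' @param chrom,pos,svtype Required fields.
#' @param end 1-based inclusive end; defaults to `pos` for INS/BND and to
#'   `pos + svlen - 1` for DEL/DUP/INV when `svlen` is given.
#' @param svlen Length in bp; derived from `seq` or `end` when missing.
#' @param seq Allele sequence (`NA` for symbolic records).
#' @param genotype,sample,modality,filter Optional metadata fields.
#' @return A tibble with the columns documented above.
#' @export
#' @examples
#' sv_records("chr1", 100, "DEL", svlen = 50)
sv_records <- function(chrom, pos, svtype, end = NULL, svlen = NULL,
                       seq = NA_character_, genotype = "./.",
                       sample = "sample", modality = "long-read",
                       filter = "PASS") {
  svtype <- as.character(svtype)
  if (!all(svtype %in% SVTYPES)) {
    stop("svtype must be one of ", paste(SVTYPES, collapse = ", "))
  }
  n <- if (length(chrom) == 0L || length(pos) == 0L) {
    0L
  } else {
    max(length(chrom), length(pos), length(svtype),
        length(svlen %||% integer(0)), length(end %||% integer(0)),
        length(seq), length(genotype), length(sample), length(modality))
  }
  genotype <- rep_len(as.character(genotype), n)
  sample <- rep_len(as.character(sample), n)
  modality <- rep_len(as.character(modality), n)
  filter <- rep_len(as.character(filter), n)
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  svtype <- rep_len(svtype, n)
  seq <- rep_len(as.character(seq), n)
  if (!is.null(svlen)) svlen <- rep_len(as.integer(svlen), n)
  if (!is.null(end)) end <- rep_len(as.integer(end), n)
  if (is.null(svlen)) {
    svlen <- ifelse(!is.na(seq), nchar(seq),
                    if (!is.null(end)) {
                      ifelse(svtype != "INS", end - pos + 1L, NA_integer_)
                    } else {
                      NA_integer_
                    })
  }
  if (is.null(end)) {
    end <- ifelse(svtype %in% c("INS", "BND"), pos, pos + svlen - 1L)
  }
  out <- tibble(
    chrom = as.character(chrom), pos = as.integer(pos),
    end = as.integer(end), svtype = svtype,
    svlen = as.integer(svlen), seq = as.character(seq),
    genotype = as.character(genotype), sample = as.character(sample),
    modality = as.character(modality), filter = as.character(filter)
  )
  validate_sv_records(out)
}

validate_sv_records <- function(x) {
  needed <- c("chrom", "pos", "end", "svtype", "svlen", "seq", "genotype",
              "sample", "modality", "filter")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    stop("callset tibble lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  spanning <- x$svtype %in% c("DEL", "DUP", "INV")
  if (any(spanning & x$end < x$pos)) stop("end < pos for a spanning SV")
  with_seq <- !is.na(x$seq)
  bad <- with_seq & nchar(x$seq) != x$svlen
  if (any(bad, na.rm = TRUE)) stop("svlen disagrees with nchar(seq)")
  x
}

# ---- VCF I/O ---------------------------------------------------------------

#' Read an SV callset from a VCF file
#'
#' Parses VCF 4.2 structural-variant records into the callset tibble.
#' Symbolic ALTs (`<DEL>`, `<INS>`, `<DUP>`, `<INV>`) are resolved through
#' the `SVLEN`/`END` INFO keys; sequence-explicit records through their
#' padded REF/ALT alleles. Breakend ALTs become `svtype = "BND"` rows with
#' `svlen = NA`. For a symbolic deletion the convention is
#' `svlen = END - POS + 1`. A symbolic record carrying neither `SVLEN` nor
#' `END` is skipped with a warning; a record that fits no representation is
#' a hard error naming the offending line.
#'
#' @param path VCF file path (plain text).
#' @param sample Sample identifier attached to every record.
#' @param modality Modality label (`assembly`, `long-read`, `short-read`,
#'   `paragraph`).
#' @return An SV callset tibble (see [sv_records()]).
#' @export
read_sv_vcf <- function(path, sample = "sample", modality = "long-read") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(sv_records(character(), integer(), character()))
  gt <- if (ncol(vcf@gt) >= 2L) {
    g <- vcfR::extract.gt(vcf, element = "GT")[, 1L]
    ifelse(is.na(g), "./.", gsub("|", "/", g, fixed = TRUE))
  } else {
    rep("./.", nrow(fix))
  }
  info_get <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(?:^|;)", key, "=([^;]+)"), info,
                                  perl = TRUE))
    if (length(m) == 0L) return(NA_character_)
    sub(paste0("^;?", key, "="), "", m)
  }

  rows <- list()
  for (i in seq_len(nrow(fix))) {
    pos <- as.integer(fix$POS[i])
    ref <- toupper(fix$REF[i])
    info <- if (is.na(fix$INFO[i])) "" else fix$INFO[i]
    filt <- if (is.na(fix$FILTER[i])) "PASS" else fix$FILTER[i]
    alts <- strsplit(toupper(fix$ALT[i]), ",", fixed = TRUE)[[1L]]
    for (alt in alts) {
      parsed <- parse_vcf_allele(pos, ref, alt, info, info_get,
                                 line = i, path = path)
      if (is.null(parsed)) next
      parsed$chrom <- fix$CHROM[i]
      parsed$genotype <- gt[i]
      flagged <- isTRUE(parsed[["flagged"]])
      parsed[["flagged"]] <- NULL
      parsed$filter <- if (flagged) paste0(filt, ";LEN_MISMATCH") else filt
      rows[[length(rows) + 1L]] <- parsed
    }
  }
  if (length(rows) == 0L) return(sv_records(character(), integer(), character()))
  out <- bind_rows(rows)
  out$sample <- sample
  out$modality <- modality
  validate_sv_records(out[, c("chrom", "pos", "end", "svtype", "svlen", "seq",
                              "genotype", "sample", "modality", "filter")])
}

# parse one (POS, REF, ALT) allele into a single-row tibble, or NULL for a
# skippable symbolic record lacking both SVLEN and END
parse_vcf_allele <- function(pos, ref, alt, info, info_get, line, path) {
  svlen_info <- suppressWarnings(abs(as.integer(info_get(info, "SVLEN"))))
  if (grepl("^<(DEL|INS|DUP|INV)>$", alt)) {
    svtype <- sub("^<(.+)>$", "\\1", alt)
    end <- suppressWarnings(as.integer(info_get(info, "END")))
    if (svtype == "INS") {
      if (is.na(svlen_info)) {
        warning("symbolic <INS> without SVLEN skipped at line ", line)
        return(NULL)
      }
      return(tibble(chrom = NA_character_, pos = pos, end = pos,
                    svtype = svtype, svlen = svlen_info, seq = NA_character_))
    }
    if (is.na(end) && is.na(svlen_info)) {
      warning("symbolic <", svtype, "> lacking both SVLEN and END skipped ",
              "at line ", line)
      return(NULL)
    }
    if (is.na(end)) end <- pos + svlen_info - 1L
    return(tibble(chrom = NA_character_, pos = pos, end = end, svtype = svtype,
                  svlen = end - pos + 1L, seq = NA_character_))
  }
  if (grepl("[\\[\\]]", alt) || identical(info_get(info, "SVTYPE"), "BND")) {
    return(tibble(chrom = NA_character_, pos = pos, end = pos, svtype = "BND",
                  svlen = NA_integer_, seq = NA_character_))
  }
  if (nchar(ref) > 1L && nchar(alt) == 1L) {
    seq <- substr(ref, 2L, nchar(ref))
    svlen <- nchar(seq)
    del_pos <- pos + 1L # padding base precedes the deleted bases
    out <- tibble(chrom = NA_character_, pos = del_pos,
                  end = del_pos + svlen - 1L, svtype = "DEL",
                  svlen = svlen, seq = seq)
    # symbolic metadata may disagree with the explicit allele; seq wins
    if (!is.na(svlen_info) && abs(svlen_info - svlen) > 1L) {
      out$flagged <- TRUE
    }
    return(out)
  }
  if (nchar(alt) > 1L && nchar(ref) == 1L) {
    seq <- substr(alt, 2L, nchar(alt))
    return(tibble(chrom = NA_character_, pos = pos, end = pos, svtype = "INS",
                  svlen = nchar(seq), seq = seq))
  }
  stop("unparseable SV record at line ", line, " of ", path,
       " (REF=", ref, ", ALT=", alt, ")")
}

#' Write an SV callset to a VCF file
#'
#' Inverse of [read_sv_vcf()]: sequence-resolved DEL/INS records are written
#' as padded REF/ALT alleles, everything else as symbolic ALTs with
#' `SVTYPE`, `SVLEN` and `END` INFO keys. Coordinates follow the VCF
#' convention (1-based; the padding base precedes a sequence-explicit
#' deletion), stated in the header.
#'
#' @param records An SV callset tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(records, path) {
  validate_sv_records(records)
  sample_name <- if (nrow(records)) unique(records$sample) else "sample"
  if (length(sample_name) != 1L) {
    stop("write_sv_vcf() writes single-sample VCFs; split by sample first")
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=svdimorph",
    "##coordinates=1-based inclusive; padding base precedes explicit indels",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"1-based inclusive end\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  body <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$svtype == "DEL" && !is.na(r$seq)) {
      pos <- r$pos - 1L; ref <- paste0("N", r$seq); alt <- "N"
    } else if (r$svtype == "INS" && !is.na(r$seq)) {
      pos <- r$pos; ref <- "N"; alt <- paste0("N", r$seq)
    } else if (r$svtype == "BND") {
      pos <- r$pos; ref <- "N"; alt <- paste0("N[", r$chrom, ":", r$pos, "[")
    } else {
      pos <- r$pos; ref <- "N"; alt <- paste0("<", r$svtype, ">")
    }
    info <- paste0("SVTYPE=", r$svtype)
    if (!is.na(r$svlen)) {
      slen <- if (r$svtype == "DEL") -r$svlen else r$svlen
      info <- paste0(info, ";SVLEN=", slen, ";END=", r$end)
    }
    body[i] <- paste(r$chrom, pos, ".", ref, alt, ".", r$filter, info, "GT",
                     r$genotype, sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- filters ---------------------------------------------------------------

#' Apply the standard callset-level filters
#'
#' Drops, in order: breakend (BND) records; homozygous-reference calls
#' (genotype `0/0`; missing `./.` is retained); insertions whose sequence
#' contains one or more `N` (unassembled or gap sequence); records shorter
#' than `min_len` (default 50 bp); records longer than `max_len` (default
#' 10 Mb, matching the caller-side deletion cap). The survivors are sorted
#' by `(chrom, pos)` and exact duplicates — identical
#' `(chrom, pos, svtype, svlen, seq)` — collapse to the first occurrence.
#' The function is idempotent and total (no errors).
#'
#' @param records An SV callset tibble.
#' @param min_len,max_len Length bounds in bp, both inclusive survivors.
#' @return The filtered, sorted, deduplicated callset tibble.
#' @export
filter_callset <- function(records, min_len = 50L, max_len = 10000000L) {
  validate_sv_records(records)
  records %>%
    filter(.data$svtype != "BND") %>%
    filter(.data$genotype != "0/0") %>%
    filter(!(.data$svtype == "INS" & !is.na(.data$seq) &
               grepl("N", .data$seq, fixed = TRUE))) %>%
    filter(!is.na(.data$svlen), .data$svlen >= min_len,
           .data$svlen <= max_len) %>%
    arrange(.data$chrom, .data$pos) %>%
    distinct(.data$chrom, .data$pos, .data$svtype, .data$svlen, .data$seq,
             .keep_all = TRUE)
}

#' Restrict a callset to a set of chromosomes
#'
#' @param records An SV callset tibble.
#' @param allowed Character vector of chromosome names to keep (e.g.
#'   `paste0("chr", c(1:38, "X"))` for the canine assembled chromosomes).
#' @return The callset restricted to `allowed`, input order preserved.
#' @export
restrict_chromosomes <- function(records, allowed) {
  records[records$chrom %in% allowed, , drop = FALSE]
}

#' Canine assembled chromosomes (chr1-chr38 and chrX)
#' @return Character vector of chromosome names.
#' @export
canine_autosomes_x <- function() paste0("chr", c(1:38, "X"))

# ---- summaries -------------------------------------------------------------

#' Summarize a callset by SV type
#'
#' Per-svtype counts, impacted base pairs (sum of `svlen`) and the
#' heterozygous fraction `#0/1 / (#0/1 + #1/1)` among genotyped records
#' (NA when no records are genotyped, never 0).
#'
#' @param records An SV callset tibble.
#' @return A tibble with columns `svtype`, `n`, `bp`, `het_frac`.
#' @export
summarize_callset <- function(records) {
  validate_sv_records(records)
  records %>%
    group_by(.data$svtype) %>%
    summarise(
      n = n(),
      bp = sum(.data$svlen, na.rm = TRUE),
      het_frac = {
        het <- sum(.data$genotype == "0/1")
        hom <- sum(.data$genotype == "1/1")
        if (het + hom == 0L) NA_real_ else het / (het + hom)
      },
      .groups = "drop"
    )
}

#' Length histogram of a callset
#'
#' @param records An SV callset tibble.
#' @param breaks Right-closed bin breaks in bp covering all lengths.
#' @return A tibble `svtype`, `bin`, `n`; within each svtype the bin counts
#'   sum to the svtype count.
#' @export
length_histogram <- function(records,
                             breaks = c(0, 100, 250, 500, 1000, 2500, 5000,
                                        10000, Inf)) {
  validate_sv_records(records)
  records %>%
    filter(!is.na(.data$svlen)) %>%
    mutate(bin = cut(.data$svlen, breaks = breaks, include.lowest = TRUE)) %>%
    count(.data$svtype, .data$bin, .drop = FALSE, name = "n") %>%
    as_tibble()
}
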