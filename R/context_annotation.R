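# Gene-context annotation of scan hits (exonic / intronic / intergenic)
# and per-record sequence-context metrics (low-complexity / tandem-repeat
# content, clustered-insertion proximity).

#' Read a gene model from GFF3 or BED
#'
#' GFF3: `gene` features (named by `ID`, `gene_id` or `Name`) and `exon`
#' features (attached to their gene by `Parent` or `gene_id`). BED: each
#' interval is an exon, the `name` column its gene; the gene span is the
#' range of its exons. Coordinates are returned 1-based inclusive.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED file path.
#' @return A tibble `gene`, `chrom`, `start`, `end`, `type`
#'   (`gene`/`exon`).
#' @export
read_gene_model <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    exons <- tibble(gene = gr$name %||% paste0("gene", seq_along(gr)),
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr), type = "exon")
    genes <- exons %>%
      group_by(.data$gene, .data$chrom) %>%
      summarise(start = min(.data$start), end = max(.data$end),
                .groups = "drop") %>%
      mutate(type = "gene")
    out <- bind_rows(genes, exons)
  } else {
    gr <- rtracklayer::import(path, format = "GFF3")
    df <- as.data.frame(gr)
    pick <- function(...) {
      cols <- list(...)
      out <- rep(NA_character_, nrow(df))
      for (cl in cols) {
        if (is.null(cl)) next
        v <- if (is.atomic(cl)) {
          as.character(cl)
        } else {
          vapply(as.list(cl), function(x) {
            if (length(x)) as.character(x[[1L]]) else NA_character_
          }, character(1))
        }
        out <- ifelse(is.na(out), v, out)
      }
      out
    }
    name <- pick(df$ID, df$gene_id, df$Name)
    parent <- pick(df$Parent, df$gene_id)
    out <- tibble(
      gene = ifelse(df$type == "gene", name, parent),
      chrom = as.character(df$seqnames),
      start = df$start, end = df$end,
      type = as.character(df$type)
    ) %>%
      filter(.data$type %in% c("gene", "exon"))
  }
  if (any(is.na(out$gene)) || any(out$end < out$start)) {
    stop("malformed gene model in ", path)
  }
  out
}

overlaps <- function(s1, e1, s2, e2) s1 <= e2 & e1 >= s2

#' Label hits by gene context
#'
#' Each hit becomes `exonic` when it overlaps an exon by at least 1 bp or
#' spans an entire gene (full feature ablation — the two conditions under
#' which an SV is considered to affect the gene), `intronic` when inside a
#' gene without touching an exon, and `intergenic` otherwise. Overlapping
#' gene symbols are attached (comma-separated).
#'
#' @param hits A tibble with `chrom`, `pos`, `end` columns (1-based
#'   inclusive), e.g. scan hits joined back to their SV records.
#' @param gene_model Tibble from [read_gene_model()].
#' @return `hits` with added `context` and `genes` columns.
#' @export
annotate_hits_genes <- function(hits, gene_model) {
  genes <- gene_model[gene_model$type == "gene", , drop = FALSE]
  exons <- gene_model[gene_model$type == "exon", , drop = FALSE]
  context <- character(nrow(hits))
  gene_lab <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    g_ov <- genes[genes$chrom == h$chrom &
                    overlaps(h$pos, h$end, genes$start, genes$end), ]
    e_ov <- exons[exons$chrom == h$chrom &
                    overlaps(h$pos, h$end, exons$start, exons$end), ]
    ablation <- any(h$pos <= g_ov$start & h$end >= g_ov$end)
    context[i] <- if (nrow(e_ov) > 0L || ablation) {
      "exonic"
    } else if (nrow(g_ov) > 0L) {
      "intronic"
    } else {
      "intergenic"
    }
    gene_lab[i] <- paste(unique(c(g_ov$gene, e_ov$gene)), collapse = ",")
  }
  hits$context <- context
  hits$genes <- ifelse(gene_lab == "", NA_character_, gene_lab)
  hits
}

#' Low-complexity / tandem-repeat fraction of an allele sequence
#'
#' Unions two detectors: DUST-style windowed triplet scoring (64 bp
#' windows, stride 16, a window is low complexity when
#' `sum c(c-1)/2 / (L-3) >= threshold` over its triplet counts) and exact
#' tandem arrays of motif length 1-6 with at least two full copies and a
#' minimum array length of 8 bp. Returns covered bp / allele length.
#'
#' @param seq DNA string.
#' @param dust_threshold DUST score threshold (default 2).
#' @param window,stride DUST window geometry in bp.
#' @return Fraction in `[0, 1]`.
#' @export
low_complexity_fraction <- function(seq, dust_threshold = 2, window = 64L,
                                    stride = 16L) {
  if (is.na(seq) || nchar(seq) == 0L) return(0)
  x <- strsplit(toupper(seq), "")[[1L]]
  n <- length(x)
  starts <- integer(0); ends <- integer(0)
  # DUST windows
  if (n >= 8L) {
    w <- min(window, n)
    for (s in unique(c(seq(1L, max(1L, n - w + 1L), by = stride),
                       n - w + 1L))) {
      win <- x[s:(s + w - 1L)]
      tri <- paste0(win[1:(w - 2L)], win[2:(w - 1L)], win[3:w])
      cnt <- table(tri)
      score <- sum(cnt * (cnt - 1) / 2) / (w - 3L)
      if (score >= dust_threshold) {
        starts <- c(starts, s); ends <- c(ends, s + w - 1L)
      }
    }
  }
  # exact tandem arrays, motif length 1-6
  for (m in 1:6) {
    if (n < 2L * m) next
    same <- c(rep(FALSE, m), x[(m + 1L):n] == x[1:(n - m)])
    r <- rle(same)
    stop_at <- cumsum(r$lengths)
    for (j in seq_along(r$lengths)) {
      if (!r$values[j]) next
      run <- r$lengths[j]
      arr_len <- run + m
      if (run >= m && arr_len >= 8L) {
        e <- stop_at[j]
        starts <- c(starts, e - arr_len + 1L); ends <- c(ends, e)
      }
    }
  }
  interval_union_width(starts, ends, bound = n) / n
}

#' Sequence- and proximity-context flags for a callset
#'
#' Computes, per record, the low-complexity/tandem-repeat fraction of the
#' allele sequence (flagged above `lc_threshold`, exclusive, default 0.70)
#' and the distance to the nearest same-type neighbour on the same
#' chromosome (flagged at `neighbor_window` bp or less, default 25).
#'
#' @param records An SV callset tibble.
#' @param lc_threshold Flag alleles with fraction strictly above this.
#' @param neighbor_window Neighbour distance flag threshold in bp.
#' @return `records` with added `lc_fraction`, `lc_flag`,
#'   `neighbor_dist`, `neighbor_flag` columns.
#' @export
callset_context <- function(records, lc_threshold = 0.70,
                            neighbor_window = 25L) {
  validate_sv_records(records)
  records$lc_fraction <- vapply(records$seq, low_complexity_fraction,
                                double(1), USE.NAMES = FALSE)
  records$lc_flag <- records$lc_fraction > lc_threshold
  nd <- rep(NA_real_, nrow(records))
  idx <- seq_len(nrow(records))
  for (block in split(idx, paste(records$chrom, records$svtype))) {
    if (length(block) < 2L) next
    o <- block[order(records$pos[block])]
    pos <- records$pos[o]
    gaps <- diff(pos)
    nd[o] <- pmin(c(Inf, gaps), c(gaps, Inf))
  }
  records$neighbor_dist <- nd
  records$neighbor_flag <- !is.na(nd) & nd <= neighbor_window
  records
}
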