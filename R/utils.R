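# Internal sequence helpers.  Sequences are plain uppercase character
# scalars over {A,C,G,T,N}; Biostrings containers are used at the I/O
# boundary only.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Reverse complement of a DNA string
#'
#' @param seq Character scalar over `{A,C,G,T,N}`.
#' @return Character scalar, the reverse complement.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# encode a DNA string as 1-based integer codes into DNA_ALPHABET
encode_dna <- function(seq) {
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  codes <- match(x, DNA_ALPHABET)
  if (anyNA(codes)) {
    bad <- unique(x[is.na(codes)])
    stop("sequence contains non-ACGTN symbols: ", paste(bad, collapse = ", "))
  }
  codes
}

# blastn-like DNA scoring matrix; N scores as a mismatch against everything
dna_submat <- function(match = 2, mismatch = -3) {
  m <- matrix(mismatch, 5L, 5L, dimnames = list(DNA_ALPHABET, DNA_ALPHABET))
  diag(m) <- match
  m["N", ] <- mismatch
  m[, "N"] <- mismatch
  m
}

# total length of the union of 1-based inclusive intervals, optionally
# restricted to [1, bound] and excluding `exclude` positions (an IRanges)
interval_union_width <- function(starts, ends, bound = NULL, exclude = NULL) {
  if (length(starts) == 0L) return(0L)
  ir <- IRanges::IRanges(start = starts, end = ends)
  if (!is.null(bound)) {
    ir <- IRanges::restrict(ir, start = 1L, end = as.integer(bound))
  }
  ir <- IRanges::reduce(ir)
  if (!is.null(exclude) && length(exclude) > 0L) {
    ir <- IRanges::setdiff(ir, exclude)
  }
  sum(IRanges::width(ir))
}

# deterministic RNG scope: evaluates `expr` under set.seed(seed) and
# restores the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
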