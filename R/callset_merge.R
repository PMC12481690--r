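# Breakpoint-proximity clustering of SV calls within and across callsets,
# representative selection, and between-modality concordance.
#
# Two merge predicates are used:
#   * the strict predicate (cluster_callsets, concordance): same chromosome,
#     same svtype when required, both breakpoints within max_dist bp; for
#     insertions end == pos, plus a length-ratio >= 0.5 guard so a 60 bp and
#     a 6 kb insertion at one spot never merge;
#   * the relaxed predicate (merge_loci): the strict 15 bp rule OR relative
#     rules scaled by L = max(svlen of the pair): breakpoint shift <=
#     rel_shift*L, size difference <= rel_size_diff*L and nearest-breakpoint
#     distance <= rel_dist*L.
# Clusters are single-linkage connected components, so distant calls can
# chain through intermediates.

#' Merge parameter set
#'
#' Defaults follow the strict callset-comparison stage: breakpoints within
#' 100 bp, matching SV type required, minimum size 50 bp, and relative
#' second-stage fractions of 0.1.
#'
#' @param max_dist Breakpoint proximity window in bp.
#' @param require_type_match Must both records share `svtype`?
#' @param min_size Minimum `svlen` in bp considered for merging.
#' @param rel_dist,rel_size_diff,rel_shift Dimensionless fractions in
#'   `[0, 1]` used by the relaxed locus-merging predicate.
#' @param ins_ratio Minimum `min(svlen)/max(svlen)` for a pair of
#'   insertions to match under the strict predicate.
#' @return A list of class `merge_params`.
#' @export
merge_params <- function(max_dist = 100, require_type_match = TRUE,
                         min_size = 50, rel_dist = 0.1, rel_size_diff = 0.1,
                         rel_shift = 0.1, ins_ratio = 0.5) {
  stopifnot(max_dist >= 0, min_size >= 0,
            rel_dist >= 0, rel_dist <= 1,
            rel_size_diff >= 0, rel_size_diff <= 1,
            rel_shift >= 0, rel_shift <= 1)
  structure(list(max_dist = max_dist,
                 require_type_match = isTRUE(require_type_match),
                 min_size = min_size, rel_dist = rel_dist,
                 rel_size_diff = rel_size_diff, rel_shift = rel_shift,
                 ins_ratio = ins_ratio),
            class = "merge_params")
}

# effective end for matching: insertions are points
match_end <- function(end, pos, svtype) ifelse(svtype == "INS", pos, end)

#' Do two SV records match under the strict merge predicate?
#'
#' Symmetric in its two arguments. Records on different chromosomes return
#' `FALSE` (not an error). Vectorised over rows when `a` and `b` have equal
#' row counts.
#'
#' @param a,b Single-row (or equal-length) SV callset tibbles.
#' @param params A [merge_params()] object.
#' @return Logical vector.
#' @export
pair_matches <- function(a, b, params = merge_params()) {
  ok <- a$chrom == b$chrom
  if (params$require_type_match) ok <- ok & a$svtype == b$svtype
  ea <- match_end(a$end, a$pos, a$svtype)
  eb <- match_end(b$end, b$pos, b$svtype)
  ok <- ok & abs(a$pos - b$pos) <= params$max_dist &
    abs(ea - eb) <= params$max_dist
  both_ins <- a$svtype == "INS" & b$svtype == "INS"
  ratio <- pmin(a$svlen, b$svlen) / pmax(a$svlen, b$svlen)
  ok & (!both_ins | (!is.na(ratio) & ratio >= params$ins_ratio))
}

# relaxed predicate used by merge_loci(); max_dist here is the strict 15 bp
# window and the rel_* fractions scale with L = max(svlen)
pair_matches_relaxed <- function(a, b, params) {
  ok <- a$chrom == b$chrom
  if (params$require_type_match) ok <- ok & a$svtype == b$svtype
  ea <- match_end(a$end, a$pos, a$svtype)
  eb <- match_end(b$end, b$pos, b$svtype)
  dstart <- abs(a$pos - b$pos)
  dend <- abs(ea - eb)
  strict <- dstart <= params$max_dist & dend <= params$max_dist
  L <- pmax(a$svlen, b$svlen)
  relaxed <- pmax(dstart, dend) <= params$rel_shift * L &
    abs(a$svlen - b$svlen) <= params$rel_size_diff * L &
    pmin(dstart, dend) <= params$rel_dist * L
  ok & (strict | relaxed)
}

# single-linkage connected components under a pairwise predicate.
# Candidate pairs are restricted to (chrom [, svtype]) blocks and, within a
# block sorted by pos, to start distances within `window` bp, which bounds
# the strict predicate and the relaxed one via window = max svlen scaling.
cluster_components <- function(records, params, predicate) {
  n <- nrow(records)
  if (n == 0L) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  key <- if (params$require_type_match) {
    paste(records$chrom, records$svtype)
  } else {
    records$chrom
  }
  max_window <- max(params$max_dist,
                    params$rel_shift * max(records$svlen, 0, na.rm = TRUE))
  for (block in split(seq_len(n), key)) {
    idx <- block[order(records$pos[block])]
    m <- length(idx)
    if (m < 2L) next
    pos <- records$pos[idx]
    # candidate pairs: start distance within the predicate's reach
    I <- integer(0); J <- integer(0)
    for (ii in seq_len(m - 1L)) {
      jj <- which(pos[(ii + 1L):m] - pos[ii] <= max_window)
      if (length(jj)) {
        I <- c(I, rep.int(ii, length(jj)))
        J <- c(J, ii + jj)
      }
    }
    if (length(I) == 0L) next
    ok <- predicate(records[idx[I], , drop = FALSE],
                    records[idx[J], , drop = FALSE], params)
    for (p in which(ok)) unite(idx[I[p]], idx[J[p]])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots[order(records$chrom, records$pos)]))
}

#' Cluster one or more callsets into merge clusters
#'
#' Single-linkage connected components of the strict pairwise match graph.
#' Every record lands in exactly one cluster; singletons are kept (minimum
#' caller support 0). The result is deterministic and invariant to input
#' order.
#'
#' @param callsets A single SV callset tibble or a list of them.
#' @param params A [merge_params()] object.
#' @return The row-bound input with a `cluster` integer column.
#' @export
cluster_callsets <- function(callsets, params = merge_params()) {
  records <- if (is.data.frame(callsets)) callsets else bind_rows(callsets)
  validate_sv_records(records)
  records <- records[is.na(records$svlen) | records$svlen >= params$min_size, ]
  records$cluster <- cluster_components(records, params, pair_matches)
  records
}

#' Pick the representative record of a cluster
#'
#' Deterministic priority: sequence-resolved over symbolic; then modality
#' quality (`long-read` > `assembly` > `paragraph` > `short-read`); then
#' longest `svlen`; ties broken by `(chrom, pos, svlen)` order. The
#' representative keeps its own genotype.
#'
#' @param members An SV callset tibble (one cluster's members).
#' @return A single-row tibble, one of `members`.
#' @export
select_representative <- function(members) {
  stopifnot(nrow(members) >= 1L)
  modality_rank <- match(members$modality,
                         c("long-read", "assembly", "paragraph", "short-read"))
  modality_rank[is.na(modality_rank)] <- 5L
  ord <- order(is.na(members$seq),        # sequence-resolved first
               modality_rank,
               -members$svlen,
               members$chrom, members$pos, members$svlen)
  members[ord[1L], , drop = FALSE]
}

#' One representative per cluster
#'
#' @param clustered Output of [cluster_callsets()] or [merge_loci()]'s
#'   clustered form: a callset tibble with a `cluster` column.
#' @return A callset tibble of representatives, one row per cluster, with
#'   `cluster` and `n_members` columns and per-modality support counts in a
#'   nested `support` list-column.
#' @export
cluster_representatives <- function(clustered) {
  stopifnot("cluster" %in% names(clustered))
  clustered %>%
    group_by(.data$cluster) %>%
    group_modify(function(df, key) {
      rep <- select_representative(df)
      rep$n_members <- nrow(df)
      rep$support <- list(table(df$modality))
      rep
    }) %>%
    ungroup()
}

#' Merge within-sample loci with the relaxed predicate
#'
#' Clusters records with the relaxed two-stage rule — breakpoints within
#' `max_dist` bp (default 15), or relative agreement scaled by the longer
#' record: shift `<= rel_shift * L`, size difference `<= rel_size_diff * L`
#' and distance `<= rel_dist * L` — then emits one representative per
#' cluster. Idempotent on its own output.
#'
#' @param records An SV callset tibble (one sample, any modalities).
#' @param max_dist Strict breakpoint window in bp (default 15).
#' @param rel_dist,rel_size_diff,rel_shift Relative fractions (default 0.1).
#' @return A callset tibble of representative records.
#' @export
merge_loci <- function(records, max_dist = 15, rel_dist = 0.1,
                       rel_size_diff = 0.1, rel_shift = 0.1) {
  validate_sv_records(records)
  params <- merge_params(max_dist = max_dist, rel_dist = rel_dist,
                         rel_size_diff = rel_size_diff, rel_shift = rel_shift,
                         min_size = 0)
  records$cluster <- cluster_components(records, params, pair_matches_relaxed)
  out <- cluster_representatives(records)
  out$n_members <- NULL
  out$support <- NULL
  out$cluster <- NULL
  arrange(out, .data$chrom, .data$pos)
}

#' Between-callset concordance
#'
#' Fraction of records in each callset matched by at least one record of
#' the other under the strict predicate with breakpoints within `window`
#' bp. A record matched by several partners counts once.
#'
#' @param a,b SV callset tibbles on the same reference.
#' @param window Breakpoint window in bp (default 100).
#' @param require_type_match Must matched records share `svtype`?
#' @return A tibble with one row: `frac_a_in_b`, `frac_b_in_a` (both in
#'   `[0, 1]`, `NA` for an empty set), `n_a`, `n_b`.
#' @export
concordance <- function(a, b, window = 100, require_type_match = TRUE) {
  params <- merge_params(max_dist = window,
                         require_type_match = require_type_match,
                         min_size = 0)
  matched_in <- function(x, y) {
    if (nrow(x) == 0L) return(NA_real_)
    if (nrow(y) == 0L) return(0)
    hit <- vapply(seq_len(nrow(x)), function(i) {
      xi <- x[rep(i, nrow(y)), , drop = FALSE]
      any(pair_matches(xi, y, params))
    }, logical(1))
    mean(hit)
  }
  tibble(frac_a_in_b = matched_in(a, b), frac_b_in_a = matched_in(b, a),
         n_a = nrow(a), n_b = nrow(b))
}
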