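# Non-reference sequence (NRS) extraction: the map-to-pan filter chain
# applied to contig-versus-reference alignment records.

#' Filter assembled contigs by length
#'
#' Retains contigs strictly longer than `min_len` (a 500 bp contig is
#' discarded at the default).
#'
#' @param contigs Named character vector or `DNAStringSet` of contig
#'   sequences.
#' @param min_len Minimum length in bp (strict inequality).
#' @return Named character vector of retained contigs.
#' @export
filter_contigs <- function(contigs, min_len = 500) {
  seqs <- as_seq_chr(contigs)
  seqs[nchar(seqs) > min_len]
}

#' Extract non-reference sequences from contig alignments
#'
#' Applies the NRS filter chain: alignment records are kept only when
#' strictly longer than `min_aln_len` with identity strictly above
#' `min_identity`; contigs with no surviving alignment are emitted whole
#' (`unaligned_contig`), and for aligned contigs the maximal query
#' intervals untouched by any surviving alignment and strictly longer
#' than `min_unaligned` are emitted as `unaligned_region`. Overlapping
#' surviving alignments are flattened (union) on the query before
#' computing unaligned intervals.
#'
#' @param contigs Named character vector or `DNAStringSet` (already
#'   length-filtered, or not — no length filter is applied here).
#' @param alignments Tibble of alignment records as returned by
#'   [read_paf()]; `query_id` must name contigs. Records whose query
#'   coordinates exceed the contig length are rejected with a warning.
#' @param min_aln_len Minimum surviving alignment length (strict).
#' @param min_identity Minimum surviving alignment identity (strict).
#' @param min_unaligned Minimum emitted unaligned-region length
#'   (strict).
#' @return A tibble (class `nrs_set`) with columns `nrs_id`,
#'   `source_contig`, `provenance` (`unaligned_contig` /
#'   `unaligned_region`), `start`, `end` (0-based half-open on the
#'   contig) and `seq`. The number of rejected alignment records is
#'   attached as attribute `n_rejected`.
#' @export
extract_nrs <- function(contigs, alignments, min_aln_len = 300,
                        min_identity = 0.90, min_unaligned = 500) {
  seqs <- as_seq_chr(contigs)
  stopifnot(all(c("query_id", "query_start", "query_end", "identity") %in%
                  names(alignments)))
  aln <- as_tibble(alignments)
  aln <- aln[aln$query_id %in% names(seqs), , drop = FALSE]
  clen <- nchar(seqs)[aln$query_id]
  bad <- aln$query_start < 0 | aln$query_end > clen |
    aln$query_start >= aln$query_end
  n_rejected <- sum(bad)
  if (n_rejected > 0) {
    warning("extract_nrs: rejected ", n_rejected,
            " alignment record(s) with coordinates outside the contig")
    aln <- aln[!bad, , drop = FALSE]
  }
  surviving <- aln[(aln$query_end - aln$query_start) > min_aln_len &
                     aln$identity > min_identity, , drop = FALSE]
  covered <- split(surviving, surviving$query_id)
  rows <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    cid <- names(seqs)[i]
    len <- nchar(seqs[[i]])
    cov <- covered[[cid]]
    if (is.null(cov) || nrow(cov) == 0) {
      rows[[i]] <- tibble(nrs_id = paste0(cid, ":whole"),
                          source_contig = cid,
                          provenance = "unaligned_contig",
                          start = 0L, end = len)
      next
    }
    flat <- IRanges::reduce(IRanges::IRanges(start = cov$query_start + 1L,
                                             end = cov$query_end))
    gaps <- IRanges::gaps(flat, start = 1L, end = len)
    if (length(gaps) == 0) next
    gs <- IRanges::start(gaps) - 1L
    ge <- IRanges::end(gaps)
    keep <- (ge - gs) > min_unaligned
    if (!any(keep)) next
    rows[[i]] <- tibble(nrs_id = sprintf("%s:%d-%d", cid, gs[keep], ge[keep]),
                        source_contig = cid,
                        provenance = "unaligned_region",
                        start = gs[keep], end = ge[keep])
  }
  out <- bind_rows(rows)
  if (nrow(out) > 0) {
    out$seq <- unname(substr(seqs[out$source_contig], out$start + 1L,
                             out$end))
  } else {
    out <- tibble(nrs_id = character(), source_contig = character(),
                  provenance = character(), start = integer(),
                  end = integer(), seq = character())
  }
  out <- arrange(out, .data$source_contig, .data$start)
  attr(out, "n_rejected") <- n_rejected
  class(out) <- c("nrs_set", class(out))
  out
}

#' Remove redundant sequences by greedy centroid clustering
#'
#' A deterministic single-pass reimplementation of redundancy removal:
#' sequences are visited in order of decreasing length; each joins the
#' first centroid with which its k-mer containment identity (fraction
#' of the shorter sequence's distinct canonical k-mers found in the
#' centroid) is at least `identity` over at least `coverage` of the
#' shorter sequence; otherwise it founds a new centroid. Only centroids
#' (cluster representatives) are returned.
#'
#' Candidate pairs are prefiltered by k-mer containment and confirmed
#' by pairwise alignment, so a few percent of substitution divergence
#' still clusters while unrelated sequences never do.
#'
#' @param nrs An `nrs_set` tibble from [extract_nrs()], or any tibble
#'   with `nrs_id` and `seq` columns, or a named character vector.
#' @param identity Minimum alignment identity.
#' @param coverage Minimum covered fraction of the shorter sequence.
#' @param k K-mer size used for the containment prefilter.
#' @return The input rows that were kept as representatives, with a
#'   `cluster` column; attribute `members` maps every input id to its
#'   representative.
#' @export
dedup_nrs <- function(nrs, identity = 0.90, coverage = 0.90, k = 15) {
  if (is.character(nrs)) {
    nrs <- tibble(nrs_id = names(as_seq_chr(nrs)), seq = as_seq_chr(nrs))
  }
  stopifnot(all(c("nrs_id", "seq") %in% names(nrs)))
  assign <- greedy_cluster(nrs$seq, identity = identity,
                           coverage = coverage, k = k)
  reps <- sort(unique(assign))
  out <- nrs[reps, , drop = FALSE]
  out$cluster <- seq_along(reps)
  attr(out, "members") <- tibble(nrs_id = nrs$nrs_id,
                                 representative = nrs$nrs_id[assign])
  out
}
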