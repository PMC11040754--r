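# Naive exact-seed chaining aligner. Serves the synthetic-scale tests
# of the loss-tracing and retention analyses; real data should use a
# dedicated aligner and be imported as PAF records.

#' Align query sequences to a genome by exact-seed chaining
#'
#' Finds exact forward-strand k-mer seed matches of each query in the
#' target sequences, groups them into diagonals (within
#' `diag_tolerance`), and emits one ungapped alignment record per
#' seed chain with at least `min_seeds` seeds. Identity is estimated
#' as the fraction of query seed positions supported within the chain.
#' Reverse-complement matches are found by aligning the
#' reverse-complemented query as well (records are reported on the
#' forward query coordinates with `strand = "-"`).
#'
#' @param queries Named character vector (or `DNAStringSet`) of query
#'   sequences (e.g. gene sequences).
#' @param target Named character vector (or `DNAStringSet`) of target
#'   chromosome sequences.
#' @param k Seed length.
#' @param diag_tolerance Maximum diagonal shift within one chain
#'   (absorbs small indels).
#' @param min_seeds Minimum seeds per reported chain.
#' @return Tibble of alignment records: `query_id`, `query_len`,
#'   `query_start`, `query_end`, `strand`, `target_id`,
#'   `target_start`, `target_end`, `n_seeds`, `identity`.
#' @export
naive_align <- function(queries, target, k = 31, diag_tolerance = 30,
                        min_seeds = 3) {
  qs <- as_seq_chr(queries)
  ts <- as_seq_chr(target)
  chain_records <- function(hits, qid, qlen, strand) {
    if (nrow(hits) == 0) return(NULL)
    hits$diag <- hits$tpos - hits$qpos
    out <- list()
    for (tgt in unique(hits$target)) {
      h <- hits[hits$target == tgt, ]
      h <- h[order(h$diag, h$qpos), ]
      brk <- c(TRUE, diff(h$diag) > diag_tolerance)
      grp <- cumsum(brk)
      for (g in unique(grp)) {
        hg <- h[grp == g, ]
        if (nrow(hg) < min_seeds) next
        q0 <- min(hg$qpos)
        q1 <- max(hg$qpos) + k
        out[[length(out) + 1L]] <- tibble(
          query_id = qid, query_len = qlen,
          query_start = if (strand == "+") q0 else qlen - q1,
          query_end = if (strand == "+") q1 else qlen - q0,
          strand = strand,
          target_id = names(ts)[tgt],
          target_start = min(hg$tpos),
          target_end = max(hg$tpos) + k,
          n_seeds = nrow(hg),
          identity = min(1, nrow(hg) / max(1, q1 - q0 - k + 1))
        )
      }
    }
    if (length(out) == 0) NULL else bind_rows(out)
  }
  fwd <- cpp_seed_hits(unname(qs), unname(ts), as.integer(k))
  rev <- cpp_seed_hits(revcomp_chr(unname(qs)), unname(ts), as.integer(k))
  rows <- lapply(seq_along(qs), function(i) {
    bind_rows(
      chain_records(as_tibble(fwd[[i]]), names(qs)[i], nchar(qs[[i]]), "+"),
      chain_records(as_tibble(rev[[i]]), names(qs)[i], nchar(qs[[i]]), "-")
    )
  })
  out <- bind_rows(rows)
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(query_id = character(), query_len = integer(),
                  query_start = integer(), query_end = integer(),
                  strand = character(), target_id = character(),
                  target_start = integer(), target_end = integer(),
                  n_seeds = integer(), identity = numeric()))
  }
  arrange(out, .data$query_id, .data$target_id, .data$target_start)
}
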