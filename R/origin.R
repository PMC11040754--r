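# Nascent-versus-lost classification of genome-specific sequence after
# polyploidization: fragmentation, fragment mapping, unmapped-region
# merging, pangenome subtraction, genome-specific k-mer masking, and a
# permutation test for distance-to-gene enrichment.

#' Split a genome into fixed-size fragments
#'
#' Runs of `N` bases are removed first; the remaining sequence of each
#' chromosome is tiled into non-overlapping windows of `window` bp,
#' with a terminal remainder shorter than `window` kept as its own
#' fragment. Fragment coordinates refer to the original chromosome.
#'
#' @param genome Named character vector (or `DNAStringSet`) of
#'   chromosome sequences.
#' @param window Fragment size in bp.
#' @return Tibble with `frag_id`, `chrom`, `start`, `end` (0-based
#'   half-open, on the original coordinates).
#' @export
fragment_genome <- function(genome, window = 1000) {
  seqs <- as_seq_chr(genome)
  rows <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    ch <- names(seqs)[i]
    # non-N runs on the original coordinates
    nruns <- gregexpr("[^N]+", seqs[[i]])[[1]]
    if (nruns[1] == -1) next
    starts <- as.integer(nruns) - 1L
    lens <- attr(nruns, "match.length")
    frs <- vector("list", length(starts))
    for (j in seq_along(starts)) {
      cut <- seq(0L, lens[j], by = window)
      if (cut[length(cut)] < lens[j]) cut <- c(cut, lens[j])
      frs[[j]] <- tibble(chrom = ch,
                         start = starts[j] + cut[-length(cut)],
                         end = starts[j] + cut[-1])
    }
    rows[[i]] <- bind_rows(frs)
  }
  out <- bind_rows(rows)
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(frag_id = character(), chrom = character(),
                  start = integer(), end = integer()))
  }
  out |>
    mutate(frag_id = sprintf("%s:%d-%d", .data$chrom, .data$start,
                             .data$end)) |>
    select("frag_id", "chrom", "start", "end")
}

# Extract fragment sequences from their genome.
fragment_seqs <- function(fragments, genome) {
  seqs <- as_seq_chr(genome)
  substr(seqs[fragments$chrom], fragments$start + 1L, fragments$end)
}

#' Map fragments to a target genome with the built-in exact-seed mapper
#'
#' The toy mapper used at simulation scale: a fragment is mapped when
#' at least `min_support` of its 31-mer seeds occur (canonically)
#' anywhere in the target genome. Full-scale analyses should instead
#' supply external alignment records and set the `mapped` flag
#' themselves.
#'
#' @param fragments Tibble from [fragment_genome()].
#' @param genome Source genome (to extract fragment sequences from).
#' @param target Target genome sequences.
#' @param k Seed length.
#' @param min_support Minimum fraction of seeds found (inclusive).
#' @return The fragments tibble with `seed_support` and logical
#'   `mapped` columns; fragments shorter than `k` get support `NA` and
#'   are treated as unmapped.
#' @export
map_fragments <- function(fragments, genome, target, k = 31,
                          min_support = 0.5) {
  fs <- fragment_seqs(fragments, genome)
  support <- cpp_seed_support(fs, unname(as_seq_chr(target)), as.integer(k))
  fragments |>
    mutate(seed_support = support,
           mapped = !is.na(support) & support >= min_support)
}

#' Merge adjacent unmapped fragments into intervals
#'
#' Maximal runs of coordinate-contiguous unmapped fragments (same
#' chromosome, each starting where the previous one ends) are merged
#' into single intervals; fragments separated by an N gap are not
#' contiguous and are not merged.
#'
#' @param fragments Tibble with `chrom`, `start`, `end` and a logical
#'   `mapped` column (or pass `mapped` separately).
#' @param mapped Optional logical vector aligned to `fragments`.
#' @return Tibble with `chrom`, `start`, `end` of merged unmapped
#'   intervals.
#' @export
merge_unmapped <- function(fragments, mapped = NULL) {
  mapped <- mapped %||% fragments$mapped
  stopifnot(length(mapped) == nrow(fragments))
  un <- fragments[!mapped, , drop = FALSE] |>
    arrange(.data$chrom, .data$start)
  if (nrow(un) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  new_run <- c(TRUE, !(un$chrom[-1] == un$chrom[-nrow(un)] &
                         un$start[-1] == un$end[-nrow(un)]))
  run_id <- cumsum(new_run)
  un |>
    group_by(run = run_id, .data$chrom) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    select("chrom", "start", "end") |>
    arrange(.data$chrom, .data$start)
}

#' Subtract pangenome-aligned intervals from reference-unmapped ones
#'
#' Removes from the reference-alignment-derived unmapped intervals any
#' part that the pangenome alignment covered; remaining sub-intervals
#' shorter than `min_len` are dropped.
#'
#' @param ref_unmapped Tibble of intervals (`chrom`, `start`, `end`).
#' @param pan_mapped Tibble of intervals covered by the pangenome
#'   alignment, same coordinates.
#' @param min_len Length threshold: only sub-intervals strictly longer
#'   than this survive (consistent with the "longer than 500 bp"
#'   convention of the extraction filters).
#' @return Tibble of remaining intervals.
#' @export
subtract_pangenome_hits <- function(ref_unmapped, pan_mapped,
                                    min_len = 500) {
  out <- iv_setdiff(ref_unmapped, pan_mapped)
  out[out$end - out$start > min_len, , drop = FALSE]
}

#' Classify genome-specific sequences as nascent or lost
#'
#' Exact (canonical) occurrences of genome-specific k-mers are masked
#' in each sequence; masked runs separated by gaps strictly smaller
#' than `gap_join` bp are joined; the masked fraction is computed after
#' joining. A sequence is called `lost` (ancestral sequence deleted
#' from the partner genome) when its masked fraction is strictly below
#' `lost_cutoff`, otherwise `nascent` (novel sequence, rich in
#' genome-specific k-mers).
#'
#' @param seqs Named character vector (or `DNAStringSet`, or a tibble
#'   with `id` and `seq`) of PAV sequences from the genome the k-mer
#'   set belongs to.
#' @param specific_kmers Character vector of genome-specific k-mers.
#' @param gap_join Join masked runs separated by less than this many
#'   bp.
#' @param lost_cutoff Masked-fraction threshold (strict).
#' @return Tibble with `id`, `length`, `masked_bp`, `masked_fraction`,
#'   `verdict`. With an empty k-mer set all sequences are `lost` and
#'   the result carries attribute `empty_kmer_set = TRUE`.
#' @export
classify_origin <- function(seqs, specific_kmers, gap_join = 50,
                            lost_cutoff = 0.20) {
  if (is.data.frame(seqs)) {
    seqs <- setNames(seqs$seq, seqs$id)
  }
  seqs <- as_seq_chr(seqs)
  empty_set <- length(specific_kmers) == 0
  if (empty_set) {
    warning("classify_origin: empty k-mer set; all sequences called lost")
    out <- tibble(id = names(seqs), length = unname(nchar(seqs)),
                  masked_bp = 0L,
                  masked_fraction = 0, verdict = "lost")
    attr(out, "empty_kmer_set") <- TRUE
    return(out)
  }
  k <- nchar(specific_kmers[1])
  hits <- cpp_match_positions(unname(seqs), specific_kmers, as.integer(k))
  masked <- vapply(seq_along(seqs), function(i) {
    pos <- hits[[i]]
    if (length(pos) == 0) return(0L)
    ir <- IRanges::reduce(IRanges::IRanges(start = pos + 1L,
                                           width = k))
    # join runs whose gap is < gap_join
    if (length(ir) > 1) {
      gaps <- IRanges::start(ir)[-1] - IRanges::end(ir)[-length(ir)] - 1L
      grp <- cumsum(c(1L, as.integer(gaps >= gap_join)))
      ir <- IRanges::IRanges(
        start = tapply(IRanges::start(ir), grp, min),
        end = tapply(IRanges::end(ir), grp, max)
      )
    }
    sum(IRanges::width(ir))
  }, integer(1))
  len <- unname(nchar(seqs))
  frac <- masked / len
  out <- tibble(id = names(seqs), length = len,
                masked_bp = as.integer(masked),
                masked_fraction = frac,
                verdict = ifelse(frac < lost_cutoff, "lost", "nascent"))
  attr(out, "empty_kmer_set") <- FALSE
  out
}

#' Permutation test for query-to-gene distances
#'
#' Compares the mean distance from query intervals to their nearest
#' gene against a null distribution obtained by placing length-matched
#' intervals uniformly at random on the same chromosomes `n_perm`
#' times. Distances are 0 for overlapping or book-ended pairs. Queries
#' on chromosomes carrying no genes are excluded; it is an error if no
#' genes exist at all. Empirical p-values use the add-one correction
#' `p = (1 + #extreme) / (n_perm + 1)`.
#'
#' @param query Tibble of query intervals (`chrom`, `start`, `end`).
#' @param genes Tibble of gene intervals (`chrom`, `start`, `end`).
#' @param genome_len Named vector (or tibble `chrom`,`length`) of
#'   chromosome lengths.
#' @param n_perm Number of permutations.
#' @param seed Optional seed.
#' @return A `perm_test` object: list with `observed` (mean distance),
#'   `null` (per-permutation means), `p_closer` (lower tail: queries
#'   closer to genes than random), `p_farther`, `n_query`, `n_perm`.
#' @export
distance_permutation_test <- function(query, genes, genome_len,
                                      n_perm = 1000, seed = NULL) {
  local_seed_if(seed)
  if (is.data.frame(genome_len)) {
    genome_len <- setNames(genome_len$length, genome_len$chrom)
  }
  if (nrow(genes) == 0) {
    stop("distance_permutation_test: no genes supplied")
  }
  gene_chroms <- unique(genes$chrom)
  usable <- query$chrom %in% gene_chroms
  query <- query[usable, , drop = FALSE]
  if (nrow(query) == 0) {
    stop("distance_permutation_test: no queries on chromosomes with genes")
  }
  obs <- mean(nearest_distance(query$chrom, query$start, query$end,
                               genes$chrom, genes$start, genes$end))
  widths <- query$end - query$start
  lens <- genome_len[gene_chroms]
  null <- vapply(seq_len(n_perm), function(p) {
    ch <- sample(gene_chroms, length(widths), replace = TRUE,
                 prob = lens)
    maxs <- lens[ch] - widths
    st <- floor(runif(length(widths), 0, pmax(1, maxs)))
    mean(nearest_distance(ch, st, st + widths,
                          genes$chrom, genes$start, genes$end))
  }, numeric(1))
  structure(list(
    observed = obs,
    null = null,
    p_closer = (1 + sum(null <= obs)) / (n_perm + 1),
    p_farther = (1 + sum(null >= obs)) / (n_perm + 1),
    n_query = nrow(query),
    n_perm = n_perm
  ), class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Permutation distance test\n")
  cat(sprintf("  observed mean distance: %.1f bp over %d queries\n",
              x$observed, x$n_query))
  cat(sprintf("  null mean (sd): %.1f (%.1f) over %d permutations\n",
              mean(x$null), sd(x$null), x$n_perm))
  cat(sprintf("  p(closer than random) = %.4g; p(farther) = %.4g\n",
              x$p_closer, x$p_farther))
  invisible(x)
}
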