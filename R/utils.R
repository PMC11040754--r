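# Shared internal helpers: sequence coercion and interval arithmetic.
# All internal coordinates are 0-based half-open; GFF3/BED conversion
# happens only at the I/O boundary.

# Accept a Biostrings::DNAStringSet or a (named) character vector and
# return a named character vector of uppercase sequences.
as_seq_chr <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    out <- as.character(x)
  } else if (is.character(x)) {
    out <- toupper(x)
  } else {
    stop("sequences must be a DNAStringSet or character vector")
  }
  if (length(out) == 0) return(setNames(character(0), character(0)))
  if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
  out
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Tibble(chrom, start, end) -> GRanges (1-based internally to GRanges).
iv_to_granges <- function(tbl) {
  GenomicRanges::GRanges(
    seqnames = tbl$chrom,
    ranges = IRanges::IRanges(start = tbl$start + 1L, end = tbl$end)
  )
}

granges_to_iv <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

# Union-merge of intervals (coalescing overlapping/adjacent spans).
iv_reduce <- function(tbl) {
  if (nrow(tbl) == 0) return(tbl[, c("chrom", "start", "end")])
  granges_to_iv(GenomicRanges::reduce(iv_to_granges(tbl)))
}

# Interval difference a \ b.
iv_setdiff <- function(a, b) {
  if (nrow(a) == 0) return(a[, c("chrom", "start", "end")])
  if (nrow(b) == 0) return(iv_reduce(a))
  gra <- iv_to_granges(a)
  grb <- iv_to_granges(b)
  GenomeInfoDb::seqlevels(grb) <- union(GenomeInfoDb::seqlevels(grb),
                                        GenomeInfoDb::seqlevels(gra))
  GenomeInfoDb::seqlevels(gra) <- GenomeInfoDb::seqlevels(grb)
  granges_to_iv(GenomicRanges::setdiff(gra, grb))
}

# Total overlap width (bp) between two interval sets.
iv_overlap_bp <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  ov <- GenomicRanges::intersect(
    GenomicRanges::reduce(iv_to_granges(a)),
    GenomicRanges::reduce(iv_to_granges(b))
  )
  sum(GenomicRanges::width(ov))
}

iv_total_bp <- function(a) {
  if (nrow(a) == 0) return(0)
  sum(GenomicRanges::width(GenomicRanges::reduce(iv_to_granges(a))))
}

# Vectorized distance from query intervals to the nearest subject
# interval on the same chromosome; 0 when overlapping or book-ended,
# matching GenomicRanges::distanceToNearest semantics. Queries on
# chromosomes with no subject get NA.
nearest_distance <- function(q_chrom, q_start, q_end,
                             s_chrom, s_start, s_end) {
  out <- rep(NA_real_, length(q_start))
  for (chr in unique(q_chrom)) {
    qi <- which(q_chrom == chr)
    si <- which(s_chrom == chr)
    if (length(si) == 0) next
    red <- iv_reduce(tibble(chrom = chr, start = s_start[si], end = s_end[si]))
    gs <- red$start
    ge <- red$end
    qs <- q_start[qi]
    qe <- q_end[qi]
    # j: last subject whose start is <= query start (left neighbour or
    # enclosing subject); j + 1 is the right neighbour / first subject
    # starting inside the query span.
    j <- findInterval(qs, gs)
    left <- rep(Inf, length(qi))
    has <- j >= 1L
    left[has] <- pmax(0, qs[has] - ge[j[has]])
    left[has][ge[j[has]] > qs[has]] <- 0  # subject j overlaps query
    right <- rep(Inf, length(qi))
    jr <- j + 1L
    hasr <- jr <= length(gs)
    right[hasr] <- pmax(0, gs[jr[hasr]] - qe[hasr])
    out[qi] <- pmin(left, right)
  }
  out
}

# Windowed k-mer identity/coverage check between a candidate (shorter)
# sequence and a centroid. The candidate is cut into windows; each
# window's k-mer containment c in the centroid converts to a per-site
# identity estimate c^(1/k) (the expected k-mer survival under
# substitution divergence). A window is "aligned" when its estimated
# identity reaches `identity`; the pair passes when at least
# `coverage` of windows align.
kmer_identity_pass <- function(candidate, centroid, identity, coverage,
                               k, window = 250L) {
  len <- nchar(candidate)
  if (len < k) return(FALSE)
  cuts <- seq(0L, len, by = window)
  if (cuts[length(cuts)] < len) cuts <- c(cuts, len)
  # fold a short terminal window into its neighbour
  if (length(cuts) > 2 &&
      cuts[length(cuts)] - cuts[length(cuts) - 1] < k + 10) {
    cuts <- cuts[-(length(cuts) - 1)]
  }
  n_win <- length(cuts) - 1
  aligned <- 0L
  for (w in seq_len(n_win)) {
    piece <- substr(candidate, cuts[w] + 1L, cuts[w + 1])
    cont <- cpp_containment(piece, centroid, as.integer(k))
    if (!is.na(cont) && cont^(1 / k) >= identity) aligned <- aligned + 1L
  }
  aligned / n_win >= coverage
}

# Greedy length-sorted centroid clustering shared by NRS redundancy
# removal and LTR 90/90 family clustering. Sequences are visited by
# decreasing length; each joins the first centroid whose windowed
# k-mer identity check passes at the identity/coverage cutoffs, else
# founds a new centroid. A whole-sequence containment prefilter skips
# hopeless comparisons. Returns the centroid row index per input.
greedy_cluster <- function(seqs, identity = 0.90, coverage = 0.90,
                           k = 15, prefilter = 0.02) {
  n <- length(seqs)
  ord <- order(-nchar(seqs), seq_len(n))
  reps <- integer(0)
  assign <- integer(n)
  for (i in ord) {
    joined <- FALSE
    for (ci in reps) {
      cont <- cpp_containment(seqs[[i]], seqs[[ci]], as.integer(k))
      if (is.na(cont) || cont < prefilter) next
      if (kmer_identity_pass(seqs[[i]], seqs[[ci]], identity, coverage,
                             k)) {
        assign[i] <- ci
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      reps <- c(reps, i)
      assign[i] <- i
    }
  }
  assign
}

standard_error <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  sd(x) / sqrt(length(x))
}
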