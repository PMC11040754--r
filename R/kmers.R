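# Genome-specific k-mer discovery between homoeologous genomes:
# canonical k-mer counting, differential assignment by relative
# abundance, and k-means clustering with bootstrap support.

#' Count canonical k-mers per genome
#'
#' Counts canonical k-mers (lexicographic minimum of a k-mer and its
#' reverse complement) in each genome and retains those whose maximum
#' count across genomes strictly exceeds `min_count`. Windows
#' containing non-ACGT characters are skipped.
#'
#' The default `min_count` scales with genome length as
#' `max(2, round(100 * genome_len / 1.6e9))`, so the count threshold
#' of 100 used on a ~1.6 Gb cotton genome maps to a usable threshold
#' on toy-scale simulations.
#'
#' @param genomes Named list of genomes; each genome is a named
#'   character vector (or `DNAStringSet`) of chromosome sequences.
#' @param k K-mer size (odd; default 15).
#' @param min_count Retention threshold (strict, on the max across
#'   genomes); `NULL` for the length-scaled default.
#' @return A `kmer_profile` tibble: `kmer` plus one count column per
#'   genome; attributes `k`, `min_count` and `totals` (per-genome total
#'   retained k-mer count, used for relative abundance).
#' @export
count_kmers <- function(genomes, k = 15, min_count = NULL) {
  stopifnot(is.list(genomes), length(genomes) >= 1,
            !is.null(names(genomes)))
  if (k %% 2 == 0) stop("count_kmers: k must be odd")
  seqs <- lapply(genomes, as_seq_chr)
  glen <- vapply(seqs, function(s) sum(nchar(s)), numeric(1))
  if (is.null(min_count)) {
    min_count <- max(2, round(100 * mean(glen) / 1.6e9))
  }
  if (any(glen < k)) {
    warning("count_kmers: genome shorter than k; empty profile")
  }
  res <- cpp_count_kmers_multi(lapply(seqs, unname), as.integer(k),
                               as.integer(min_count))
  prof <- tibble(kmer = res$kmer)
  for (g in seq_along(genomes)) {
    prof[[names(genomes)[g]]] <- res$counts[[g]]
  }
  prof <- arrange(prof, .data$kmer)
  totals <- colSums(as.matrix(prof[, names(genomes), drop = FALSE]))
  attr(prof, "k") <- k
  attr(prof, "min_count") <- min_count
  attr(prof, "totals") <- totals
  class(prof) <- c("kmer_profile", class(prof))
  prof
}

#' Assign genome-specific k-mers between two genomes
#'
#' A k-mer is assigned to genome `a` when its relative abundance there
#' strictly exceeds `ratio` times its relative abundance in genome `b`
#' (and symmetrically for `b`). Relative abundance is the count
#' normalized by the genome's total retained k-mer count. A k-mer
#' absent from one genome is assigned to the other (its abundance
#' ratio is infinite); retention thresholds were already applied when
#' the profile was built.
#'
#' @param profile A `kmer_profile` from [count_kmers()].
#' @param genome_a,genome_b Genome names present in the profile.
#' @param ratio Relative-abundance ratio threshold (strict).
#' @return Tibble with `kmer`, `count_a`, `count_b`, `rel_a`, `rel_b`,
#'   `genome` (the assignment, or `NA` for unassigned k-mers).
#' @export
differential_kmers <- function(profile, genome_a, genome_b, ratio = 2.0) {
  stopifnot(all(c(genome_a, genome_b) %in% names(profile)))
  totals <- attr(profile, "totals")
  ta <- totals[[genome_a]]
  tb <- totals[[genome_b]]
  if (ta == 0 && tb == 0) stop("differential_kmers: zero total counts")
  ca <- profile[[genome_a]]
  cb <- profile[[genome_b]]
  rel_a <- if (ta > 0) ca / ta else rep(0, length(ca))
  rel_b <- if (tb > 0) cb / tb else rep(0, length(cb))
  keep <- ca > 0 | cb > 0
  assigned <- dplyr::case_when(
    rel_a > ratio * rel_b & ca > 0 ~ genome_a,
    rel_b > ratio * rel_a & cb > 0 ~ genome_b,
    TRUE ~ NA_character_
  )
  tibble(kmer = profile$kmer[keep], count_a = ca[keep],
         count_b = cb[keep], rel_a = rel_a[keep], rel_b = rel_b[keep],
         genome = assigned[keep])
}

#' Cluster candidate genome-specific k-mers with bootstrap support
#'
#' K-means clustering of k-mers on their z-scaled relative abundance
#' profiles: counts are normalized per genome (column) and then each
#' k-mer's profile is standardized across genomes (row z-scale), so
#' clustering follows the abundance *pattern* rather than the copy
#' number. Bootstrap resampling follows: in each of `n_boot` rounds a
#' fraction `boot_frac` of the k-mers is resampled and re-clustered,
#' bootstrap clusters are matched to the full-data clusters by nearest
#' centroid, and a k-mer's support is the fraction of rounds (among
#' those sampling it) in which it lands in its full-data cluster.
#'
#' @param candidates Tibble with `kmer` plus one numeric abundance
#'   column per genome (e.g. counts from a `kmer_profile` subset).
#' @param n_groups Number of k-means groups.
#' @param n_boot Bootstrap rounds (0 skips support estimation).
#' @param boot_frac Fraction of k-mers resampled per round.
#' @param seed Optional seed.
#' @return Tibble with `kmer`, `cluster`, `support` (`NA` when
#'   `n_boot = 0`).
#' @export
cluster_and_bootstrap <- function(candidates, n_groups, n_boot = 1000,
                                  boot_frac = 0.5, seed = NULL) {
  local_seed_if(seed)
  stopifnot("kmer" %in% names(candidates), nrow(candidates) > 0)
  m <- as.matrix(candidates[, setdiff(names(candidates), "kmer"),
                            drop = FALSE])
  storage.mode(m) <- "double"
  # relative abundance per genome column, then z-scale each k-mer's
  # profile across genomes (rows with no variance become flat zeros)
  tot <- colSums(m)
  tot[tot == 0] <- 1
  m <- sweep(m, 2, tot, "/")
  mu <- rowMeans(m)
  sds <- apply(m, 1, sd)
  sds[sds == 0] <- 1
  m <- (m - mu) / sds
  if (n_groups > nrow(unique(as.data.frame(m)))) {
    stop("cluster_and_bootstrap: n_groups exceeds distinct profiles")
  }
  km <- kmeans(m, centers = n_groups, nstart = 10)
  full_cluster <- km$cluster
  support <- rep(NA_real_, nrow(m))
  if (n_boot > 0) {
    hits <- numeric(nrow(m))
    tries <- numeric(nrow(m))
    n_take <- max(n_groups, round(boot_frac * nrow(m)))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nrow(m), n_take)
      sub <- m[idx, , drop = FALSE]
      if (nrow(unique(as.data.frame(sub))) < n_groups) next
      kb <- kmeans(sub, centers = n_groups, nstart = 2)
      # map bootstrap clusters onto full-data clusters by centroid
      map <- apply(kb$centers, 1, function(ctr) {
        which.min(colSums((t(km$centers) - ctr)^2))
      })
      tries[idx] <- tries[idx] + 1
      hits[idx] <- hits[idx] + (map[kb$cluster] == full_cluster[idx])
    }
    support <- ifelse(tries > 0, hits / tries, NA_real_)
  }
  tibble(kmer = candidates$kmer, cluster = as.integer(full_cluster),
         support = support)
}

#' Locate occurrences of a k-mer set in sequences
#'
#' Exact canonical matching: a window matches when its canonical form
#' equals a canonical k-mer of the set, so matching is strand
#' symmetric.
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param kmers Character vector of k-mers (all the same length).
#' @param k K-mer length (default taken from the set).
#' @return Tibble with `seq_id`, `start` (0-based), `end`.
#' @export
locate_kmers <- function(seqs, kmers, k = NULL) {
  seqs <- as_seq_chr(seqs)
  if (length(kmers) == 0) {
    return(tibble(seq_id = character(), start = integer(),
                  end = integer()))
  }
  k <- k %||% nchar(kmers[1])
  stopifnot(all(nchar(kmers) == k))
  hits <- cpp_match_positions(unname(seqs), kmers, as.integer(k))
  bind_rows(lapply(seq_along(seqs), function(i) {
    if (length(hits[[i]]) == 0) return(NULL)
    tibble(seq_id = names(seqs)[i], start = hits[[i]],
           end = hits[[i]] + as.integer(k))
  }))
}
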