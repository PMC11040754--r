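# Full-length LTR retrotransposon dynamics: terminal-repeat dating
# under the Jukes-Cantor model, 90/90 family clustering,
# genome-specificity assignment, amplification lifespans,
# retention/deletion rates, and LTR-gene spatial statistics.

#' Date LTR elements from terminal-repeat divergence
#'
#' The two terminal repeats of an element are identical at insertion
#' and diverge with age. Each pair is aligned globally with free end
#' gaps; gap columns are excluded, the mismatch proportion `p` over
#' compared sites is corrected with the Jukes-Cantor model
#' `K = -(3/4) log(1 - (4/3) p)`, and the age is `T = K / (f * r)`
#' with mutation rate `r` and divergence factor `f`.
#'
#' The default `divergence_factor = 1` follows the printed cotton
#' dating convention `T = K/r` with `r = 9e-9`; the conventional
#' two-sided LTR clock `T = K/(2r)` is obtained with
#' `divergence_factor = 2` (absolute ages shift by 2x between the two
#' conventions).
#'
#' @param elements Tibble with `element`, `ltr5_seq`, `ltr3_seq`
#'   columns (e.g. the `ltr` table of a simulated quartet), or a
#'   two-column list of sequences.
#' @param r Nucleotide mutation rate per site per year.
#' @param divergence_factor Divisor applied to `r` (see above).
#' @return Tibble with `element`, `p` (mismatch proportion), `K`
#'   (Jukes-Cantor distance), `T_years`.
#' @export
date_ltr <- function(elements, r = 9e-9, divergence_factor = 1) {
  stopifnot(all(c("element", "ltr5_seq", "ltr3_seq") %in% names(elements)))
  n <- nrow(elements)
  p <- numeric(n)
  for (i in seq_len(n)) {
    a <- elements$ltr5_seq[i]
    b <- elements$ltr3_seq[i]
    if (!nzchar(a) || !nzchar(b)) stop("date_ltr: empty terminal repeat")
    if (nchar(a) == nchar(b)) {
      # equal-length repeats are compared positionally: LTR divergence
      # is substitution-driven, and a shrinking local alignment would
      # underestimate p for highly diverged (saturated) pairs
      p[i] <- mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
      next
    }
    aln <- Biostrings::pairwiseAlignment(pattern = a, subject = b,
                                         type = "overlap")
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    keep <- pa != "-" & sa != "-"
    if (!any(keep)) stop("date_ltr: no comparable sites after alignment")
    p[i] <- mean(pa[keep] != sa[keep])
  }
  if (any(p >= 0.75)) {
    stop("date_ltr: terminal repeats saturated (p >= 0.75) for element ",
         elements$element[which(p >= 0.75)[1]],
         "; Jukes-Cantor distance undefined")
  }
  K <- -0.75 * log(1 - 4 / 3 * p)
  tibble(element = elements$element, p = p, K = K,
         T_years = K / (divergence_factor * r))
}

#' Extract full element sequences from a quartet
#'
#' @param quartet A [simulate_quartet()] result.
#' @return Named character vector of element sequences (from their
#'   host genome).
#' @export
ltr_element_seqs <- function(quartet) {
  stopifnot(inherits(quartet, "genome_quartet"))
  ltr <- quartet$ltr
  out <- vapply(seq_len(nrow(ltr)), function(i) {
    substr(quartet$genomes[[ltr$genome[i]]][[ltr$chrom[i]]],
           ltr$start[i] + 1L, ltr$end[i])
  }, character(1))
  setNames(out, ltr$element)
}

#' Cluster full-length LTR elements at 90/90 cutoffs
#'
#' Deterministic greedy centroid clustering: elements are visited by
#' decreasing length; each joins the first centroid with at least
#' `identity` aligned identity over at least `coverage` of the shorter
#' sequence (k-mer containment prefilter, alignment confirmation),
#' else founds a new centroid.
#'
#' @param elements Tibble with `element` and `seq` columns, or a named
#'   character vector of element sequences.
#' @param identity,coverage Clustering cutoffs (default 90/90).
#' @param k Prefilter k-mer size.
#' @return Tibble with `element`, `cluster` (integer ids in order of
#'   centroid discovery by length rank).
#' @export
cluster_ltr <- function(elements, identity = 0.90, coverage = 0.90,
                        k = 15) {
  if (is.character(elements)) {
    elements <- tibble(element = names(as_seq_chr(elements)),
                       seq = unname(as_seq_chr(elements)))
  }
  stopifnot(all(c("element", "seq") %in% names(elements)),
            nrow(elements) >= 1)
  assign <- greedy_cluster(elements$seq, identity = identity,
                           coverage = coverage, k = k)
  reps <- unique(assign[order(-nchar(elements$seq), seq_along(assign))])
  tibble(element = elements$element,
         cluster = match(assign, reps))
}

#' Assign genome specificity to LTR clusters
#'
#' Decision tree applied in order to each cluster's per-genome member
#' composition: (1) one genome contributes strictly more than
#' `single_frac` of members: genome-specific; (2) the best genome pair
#' contributes strictly more than `pair_frac`: pair label; (3) exactly
#' one genome contributes strictly less than `minor_frac`: labelled by
#' the other three genomes; (4) otherwise `common`. Labels join genome
#' names in the canonical order A2, D5, At, Dt.
#'
#' @param composition Tibble with `cluster` and integer columns `A2`,
#'   `D5`, `At`, `Dt` (member counts).
#' @param single_frac,pair_frac,minor_frac Decision-tree thresholds.
#' @return Tibble with `cluster`, `n`, `label`.
#' @export
assign_specificity <- function(composition, single_frac = 0.90,
                               pair_frac = 0.90, minor_frac = 0.10) {
  genomes <- c("A2", "D5", "At", "Dt")
  stopifnot(all(c("cluster", genomes) %in% names(composition)))
  m <- as.matrix(composition[, genomes, drop = FALSE])
  labels <- vapply(seq_len(nrow(m)), function(i) {
    specificity_label(m[i, ], genomes, single_frac, pair_frac, minor_frac)
  }, character(1))
  tibble(cluster = composition$cluster, n = as.integer(rowSums(m)),
         label = labels)
}

specificity_label <- function(counts, genomes, single_frac, pair_frac,
                              minor_frac) {
  n <- sum(counts)
  if (n == 0) stop("assign_specificity: empty cluster")
  props <- counts / n
  if (any(props > single_frac)) {
    return(genomes[which.max(props)])
  }
  pairs <- combn(4, 2)
  pair_sums <- props[pairs[1, ]] + props[pairs[2, ]]
  if (max(pair_sums) > pair_frac) {
    best <- pairs[, which.max(pair_sums)]
    return(paste(genomes[sort(best)], collapse = "_"))
  }
  minor <- props < minor_frac
  if (sum(minor) == 1) {
    return(paste(genomes[!minor], collapse = "_"))
  }
  "common"
}

#' Amplification lifespan of an LTR cluster
#'
#' The lifespan spans the 95th (oldest, `t_start`) to the 5th
#' (youngest, `t_end`) percentile of member insertion ages, using
#' linear-interpolation percentiles. Clusters with fewer than 2 dated
#' members get `NA`.
#'
#' @param ages Tibble with `cluster` and `T_years` (e.g. a
#'   [cluster_ltr()] result joined to [date_ltr()] output).
#' @return Tibble with `cluster`, `n_dated`, `t_start`, `t_end`.
#' @export
cluster_lifespan <- function(ages) {
  stopifnot(all(c("cluster", "T_years") %in% names(ages)))
  ages |>
    filter(!is.na(.data$T_years)) |>
    group_by(.data$cluster) |>
    summarise(n_dated = n(),
              t_start = if (n() >= 2) {
                unname(quantile(.data$T_years, 0.95, type = 7))
              } else NA_real_,
              t_end = if (n() >= 2) {
                unname(quantile(.data$T_years, 0.05, type = 7))
              } else NA_real_,
              .groups = "drop")
}

#' LTR retention rates in homologous regions by CV cutoff
#'
#' Each homologous locus carries one truncated-LTR retention length
#' per genome and a shared alignment length; the retention rate is
#' `retained / alignment length`. For every CV cutoff, loci whose
#' coefficient of variation (sd/mean of the four retained lengths) is
#' at least the cutoff are kept, and per-genome mean retention rates
#' plus pairwise two-sided t-tests are reported. Loci with zero
#' alignment length are skipped.
#'
#' @param loci Tibble with `locus`, `genome`, `retained_length`,
#'   `aln_length`.
#' @param cv_cutoffs Numeric vector of CV cutoffs.
#' @return List with `rates` (per-cutoff per-genome tibble: `cv_cutoff`,
#'   `genome`, `n_loci`, `mean_retention`) and `tests` (`cv_cutoff`,
#'   `genome_a`, `genome_b`, `p`).
#' @export
retention_rates <- function(loci, cv_cutoffs = c(0, 0.25, 0.5, 0.75, 1)) {
  stopifnot(all(c("locus", "genome", "retained_length", "aln_length") %in%
                  names(loci)))
  loci <- loci |> filter(.data$aln_length > 0)
  wide <- loci |>
    mutate(rate = .data$retained_length / .data$aln_length)
  cvs <- wide |>
    group_by(.data$locus) |>
    summarise(cv = {
      m <- mean(.data$retained_length)
      if (m == 0) NA_real_ else sd(.data$retained_length) / m
    }, .groups = "drop")
  wide <- left_join(wide, cvs, by = "locus")
  genomes <- sort(unique(wide$genome))
  rates <- bind_rows(lapply(cv_cutoffs, function(cut) {
    sel <- wide |> filter(!is.na(.data$cv), .data$cv >= cut)
    sel |>
      group_by(.data$genome) |>
      summarise(n_loci = dplyr::n_distinct(.data$locus),
                mean_retention = mean(.data$rate), .groups = "drop") |>
      mutate(cv_cutoff = cut)
  }))
  pairs <- if (length(genomes) >= 2) combn(genomes, 2) else {
    matrix(character(0), nrow = 2)
  }
  tests <- bind_rows(lapply(cv_cutoffs, function(cut) {
    sel <- wide |> filter(!is.na(.data$cv), .data$cv >= cut)
    bind_rows(lapply(seq_len(ncol(pairs)), function(j) {
      xa <- sel$rate[sel$genome == pairs[1, j]]
      xb <- sel$rate[sel$genome == pairs[2, j]]
      p <- if (length(xa) < 2 || length(xb) < 2) NA_real_ else {
        t.test(xa, xb)$p.value
      }
      tibble(cv_cutoff = cut, genome_a = pairs[1, j],
             genome_b = pairs[2, j], p = p)
    }))
  }))
  list(rates = select(rates, "cv_cutoff", "genome", "n_loci",
                      "mean_retention"),
       tests = tests)
}

#' LTR-to-gene distance statistics per superfamily
#'
#' For each superfamily: the distance from every element to its
#' nearest gene, a permutation test against length-matched random
#' placements, and an ordinary least-squares regression of distance
#' (kb) on insertion age (Myr).
#'
#' @param elements Tibble with `element`, `superfamily`, `chrom`,
#'   `start`, `end` and optionally `T_years` (or supply `ages`).
#' @param genes Tibble of gene intervals (`chrom`, `start`, `end`).
#' @param genome_len Named vector or tibble (`chrom`, `length`).
#' @param ages Optional tibble (`element`, `T_years`) joined onto
#'   `elements`.
#' @param n_perm Permutations for the distance test.
#' @param seed Optional seed.
#' @return List of class `ltr_distance_stats` with `stats` (tibble per
#'   superfamily: `n`, `mean_distance`, `p_closer`, `p_farther`,
#'   `slope_kb_per_myr`, `slope_lo`, `slope_hi`, `slope_p`) and
#'   `distances` (per-element tibble).
#' @export
ltr_gene_distance_stats <- function(elements, genes, genome_len,
                                    ages = NULL, n_perm = 1000,
                                    seed = NULL) {
  local_seed_if(seed)
  if (!is.null(ages)) {
    elements <- left_join(elements, ages, by = "element")
  }
  if (nrow(genes) == 0) stop("ltr_gene_distance_stats: no genes")
  elements <- elements |>
    mutate(distance = nearest_distance(.data$chrom, .data$start,
                                       .data$end, genes$chrom,
                                       genes$start, genes$end))
  per_sf <- lapply(split(elements, elements$superfamily), function(el) {
    pt <- distance_permutation_test(
      el[, c("chrom", "start", "end")], genes, genome_len,
      n_perm = n_perm, seed = NULL
    )
    has_age <- "T_years" %in% names(el) && sum(!is.na(el$T_years)) >= 2
    if (has_age && sd(el$T_years, na.rm = TRUE) > 0) {
      fit <- lm(I(distance / 1e3) ~ I(T_years / 1e6), data = el)
      ci <- suppressWarnings(confint(fit))
      slope <- unname(coef(fit)[2])
      slope_lo <- ci[2, 1]
      slope_hi <- ci[2, 2]
      slope_p <- summary(fit)$coefficients[2, 4]
    } else {
      slope <- slope_lo <- slope_hi <- slope_p <- NA_real_
    }
    tibble(superfamily = el$superfamily[1], n = nrow(el),
           mean_distance = mean(el$distance, na.rm = TRUE),
           p_closer = pt$p_closer, p_farther = pt$p_farther,
           slope_kb_per_myr = slope, slope_lo = slope_lo,
           slope_hi = slope_hi, slope_p = slope_p)
  })
  structure(list(stats = bind_rows(per_sf),
                 distances = elements[, intersect(
                   c("element", "superfamily", "chrom", "start", "end",
                     "T_years", "distance"), names(elements))]),
            class = "ltr_distance_stats")
}

#' @export
print.ltr_distance_stats <- function(x, ...) {
  cat("LTR-to-gene distance statistics\n")
  print(x$stats)
  invisible(x)
}

#' Adjacent-homolog spacing conservation test
#'
#' Compares the spacing of adjacent homologous genes between a diploid
#' genome and the corresponding tetraploid subgenome. The observed
#' statistic is the histogram of log2(tetraploid / diploid) spacing
#' ratios; the null preserves gene order but randomizes the
#' inter-gene distances within each genome (spacings are permuted
#' independently and re-paired). A chi-square test compares observed
#' bin counts with the null bin proportions (Laplace-smoothed).
#'
#' @param spacing Tibble with paired columns `diploid` and
#'   `tetraploid` (positive adjacent-homolog spacings, one row per
#'   adjacent pair).
#' @param n_rand Number of randomization rounds.
#' @param breaks Histogram breaks on the log2-ratio scale (values
#'   outside are clamped to the end bins).
#' @param seed Optional seed.
#' @return A `spacing_test` object: list with `log2_ratio`,
#'   `observed` (bin counts), `null_prop` (expected bin proportions),
#'   `statistic`, `p`, `n_pairs`, `n_rand`.
#' @export
homolog_spacing_test <- function(spacing, n_rand = 1000,
                                 breaks = seq(-4, 4, by = 0.5),
                                 seed = NULL) {
  local_seed_if(seed)
  stopifnot(all(c("diploid", "tetraploid") %in% names(spacing)))
  if (any(is.na(spacing$diploid) | is.na(spacing$tetraploid))) {
    stop("homolog_spacing_test: unpaired (NA) spacing values")
  }
  if (any(spacing$diploid <= 0 | spacing$tetraploid <= 0)) {
    stop("homolog_spacing_test: spacings must be positive")
  }
  lr <- log2(spacing$tetraploid / spacing$diploid)
  clamp <- function(x) pmin(pmax(x, min(breaks) + 1e-9),
                            max(breaks) - 1e-9)
  bin <- function(x) {
    tabulate(findInterval(clamp(x), breaks), nbins = length(breaks) - 1)
  }
  obs <- bin(lr)
  n <- nrow(spacing)
  if (n < 2) {
    return(structure(list(log2_ratio = lr, observed = obs,
                          null_prop = rep(NA_real_, length(obs)),
                          statistic = NA_real_, p = NA_real_,
                          n_pairs = n, n_rand = n_rand),
                     class = "spacing_test"))
  }
  null_counts <- numeric(length(obs))
  for (b in seq_len(n_rand)) {
    lr_null <- log2(sample(spacing$tetraploid) / sample(spacing$diploid))
    null_counts <- null_counts + bin(lr_null)
  }
  null_prop <- (null_counts + 1) / (sum(null_counts) + length(null_counts))
  ct <- suppressWarnings(chisq.test(obs, p = null_prop))
  structure(list(log2_ratio = lr, observed = obs, null_prop = null_prop,
                 statistic = unname(ct$statistic), p = ct$p.value,
                 n_pairs = n, n_rand = n_rand),
            class = "spacing_test")
}

#' @export
print.spacing_test <- function(x, ...) {
  cat("Adjacent-homolog spacing conservation test\n")
  cat(sprintf("  %d pairs; chi-square = %.2f, p = %.4g (%d randomizations)\n",
              x$n_pairs, x$statistic, x$p, x$n_rand))
  invisible(x)
}
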