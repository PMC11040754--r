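# Gene presence/absence (PAV) analysis: coverage-based presence
# calling, occupancy classification, pan/core rarefaction, and the
# group-differential gene-frequency scan.

#' Call gene presence from per-exon coverage summaries
#'
#' A gene is called present in an accession when strictly more than
#' `present_frac` of its total exon length is covered by short reads at
#' depth >= `min_cov`. The input table must already summarise covered
#' bases at that depth (the `min_cov` argument is recorded in the
#' output attributes for provenance).
#'
#' @param depth_table Tibble with columns `accession`, `gene`, `exon`,
#'   `exon_length`, `covered_bases` (covered at depth >= `min_cov`).
#' @param min_cov Depth threshold the `covered_bases` column was
#'   computed at.
#' @param present_frac Covered-fraction threshold (strict).
#' @return A presence matrix tibble: one row per gene (`gene` column)
#'   and one 0/1 column per accession.
#' @export
call_presence <- function(depth_table, min_cov = 2, present_frac = 0.8) {
  stopifnot(all(c("accession", "gene", "exon_length", "covered_bases") %in%
                  names(depth_table)))
  tot <- depth_table |>
    group_by(.data$accession, .data$gene) |>
    summarise(exon_len = sum(.data$exon_length),
              covered = sum(.data$covered_bases), .groups = "drop")
  if (any(tot$exon_len == 0)) {
    stop("call_presence: gene with zero total exon length: ",
         tot$gene[tot$exon_len == 0][1])
  }
  out <- tot |>
    mutate(present = as.integer(.data$covered / .data$exon_len >
                                  present_frac)) |>
    select("accession", "gene", "present") |>
    tidyr::pivot_wider(names_from = "accession", values_from = "present") |>
    arrange(.data$gene)
  attr(out, "min_cov") <- min_cov
  attr(out, "present_frac") <- present_frac
  out
}

#' Occupancy thresholds for core/soft-core/shell/cloud classes
#'
#' With `n` accessions and presence count `c`, genes are core when
#' `c > floor(core_q * n)`, soft-core when
#' `ceiling(soft_q * n) <= c <= floor(core_q * n)`, cloud when
#' `c < ceiling(cloud_q * n)`, and shell otherwise. At `n = 341` the
#' boundaries are 337 (core, exclusive), 324 (soft-core, inclusive
#' lower) and 4 (cloud, exclusive upper).
#'
#' @param n Number of accessions.
#' @param core_q,soft_q,cloud_q Occupancy quantiles.
#' @return Tibble with one row of integer boundaries: `core_gt`
#'   (present in more than this many accessions => core), `soft_ge`
#'   (lower inclusive soft-core bound) and `cloud_lt` (fewer than this
#'   many => cloud).
#' @export
occupancy_thresholds <- function(n, core_q = 0.99, soft_q = 0.95,
                                 cloud_q = 0.01) {
  tibble(n = n,
         core_gt = floor(core_q * n),
         soft_ge = ceiling(soft_q * n),
         cloud_lt = ceiling(cloud_q * n))
}

#' Classify pangenes into core/soft-core/shell/cloud occupancy classes
#'
#' @param pav Presence matrix tibble from [call_presence()] (a `gene`
#'   column plus one 0/1 column per accession).
#' @inheritParams occupancy_thresholds
#' @return Tibble with `gene`, `presence_count`, `occupancy`
#'   (`core`/`softcore`/`shell`/`cloud`); the thresholds used are
#'   attached as attribute `thresholds`.
#' @export
classify_occupancy <- function(pav, core_q = 0.99, soft_q = 0.95,
                               cloud_q = 0.01) {
  m <- pav_to_matrix(pav)
  n <- ncol(m)
  stopifnot(n >= 4)
  thr <- occupancy_thresholds(n, core_q, soft_q, cloud_q)
  cnt <- rowSums(m)
  cls <- dplyr::case_when(
    cnt > thr$core_gt ~ "core",
    cnt >= thr$soft_ge ~ "softcore",
    cnt < thr$cloud_lt ~ "cloud",
    TRUE ~ "shell"
  )
  out <- tibble(gene = rownames(m), presence_count = as.integer(cnt),
                occupancy = cls)
  attr(out, "thresholds") <- thr
  out
}

# presence tibble -> integer matrix (genes x accessions)
pav_to_matrix <- function(pav) {
  stopifnot("gene" %in% names(pav))
  m <- as.matrix(pav[, setdiff(names(pav), "gene"), drop = FALSE])
  stopifnot(all(m %in% c(0L, 1L)))
  storage.mode(m) <- "integer"
  rownames(m) <- pav$gene
  m
}

#' Pan-gene and core-gene rarefaction curves
#'
#' For each panel size, accessions are drawn without replacement
#' `n_samplings` times; pan genes are those present in at least one
#' sampled accession and core genes those present in all of them. The
#' per-size mean and a central 99% interval (0.5 and 99.5 percentiles)
#' are reported. With `nested = TRUE` each sampling draws one
#' accession permutation and evaluates its prefixes, making the pan
#' curve non-decreasing and the core curve non-increasing within every
#' sampling.
#'
#' @param pav Presence matrix tibble (`gene` column + accession
#'   columns).
#' @param n_samplings Number of random draws per size.
#' @param sizes Panel sizes to evaluate (default 2..N).
#' @param seed Optional seed.
#' @param nested Use nested (prefix) draws instead of independent ones.
#' @return Tibble with `size`, `pan_mean`, `pan_lo`, `pan_hi`,
#'   `core_mean`, `core_lo`, `core_hi`.
#' @export
pan_core_curve <- function(pav, n_samplings = 1000, sizes = NULL,
                           seed = NULL, nested = FALSE) {
  local_seed_if(seed)
  m <- pav_to_matrix(pav)
  n_acc <- ncol(m)
  stopifnot(n_acc >= 2)
  sizes <- sizes %||% seq(2L, n_acc)
  stopifnot(all(sizes >= 1 & sizes <= n_acc))
  pan <- matrix(0L, nrow = n_samplings, ncol = length(sizes))
  core <- matrix(0L, nrow = n_samplings, ncol = length(sizes))
  for (s in seq_len(n_samplings)) {
    if (nested) {
      perm <- sample.int(n_acc)
      for (j in seq_along(sizes)) {
        sub <- m[, perm[seq_len(sizes[j])], drop = FALSE]
        rs <- rowSums(sub)
        pan[s, j] <- sum(rs > 0)
        core[s, j] <- sum(rs == sizes[j])
      }
    } else {
      for (j in seq_along(sizes)) {
        sub <- m[, sample.int(n_acc, sizes[j]), drop = FALSE]
        rs <- rowSums(sub)
        pan[s, j] <- sum(rs > 0)
        core[s, j] <- sum(rs == sizes[j])
      }
    }
  }
  tibble(
    size = sizes,
    pan_mean = colMeans(pan),
    pan_lo = apply(pan, 2, quantile, probs = 0.005),
    pan_hi = apply(pan, 2, quantile, probs = 0.995),
    core_mean = colMeans(core),
    core_lo = apply(core, 2, quantile, probs = 0.005),
    core_hi = apply(core, 2, quantile, probs = 0.995)
  )
}

#' Scan for group-differential gene frequencies
#'
#' Compares per-gene presence frequency between a focal accession group
#' and all other accessions. The fold change is
#' `freq(focal) / freq(other)`; when any cell of the 2x2
#' presence-by-group table is zero, 0.5 is added to all four cells
#' (Haldane correction) before computing frequencies for the fold
#' change. Significance comes from Fisher's exact test on the
#' (uncorrected) 2x2 table with Benjamini-Hochberg FDR adjustment.
#' A gene is `favorable` when `fold_change > fc_hi` and `q < fdr`,
#' `unfavorable` when `fold_change < fc_lo` and `q < fdr`, otherwise
#' `ns`. Genes absent from both groups are excluded with a message.
#'
#' @param pav Presence matrix tibble (typically restricted to
#'   dispensable genes).
#' @param groups Tibble with `accession`, `group` covering the matrix
#'   accessions.
#' @param focal_group Group label to contrast against the rest.
#' @param fc_hi,fc_lo Fold-change thresholds.
#' @param fdr FDR threshold on the BH-adjusted p-value.
#' @return Tibble with `gene`, presence counts and frequencies per
#'   side, `fold_change`, `p`, `q`, `verdict`.
#' @export
frequency_change_scan <- function(pav, groups, focal_group, fc_hi = 2.0,
                                  fc_lo = 0.5, fdr = 0.001) {
  m <- pav_to_matrix(pav)
  stopifnot(all(colnames(m) %in% groups$accession))
  grp <- groups$group[match(colnames(m), groups$accession)]
  focal <- grp == focal_group
  n1 <- sum(focal)
  n2 <- sum(!focal)
  stopifnot(n1 > 0, n2 > 0)
  p1 <- rowSums(m[, focal, drop = FALSE])
  p2 <- rowSums(m[, !focal, drop = FALSE])
  none <- p1 == 0 & p2 == 0
  if (any(none)) {
    message("frequency_change_scan: excluded ", sum(none),
            " gene(s) absent in both groups")
  }
  keep <- which(!none)
  p <- vapply(keep, function(i) {
    fisher.test(matrix(c(p1[i], n1 - p1[i], p2[i], n2 - p2[i]), 2))$p.value
  }, numeric(1))
  a <- p1[keep]; b <- n1 - a; c <- p2[keep]; d <- n2 - c
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  f1 <- ifelse(zero, (a + 0.5) / (a + b + 1), a / (a + b))
  f2 <- ifelse(zero, (c + 0.5) / (c + d + 1), c / (c + d))
  fc <- f1 / f2
  q <- p.adjust(p, method = "BH")
  tibble(
    gene = rownames(m)[keep],
    present_focal = as.integer(unname(a)), n_focal = n1,
    present_other = as.integer(unname(c)), n_other = n2,
    freq_focal = unname(a) / n1, freq_other = unname(c) / n2,
    fold_change = unname(fc), p = unname(p), q = unname(q),
    verdict = dplyr::case_when(
      fc > fc_hi & q < fdr ~ "favorable",
      fc < fc_lo & q < fdr ~ "unfavorable",
      TRUE ~ "ns"
    )
  )
}

#' Cluster dispensable genes by their presence pattern
#'
#' K-means on the rows of the binary presence matrix (accessions as
#' dimensions, 0/1 values fed as reals to Euclidean k-means).
#'
#' @param pav Presence matrix tibble restricted to dispensable genes.
#' @param k Number of clusters.
#' @param seed Optional seed.
#' @param nstart Random restarts.
#' @return Tibble with `gene`, `cluster`.
#' @export
cluster_dispensable <- function(pav, k = 4, seed = NULL, nstart = 10) {
  local_seed_if(seed)
  m <- pav_to_matrix(pav)
  if (k > nrow(m)) stop("cluster_dispensable: k exceeds number of genes")
  uniq <- unique(as.data.frame(m))
  if (k == 1) {
    return(tibble(gene = rownames(m), cluster = 1L))
  }
  km <- kmeans(m, centers = min(k, nrow(uniq)), nstart = nstart)
  tibble(gene = rownames(m), cluster = as.integer(km$cluster))
}

#' Jaccard distance between accessions' gene content
#'
#' Export for external tree building on PAV profiles.
#'
#' @param pav Presence matrix tibble.
#' @return A `dist` object over accessions.
#' @export
pav_jaccard <- function(pav) {
  m <- t(pav_to_matrix(pav))
  inter <- m %*% t(m)
  sizes <- rowSums(m)
  uni <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / pmax(uni, 1)
  stats::as.dist(d)
}
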