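# Single-copy gene fate classification after polyploidization, and
# tracing of TE-driven gene losses.

#' Classify single-copy gene family fates in the tetraploid
#'
#' Families with exactly one member in each diploid (A2 and D5) are
#' classified by their tetraploid member count: 2 with one member per
#' subgenome is `balanced` (a 2+0 split on one subgenome is flagged
#' `unbalanced_retention` instead); 0 is `lost_both`; 1 is
#' `reverted_single` with the empty subgenome recorded; more than 2 is
#' `gained`. Families violating the diploid single-copy requirement
#' are skipped (attribute `n_ineligible`).
#'
#' @param families Tibble with `family`, `n_A2`, `n_D5`, `n_At`,
#'   `n_Dt` member counts.
#' @return Tibble with `family`, `fate`, `lost_subgenome`
#'   (`At`/`Dt`/`both`/`none`) for eligible families; attribute
#'   `n_ineligible` counts skipped families.
#' @export
classify_fate <- function(families) {
  stopifnot(all(c("family", "n_A2", "n_D5", "n_At", "n_Dt") %in%
                  names(families)))
  eligible <- families$n_A2 == 1L & families$n_D5 == 1L
  f <- families[eligible, , drop = FALSE]
  total <- f$n_At + f$n_Dt
  fate <- dplyr::case_when(
    total == 2L & f$n_At == 1L ~ "balanced",
    total == 2L ~ "unbalanced_retention",
    total == 0L ~ "lost_both",
    total == 1L ~ "reverted_single",
    total > 2L ~ "gained"
  )
  lost <- dplyr::case_when(
    fate == "lost_both" ~ "both",
    fate == "reverted_single" & f$n_At == 0L ~ "At",
    fate == "reverted_single" ~ "Dt",
    TRUE ~ "none"
  )
  out <- tibble(family = f$family, fate = fate, lost_subgenome = lost)
  attr(out, "n_ineligible") <- sum(!eligible)
  out
}

#' Count gene-family members per genome of a quartet
#'
#' Convenience accessor building the [classify_fate()] input from a
#' simulated quartet's gene annotations.
#'
#' @param quartet A [simulate_quartet()] result.
#' @return Tibble with `family`, `n_A2`, `n_D5`, `n_At`, `n_Dt`.
#' @export
family_counts <- function(quartet) {
  stopifnot(inherits(quartet, "genome_quartet"))
  quartet$genes |>
    dplyr::count(.data$family, .data$genome) |>
    tidyr::pivot_wider(names_from = "genome", values_from = "n",
                       names_prefix = "n_", values_fill = 0L) |>
    (\(d) {
      for (col in c("n_A2", "n_D5", "n_At", "n_Dt")) {
        if (!col %in% names(d)) d[[col]] <- 0L
      }
      d
    })() |>
    select("family", "n_A2", "n_D5", "n_At", "n_Dt") |>
    arrange(.data$family)
}

#' Trace the mechanism behind a lost gene copy
#'
#' Given alignments of the retained diploid gene sequence against the
#' subgenome that lost the copy: a single alignment covering strictly
#' more than `cover_frac` of the gene indicates an annotation omission
#' or loss by small variations; otherwise, two or more alignments
#' whose target spans lie within `span_max` of each other (gap between
#' consecutive spans) with at least one TE annotation overlapping the
#' inter-alignment gap indicate TE disruption; anything else (including
#' no alignments at all) is unexplained.
#'
#' @param alignments Alignment records (e.g. from [naive_align()] or
#'   [read_paf()]) of one or more lost genes versus the losing
#'   subgenome; must contain `query_id`, `query_len`, `query_start`,
#'   `query_end`, `target_id`, `target_start`, `target_end`.
#' @param te_annotation Tibble of TE intervals on the subgenome
#'   (`chrom`, `start`, `end`).
#' @param genes Character vector of the lost gene ids to report (so
#'   genes without any alignment are still returned as unexplained).
#' @param cover_frac Single-alignment coverage threshold (strict).
#' @param span_max Maximum gap between consecutive alignment target
#'   spans (inclusive), default 25 kb.
#' @return Tibble with `gene`, `mechanism` in
#'   `small_variation_or_annotation` / `TE_disruption` / `unexplained`.
#' @export
trace_loss_mechanism <- function(alignments, te_annotation,
                                 genes = NULL, cover_frac = 0.90,
                                 span_max = 25000) {
  genes <- genes %||% unique(alignments$query_id)
  by_gene <- split(alignments, alignments$query_id)
  mech <- vapply(genes, function(g) {
    aln <- by_gene[[g]]
    if (is.null(aln) || nrow(aln) == 0) return("unexplained")
    qcov <- (aln$query_end - aln$query_start) / aln$query_len
    if (any(qcov > cover_frac)) {
      return("small_variation_or_annotation")
    }
    if (nrow(aln) >= 2) {
      for (chr in unique(aln$target_id)) {
        a <- aln[aln$target_id == chr, , drop = FALSE]
        if (nrow(a) < 2) next
        a <- a[order(a$target_start), , drop = FALSE]
        for (i in seq_len(nrow(a) - 1)) {
          gap_start <- a$target_end[i]
          gap_end <- a$target_start[i + 1]
          if (gap_end <= gap_start) next
          if (gap_end - gap_start > span_max) next
          te_hit <- any(te_annotation$chrom == chr &
                          te_annotation$start < gap_end &
                          te_annotation$end > gap_start)
          if (te_hit) return("TE_disruption")
        }
      }
    }
    "unexplained"
  }, character(1))
  tibble(gene = genes, mechanism = unname(mech))
}

#' Compare genomic features across gene-fate classes
#'
#' Per-fate mean and standard error for each feature, plus two-sided
#' Mann-Whitney (Wilcoxon rank-sum) tests for every fate pair and
#' feature. Pairs where either class has fewer than 2 members get `NA`
#' p-values.
#'
#' @param calls Tibble with `gene` and `fate` columns (e.g. fate calls
#'   joined to member gene ids).
#' @param features Tibble with `gene` plus numeric feature columns
#'   (coding length, exon count, Ka/Ks, expression, TE coverage, ...).
#' @return List with `summary` (fate x feature mean/SE tibble) and
#'   `tests` (tibble `feature`, `fate_a`, `fate_b`, `p`).
#' @export
compare_fate_features <- function(calls, features) {
  stopifnot(all(c("gene", "fate") %in% names(calls)),
            "gene" %in% names(features))
  joined <- inner_join(calls, features, by = "gene")
  feats <- setdiff(names(features), "gene")
  summary_tbl <- joined |>
    group_by(.data$fate) |>
    summarise(n = n(),
              across(dplyr::all_of(feats),
                     list(mean = ~ mean(.x, na.rm = TRUE),
                          se = ~ standard_error(.x))),
              .groups = "drop")
  fates <- sort(unique(joined$fate))
  pairs <- if (length(fates) >= 2) combn(fates, 2) else {
    matrix(character(0), nrow = 2)
  }
  tests <- bind_rows(lapply(feats, function(f) {
    bind_rows(lapply(seq_len(ncol(pairs)), function(j) {
      xa <- joined[[f]][joined$fate == pairs[1, j]]
      xb <- joined[[f]][joined$fate == pairs[2, j]]
      xa <- xa[!is.na(xa)]
      xb <- xb[!is.na(xb)]
      p <- if (length(xa) < 2 || length(xb) < 2) NA_real_ else {
        suppressWarnings(wilcox.test(xa, xb)$p.value)
      }
      tibble(feature = f, fate_a = pairs[1, j], fate_b = pairs[2, j],
             p = p)
    }))
  }))
  list(summary = summary_tbl, tests = tests)
}
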