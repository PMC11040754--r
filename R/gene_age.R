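# Phylostratigraphic gene-age binning from orthogroup membership, and
# the relation of gene age to nascent-sequence proximity and genomic
# features.

# Default taxon ladder, deepest (oldest) first. Age1 = shared with
# O. sativa (oldest) ... Age5 = pangenome-only (youngest).
default_taxon_ladder <- c("O_sativa", "A_thaliana", "G_kirkii",
                          "G_raimondii")

#' Assign phylostratigraphic age bins from orthogroup membership
#'
#' A pangene's age bin is the deepest taxon sharing its orthogroup:
#' an ortholog in *O. sativa* gives `Age1` (oldest), else
#' *A. thaliana* `Age2`, else *G. kirkii* `Age3`, else *G. raimondii*
#' `Age4`, else `Age5` (pangenome-only, youngest). Pangenes absent
#' from the table (unclustered singletons) can be supplied via
#' `all_genes` and get `Age5`.
#'
#' @param orthogroups Tibble with columns `orthogroup`, `taxon`,
#'   `gene`; `taxon` must be one of `pangenes`, `G_raimondii`,
#'   `G_kirkii`, `A_thaliana`, `O_sativa` (or the custom ladder).
#' @param all_genes Optional character vector of all pangene ids;
#'   pangenes missing from `orthogroups` are added as singletons.
#' @param ladder Character vector of non-pangene taxa ordered deepest
#'   first (for reuse with other taxon sets).
#' @return Tibble with `gene`, `age` (`Age1` ... `AgeN`), where
#'   `AgeN = Age(length(ladder) + 1)` is the pangenome-only bin.
#' @export
assign_age <- function(orthogroups, all_genes = NULL,
                       ladder = default_taxon_ladder) {
  stopifnot(all(c("orthogroup", "taxon", "gene") %in% names(orthogroups)))
  known <- c("pangenes", ladder)
  bad <- setdiff(unique(orthogroups$taxon), known)
  if (length(bad) > 0) {
    stop("assign_age: unknown taxon label(s): ", paste(bad, collapse = ", "))
  }
  youngest <- length(ladder) + 1L
  # deepest taxon per orthogroup
  og_depth <- orthogroups |>
    group_by(.data$orthogroup) |>
    summarise(depth = {
      m <- match(.data$taxon, ladder)
      if (all(is.na(m))) youngest else min(m, na.rm = TRUE)
    }, .groups = "drop")
  pan <- orthogroups |>
    filter(.data$taxon == "pangenes") |>
    dplyr::distinct(.data$orthogroup, .data$gene)
  if (anyDuplicated(pan$gene)) {
    stop("assign_age: a pangene appears in more than one orthogroup")
  }
  out <- pan |>
    left_join(og_depth, by = "orthogroup") |>
    mutate(age = paste0("Age", .data$depth)) |>
    select("gene", "age")
  if (!is.null(all_genes)) {
    missing <- setdiff(all_genes, out$gene)
    out <- bind_rows(out, tibble(gene = missing,
                                 age = paste0("Age", youngest)))
  }
  arrange(out, .data$gene)
}

#' Relate gene age to nascent-sequence proximity
#'
#' For each age bin: the fraction of genes overlapping at least one
#' nascent interval, and the mean distance to the nearest nascent
#' interval (0 when overlapping).
#'
#' @param ages Tibble from [assign_age()] (`gene`, `age`).
#' @param genes Tibble of gene intervals with `gene`, `chrom`,
#'   `start`, `end`.
#' @param nascent Tibble of nascent intervals (`chrom`, `start`,
#'   `end`).
#' @return Tibble with `age`, `n`, `overlap_fraction`,
#'   `mean_distance` (all-`NA` distance when `nascent` is empty; bins
#'   with no genes are absent).
#' @export
age_vs_nascent <- function(ages, genes, nascent) {
  joined <- inner_join(ages, genes, by = "gene")
  if (nrow(nascent) == 0) {
    return(joined |>
             group_by(.data$age) |>
             summarise(n = n(), overlap_fraction = 0,
                       mean_distance = NA_real_, .groups = "drop"))
  }
  d <- nearest_distance(joined$chrom, joined$start, joined$end,
                        nascent$chrom, nascent$start, nascent$end)
  ovl <- vapply(seq_len(nrow(joined)), function(i) {
    any(nascent$chrom == joined$chrom[i] &
          nascent$start < joined$end[i] &
          nascent$end > joined$start[i])
  }, logical(1))
  joined |>
    mutate(dist = d, ovl = ovl) |>
    group_by(.data$age) |>
    summarise(n = n(),
              overlap_fraction = mean(.data$ovl),
              mean_distance = mean(.data$dist, na.rm = TRUE),
              .groups = "drop") |>
    arrange(.data$age)
}

#' Per-age-bin feature medians and age-feature rank correlations
#'
#' Computes the per-bin median of each feature and the Spearman rank
#' correlation of the feature against the numeric bin index (Age1 = 1,
#' oldest). A feature constant across genes gets correlation 0 with
#' p = 1 (no trend).
#'
#' @param ages Tibble from [assign_age()].
#' @param features Tibble with `gene` plus numeric feature columns
#'   (e.g. `length`, `exon_count`, `expression`, `presence_freq`,
#'   `ka_ks`).
#' @return List with `medians` (tibble age x feature medians) and
#'   `correlations` (tibble `feature`, `rho`, `p`).
#' @export
age_feature_trends <- function(ages, features) {
  stopifnot("gene" %in% names(features))
  joined <- inner_join(ages, features, by = "gene") |>
    mutate(age_index = as.integer(sub("^Age", "", .data$age)))
  feats <- setdiff(names(features), "gene")
  medians <- joined |>
    group_by(.data$age) |>
    summarise(n = n(),
              across(dplyr::all_of(feats), ~ median(.x, na.rm = TRUE)),
              .groups = "drop") |>
    arrange(.data$age)
  correlations <- bind_rows(lapply(feats, function(f) {
    x <- joined[[f]]
    ok <- !is.na(x)
    if (sum(ok) < 3 || all(is.na(x))) {
      return(tibble(feature = f, rho = NA_real_, p = NA_real_))
    }
    if (sd(x[ok]) == 0 || sd(joined$age_index[ok]) == 0) {
      return(tibble(feature = f, rho = 0, p = 1))
    }
    ct <- suppressWarnings(cor.test(joined$age_index[ok], x[ok],
                                    method = "spearman"))
    tibble(feature = f, rho = unname(ct$estimate), p = ct$p.value)
  }))
  list(medians = medians, correlations = correlations)
}
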