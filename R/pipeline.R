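# Pipeline configuration and the umbrella runner tying the simulated
# quartet through every analysis stage.

#' Pipeline configuration
#'
#' Aggregates every analysis threshold with its standard default, the
#' master seed, and the simulation configuration. Per-stage seeds are
#' derived deterministically from the master seed so stages can be
#' rerun independently with identical results.
#'
#' @param seed Master seed.
#' @param simulation Named list of overrides for [simulation_config()].
#' @param ... Named overrides for any threshold (see Details).
#'
#' @details Thresholds and defaults: `contig_min_len` 500 bp,
#' `aln_min_len` 300 bp, `aln_min_identity` 0.90, `nrs_min_unaligned`
#' 500 bp, `dedup_identity`/`dedup_coverage` 0.90, `present_frac` 0.80,
#' `min_cov` 2, `fragment_window` 1000 bp, `mask_gap_join` 50 bp,
#' `lost_cutoff` 0.20, `kmer_k` 15, `kmer_ratio` 2.0,
#' `trace_cover_frac` 0.90, `trace_span_max` 25000 bp,
#' `ltr_cluster_identity`/`ltr_cluster_coverage` 0.90,
#' `lifespan_quantiles` c(0.05, 0.95), `mutation_rate` 9e-9,
#' `fc_hi` 2.0, `fc_lo` 0.5, `fdr` 0.001, `n_perm` 1000,
#' `n_samplings` 200 (pan/core curve draws), `n_boot` 100 (k-mer
#' bootstraps).
#'
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, simulation = list(), ...) {
  defaults <- list(
    seed = as.integer(seed),
    contig_min_len = 500,
    aln_min_len = 300,
    aln_min_identity = 0.90,
    nrs_min_unaligned = 500,
    dedup_identity = 0.90,
    dedup_coverage = 0.90,
    present_frac = 0.80,
    min_cov = 2,
    fragment_window = 1000,
    mask_gap_join = 50,
    lost_cutoff = 0.20,
    kmer_k = 15,
    kmer_ratio = 2.0,
    trace_cover_frac = 0.90,
    trace_span_max = 25000,
    ltr_cluster_identity = 0.90,
    ltr_cluster_coverage = 0.90,
    lifespan_quantiles = c(0.05, 0.95),
    mutation_rate = 9e-9,
    divergence_factor = 1,
    fc_hi = 2.0,
    fc_lo = 0.5,
    fdr = 0.001,
    n_perm = 1000,
    n_samplings = 200,
    n_boot = 100,
    simulation = simulation
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop("pipeline_config: unknown option(s): ",
         paste(unknown, collapse = ", "))
  }
  defaults[names(overrides)] <- overrides
  structure(defaults, class = "pipeline_config")
}

# Deterministic per-stage seed derived from the master seed and the
# stage name (stable across sessions; kept below 2^31).
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 1009L + h) %% 2147480009L
}

#' Read/write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_pipeline_config`: a `pipeline_config`;
#'   `write_pipeline_config`: `path`, invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- raw$simulation %||% list()
  raw$simulation <- NULL
  do.call(pipeline_config,
          c(list(seed = raw$seed %||% 1L, simulation = sim),
            raw[setdiff(names(raw), "seed")]))
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full comparative-pangenome pipeline on a simulated quartet
#'
#' Simulates the quartet, then runs presence/absence calling and
#' occupancy classification, the pan/core rarefaction curve, the
#' group-frequency scan, genome-specific k-mer discovery, the
#' nascent/lost origin classification (A2 versus At), single-copy fate
#' classification with loss-mechanism tracing, and LTR dating/
#' clustering/specificity/lifespan analysis. Planted-truth recovery
#' metrics are attached wherever the truth tables apply.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, a JSON report and a
#'   log are written there.
#' @return A `pipeline_report` list of per-stage summary statistics.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(seed = config$seed,
                 thresholds = unclass(config)[setdiff(names(config),
                                                      c("simulation"))])

  # --- simulate ---
  sim_args <- config$simulation
  sim_args$seed <- sim_args$seed %||% stage_seed(config$seed, "simulate")
  quartet <- simulate_quartet(do.call(simulation_config, sim_args))
  report$simulate <- list(
    genome_mb = vapply(quartet$genomes,
                       function(g) sum(nchar(g)) / 1e6, numeric(1)),
    n_genes = nrow(quartet$genes),
    n_ltr = nrow(quartet$ltr)
  )

  # --- PAV ---
  depth <- simulate_depth_table(quartet,
                                seed = stage_seed(config$seed, "depth"))
  pav <- call_presence(depth, min_cov = config$min_cov,
                       present_frac = config$present_frac)
  truth_pav <- quartet$truth$pav |> arrange(.data$gene)
  pav_acc <- mean(as.matrix(pav[, -1]) ==
                    as.matrix(truth_pav[, names(pav)[-1]]))
  occ <- classify_occupancy(pav)
  curve <- pan_core_curve(pav, n_samplings = config$n_samplings,
                          seed = stage_seed(config$seed, "curve"))
  disp <- occ$gene[occ$occupancy != "core"]
  scan <- if (length(disp) >= 2) {
    frequency_change_scan(pav[pav$gene %in% disp, ],
                          quartet$truth$groups, focal_group = "CHN",
                          fc_hi = config$fc_hi, fc_lo = config$fc_lo,
                          fdr = config$fdr)
  }
  report$pav <- list(
    presence_call_accuracy = pav_acc,
    occupancy_counts = as.list(table(occ$occupancy)),
    occupancy_thresholds_341 = as.list(occupancy_thresholds(341)),
    pan_final = curve$pan_mean[nrow(curve)],
    core_final = curve$core_mean[nrow(curve)],
    n_dispensable = length(disp),
    n_favorable = if (!is.null(scan)) sum(scan$verdict == "favorable"),
    n_unfavorable = if (!is.null(scan)) sum(scan$verdict == "unfavorable")
  )

  # --- genome-specific k-mers ---
  prof_A <- count_kmers(quartet$genomes[c("A2", "At")], k = config$kmer_k)
  diff_A <- differential_kmers(prof_A, "A2", "At",
                               ratio = config$kmer_ratio)
  prof_D <- count_kmers(quartet$genomes[c("D5", "Dt")], k = config$kmer_k)
  diff_D <- differential_kmers(prof_D, "D5", "Dt",
                               ratio = config$kmer_ratio)
  report$kmers <- list(
    specific_A2 = sum(diff_A$genome == "A2", na.rm = TRUE),
    specific_At = sum(diff_A$genome == "At", na.rm = TRUE),
    specific_D5 = sum(diff_D$genome == "D5", na.rm = TRUE),
    specific_Dt = sum(diff_D$genome == "Dt", na.rm = TRUE)
  )

  # --- origin classification (A2 versus At) ---
  orig <- classify_quartet_origin(quartet, diff_A, config)
  report$origin <- orig$summary

  # --- single-copy fates ---
  fates <- classify_fate(family_counts(quartet))
  truth_f <- quartet$truth$family_fates
  joined <- inner_join(fates, truth_f, by = "family",
                       suffix = c("_called", "_true"))
  fate_acc <- mean(joined$fate_called == joined$fate_true)
  trace <- trace_quartet_losses(quartet, config)
  report$fates <- list(
    fate_counts = as.list(table(fates$fate)),
    fate_accuracy = fate_acc,
    te_recovery = trace$te_recovery,
    te_false_on_small = trace$te_false_on_small
  )

  # --- LTR dynamics ---
  ages <- date_ltr(quartet$ltr, r = config$mutation_rate,
                   divergence_factor = config$divergence_factor)
  truth_ages <- quartet$truth$ltr_ages
  age_join <- inner_join(ages, truth_ages, by = "element")
  clus <- cluster_ltr(tibble(element = quartet$ltr$element,
                             seq = unname(ltr_element_seqs(quartet))),
                      identity = config$ltr_cluster_identity,
                      coverage = config$ltr_cluster_coverage)
  comp <- quartet$ltr |>
    left_join(clus, by = "element") |>
    dplyr::count(.data$cluster, .data$genome) |>
    tidyr::pivot_wider(names_from = "genome", values_from = "n",
                       values_fill = 0L)
  for (g in c("A2", "D5", "At", "Dt")) {
    if (!g %in% names(comp)) comp[[g]] <- 0L
  }
  spec <- assign_specificity(comp)
  lifespan <- cluster_lifespan(left_join(clus, ages, by = "element"))
  report$ltr <- list(
    n_elements = nrow(ages),
    age_ratio_mean = mean(age_join$T_years / age_join$age),
    age_spearman = suppressWarnings(
      stats::cor(age_join$T_years, age_join$age, method = "spearman")),
    n_clusters = max(clus$cluster),
    specificity = as.list(table(spec$label)),
    lifespan_range_years = range(c(lifespan$t_start, lifespan$t_end),
                                 na.rm = TRUE)
  )

  report <- structure(report, class = "pipeline_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass_deep(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(c(
      paste("panploid", as.character(utils::packageVersion("panploid"))),
      paste("R", paste(R.version$major, R.version$minor, sep = ".")),
      paste("seed", config$seed),
      paste("date", "(unset; deterministic output)")
    ), file.path(out_dir, "run.log"))
  }
  report
}

# Fragment the diploid, map against the subgenome, merge unmapped runs,
# classify with diploid-specific k-mers, and score against truth.
classify_quartet_origin <- function(quartet, diff_kmers, config,
                                    diploid = "A2", subgenome = "At") {
  frags <- fragment_genome(quartet$genomes[[diploid]],
                           window = config$fragment_window)
  mapped <- map_fragments(frags, quartet$genomes[[diploid]],
                          quartet$genomes[[subgenome]])
  pav_iv <- merge_unmapped(mapped)
  pav_iv <- pav_iv[pav_iv$end - pav_iv$start >= config$nrs_min_unaligned, ]
  seqs <- setNames(
    substr(as_seq_chr(quartet$genomes[[diploid]])[pav_iv$chrom],
           pav_iv$start + 1L, pav_iv$end),
    sprintf("%s:%d-%d", pav_iv$chrom, pav_iv$start, pav_iv$end))
  spec_kmers <- diff_kmers$kmer[!is.na(diff_kmers$genome) &
                                  diff_kmers$genome == diploid]
  calls <- classify_origin(seqs, spec_kmers,
                           gap_join = config$mask_gap_join,
                           lost_cutoff = config$lost_cutoff)
  calls <- bind_cols(pav_iv, calls[, c("masked_bp", "masked_fraction",
                                       "verdict")])
  truth_nas <- quartet$truth$nascent[
    quartet$truth$nascent$genome == diploid, c("chrom", "start", "end")]
  truth_lost <- quartet$truth$lost[
    quartet$truth$lost$subgenome == subgenome, c("chrom", "start", "end")]
  called_nas <- calls[calls$verdict == "nascent", c("chrom", "start", "end")]
  called_lost <- calls[calls$verdict == "lost", c("chrom", "start", "end")]
  nas_total <- iv_total_bp(truth_nas)
  lost_total <- iv_total_bp(truth_lost)
  list(
    calls = calls,
    summary = list(
      n_pav_intervals = nrow(calls),
      pav_mb = sum(calls$end - calls$start) / 1e6,
      nascent_recall = iv_overlap_bp(called_nas, truth_nas) /
        max(1, nas_total),
      lost_recall = iv_overlap_bp(called_lost, truth_lost) /
        max(1, lost_total),
      nascent_precision = iv_overlap_bp(called_nas, truth_nas) /
        max(1, iv_total_bp(called_nas)),
      lost_precision = iv_overlap_bp(called_lost, truth_lost) /
        max(1, iv_total_bp(called_lost))
    )
  )
}

# Trace loss mechanisms for every reverted-single family of the
# quartet and score recovery against the planted mechanisms.
trace_quartet_losses <- function(quartet, config) {
  truth <- quartet$truth$family_fates |>
    filter(.data$fate == "reverted_single")
  results <- list()
  for (sg in c("At", "Dt")) {
    fams <- truth$family[truth$lost_subgenome == sg]
    if (length(fams) == 0) next
    diploid <- if (sg == "At") "A2" else "D5"
    gtab <- quartet$genes |>
      filter(.data$genome == diploid, .data$family %in% fams)
    qseqs <- setNames(
      substr(as_seq_chr(quartet$genomes[[diploid]])[gtab$chrom],
             gtab$start + 1L, gtab$end),
      gtab$family)
    aln <- naive_align(qseqs, quartet$genomes[[sg]])
    te <- quartet$ltr |>
      filter(.data$genome == sg) |>
      select("chrom", "start", "end")
    results[[sg]] <- trace_loss_mechanism(
      aln, te, genes = gtab$family,
      cover_frac = config$trace_cover_frac,
      span_max = config$trace_span_max)
  }
  mech <- bind_rows(results) |>
    left_join(truth |> select(gene = "family", true_mech = "mechanism"),
              by = "gene")
  te_true <- mech$true_mech == "TE_disruption"
  small_true <- mech$true_mech == "small_variation_or_annotation"
  list(
    mechanisms = mech,
    te_recovery = if (any(te_true)) {
      mean(mech$mechanism[te_true] == "TE_disruption")
    } else NA_real_,
    te_false_on_small = if (any(small_true)) {
      sum(mech$mechanism[small_true] == "TE_disruption")
    } else NA_integer_
  )
}

# Recursively strip classes/attributes for JSON serialization.
unclass_deep <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), unclass_deep)
  } else {
    unname_keep <- x
    attributes(unname_keep) <- if (!is.null(names(x))) {
      list(names = names(x))
    }
    unname_keep
  }
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> seed", x$seed, "\n")
  cat("  PAV: presence-call accuracy",
      sprintf("%.3f", x$pav$presence_call_accuracy),
      "| occupancy:", paste(names(x$pav$occupancy_counts),
                            unlist(x$pav$occupancy_counts),
                            collapse = ", "), "\n")
  cat("  origin: nascent recall",
      sprintf("%.3f", x$origin$nascent_recall),
      "| lost recall", sprintf("%.3f", x$origin$lost_recall), "\n")
  cat("  fates: accuracy", sprintf("%.3f", x$fates$fate_accuracy),
      "| TE recovery", sprintf("%.3f", x$fates$te_recovery), "\n")
  cat("  LTR: age ratio", sprintf("%.3f", x$ltr$age_ratio_mean),
      "| clusters", x$ltr$n_clusters, "\n")
  invisible(x)
}
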