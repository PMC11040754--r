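# Synthetic four-genome quartet generator with planted ground truth.
#
# The quartet emulates the comparative setting of diploid progenitor
# genomes (A2, D5) and an allotetraploid carrying At and Dt subgenomes:
# each subgenome is derived from its diploid's sequence, after which
# nascent sequence is inserted independently per genome and ancestral
# intervals are deleted from the subgenome copies. LTR retrotransposons
# are planted as TR-interior-TR blocks whose terminal repeats age under
# a forward Jukes-Cantor substitution model, so the dating estimator's
# assumed model matches the generator exactly.

#' Configuration for the synthetic genome quartet
#'
#' Defaults define the toy study scale: 4 chromosomes of 1 Mb per
#' genome, 200 gene families, and roughly 200 planted full-length LTR
#' elements across the four genomes, so that every pipeline stage
#' completes in minutes on one CPU.
#'
#' @param seed Integer seed fixing all generator output bit-for-bit.
#' @param n_chromosomes Chromosomes per genome.
#' @param chromosome_length_bp Backbone length of each chromosome.
#' @param n_genes Number of single-copy gene families (one member in
#'   each diploid genome).
#' @param gene_length_range Min/max gene length (bp).
#' @param n_ltr_families Number of LTR families used (at most 6);
#'   families carry fixed genome scopes: genome-specific (A2, D5),
#'   tetraploid-shared (At+Dt), diploid+subgenome (A2+At, D5+Dt) and
#'   common to all four genomes.
#' @param ltr_events_scale Multiplier on the per-family insertion-event
#'   counts (0 disables LTR planting entirely).
#' @param ltr_interior_bp Interior (between-repeat) length of planted
#'   elements.
#' @param terminal_repeat_bp Length of each terminal repeat.
#' @param mutation_rate_per_site_per_year Clock rate `r` used to age
#'   terminal repeats (default 9e-9, the rate used for cotton LTR
#'   dating). The repeat PAIR diverges at `r` per site per year (each
#'   repeat accumulates half), so the dating formula `T = K/r` recovers
#'   the planted age without rescaling.
#' @param age_range_years Range of planted insertion ages.
#' @param n_nascent_per_genome Nascent (novel) insertions planted per
#'   genome.
#' @param nascent_length_range Min/max nascent insertion length.
#' @param n_lost_per_subgenome Ancestral non-genic intervals deleted
#'   from each subgenome (besides gene-fate deletions).
#' @param lost_length_range Min/max deleted interval length.
#' @param n_accessions Accession panel size for the PAV truth matrix.
#' @param group_labels Named proportions of accession group labels.
#' @param core_fraction Fraction of gene families present in every
#'   accession.
#' @param presence_sfs Range of presence frequencies for dispensable
#'   genes (uniform site-frequency spectrum).
#' @param depth_mean Nominal sequencing depth recorded in depth tables.
#' @param backbone_divergence Substitution rate applied to each
#'   subgenome backbone after derivation (default 0.5%).
#' @param family_divergence Per-member substitution divergence from the
#'   LTR family consensus.
#' @param nascent_copy_divergence Per-copy divergence of nascent
#'   insertions from their family donor.
#' @param fate_counts Named counts of gene-family fates (`balanced`,
#'   `lost_both`, `reverted_At`, `reverted_Dt`, `gained`). Each reverted
#'   group is split as evenly as possible between TE-disruption,
#'   annotation-omission and clean-deletion loss mechanisms; `gained`
#'   families are split between the two subgenomes.
#'
#' @return A `simulation_config` list.
#' @seealso [simulate_quartet()]
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 4L,
                              chromosome_length_bp = 1e6,
                              n_genes = 200L,
                              gene_length_range = c(1000, 2500),
                              n_ltr_families = 6L,
                              ltr_events_scale = 1,
                              ltr_interior_bp = 2000L,
                              terminal_repeat_bp = 4000L,
                              mutation_rate_per_site_per_year = 9e-9,
                              age_range_years = c(1e5, 3e6),
                              n_nascent_per_genome = 25L,
                              nascent_length_range = c(2000, 6000),
                              n_lost_per_subgenome = 24L,
                              lost_length_range = c(8000, 16000),
                              n_accessions = 60L,
                              group_labels = c(CHN = 0.645, SouthAsia = 0.151,
                                               US = 0.076, other = 0.128),
                              core_fraction = 0.8,
                              presence_sfs = c(0.05, 0.95),
                              depth_mean = 20,
                              backbone_divergence = 0.005,
                              family_divergence = 0.02,
                              nascent_copy_divergence = 0.01,
                              fate_counts = c(balanced = 150, lost_both = 10,
                                              reverted_At = 15,
                                              reverted_Dt = 15,
                                              gained = 10)) {
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length_bp = as.integer(chromosome_length_bp),
    n_genes = as.integer(n_genes),
    gene_length_range = gene_length_range,
    n_ltr_families = as.integer(n_ltr_families),
    ltr_events_scale = ltr_events_scale,
    ltr_interior_bp = as.integer(ltr_interior_bp),
    terminal_repeat_bp = as.integer(terminal_repeat_bp),
    mutation_rate_per_site_per_year = mutation_rate_per_site_per_year,
    age_range_years = age_range_years,
    n_nascent_per_genome = as.integer(n_nascent_per_genome),
    nascent_length_range = nascent_length_range,
    n_lost_per_subgenome = as.integer(n_lost_per_subgenome),
    lost_length_range = lost_length_range,
    n_accessions = as.integer(n_accessions),
    group_labels = group_labels,
    core_fraction = core_fraction,
    presence_sfs = presence_sfs,
    depth_mean = depth_mean,
    backbone_divergence = backbone_divergence,
    family_divergence = family_divergence,
    nascent_copy_divergence = nascent_copy_divergence,
    fate_counts = fate_counts
  )
  needed <- c("balanced", "lost_both", "reverted_At", "reverted_Dt", "gained")
  stopifnot(all(needed %in% names(cfg$fate_counts)))
  if (sum(cfg$fate_counts) != cfg$n_genes) {
    stop("fate_counts must sum to n_genes")
  }
  mean_gene <- mean(cfg$gene_length_range)
  ancestor <- cfg$n_chromosomes * cfg$chromosome_length_bp
  if (ancestor < 10 * cfg$n_genes * mean_gene) {
    stop("ancestor length must be at least 10x total gene length")
  }
  if (abs(sum(cfg$group_labels) - 1) > 1e-6) {
    stop("group_labels proportions must sum to 1")
  }
  structure(cfg, class = "simulation_config")
}

# ---- sequence mutation helpers -----------------------------------------

# Point substitutions at `rate` per site (uniform among the 3
# alternative bases).
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  idx <- which(runif(n) < rate)
  if (length(idx) == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  cur <- match(chars[idx], bases)
  shift <- sample.int(3L, length(idx), replace = TRUE)
  chars[idx] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  paste(chars, collapse = "")
}

# Forward Jukes-Cantor aging: per-site Poisson(lambda) substitution
# events, each replacing the current base uniformly among the three
# alternatives; multiple hits per site are permitted (they are what the
# JC correction later undoes).
jc_age_seq <- function(seq, lambda) {
  if (lambda <= 0) return(seq)
  n <- nchar(seq)
  m <- rpois(n, lambda)
  hit <- which(m > 0)
  if (length(hit) == 0) return(seq)
  p_same <- 1 / 4 + 3 / 4 * (-1 / 3)^m[hit]  # final-base law after m events
  change <- runif(length(hit)) >= p_same
  idx <- hit[change]
  if (length(idx) == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  cur <- match(chars[idx], bases)
  shift <- sample.int(3L, length(idx), replace = TRUE)
  chars[idx] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  paste(chars, collapse = "")
}

# ---- edit engine -------------------------------------------------------

# Apply non-overlapping edits to one chromosome. `edits`:
# tibble(id, pos, del_len, ins_seq) in source coordinates (0-based;
# insertions take effect before the base at `pos`). Returns the edited
# sequence, the new coordinates of each insertion, and a vectorized
# source->edited position mapper (NA strictly inside deletions).
apply_edits <- function(seq, edits) {
  if (is.null(edits) || nrow(edits) == 0) {
    return(list(seq = seq,
                inserted = tibble(id = character(), start = integer(),
                                  end = integer()),
                map = function(x) as.integer(x)))
  }
  edits <- dplyr::arrange(edits, .data$pos)
  ends <- edits$pos + edits$del_len
  if (nrow(edits) > 1 && any(edits$pos[-1] < ends[-nrow(edits)])) {
    stop("apply_edits: overlapping edits")
  }
  n <- nchar(seq)
  if (any(ends > n)) stop("apply_edits: edit beyond sequence end")
  ins_len <- nchar(edits$ins_seq)
  delta <- cumsum(ins_len - edits$del_len)
  pieces <- character(2 * nrow(edits) + 1)
  prev <- 0L
  for (i in seq_len(nrow(edits))) {
    pieces[2 * i - 1] <- substr(seq, prev + 1L, edits$pos[i])
    pieces[2 * i] <- edits$ins_seq[i]
    prev <- ends[i]
  }
  pieces[2 * nrow(edits) + 1] <- substr(seq, prev + 1L, n)
  delta_before <- c(0, delta[-length(delta)])
  ins_start <- as.integer(edits$pos + delta_before)
  inserted <- tibble(id = edits$id, start = ins_start,
                     end = as.integer(ins_start + ins_len))
  inserted <- inserted[ins_len > 0, , drop = FALSE]
  pos_v <- edits$pos
  ends_v <- ends
  delta_v <- delta
  map <- function(x) {
    i <- findInterval(x, ends_v)
    out <- x + ifelse(i == 0, 0, delta_v[pmax(i, 1L)])
    j <- findInterval(x, pos_v)
    inside <- j >= 1 & x > pos_v[pmax(j, 1L)] & x < ends_v[pmax(j, 1L)]
    out[inside] <- NA_integer_
    as.integer(out)
  }
  list(seq = paste(pieces, collapse = ""), inserted = inserted, map = map)
}

# Sample non-overlapping placement windows of the given widths, avoiding
# `blocked` intervals with a safety margin. Returns the placements and
# the updated blocked set so successive calls share one ledger.
sample_placements <- function(chrom_lens, widths, blocked, margin = 200L,
                              max_try = 200L) {
  blocked_by_chr <- split(blocked[, c("start", "end")], blocked$chrom)
  chrom <- character(length(widths))
  pos <- integer(length(widths))
  chr_names <- names(chrom_lens)
  for (i in seq_along(widths)) {
    w <- widths[i]
    placed <- FALSE
    for (try in seq_len(max_try)) {
      ch <- sample(chr_names, 1, prob = chrom_lens)
      len <- chrom_lens[[ch]]
      if (len - w - 2 * margin <= 0) next
      p <- sample.int(as.integer(len - w - 2L * margin), 1L) + margin
      blk <- blocked_by_chr[[ch]]
      clash <- !is.null(blk) && nrow(blk) > 0 &&
        any(p < blk$end + margin & p + w > blk$start - margin)
      if (!clash) {
        chrom[i] <- ch
        pos[i] <- p
        blocked_by_chr[[ch]] <- bind_rows(blk, tibble(start = p, end = p + w))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("overlap-exhaustion: could not place interval of width ", w,
           " after ", max_try, " attempts; reduce the insertion load or ",
           "increase chromosome length")
    }
  }
  out_blocked <- bind_rows(lapply(names(blocked_by_chr), function(ch) {
    mutate(blocked_by_chr[[ch]], chrom = ch)
  }))
  list(placements = tibble(chrom = chrom, pos = pos, width = widths),
       blocked = out_blocked[, c("chrom", "start", "end")])
}

# ---- main generator ----------------------------------------------------

#' Simulate a diploid/tetraploid genome quartet with planted truth
#'
#' Generates A2 and D5 diploid backbones, derives the At and Dt
#' subgenomes from them, and plants (i) full-length LTR elements of
#' known age organised into families with controlled genome scope,
#' (ii) nascent sequence insertions per genome drawn from repeated
#' donor families (so their k-mers are abundant, as TE-driven nascent
#' sequence is in real genomes), (iii) deleted ancestral intervals per
#' subgenome, (iv) single-copy gene families with known fates including
#' TE-disruption and annotation-omission losses, and (v) an accession
#' panel with a structured gene presence/absence matrix. Every planted
#' entity is recorded in a truth table.
#'
#' @param config A [simulation_config()].
#' @return A `genome_quartet` list with elements:
#'   * `genomes`: named list (`A2`, `At`, `D5`, `Dt`) of named
#'     chromosome sequence vectors;
#'   * `genes`, `exons`: annotation tibbles (0-based half-open);
#'   * `ltr`: planted full-length LTR element records with terminal
#'     repeat sequences;
#'   * `truth`: list of truth tables (`nascent`, `lost`, `ltr_ages`,
#'     `family_fates`, `te_disrupted`, `pav`, `groups`,
#'     `nascent_families`);
#'   * `config`: the configuration used.
#' @export
simulate_quartet <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  local_seed_if(cfg$seed)
  chr_names <- sprintf("chr%02d", seq_len(cfg$n_chromosomes))
  chrom_lens <- setNames(rep(cfg$chromosome_length_bp, cfg$n_chromosomes),
                         chr_names)
  r <- cfg$mutation_rate_per_site_per_year
  tr_len <- cfg$terminal_repeat_bp

  # --- backbones, genes, exons (per lineage) ---
  make_backbone <- function() {
    setNames(vapply(chr_names, function(ch) random_dna(chrom_lens[[ch]]),
                    character(1)), chr_names)
  }
  place_genes <- function() {
    per_chr <- diff(round(seq(0, cfg$n_genes,
                              length.out = cfg$n_chromosomes + 1)))
    rows <- vector("list", cfg$n_genes)
    gi <- 0L
    for (ci in seq_len(cfg$n_chromosomes)) {
      ng <- per_chr[ci]
      if (ng == 0) next
      slot <- chrom_lens[[ci]] / ng
      for (j in seq_len(ng)) {
        gi <- gi + 1L
        len <- as.integer(round(runif(1, cfg$gene_length_range[1],
                                      cfg$gene_length_range[2])))
        lo <- (j - 1) * slot + 0.1 * slot
        hi <- max(lo + 1, j * slot - 0.1 * slot - len)
        start <- as.integer(round(runif(1, lo, hi)))
        rows[[gi]] <- tibble(family = sprintf("fam%03d", gi),
                             chrom = chr_names[ci],
                             start = start, end = start + len)
      }
    }
    bind_rows(rows)
  }
  # exon layout relative to the gene start; reused for every genome copy
  make_exons_rel <- function(genes) {
    rows <- vector("list", nrow(genes))
    for (i in seq_len(nrow(genes))) {
      len <- genes$end[i] - genes$start[i]
      n_ex <- sample.int(4L, 1L)
      if (n_ex == 1) {
        bmat <- cbind(0L, len)
      } else {
        cuts <- sort(sample(seq_len(len - 1L), 2L * (n_ex - 1L)))
        starts <- c(0L, cuts[seq(2, length(cuts), by = 2)])
        stops <- c(cuts[seq(1, length(cuts), by = 2)], len)
        bmat <- cbind(starts, stops)
      }
      rows[[i]] <- tibble(family = genes$family[i],
                          exon = seq_len(nrow(bmat)),
                          rel_start = as.integer(bmat[, 1]),
                          rel_end = as.integer(bmat[, 2]))
    }
    bind_rows(rows)
  }

  backbone_A <- make_backbone()
  genes_A <- place_genes()
  exons_rel <- make_exons_rel(genes_A)  # shared exon layout per family
  backbone_D <- make_backbone()
  genes_D <- place_genes()

  # --- LTR family scaffolding ---
  fam_tbl <- tibble(
    family = c("ltrfam_A2", "ltrfam_D5", "ltrfam_AtDt", "ltrfam_A2At",
               "ltrfam_D5Dt", "ltrfam_common"),
    superfamily = c("Gypsy", "Gypsy", "Gypsy", "Copia", "Copia", "Copia"),
    scope = c("A2", "D5", "AtDt", "preA", "preD", "preBoth"),
    n_events = c(36L, 12L, 60L, 14L, 14L, 20L)
  )
  fam_tbl <- fam_tbl[seq_len(min(nrow(fam_tbl), cfg$n_ltr_families)), ]
  fam_tbl$n_events <- as.integer(round(fam_tbl$n_events *
                                         cfg$ltr_events_scale))
  fam_donor_tr <- setNames(
    vapply(fam_tbl$family, function(f) random_dna(tr_len), character(1)),
    fam_tbl$family)
  fam_donor_int <- setNames(
    vapply(fam_tbl$family, function(f) random_dna(cfg$ltr_interior_bp),
           character(1)),
    fam_tbl$family)

  element_counter <- 0L
  # One insertion event: member divergence is applied once to a single
  # TR template (and the interior), the TR is then duplicated and each
  # copy aged independently so the pair diverges at r * age.
  build_element <- function(family, age) {
    element_counter <<- element_counter + 1L
    tr_m <- mutate_seq(fam_donor_tr[[family]], cfg$family_divergence)
    int_m <- mutate_seq(fam_donor_int[[family]], cfg$family_divergence)
    lambda <- r * age / 2
    ltr5 <- jc_age_seq(tr_m, lambda)
    ltr3 <- jc_age_seq(tr_m, lambda)
    sf <- fam_tbl$superfamily[match(family, fam_tbl$family)]
    tibble(event = sprintf("ltr%04d", element_counter),
           family = family, superfamily = sf, age = age,
           ltr5_seq = ltr5, ltr3_seq = ltr3,
           seq = paste0(ltr5, int_m, ltr3))
  }
  build_elements <- function(family, n, ages = NULL) {
    if (n == 0) return(NULL)
    if (is.null(ages)) {
      ages <- runif(n, cfg$age_range_years[1], cfg$age_range_years[2])
    }
    bind_rows(lapply(seq_len(n), function(i) build_element(family, ages[i])))
  }

  # --- plant pre-derivation elements into a diploid backbone ---
  plant_pre <- function(backbone, genes, scopes) {
    fams <- fam_tbl[fam_tbl$scope %in% scopes, ]
    ev <- bind_rows(lapply(seq_len(nrow(fams)), function(i) {
      n_ev <- fams$n_events[i]
      if (fams$scope[i] == "preBoth") n_ev <- n_ev %/% 2L
      build_elements(fams$family[i], n_ev)
    }))
    blocked <- genes[, c("chrom", "start", "end")]
    if (is.null(ev) || nrow(ev) == 0) {
      return(list(backbone = backbone, genes = genes, elements = NULL,
                  blocked = blocked))
    }
    sp <- sample_placements(chrom_lens, nchar(ev$seq), blocked)
    ev$chrom <- sp$placements$chrom
    ev$pos <- sp$placements$pos
    new_backbone <- backbone
    placed <- vector("list", length(chr_names))
    for (ci in seq_along(chr_names)) {
      ch <- chr_names[ci]
      idx <- which(ev$chrom == ch)
      gsel <- which(genes$chrom == ch)
      if (length(idx) == 0) next
      res <- apply_edits(backbone[[ch]],
                         tibble(id = ev$event[idx], pos = ev$pos[idx],
                                del_len = 0L, ins_seq = ev$seq[idx]))
      new_backbone[[ch]] <- res$seq
      if (length(gsel) > 0) {
        glen <- genes$end[gsel] - genes$start[gsel]
        genes$start[gsel] <- res$map(genes$start[gsel])
        genes$end[gsel] <- genes$start[gsel] + glen
      }
      m <- match(res$inserted$id, ev$event)
      placed[[ci]] <- mutate(ev[m, c("event", "family", "superfamily",
                                     "age", "ltr5_seq", "ltr3_seq")],
                             chrom = ch, start = res$inserted$start,
                             end = res$inserted$end)
    }
    elements <- bind_rows(placed)
    blocked <- bind_rows(genes[, c("chrom", "start", "end")],
                         elements[, c("chrom", "start", "end")])
    list(backbone = new_backbone, genes = genes, elements = elements,
         blocked = blocked)
  }

  preA <- plant_pre(backbone_A, genes_A, c("preA", "preBoth"))
  backbone_A <- preA$backbone
  genes_A <- preA$genes
  preD <- plant_pre(backbone_D, genes_D, c("preD", "preBoth"))
  backbone_D <- preD$backbone
  genes_D <- preD$genes

  # --- gene-family fates ---
  fc <- cfg$fate_counts
  shuffled <- sample(genes_A$family)
  take <- function(n) {
    out <- shuffled[seq_len(n)]
    shuffled <<- shuffled[-seq_len(n)]
    out
  }
  fam_lost_both <- take(fc[["lost_both"]])
  fam_rev_At <- take(fc[["reverted_At"]])
  fam_rev_Dt <- take(fc[["reverted_Dt"]])
  fam_gained <- take(fc[["gained"]])
  fam_balanced <- shuffled
  split_mech <- function(fams) {
    n <- length(fams)
    mech <- rep(c("TE_disruption", "small_variation_or_annotation",
                  "deletion"), length.out = n)
    setNames(mech, fams)
  }
  mech_At <- split_mech(fam_rev_At)
  mech_Dt <- split_mech(fam_rev_Dt)
  gained_At <- fam_gained[seq_len(length(fam_gained) %/% 2)]
  gained_Dt <- setdiff(fam_gained, gained_At)

  # --- nascent donor families ---
  nas_scopes <- c(nasA2_1 = "A2", nasA2_2 = "A2", nasD5_1 = "D5",
                  nasD5_2 = "D5", nasAt_1 = "At", nasAt_2 = "At",
                  nasDt_1 = "Dt", nasDt_2 = "Dt", nasAtDt_1 = "AtDt",
                  nasAtDt_2 = "AtDt")
  nas_donor <- setNames(
    vapply(names(nas_scopes),
           function(f) random_dna(cfg$nascent_length_range[2]), character(1)),
    names(nas_scopes))
  nascent_counter <- 0L
  build_nascent <- function(genome) {
    n <- cfg$n_nascent_per_genome
    if (n == 0) return(NULL)
    fams <- names(nas_scopes)[nas_scopes %in%
                                c(genome, if (genome %in% c("At", "Dt")) "AtDt")]
    pick <- sample(fams, n, replace = TRUE)
    lens <- as.integer(round(runif(n, cfg$nascent_length_range[1],
                                   cfg$nascent_length_range[2])))
    seqs <- vapply(seq_len(n), function(i) {
      mutate_seq(substr(nas_donor[[pick[i]]], 1L, lens[i]),
                 cfg$nascent_copy_divergence)
    }, character(1))
    ids <- sprintf("nas%04d", nascent_counter + seq_len(n))
    nascent_counter <<- nascent_counter + n
    tibble(id = ids, family = pick, seq = seqs)
  }

  # --- assemble one lineage (diploid + derived subgenome) ---
  # Shares a single placement ledger so diploid insertions never fall
  # inside subgenome deletions (keeps lost-interval truth clean).
  assemble_lineage <- function(backbone, genes, pre_blocked, pre_elements,
                               diploid, subgenome,
                               fam_lost_here, mech_here, gained_here) {
    blocked <- pre_blocked
    glen <- function(f) {
      i <- match(f, genes$family)
      genes$end[i] - genes$start[i]
    }
    # subgenome deletions: sampled non-genic lost intervals + gene bodies
    n_lost <- cfg$n_lost_per_subgenome
    del_tbl <- NULL
    if (n_lost > 0) {
      widths <- as.integer(round(runif(n_lost, cfg$lost_length_range[1],
                                       cfg$lost_length_range[2])))
      sp <- sample_placements(chrom_lens, widths, blocked)
      blocked <- sp$blocked
      del_tbl <- mutate(sp$placements,
                        id = sprintf("lost_%s_%02d", subgenome,
                                     seq_len(n_lost)))
    }
    del_genes <- c(fam_lost_both,
                   names(mech_here)[mech_here == "deletion"])
    del_gene_tbl <- NULL
    if (length(del_genes) > 0) {
      gi <- match(del_genes, genes$family)
      del_gene_tbl <- tibble(chrom = genes$chrom[gi], pos = genes$start[gi],
                             width = genes$end[gi] - genes$start[gi],
                             id = paste0("loss_", del_genes))
    }
    # diploid insertions: genome-specific LTR family + nascent copies
    dip_fam <- fam_tbl$family[fam_tbl$scope == diploid]
    dip_ltr <- if (length(dip_fam) == 1) {
      build_elements(dip_fam, fam_tbl$n_events[fam_tbl$scope == diploid])
    }
    dip_nas <- build_nascent(diploid)
    dip_ins <- bind_rows(
      if (!is.null(dip_ltr)) tibble(id = dip_ltr$event, seq = dip_ltr$seq,
                                    kind = "ltr"),
      if (!is.null(dip_nas)) tibble(id = dip_nas$id, seq = dip_nas$seq,
                                    kind = "nascent")
    )
    if (!is.null(dip_ins) && nrow(dip_ins) > 0) {
      sp <- sample_placements(chrom_lens, nchar(dip_ins$seq), blocked)
      blocked <- sp$blocked
      dip_ins <- bind_cols(dip_ins, sp$placements[, c("chrom", "pos")])
    }
    # subgenome insertions: tetraploid-burst LTRs, nascent copies,
    # gained-gene duplicates
    sub_ltr_n <- fam_tbl$n_events[fam_tbl$scope == "AtDt"]
    sub_ltr <- if (length(sub_ltr_n) == 1) {
      build_elements("ltrfam_AtDt", sub_ltr_n %/% 2L)
    }
    sub_nas <- build_nascent(subgenome)
    dup_tbl <- NULL
    if (length(gained_here) > 0) {
      gi <- match(gained_here, genes$family)
      dup_tbl <- tibble(id = paste0("dup_", gained_here),
                        seq = vapply(seq_along(gi), function(k) {
                          substr(backbone[[genes$chrom[gi[k]]]],
                                 genes$start[gi[k]] + 1L, genes$end[gi[k]])
                        }, character(1)),
                        kind = "gained_dup")
    }
    sub_ins <- bind_rows(
      if (!is.null(sub_ltr)) tibble(id = sub_ltr$event, seq = sub_ltr$seq,
                                    kind = "ltr"),
      if (!is.null(sub_nas)) tibble(id = sub_nas$id, seq = sub_nas$seq,
                                    kind = "nascent"),
      dup_tbl
    )
    if (!is.null(sub_ins) && nrow(sub_ins) > 0) {
      sp <- sample_placements(chrom_lens, nchar(sub_ins$seq), blocked)
      blocked <- sp$blocked
      sub_ins <- bind_cols(sub_ins, sp$placements[, c("chrom", "pos")])
    }
    # TE-disruption insertions: young elements mid-gene (subgenome only)
    te_fams <- names(mech_here)[mech_here == "TE_disruption"]
    te_ins <- NULL
    if (length(te_fams) > 0) {
      ages <- runif(length(te_fams), cfg$age_range_years[1],
                    mean(cfg$age_range_years))
      te_el <- bind_rows(lapply(seq_along(te_fams), function(i) {
        build_element("ltrfam_AtDt", ages[i])
      }))
      gi <- match(te_fams, genes$family)
      te_ins <- tibble(id = te_el$event, seq = te_el$seq, kind = "te_disrupt",
                       chrom = genes$chrom[gi],
                       pos = as.integer(genes$start[gi] +
                                          (genes$end[gi] - genes$start[gi]) %/% 2L),
                       disrupted_family = te_fams)
      sub_ltr <- bind_rows(sub_ltr, te_el)
    }
    # --- apply edits per chromosome ---
    dip_seq <- backbone
    sub_seq <- vapply(backbone, mutate_seq, character(1),
                      rate = cfg$backbone_divergence)
    dip_new <- list()
    sub_new <- list()
    dip_maps <- list()
    sub_maps <- list()
    for (ch in chr_names) {
      d_ed <- if (!is.null(dip_ins) && nrow(dip_ins) > 0) {
        di <- dip_ins[dip_ins$chrom == ch, ]
        tibble(id = di$id, pos = di$pos, del_len = 0L, ins_seq = di$seq)
      }
      res_d <- apply_edits(backbone[[ch]], d_ed)
      dip_new[[ch]] <- res_d
      dip_maps[[ch]] <- res_d$map
      s_rows <- bind_rows(
        if (!is.null(del_tbl)) {
          dd <- del_tbl[del_tbl$chrom == ch, ]
          tibble(id = dd$id, pos = dd$pos, del_len = dd$width, ins_seq = "")
        },
        if (!is.null(del_gene_tbl)) {
          dd <- del_gene_tbl[del_gene_tbl$chrom == ch, ]
          tibble(id = dd$id, pos = dd$pos, del_len = dd$width, ins_seq = "")
        },
        if (!is.null(sub_ins) && nrow(sub_ins) > 0) {
          si <- sub_ins[sub_ins$chrom == ch, ]
          tibble(id = si$id, pos = si$pos, del_len = 0L, ins_seq = si$seq)
        },
        if (!is.null(te_ins)) {
          ti <- te_ins[te_ins$chrom == ch, ]
          tibble(id = ti$id, pos = ti$pos, del_len = 0L, ins_seq = ti$seq)
        }
      )
      res_s <- apply_edits(sub_seq[[ch]], s_rows)
      sub_new[[ch]] <- res_s
      sub_maps[[ch]] <- res_s$map
    }
    map_pos <- function(maps, chrom, x) {
      out <- integer(length(x))
      for (ch in unique(chrom)) {
        sel <- chrom == ch
        out[sel] <- maps[[ch]](x[sel])
      }
      out
    }
    list(
      diploid_seq = setNames(vapply(dip_new, `[[`, character(1), "seq"),
                             chr_names),
      sub_seq = setNames(vapply(sub_new, `[[`, character(1), "seq"),
                         chr_names),
      dip_map = function(chrom, x) map_pos(dip_maps, chrom, x),
      sub_map = function(chrom, x) map_pos(sub_maps, chrom, x),
      dip_inserted = bind_rows(lapply(chr_names, function(ch) {
        mutate(dip_new[[ch]]$inserted, chrom = ch)
      })),
      sub_inserted = bind_rows(lapply(chr_names, function(ch) {
        mutate(sub_new[[ch]]$inserted, chrom = ch)
      })),
      genes = genes, pre_elements = pre_elements,
      dip_ltr = dip_ltr, sub_ltr = sub_ltr,
      dip_nas = dip_nas, sub_nas = sub_nas,
      dip_ins = dip_ins, sub_ins = sub_ins,
      del_tbl = del_tbl, del_gene_tbl = del_gene_tbl, te_ins = te_ins
    )
  }

  linA <- assemble_lineage(backbone_A, genes_A, preA$blocked, preA$elements,
                           "A2", "At", fam_lost_both, mech_At, gained_At)
  linD <- assemble_lineage(backbone_D, genes_D, preD$blocked, preD$elements,
                           "D5", "Dt", fam_lost_both, mech_Dt, gained_Dt)

  # --- per-genome annotations ---
  lost_fams <- list(
    At = union(fam_lost_both, fam_rev_At),
    Dt = union(fam_lost_both, fam_rev_Dt)
  )
  gene_rows <- function(lin, genome, is_sub, lost, gained_here) {
    genes <- lin$genes
    mapf <- if (is_sub) lin$sub_map else lin$dip_map
    keep <- if (is_sub) !(genes$family %in% lost) else rep(TRUE, nrow(genes))
    g <- genes[keep, ]
    glen <- g$end - g$start
    # TE-disrupted genes never reach here (they are in `lost`), so gene
    # spans map cleanly; intact genes contain no internal edits.
    new_start <- mapf(g$chrom, g$start)
    out <- tibble(genome = genome, gene_id = paste0(g$family, "_", genome),
                  family = g$family, chrom = g$chrom,
                  start = new_start, end = new_start + glen,
                  strand = "+", copy = 1L)
    if (is_sub && length(gained_here) > 0) {
      ins <- lin$sub_inserted
      di <- ins[ins$id %in% paste0("dup_", gained_here), ]
      fam <- sub("^dup_", "", di$id)
      out <- bind_rows(out, tibble(
        genome = genome, gene_id = paste0(fam, "_", genome, "_copy2"),
        family = fam, chrom = di$chrom, start = di$start, end = di$end,
        strand = "+", copy = 2L))
    }
    out
  }
  genes_all <- bind_rows(
    gene_rows(linA, "A2", FALSE, character(), character()),
    gene_rows(linA, "At", TRUE, lost_fams$At, gained_At),
    gene_rows(linD, "D5", FALSE, character(), character()),
    gene_rows(linD, "Dt", TRUE, lost_fams$Dt, gained_Dt)
  )
  exons_all <- genes_all |>
    filter(.data$copy == 1L) |>
    inner_join(exons_rel, by = "family", relationship = "many-to-many") |>
    mutate(ex_start = .data$start + .data$rel_start,
           ex_end = .data$start + .data$rel_end) |>
    select("genome", "gene_id", "family", "chrom", "exon",
           start = "ex_start", end = "ex_end")

  # --- per-genome LTR records ---
  ltr_records <- function(lin, genome, is_sub) {
    mapf <- if (is_sub) lin$sub_map else lin$dip_map
    recs <- list()
    pre <- lin$pre_elements
    if (!is.null(pre) && nrow(pre) > 0) {
      w <- pre$end - pre$start
      s <- mapf(pre$chrom, pre$start)
      recs[[1]] <- mutate(pre[, c("event", "family", "superfamily", "age",
                                  "ltr5_seq", "ltr3_seq", "chrom")],
                          start = s, end = s + w)
    }
    post <- if (is_sub) lin$sub_ltr else lin$dip_ltr
    ins <- if (is_sub) lin$sub_inserted else lin$dip_inserted
    if (!is.null(post) && nrow(post) > 0) {
      m <- match(post$event, ins$id)
      ok <- !is.na(m)
      recs[[2]] <- mutate(post[ok, c("event", "family", "superfamily", "age",
                                     "ltr5_seq", "ltr3_seq")],
                          chrom = ins$chrom[m[ok]], start = ins$start[m[ok]],
                          end = ins$end[m[ok]])
    }
    out <- bind_rows(recs)
    if (nrow(out) == 0) return(NULL)
    mutate(out, genome = genome, element = paste0(.data$event, "_", genome))
  }
  ltr_all <- bind_rows(
    ltr_records(linA, "A2", FALSE), ltr_records(linA, "At", TRUE),
    ltr_records(linD, "D5", FALSE), ltr_records(linD, "Dt", TRUE)
  )
  if (nrow(ltr_all) > 0) {
    ltr_all <- ltr_all[, c("element", "event", "genome", "family",
                           "superfamily", "chrom", "start", "end", "age",
                           "ltr5_seq", "ltr3_seq")]
  }

  # --- truth tables ---
  nascent_truth <- function(lin, genome, is_sub) {
    ins <- if (is_sub) lin$sub_ins else lin$dip_ins
    inserted <- if (is_sub) lin$sub_inserted else lin$dip_inserted
    rows <- list()
    if (!is.null(ins) && nrow(ins) > 0) {
      keep <- ins$kind %in% c("ltr", "nascent")  # gained duplicates excluded
      m <- match(ins$id[keep], inserted$id)
      rows[[1]] <- tibble(genome = genome, id = ins$id[keep],
                          kind = ins$kind[keep],
                          chrom = inserted$chrom[m],
                          start = inserted$start[m], end = inserted$end[m])
    }
    if (is_sub && !is.null(lin$te_ins)) {
      m <- match(lin$te_ins$id, inserted$id)
      rows[[2]] <- tibble(genome = genome, id = lin$te_ins$id,
                          kind = "te_disrupt", chrom = inserted$chrom[m],
                          start = inserted$start[m], end = inserted$end[m])
    }
    bind_rows(rows)
  }
  nascent_all <- bind_rows(
    nascent_truth(linA, "A2", FALSE), nascent_truth(linA, "At", TRUE),
    nascent_truth(linD, "D5", FALSE), nascent_truth(linD, "Dt", TRUE)
  )
  lost_truth <- function(lin, subgenome) {
    rows <- bind_rows(
      if (!is.null(lin$del_tbl)) {
        select(lin$del_tbl, "id", "chrom", "pos", "width")
      },
      if (!is.null(lin$del_gene_tbl)) {
        select(lin$del_gene_tbl, "id", "chrom", "pos", "width")
      }
    )
    if (is.null(rows) || nrow(rows) == 0) {
      return(tibble(subgenome = character(), id = character(),
                    chrom = character(), start = integer(),
                    end = integer()))
    }
    # coordinates on the retaining diploid's FINAL sequence
    s <- lin$dip_map(rows$chrom, rows$pos)
    tibble(subgenome = subgenome, id = rows$id, chrom = rows$chrom,
           start = s, end = s + rows$width)
  }
  lost_all <- bind_rows(lost_truth(linA, "At"), lost_truth(linD, "Dt"))

  fates <- bind_rows(
    tibble(family = fam_balanced, fate = "balanced",
           lost_subgenome = "none", mechanism = NA_character_),
    tibble(family = fam_lost_both, fate = "lost_both",
           lost_subgenome = "both", mechanism = "deletion"),
    tibble(family = fam_rev_At, fate = "reverted_single",
           lost_subgenome = "At", mechanism = unname(mech_At)),
    tibble(family = fam_rev_Dt, fate = "reverted_single",
           lost_subgenome = "Dt", mechanism = unname(mech_Dt)),
    tibble(family = fam_gained, fate = "gained",
           lost_subgenome = "none", mechanism = NA_character_)
  ) |> arrange(.data$family)
  te_disrupted <- bind_rows(
    tibble(family = names(mech_At)[mech_At == "TE_disruption"],
           subgenome = "At"),
    tibble(family = names(mech_Dt)[mech_Dt == "TE_disruption"],
           subgenome = "Dt")
  )
  if (nrow(te_disrupted) > 0) {
    te_disrupted$gene_id <- paste0(te_disrupted$family, "_",
                                   te_disrupted$subgenome)
  }

  # --- accession panel and PAV truth ---
  n_acc <- cfg$n_accessions
  grp_counts <- diff(round(cumsum(c(0, cfg$group_labels)) * n_acc))
  groups <- tibble(
    accession = sprintf("acc%03d", seq_len(n_acc)),
    group = rep(names(cfg$group_labels), grp_counts)
  )
  fam_ids <- sort(genes_A$family)
  n_core <- round(cfg$core_fraction * length(fam_ids))
  disp <- sample(fam_ids, length(fam_ids) - n_core)
  freq <- setNames(rep(1, length(fam_ids)), fam_ids)
  freq[disp] <- runif(length(disp), cfg$presence_sfs[1], cfg$presence_sfs[2])
  # structured PAV: a tenth of dispensable genes are enriched in the
  # first (largest) group
  chn_genes <- disp[seq_len(max(1, length(disp) %/% 10))]
  pav <- matrix(0L, nrow = length(fam_ids), ncol = n_acc,
                dimnames = list(fam_ids, groups$accession))
  major <- groups$group == names(cfg$group_labels)[1]
  for (g in fam_ids) {
    f <- freq[[g]]
    if (g %in% chn_genes) {
      p_acc <- ifelse(major, pmin(0.98, 2 * f), pmax(0.02, f / 2))
    } else {
      p_acc <- rep(f, n_acc)
    }
    pav[g, ] <- rbinom(n_acc, 1L, p_acc)
  }
  pav_tbl <- bind_cols(tibble(gene = fam_ids),
                       as_tibble(pav, .name_repair = "minimal"))

  nascent_families <- bind_rows(
    tibble(family = names(nas_scopes), scope = unname(nas_scopes),
           donor = unname(nas_donor)),
    tibble(family = fam_tbl$family, scope = fam_tbl$scope,
           donor = paste0(fam_donor_tr, fam_donor_int, fam_donor_tr))
  )

  structure(list(
    genomes = list(A2 = linA$diploid_seq, At = linA$sub_seq,
                   D5 = linD$diploid_seq, Dt = linD$sub_seq),
    genes = genes_all,
    exons = exons_all,
    ltr = ltr_all,
    truth = list(
      nascent = nascent_all,
      lost = lost_all,
      ltr_ages = if (nrow(ltr_all) > 0) {
        ltr_all[, c("element", "event", "genome", "age")]
      } else {
        tibble(element = character(), event = character(),
               genome = character(), age = numeric())
      },
      family_fates = fates,
      te_disrupted = te_disrupted,
      pav = pav_tbl,
      groups = groups,
      nascent_families = nascent_families
    ),
    config = cfg
  ), class = "genome_quartet")
}

#' @export
print.genome_quartet <- function(x, ...) {
  lens <- vapply(x$genomes, function(g) sum(nchar(g)), numeric(1))
  cat("<genome_quartet>\n")
  cat("  genomes:",
      paste(sprintf("%s (%.2f Mb)", names(lens), lens / 1e6),
            collapse = ", "), "\n")
  cat("  genes:", nrow(x$genes), "annotations;",
      length(unique(x$genes$family)), "families\n")
  cat("  LTR elements:", nrow(x$ltr), "\n")
  cat("  accessions:", nrow(x$truth$groups), "\n")
  invisible(x)
}

#' Simulate a per-accession per-exon read-depth summary table
#'
#' Emits, for every accession and every pangene exon, the number of
#' exon bases covered at or above the presence-calling depth. Genes
#' present in an accession (per the planted PAV truth) receive a
#' covered fraction safely above the calling threshold; absent genes
#' receive one safely below, so at `noise = 0` presence calling
#' round-trips the truth exactly.
#'
#' @param quartet A [simulate_quartet()] result.
#' @param noise Probability that a gene/accession pair is emitted on the
#'   wrong side of the calling threshold (default 0).
#' @param seed Optional seed (defaults to the quartet seed + 1).
#' @return Tibble with columns `accession`, `gene`, `exon`,
#'   `exon_length`, `covered_bases`.
#' @export
simulate_depth_table <- function(quartet, noise = 0, seed = NULL) {
  stopifnot(inherits(quartet, "genome_quartet"))
  local_seed_if(seed %||% (quartet$config$seed + 1L))
  pav <- quartet$truth$pav
  acc <- names(pav)[-1]
  exons <- quartet$exons |>
    filter(.data$genome == "A2") |>
    mutate(exon_length = .data$end - .data$start) |>
    select(gene = "family", "exon", "exon_length")
  grid <- tidyr::crossing(accession = acc, exons)
  pres_long <- pav |>
    tidyr::pivot_longer(-"gene", names_to = "accession",
                        values_to = "present")
  grid <- left_join(grid, pres_long, by = c("gene", "accession"))
  flip <- runif(nrow(grid)) < noise
  present <- xor(grid$present == 1L, flip)
  frac <- ifelse(present, runif(nrow(grid), 0.85, 1.0),
                 runif(nrow(grid), 0, 0.5))
  grid |>
    mutate(covered_bases = as.integer(round(frac * .data$exon_length))) |>
    select("accession", "gene", "exon", "exon_length", "covered_bases") |>
    arrange(.data$accession, .data$gene, .data$exon)
}

#' Write quartet FASTA/GFF3/TSV fixture files
#'
#' Serializes the four genomes (FASTA), their gene/exon/LTR annotations
#' (GFF3, 1-based inclusive) and all truth tables (TSV) into a
#' directory, mirroring the on-disk layout a real analysis would
#' consume.
#'
#' @param quartet A [simulate_quartet()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_quartet <- function(quartet, dir) {
  stopifnot(inherits(quartet, "genome_quartet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in names(quartet$genomes)) {
    write_fasta(quartet$genomes[[g]],
                file.path(dir, paste0(g, ".fa")))
    genes <- quartet$genes |> filter(.data$genome == g)
    exons <- quartet$exons |> filter(.data$genome == g)
    ltr <- quartet$ltr |> filter(.data$genome == g)
    feats <- bind_rows(
      tibble(seqid = genes$chrom, type = "gene", start = genes$start,
             end = genes$end, strand = genes$strand, ID = genes$gene_id),
      tibble(seqid = exons$chrom, type = "exon", start = exons$start,
             end = exons$end, strand = "+",
             ID = paste0(exons$gene_id, ".e", exons$exon),
             Parent = exons$gene_id),
      if (nrow(ltr) > 0) {
        tibble(seqid = ltr$chrom, type = "LTR_retrotransposon",
               start = ltr$start, end = ltr$end, strand = "+",
               ID = ltr$element, family = ltr$family,
               superfamily = ltr$superfamily)
      }
    )
    feats <- arrange(feats, .data$seqid, .data$start)
    write_gff3(feats, file.path(dir, paste0(g, ".gff3")))
  }
  tr <- quartet$truth
  readr::write_tsv(tr$nascent, file.path(dir, "truth_nascent.tsv"))
  readr::write_tsv(tr$lost, file.path(dir, "truth_lost.tsv"))
  readr::write_tsv(tr$ltr_ages, file.path(dir, "truth_ltr_ages.tsv"))
  readr::write_tsv(tr$family_fates, file.path(dir, "truth_family_fates.tsv"))
  readr::write_tsv(tr$te_disrupted, file.path(dir, "truth_te_disrupted.tsv"))
  readr::write_tsv(tr$pav, file.path(dir, "truth_pav.tsv"))
  readr::write_tsv(tr$groups, file.path(dir, "accession_groups.tsv"))
  invisible(dir)
}
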