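# Canonical k-mer counting, differential assignment, and clustering
# with bootstrap support.

test_that("counting is canonical and windows match the direct enumeration", {
  set.seed(1)
  s <- random_dna_chr(1e5)
  prof <- count_kmers(list(g = c(chr = s)), k = 15, min_count = 0)
  # total counted k-mers equals the number of valid windows
  expect_equal(sum(prof$g), 1e5 - 15 + 1)
  # a sequence and its reverse complement give identical profiles
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
  prof_rc <- count_kmers(list(g = c(chr = rc)), k = 15, min_count = 0)
  expect_identical(as.data.frame(prof), as.data.frame(prof_rc))
})

test_that("sequences shorter than k give an empty profile with a warning", {
  expect_warning(prof <- count_kmers(list(g = c(chr = "ACGTACGT")),
                                     k = 15, min_count = 0),
                 "shorter than k")
  expect_equal(nrow(prof), 0)
})

test_that("non-ACGT characters break k-mer windows", {
  s <- paste0(strrep("A", 20), "N", strrep("C", 20))
  prof <- count_kmers(list(g = c(chr = s)), k = 15, min_count = 0)
  expect_equal(sum(prof$g), 6 + 6)  # 20-15+1 valid windows per run
})

test_that("differential assignment uses a strict twofold abundance rule", {
  prof <- tibble::tibble(kmer = c("AAAAA", "CCCCC", "GGGGG", "TTTTT"),
                         ga = c(250L, 200L, 50L, 0L),
                         gb = c(100L, 100L, 0L, 70L))
  attr(prof, "totals") <- c(ga = 500, gb = 270)
  # equalize totals so the ratio acts on raw counts
  attr(prof, "totals") <- c(ga = 500, gb = 500)
  d <- differential_kmers(prof, "ga", "gb")
  expect_equal(d$genome, c("ga", NA, "ga", "gb"))
})

test_that("assignments swap exactly when genome labels swap", {
  set.seed(2)
  prof <- tibble::tibble(kmer = sprintf("k%03d", 1:50),
                         ga = rpois(50, 40), gb = rpois(50, 40))
  attr(prof, "totals") <- c(ga = sum(prof$ga), gb = sum(prof$gb))
  d1 <- differential_kmers(prof, "ga", "gb")
  d2 <- differential_kmers(prof, "gb", "ga")
  expect_equal(d1$genome == "ga", d2$genome == "ga")
  expect_equal(d1$genome == "gb", d2$genome == "gb")
})

test_that("zero total counts raise an error", {
  prof <- tibble::tibble(kmer = "AAAAA", ga = 0L, gb = 0L)
  attr(prof, "totals") <- c(ga = 0, gb = 0)
  expect_error(differential_kmers(prof, "ga", "gb"), "zero total")
})

test_that("perfectly separated abundance blocks cluster with full support", {
  set.seed(3)
  cand <- tibble::tibble(
    kmer = sprintf("k%03d", 1:40),
    g1 = c(rpois(20, 100), rpois(20, 2)),
    g2 = c(rpois(20, 2), rpois(20, 100))
  )
  res <- cluster_and_bootstrap(cand, n_groups = 2, n_boot = 50, seed = 4)
  expect_equal(length(unique(res$cluster[1:20])), 1)
  expect_equal(length(unique(res$cluster[21:40])), 1)
  expect_true(all(res$support == 1))
  # no bootstrap: assignments only
  res0 <- cluster_and_bootstrap(cand, n_groups = 2, n_boot = 0, seed = 5)
  expect_true(all(is.na(res0$support)))
})

test_that("backbone k-mers are never called genome-specific on a shared backbone", {
  cfg <- simulation_config(seed = 21, n_chromosomes = 2,
                           chromosome_length_bp = 5e5, n_genes = 40,
                           fate_counts = c(balanced = 40, lost_both = 0,
                                           reverted_At = 0, reverted_Dt = 0,
                                           gained = 0),
                           n_nascent_per_genome = 10,
                           n_lost_per_subgenome = 4,
                           ltr_events_scale = 0.3,
                           terminal_repeat_bp = 600L,
                           ltr_interior_bp = 1200L,
                           backbone_divergence = 0,
                           n_accessions = 8)
  q <- simulate_quartet(cfg)
  prof <- count_kmers(q$genomes[c("A2", "At")])
  d <- differential_kmers(prof, "A2", "At")
  a2_spec <- d$kmer[!is.na(d$genome) & d$genome == "A2"]
  expect_gt(length(a2_spec), 50)
  # every assigned k-mer must derive from planted A2 content: no
  # k-mer whose occurrences all lie in the shared backbone may be
  # called specific (a nascent-donor k-mer may additionally hit the
  # backbone once by coincidence, which is why the per-occurrence
  # check is a majority, not a universal, condition)
  hits <- locate_kmers(q$genomes$A2, a2_spec)
  truth <- q$truth$nascent[q$truth$nascent$genome == "A2", ]
  inside <- vapply(seq_len(nrow(hits)), function(i) {
    any(truth$chrom == hits$seq_id[i] &
          truth$start < hits$end[i] & truth$end > hits$start[i])
  }, logical(1))
  km <- substr(fragment_seqs(
    tibble::tibble(chrom = hits$seq_id, start = hits$start,
                   end = hits$end), q$genomes$A2), 1, 15)
  km <- pmin(km, as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(km))))  # canonical form
  frac_inside_per_kmer <- tapply(inside, km, mean)
  expect_true(all(frac_inside_per_kmer > 0))   # no pure-backbone k-mer
  expect_gte(mean(inside), 0.99)               # occurrences are planted
})

test_that("k-mers of tetraploid-shared nascent families co-cluster", {
  q <- test_quartet()
  prof <- count_kmers(q$genomes)
  # candidates: k-mers specific to the tetraploid side in both
  # subgenome comparisons, plus diploid-specific ones as contrast
  dA <- differential_kmers(prof, "A2", "At")
  spec <- dA[!is.na(dA$genome), ]
  cand <- dplyr::inner_join(spec["kmer"], as.data.frame(prof),
                            by = "kmer")
  res <- cluster_and_bootstrap(
    cand[, c("kmer", "A2", "At", "Dt", "D5")],
    n_groups = 3, n_boot = 0, seed = 6)
  # truth: k-mers from the donors of the At+Dt-shared nascent families
  donors <- q$truth$nascent_families
  shared <- donors$donor[donors$scope == "AtDt"]
  shared_kmers <- unique(unlist(lapply(shared, function(s) {
    res <- panploid:::cpp_count_kmers(s, 15L)
    res$kmer
  })))
  sel <- res[res$kmer %in% shared_kmers, ]
  expect_gt(nrow(sel), 100)
  main <- max(table(sel$cluster)) / nrow(sel)
  expect_gte(main, 0.95)
})

test_that("k-mer locations are reported canonically on both strands", {
  set.seed(7)
  bg <- random_ac(300)
  km <- "GGGTTTGGGTTTGGG"  # contains G/T only: absent from A/C background
  s <- paste0(substr(bg, 1, 100), km, substr(bg, 101, 300))
  hits <- locate_kmers(c(x = s), km)
  expect_equal(hits$start, 100)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
  hits_rc <- locate_kmers(c(x = rc), km)
  expect_equal(nrow(hits_rc), 1)
})
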