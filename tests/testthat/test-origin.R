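# Fragmentation, unmapped merging, interval subtraction, k-mer
# masking classification, and the distance permutation test.

test_that("fragmentation tiles chromosomes with the remainder policy", {
  g <- c(chrA = strrep("A", 2500))
  fr <- fragment_genome(g)
  expect_equal(fr$start, c(0, 1000, 2000))
  expect_equal(fr$end, c(1000, 2000, 2500))
  # all-N chromosome yields nothing
  expect_equal(nrow(fragment_genome(c(chrN = strrep("N", 5000)))), 0)
  # sub-window chromosome is one fragment
  fr2 <- fragment_genome(c(chrB = strrep("C", 999)))
  expect_equal(fr2$end - fr2$start, 999)
})

test_that("N runs are removed before tiling and break contiguity", {
  g <- c(chr = paste0(strrep("A", 1500), strrep("N", 300),
                      strrep("C", 1200)))
  fr <- fragment_genome(g)
  expect_equal(fr$start, c(0, 1000, 1800, 2800))
  expect_equal(fr$end, c(1000, 1500, 2800, 3000))
  # partition property: fragments cover all non-N bases exactly once
  expect_equal(sum(fr$end - fr$start), 2700)
  expect_true(all(fr$start[-1] >= fr$end[-nrow(fr)]))
})

test_that("unmapped fragments merge only when coordinate-contiguous", {
  fr <- tibble::tibble(
    chrom = "chr",
    start = c(0L, 1000L, 2000L, 3000L),
    end = c(1000L, 2000L, 3000L, 4000L)
  )
  out <- merge_unmapped(fr, mapped = c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(out$start, c(0L, 3000L))
  expect_equal(out$end, c(2000L, 4000L))
  expect_equal(nrow(merge_unmapped(fr, mapped = rep(TRUE, 4))), 0)
  # an N gap between fragments blocks merging
  frN <- tibble::tibble(chrom = "chr", start = c(0L, 1300L),
                        end = c(1000L, 2300L))
  outN <- merge_unmapped(frN, mapped = c(FALSE, FALSE))
  expect_equal(nrow(outN), 2)
})

test_that("pangenome subtraction is exact interval arithmetic", {
  ref <- tibble::tibble(chrom = "c", start = 0L, end = 2000L)
  pan <- tibble::tibble(chrom = "c", start = 500L, end = 800L)
  out <- subtract_pangenome_hits(ref, pan)
  # [0,500) dropped (< 500 bp), [800,2000) kept
  expect_equal(out$start, 800)
  expect_equal(out$end, 2000)
  expect_equal(subtract_pangenome_hits(ref, ref)$start, integer(0))
  none <- subtract_pangenome_hits(ref, ref[0, ])
  expect_equal(none$start, 0)
  expect_equal(none$end, 2000)
})

# Build a sequence over A/C with the given G/T-alphabet k-mers planted
# at chosen 0-based positions; the k-mer set can then never collide
# with the background.
plant_kmers <- function(len, plants) {
  chars <- strsplit(random_ac(len), "")[[1]]
  for (i in seq_len(nrow(plants))) {
    km <- strsplit(plants$kmer[i], "")[[1]]
    chars[(plants$pos[i] + 1):(plants$pos[i] + length(km))] <- km
  }
  paste(chars, collapse = "")
}

# K-mer i: "GA" followed by i in binary over {G,T}. It contains a G
# (so it cannot occur in the A/C background) and an A (so its reverse
# complement contains a T and cannot occur there either), and distinct
# i give distinct k-mers.
gt_kmer <- function(i) {
  bits <- as.integer(intToBits(i))[1:13]
  paste0("GA", paste(c("G", "T")[bits + 1L], collapse = ""))
}

test_that("masking classifies by the strict 20% rule", {
  set.seed(1)
  kms <- vapply(1:20, gt_kmer, character(1))
  # 150 of 1000 bp masked: ten disjoint k-mers spaced >= 50 apart
  pos_lost <- seq(0, by = 65, length.out = 10)
  s_lost <- plant_kmers(1000, tibble::tibble(kmer = kms[1:10],
                                             pos = pos_lost))
  out <- classify_origin(c(x = s_lost), kms)
  expect_equal(out$masked_bp, 150L)
  expect_equal(out$verdict, "lost")
  # exactly 200 bp masked -> fraction 0.20 is NOT < 0.20 -> nascent
  plants20 <- tibble::tibble(
    kmer = kms[1:12],
    pos = c(seq(0, by = 65, length.out = 10), 800L, 835L)
  )
  # ten isolated 15 bp runs (150) plus [800,815)+[835,850) joined
  # across a 20 bp gap into one 50 bp run: 200 bp total
  s_20 <- plant_kmers(1000, plants20)
  out20 <- classify_origin(c(x = s_20), kms[1:12])
  expect_equal(out20$masked_bp, 200L)
  expect_equal(out20$masked_fraction, 0.2)
  expect_equal(out20$verdict, "nascent")
})

test_that("masked runs joined across sub-50 bp gaps before the fraction", {
  set.seed(2)
  km1 <- gt_kmer(11)
  km2 <- gt_kmer(12)
  # runs [100,115) and [155,170): gap 40 < 50 -> joined to [100,170)
  s <- plant_kmers(1000, tibble::tibble(kmer = c(km1, km2),
                                        pos = c(100L, 155L)))
  out <- classify_origin(c(x = s), c(km1, km2))
  expect_equal(out$masked_bp, 70L)
  # runs 50 apart stay separate
  s2 <- plant_kmers(1000, tibble::tibble(kmer = c(km1, km2),
                                         pos = c(100L, 165L)))
  out2 <- classify_origin(c(x = s2), c(km1, km2))
  expect_equal(out2$masked_bp, 30L)
})

test_that("classification is invariant to reverse complementing the sequence", {
  set.seed(3)
  kms <- vapply(21:40, gt_kmer, character(1))
  s <- plant_kmers(800, tibble::tibble(kmer = kms[1:12],
                                       pos = seq(0, by = 65,
                                                 length.out = 12)))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(s)))
  a <- classify_origin(c(x = s), kms)
  b <- classify_origin(c(x = rc), kms)
  expect_equal(a$masked_bp, b$masked_bp)
  expect_equal(a$verdict, b$verdict)
})

test_that("an empty k-mer set calls everything lost with a warning", {
  expect_warning(out <- classify_origin(c(x = strrep("ACGT", 100)),
                                        character(0)),
                 "empty k-mer set")
  expect_equal(out$verdict, "lost")
  expect_true(attr(out, "empty_kmer_set"))
})

test_that("fragment-merge round trip partitions every base exactly once", {
  q <- test_quartet()
  g <- q$genomes$A2[1]
  fr <- fragment_genome(g)
  expect_equal(sum(fr$end - fr$start), nchar(g[[1]]))
  # any mapped/unmapped split keeps intervals disjoint and inside
  set.seed(4)
  mp <- runif(nrow(fr)) < 0.7
  merged <- merge_unmapped(fr, mp)
  expect_equal(sum(merged$end - merged$start),
               sum((fr$end - fr$start)[!mp]))
})

test_that("distance permutation test is exact at its trivial extremes", {
  genes <- tibble::tibble(chrom = "c", start = c(100000L, 500000L),
                          end = c(101000L, 501000L))
  glen <- c(c = 1000000)
  pt <- distance_permutation_test(genes, genes, glen, n_perm = 99,
                                  seed = 1)
  expect_equal(pt$observed, 0)
  expect_equal(pt$p_closer, 1 / 100)
  expect_error(distance_permutation_test(genes, genes[0, ], glen),
               "no genes")
  # queries only on gene-free chromosomes cannot be tested
  far <- tibble::tibble(chrom = "other", start = 0L, end = 100L)
  expect_error(distance_permutation_test(far, genes, glen),
               "no queries")
})

test_that("nearest distances agree with GenomicRanges::distanceToNearest", {
  set.seed(5)
  q_iv <- tibble::tibble(chrom = sample(c("c1", "c2"), 50, TRUE),
                         start = sample.int(99000, 50))
  q_iv$end <- q_iv$start + sample(50:500, 50, TRUE)
  s_iv <- tibble::tibble(chrom = sample(c("c1", "c2"), 20, TRUE),
                         start = sample.int(99000, 20))
  s_iv$end <- s_iv$start + sample(100:1000, 20, TRUE)
  mine <- panploid:::nearest_distance(q_iv$chrom, q_iv$start, q_iv$end,
                                      s_iv$chrom, s_iv$start, s_iv$end)
  gq <- GenomicRanges::GRanges(q_iv$chrom,
                               IRanges::IRanges(q_iv$start + 1,
                                                q_iv$end))
  gs <- GenomicRanges::GRanges(s_iv$chrom,
                               IRanges::IRanges(s_iv$start + 1,
                                                s_iv$end))
  hit <- GenomicRanges::distanceToNearest(gq, gs)
  ref <- rep(NA_real_, 50)
  ref[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
  expect_equal(mine, ref)
})

test_that("uniformly placed queries are not flagged as gene-associated", {
  set.seed(6)
  genes <- tibble::tibble(chrom = "c",
                          start = as.integer(seq(0, 9e5, by = 5e4)))
  genes$end <- genes$start + 2000L
  glen <- c(c = 1e6)
  hits <- 0
  n_seeds <- 40
  for (s in seq_len(n_seeds)) {
    st <- as.integer(runif(30, 0, 1e6 - 500))
    qs <- tibble::tibble(chrom = "c", start = st, end = st + 500L)
    pt <- distance_permutation_test(qs, genes, glen, n_perm = 199,
                                    seed = 1000 + s)
    if (pt$p_closer < 0.05) hits <- hits + 1
  }
  # observed false-positive rate consistent with the nominal 5% level
  expect_gt(binom.test(hits, n_seeds, 0.05,
                       alternative = "greater")$p.value, 0.01)
})
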