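# Presence calling, occupancy classes, rarefaction curves, the
# frequency-change scan, and dispensable-gene clustering.

depth_row <- function(acc, gene, exon_len, covered) {
  tibble::tibble(accession = acc, gene = gene, exon = 1L,
                 exon_length = exon_len, covered_bases = covered)
}

test_that("presence calling applies the strict >80% covered rule", {
  d <- dplyr::bind_rows(
    depth_row("a1", "g1", 100L, 85L),   # 0.85 -> present
    depth_row("a1", "g2", 100L, 80L),   # exactly 0.80 -> absent
    depth_row("a1", "g3", 100L, 0L)     # no depth-2 coverage -> absent
  )
  pav <- call_presence(d)
  expect_equal(pav$a1, c(1L, 0L, 0L))
  expect_error(call_presence(depth_row("a1", "g1", 0L, 0L)),
               "zero total exon length")
})

test_that("presence aggregates across exons of a gene", {
  d <- dplyr::bind_rows(
    tibble::tibble(accession = "a1", gene = "g1", exon = 1:2,
                   exon_length = c(100L, 100L),
                   covered_bases = c(100L, 65L))  # 165/200 = 0.825
  )
  expect_equal(call_presence(d)$a1, 1L)
})

test_that("occupancy boundaries reproduce the printed 341-accession thresholds", {
  thr <- occupancy_thresholds(341)
  expect_equal(thr$core_gt, 337)
  expect_equal(thr$soft_ge, 324)
  expect_equal(thr$cloud_lt, 4)
  # boundary presence counts at n = 341
  counts <- c(341, 338, 337, 324, 323, 4, 3, 0)
  pav <- tibble::tibble(gene = paste0("g", seq_along(counts)))
  m <- t(vapply(counts, function(cnt) {
    as.integer(seq_len(341) <= cnt)
  }, integer(341)))
  for (j in seq_len(341)) pav[[paste0("acc", j)]] <- m[, j]
  occ <- classify_occupancy(pav)
  expect_equal(occ$occupancy,
               c("core", "core", "softcore", "softcore", "shell",
                 "shell", "cloud", "cloud"))
})

test_that("pan and core curves are exact in the degenerate cases", {
  pav <- tibble::tibble(gene = paste0("g", 1:5))
  for (j in 1:6) pav[[paste0("a", j)]] <- 1L
  curve <- pan_core_curve(pav, n_samplings = 20, seed = 1)
  expect_true(all(curve$pan_mean == 5))
  expect_true(all(curve$core_mean == 5))
  expect_true(all(curve$pan_lo == curve$pan_hi))
  # at size = N every sampling equals the full panel
  set.seed(2)
  pav2 <- tibble::tibble(gene = paste0("g", 1:8))
  for (j in 1:5) pav2[[paste0("a", j)]] <- rbinom(8, 1, 0.6)
  full <- pan_core_curve(pav2, n_samplings = 10, sizes = 5, seed = 3)
  m <- as.matrix(pav2[, -1])
  expect_equal(full$pan_mean, sum(rowSums(m) > 0))
  expect_equal(full$core_mean, sum(rowSums(m) == 5))
})

test_that("mean pan count at size two matches exhaustive pair enumeration", {
  set.seed(4)
  pav <- tibble::tibble(gene = paste0("g", 1:5))
  for (j in 1:10) pav[[paste0("a", j)]] <- rbinom(5, 1, 0.5)
  m <- as.matrix(pav[, -1])
  # independent oracle: enumerate all 45 pairs
  pairs <- utils::combn(10, 2)
  pan_pairs <- vapply(seq_len(ncol(pairs)), function(i) {
    sum(rowSums(m[, pairs[, i], drop = FALSE]) > 0)
  }, numeric(1))
  core_pairs <- vapply(seq_len(ncol(pairs)), function(i) {
    sum(rowSums(m[, pairs[, i], drop = FALSE]) == 2)
  }, numeric(1))
  curve <- pan_core_curve(pav, n_samplings = 4000, sizes = 2, seed = 5)
  expect_lt(abs(curve$pan_mean - mean(pan_pairs)), 0.1)
  expect_lt(abs(curve$core_mean - mean(core_pairs)), 0.1)
})

test_that("nested sampling makes pan non-decreasing and core non-increasing", {
  set.seed(6)
  pav <- tibble::tibble(gene = paste0("g", 1:30))
  for (j in 1:12) pav[[paste0("a", j)]] <- rbinom(30, 1, 0.7)
  curve <- pan_core_curve(pav, n_samplings = 50, seed = 7, nested = TRUE)
  expect_true(all(diff(curve$pan_mean) >= 0))
  expect_true(all(diff(curve$core_mean) <= 0))
})

test_that("frequency scan: equal frequencies are ns with fold change 1", {
  pav <- tibble::tibble(gene = paste0("g", 1:3))
  for (j in 1:10) pav[[paste0("a", j)]] <- c(1L, 1L, 0L)
  groups <- tibble::tibble(accession = paste0("a", 1:10),
                           group = rep(c("CHN", "other"), each = 5))
  scan <- frequency_change_scan(pav[1:2, ], groups, "CHN")
  expect_true(all(scan$fold_change == 1))
  expect_true(all(scan$verdict == "ns"))
})

test_that("frequency scan p-values equal full hypergeometric enumeration", {
  # focal (90 present, 10 absent) vs other (40 present, 60 absent)
  pav <- tibble::tibble(gene = "g1")
  acc <- c(paste0("f", 1:100), paste0("o", 1:100))
  pres <- c(rep(1L, 90), rep(0L, 10), rep(1L, 40), rep(0L, 60))
  for (j in seq_along(acc)) pav[[acc[j]]] <- pres[j]
  groups <- tibble::tibble(accession = acc,
                           group = rep(c("CHN", "other"), each = 100))
  scan <- frequency_change_scan(pav, groups, "CHN")
  # oracle: enumerate the hypergeometric distribution of the top-left
  # cell and sum the probabilities of tables at most as likely
  a <- 90; m <- 100; n <- 100; k <- 90 + 40
  dens <- dhyper(max(0, k - n):min(m, k), m, n, k)
  p_enum <- sum(dens[dens <= dhyper(a, m, n, k) * (1 + 1e-7)])
  expect_equal(scan$p, p_enum, tolerance = 1e-10)
})

test_that("planted fourfold frequency changes are flagged and nulls are not", {
  set.seed(8)
  n_per <- 100
  n_fav <- 50
  n_null <- 450
  freqs_f <- c(rep(0.8, n_fav), rep(0.45, n_null))
  freqs_o <- c(rep(0.2, n_fav), rep(0.45, n_null))
  genes <- sprintf("g%03d", seq_len(n_fav + n_null))
  m <- cbind(
    matrix(rbinom(n_per * length(genes), 1, rep(freqs_f, n_per)),
           ncol = n_per),
    matrix(rbinom(n_per * length(genes), 1, rep(freqs_o, n_per)),
           ncol = n_per)
  )
  pav <- dplyr::bind_cols(
    tibble::tibble(gene = genes),
    tibble::as_tibble(`colnames<-`(m, paste0("a", seq_len(2 * n_per))),
                      .name_repair = "minimal")
  )
  groups <- tibble::tibble(accession = paste0("a", seq_len(2 * n_per)),
                           group = rep(c("CHN", "other"), each = n_per))
  scan <- frequency_change_scan(pav, groups, "CHN")
  flagged <- scan$gene[scan$verdict == "favorable"]
  expect_setequal(flagged, genes[seq_len(n_fav)])
  expect_equal(sum(scan$verdict[-seq_len(n_fav)] != "ns"), 0)
})

test_that("genes absent everywhere are excluded with a notice", {
  pav <- tibble::tibble(gene = c("g1", "g2"))
  for (j in 1:8) pav[[paste0("a", j)]] <- c(1L, 0L)
  groups <- tibble::tibble(accession = paste0("a", 1:8),
                           group = rep(c("CHN", "other"), each = 4))
  expect_message(scan <- frequency_change_scan(pav, groups, "CHN"),
                 "excluded 1")
  expect_equal(scan$gene, "g1")
})

test_that("k-means recovers perfectly separated presence blocks", {
  skip_if_not_installed("mclust")
  set.seed(9)
  blocks <- rep(1:4, each = 15)
  m <- matrix(0L, nrow = 60, ncol = 40)
  for (b in 1:4) m[blocks == b, ((b - 1) * 10 + 1):(b * 10)] <- 1L
  pav <- dplyr::bind_cols(tibble::tibble(gene = sprintf("g%02d", 1:60)),
                          tibble::as_tibble(`colnames<-`(
                            m, paste0("a", 1:40)), .name_repair = "minimal"))
  cl <- cluster_dispensable(pav, k = 4, seed = 10)
  expect_equal(mclust::adjustedRandIndex(cl$cluster, blocks), 1)
  # identical rows always share a cluster
  expect_true(all(tapply(cl$cluster, blocks, function(x) {
    length(unique(x))
  }) == 1))
  # k = 1 puts everything together
  one <- cluster_dispensable(pav, k = 1, seed = 11)
  expect_true(all(one$cluster == 1L))
  expect_error(cluster_dispensable(pav[1:3, ], k = 5), "exceeds")
})

test_that("jaccard distances are zero for identical accessions and one for disjoint", {
  pav <- tibble::tibble(gene = paste0("g", 1:4),
                        a1 = c(1L, 1L, 0L, 0L),
                        a2 = c(1L, 1L, 0L, 0L),
                        a3 = c(0L, 0L, 1L, 1L))
  d <- as.matrix(pav_jaccard(pav))
  expect_equal(d["a1", "a2"], 0)
  expect_equal(d["a1", "a3"], 1)
})
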