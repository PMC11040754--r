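# LTR dating, clustering, specificity, lifespan, retention, and
# spatial statistics.

el_row <- function(id, ltr5, ltr3) {
  tibble::tibble(element = id, ltr5_seq = ltr5, ltr3_seq = ltr3)
}

test_that("dating follows the Jukes-Cantor closed form", {
  set.seed(1)
  tr <- random_dna_chr(1000)
  out0 <- date_ltr(el_row("e0", tr, tr))
  expect_equal(out0$p, 0)
  expect_equal(out0$T_years, 0)
  # p = 0.018 exactly: mutate 18 of 1000 sites
  chars <- strsplit(tr, "")[[1]]
  idx <- sample.int(1000, 18)
  bases <- c("A", "C", "G", "T")
  chars[idx] <- bases[(match(chars[idx], bases) %% 4) + 1]
  out <- date_ltr(el_row("e1", tr, paste(chars, collapse = "")))
  expect_equal(out$p, 0.018)
  expect_equal(out$K, 0.0182195194268, tolerance = 1e-9)
  expect_equal(out$T_years, 2024391.047, tolerance = 1e-6)
  # the two-sided clock convention halves the age
  out2 <- date_ltr(el_row("e1", tr, paste(chars, collapse = "")),
                   divergence_factor = 2)
  expect_equal(out2$T_years, out$T_years / 2)
})

test_that("saturated repeats are a dating error", {
  a <- strrep("A", 400)
  b <- strrep("C", 400)
  expect_error(date_ltr(el_row("e", a, b)), "saturated")
})

test_that("dating is monotone in divergence", {
  set.seed(2)
  tr <- random_dna_chr(2000)
  ps <- c(0.002, 0.01, 0.05, 0.2)
  els <- dplyr::bind_rows(lapply(seq_along(ps), function(i) {
    n_mut <- round(ps[i] * 2000)
    chars <- strsplit(tr, "")[[1]]
    idx <- sample.int(2000, n_mut)
    bases <- c("A", "C", "G", "T")
    chars[idx] <- bases[(match(chars[idx], bases) %% 4) + 1]
    el_row(paste0("e", i), tr, paste(chars, collapse = ""))
  }))
  out <- date_ltr(els)
  expect_true(all(diff(out$T_years) > 0))
})

test_that("clustering collapses identical elements and separates families", {
  set.seed(3)
  s <- random_dna_chr(3000)
  ident <- cluster_ltr(setNames(rep(s, 10), paste0("e", 1:10)))
  expect_equal(ident$cluster, rep(1L, 10))
  one <- cluster_ltr(c(solo = s))
  expect_equal(one$cluster, 1L)
  # two families: 2% within, 25% between
  f1 <- random_dna_chr(4000)
  f2 <- mutate_chr(f1, 0.25)
  seqs <- c(
    setNames(vapply(1:6, function(i) mutate_chr(f1, 0.02), character(1)),
             paste0("a", 1:6)),
    setNames(vapply(1:6, function(i) mutate_chr(f2, 0.02), character(1)),
             paste0("b", 1:6))
  )
  cl <- cluster_ltr(seqs)
  expect_equal(length(unique(cl$cluster)), 2)
  expect_equal(length(unique(cl$cluster[1:6])), 1)
  expect_equal(length(unique(cl$cluster[7:12])), 1)
})

test_that("specificity decision tree matches its printed examples", {
  comp <- tibble::tibble(cluster = 1:3,
                         A2 = c(95L, 2L, 30L), At = c(3L, 50L, 25L),
                         Dt = c(2L, 48L, 25L), D5 = c(0L, 0L, 20L))
  out <- assign_specificity(comp)
  expect_equal(out$label, c("A2", "At_Dt", "common"))
  expect_error(assign_specificity(tibble::tibble(cluster = 1, A2 = 0L,
                                                 At = 0L, Dt = 0L,
                                                 D5 = 0L)),
               "empty cluster")
})

test_that("specificity equals exhaustive rule evaluation on all small compositions", {
  # independent oracle: literal re-evaluation of the four rules
  oracle <- function(v) {
    genomes <- c("A2", "D5", "At", "Dt")
    names(v) <- c("A2", "D5", "At", "Dt")
    n <- sum(v)
    pr <- v / n
    if (max(pr) > 0.9) return(genomes[which.max(pr)])
    best <- ""
    best_sum <- -1
    for (i in 1:3) for (j in (i + 1):4) {
      s <- pr[i] + pr[j]
      if (s > best_sum) {
        best_sum <- s
        best <- paste(genomes[c(i, j)], collapse = "_")
      }
    }
    if (best_sum > 0.9) return(best)
    if (sum(pr < 0.1) == 1) {
      return(paste(genomes[pr >= 0.1], collapse = "_"))
    }
    "common"
  }
  combos <- expand.grid(A2 = 0:12, D5 = 0:12, At = 0:12, Dt = 0:12)
  combos <- combos[rowSums(combos) > 0 & rowSums(combos) <= 12, ]
  comp <- tibble::tibble(cluster = seq_len(nrow(combos)),
                         A2 = combos$A2, D5 = combos$D5,
                         At = combos$At, Dt = combos$Dt)
  got <- assign_specificity(comp)
  want <- apply(as.matrix(combos[, c("A2", "D5", "At", "Dt")]), 1,
                oracle)
  expect_equal(got$label, unname(want))
})

test_that("lifespans use linear-interpolation percentiles", {
  ages <- tibble::tibble(cluster = 1L, T_years = (1:100) * 1e4)
  out <- cluster_lifespan(ages)
  expect_equal(out$t_start, 950500)
  expect_equal(out$t_end, 59500)
  same <- cluster_lifespan(tibble::tibble(cluster = 1L,
                                          T_years = rep(7e5, 5)))
  expect_equal(same$t_start, 7e5)
  expect_equal(same$t_end, 7e5)
  single <- cluster_lifespan(tibble::tibble(cluster = 1L, T_years = 1e5))
  expect_true(is.na(single$t_start))
})

test_that("retention rates honor the CV cutoff and detect planted deletion bias", {
  loci <- dplyr::bind_rows(
    tibble::tibble(locus = "l1", genome = c("A2", "D5", "At", "Dt"),
                   retained_length = c(400, 400, 400, 400),
                   aln_length = 1000),
    tibble::tibble(locus = "l2", genome = c("A2", "D5", "At", "Dt"),
                   retained_length = c(800, 800, 200, 200),
                   aln_length = 1000)
  )
  out <- retention_rates(loci, cv_cutoffs = c(0, 0.5))
  r0 <- out$rates[out$rates$cv_cutoff == 0, ]
  expect_equal(sort(unique(r0$n_loci)), 2)
  r5 <- out$rates[out$rates$cv_cutoff == 0.5, ]
  # only l2 has CV 0.6928 >= 0.5; the uniform locus is excluded
  expect_true(all(r5$n_loci == 1))
  expect_equal(r5$mean_retention[r5$genome == "A2"], 0.8)
  expect_equal(r5$mean_retention[r5$genome == "At"], 0.2)
  # zero alignment length drops the locus
  loci_bad <- dplyr::bind_rows(loci,
    tibble::tibble(locus = "l3", genome = c("A2", "D5", "At", "Dt"),
                   retained_length = 100, aln_length = 0))
  out_b <- retention_rates(loci_bad, cv_cutoffs = 0)
  expect_equal(sort(unique(out_b$rates$n_loci)), 2)
})

test_that("retention means are invariant to locus order and find planted bias", {
  set.seed(4)
  n_loci <- 60
  # tetraploid genomes delete faster at variable loci
  loci <- dplyr::bind_rows(lapply(seq_len(n_loci), function(i) {
    variable <- i <= 20
    ret_dip <- if (variable) runif(2, 700, 900) else runif(2, 500, 560)
    ret_tet <- if (variable) runif(2, 150, 350) else runif(2, 480, 540)
    tibble::tibble(locus = paste0("l", i),
                   genome = c("A2", "D5", "At", "Dt"),
                   retained_length = c(ret_dip, ret_tet),
                   aln_length = 1000)
  }))
  out <- retention_rates(loci, cv_cutoffs = c(0, 0.4))
  shuf <- retention_rates(loci[sample.int(nrow(loci)), ],
                          cv_cutoffs = c(0, 0.4))
  expect_equal(dplyr::arrange(out$rates, cv_cutoff, genome),
               dplyr::arrange(shuf$rates, cv_cutoff, genome))
  hi <- out$rates[out$rates$cv_cutoff == 0.4, ]
  mean_tet <- mean(hi$mean_retention[hi$genome %in% c("At", "Dt")])
  mean_dip <- mean(hi$mean_retention[hi$genome %in% c("A2", "D5")])
  expect_lt(mean_tet, mean_dip)
})

test_that("distance-age regression finds planted trends and not null ones", {
  glen <- c(c = 2e6)
  genes <- tibble::tibble(chrom = "c",
                          start = as.integer(seq(0, 1.9e6, by = 1e5)))
  genes$end <- genes$start + 3000L
  # planted: old elements near genes, young ones far
  set.seed(5)
  age <- runif(60, 1e5, 3e6)
  offset <- 500 + (age / 3e6) * 40000  # distance grows with age
  anchor <- sample(genes$start, 60, replace = TRUE)
  els <- tibble::tibble(
    element = paste0("e", 1:60), superfamily = "Gypsy", chrom = "c",
    start = as.integer(anchor + 3000 + offset), T_years = age)
  els$end <- els$start + 5000L
  out <- ltr_gene_distance_stats(els, genes, glen, n_perm = 199,
                                 seed = 6)
  st <- out$stats
  expect_gt(st$slope_kb_per_myr, 0)
  expect_lt(st$slope_p, 0.05)
  # a single element cannot support a regression
  one <- ltr_gene_distance_stats(els[1, ], genes, glen, n_perm = 49,
                                 seed = 7)
  expect_true(is.na(one$stats$slope_kb_per_myr))
  # age independent of placement: slope CI covers zero in most seeds
  cover <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    st2 <- as.integer(runif(60, 0, 2e6 - 5000))
    els2 <- tibble::tibble(element = paste0("e", 1:60),
                           superfamily = "Gypsy", chrom = "c",
                           start = st2, end = st2 + 5000L,
                           T_years = runif(60, 1e5, 3e6))
    o2 <- ltr_gene_distance_stats(els2, genes, glen, n_perm = 9,
                                  seed = s)
    if (o2$stats$slope_lo <= 0 && o2$stats$slope_hi >= 0) {
      cover <- cover + 1
    }
  }
  expect_gte(cover, 8)
})

test_that("identical spacings give a zero-centred ratio distribution", {
  sp <- tibble::tibble(diploid = c(1000, 2000, 4000, 800),
                       tetraploid = c(1000, 2000, 4000, 800))
  out <- homolog_spacing_test(sp, n_rand = 99, seed = 1)
  expect_true(all(out$log2_ratio == 0))
  one <- homolog_spacing_test(sp[1, ], n_rand = 9, seed = 2)
  expect_true(is.na(one$p))
  expect_error(homolog_spacing_test(
    tibble::tibble(diploid = c(1000, NA), tetraploid = c(1000, 2000))),
    "unpaired")
})

test_that("spacing test is calibrated against its own null", {
  set.seed(8)
  low <- 0
  n_seeds <- 30
  for (s in seq_len(n_seeds)) {
    sp <- tibble::tibble(diploid = rlnorm(80, 8, 0.7),
                         tetraploid = rlnorm(80, 8, 0.7))
    out <- homolog_spacing_test(sp, n_rand = 200, seed = 300 + s)
    if (!is.na(out$p) && out$p < 0.05) low <- low + 1
  }
  expect_gt(binom.test(low, n_seeds, 0.05,
                       alternative = "greater")$p.value, 0.01)
})

test_that("tidiers return one-row glances and full tidy tables", {
  genes <- tibble::tibble(chrom = "c", start = c(1000L, 9000L),
                          end = c(2000L, 9900L))
  pt <- distance_permutation_test(genes, genes, c(c = 2e4),
                                  n_perm = 49, seed = 1)
  td <- generics::tidy(pt)
  expect_equal(nrow(td), 1)
  expect_named(td, c("observed", "null_mean", "null_sd", "p_closer",
                     "p_farther", "n_query", "n_perm"))
  sp <- homolog_spacing_test(
    tibble::tibble(diploid = runif(30, 500, 5000),
                   tetraploid = runif(30, 500, 5000)),
    n_rand = 50, seed = 2)
  expect_equal(sum(generics::tidy(sp)$observed), 30)
  expect_equal(nrow(generics::glance(sp)), 1)
})
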