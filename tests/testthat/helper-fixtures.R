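# Shared fixtures. The default quartet and its derived artifacts are
# expensive (seconds each), so they are built lazily once per test run
# and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

test_quartet <- function() {
  cached("quartet42", function() {
    simulate_quartet(simulation_config(seed = 42))
  })
}

test_kmer_profile_A <- function() {
  cached("profA", function() {
    q <- test_quartet()
    count_kmers(q$genomes[c("A2", "At")])
  })
}

test_diff_A <- function() {
  cached("diffA", function() {
    differential_kmers(test_kmer_profile_A(), "A2", "At")
  })
}

test_origin_A <- function() {
  cached("originA", function() {
    panploid:::classify_quartet_origin(test_quartet(), test_diff_A(),
                                       pipeline_config())
  })
}

test_ltr_ages <- function() {
  cached("ltr_ages", function() {
    date_ltr(test_quartet()$ltr)
  })
}

# Random DNA over a two-letter alphabet (A/C only). K-mers containing
# G or T can then be planted with zero risk of background collisions.
random_ac <- function(n) {
  paste(sample(c("A", "C"), n, replace = TRUE), collapse = "")
}

random_dna_chr <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitute a fraction of positions (always to a different base).
mutate_chr <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  idx <- which(runif(length(chars)) < rate)
  bases <- c("A", "C", "G", "T")
  cur <- match(chars[idx], bases)
  chars[idx] <- bases[((cur - 1L + sample.int(3, length(idx),
                                              replace = TRUE)) %% 4L) + 1L]
  paste(chars, collapse = "")
}
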