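---
title: "Methods: comparative pangenome analysis of a diploid/tetraploid quartet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative pangenome analysis of a diploid/tetraploid quartet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The analytical setting

Allotetraploid cotton carries two subgenomes, At and Dt, derived from
diploid progenitors resembling modern *G. arboreum* (A2) and
*G. raimondii* (D5). Comparing a tetraploid subgenome with its diploid
relative confounds three processes: sequence *gained* by the diploid
after divergence, sequence *gained* by the subgenome, and ancestral
sequence *lost* by either lineage. A pangenome built from many diploid
accessions reduces the reference bias, and genome-specific k-mers
separate gain from loss: novel sequence is dominated by recently
amplified repeat families whose k-mers are abundant in exactly one
genome, while a deleted ancestral segment is unique sequence whose
k-mers are too rare to pass any abundance threshold.

`panploid` implements the computations around that idea as composable
functions over tibbles, with the sequence containers and interval
arithmetic delegated to Biostrings / IRanges / GenomicRanges. This
vignette records the models, the parameter choices, and the design
decisions a maintainer would want to know; it states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

# The synthetic quartet and what it does (not) emulate

`simulate_quartet()` builds the A and D lineages independently: a
random backbone per lineage, single-copy genes placed in regular slots
with jitter, and the subgenome derived from the diploid backbone. All
planted features are recorded in truth tables.

* **LTR elements** are TR–interior–TR blocks organised into families
  with controlled genome scope. Families shared between a diploid and
  its subgenome (and "common" families) are planted *before*
  subgenome derivation, so their members sit at orthologous loci in
  both genomes — as real pre-divergence insertions do. Genome-specific
  and tetraploid-burst families are planted after derivation and are
  therefore genuinely nascent sequence.
* **Terminal-repeat aging** follows a forward Jukes–Cantor process:
  per site, a Poisson number of substitution events, each replacing
  the current base uniformly among the three alternatives, so multiple
  hits per site occur and the dating step's JC correction undoes
  exactly the process that generated the data. Indels are not
  simulated inside repeats; the dating method is substitution-only.
* **Dating convention.** The package follows the one-sided clock
  printed for cotton, `T = K/r` with `r = 9e-9` per site per year.
  The generator is calibrated to the same convention: a planted age
  `a` gives each repeat an expected `r*a/2` substitutions per site, so
  the *pair* diverges at `r*a` and `T = K/r` recovers `a` without
  rescaling. Users preferring the two-sided convention `T = K/(2r)`
  set `divergence_factor = 2` in `date_ltr()`; all ages shift by
  exactly a factor 2 between conventions.
* **Terminal-repeat length** defaults to 4 kb (long-LTR, Gypsy-like
  elements). The choice is statistical as much as biological: with
  ages spanning 0.1–3 Myr, a 4 kb repeat pair accumulates enough
  substitutions that observed divergence is monotone in age across a
  200-element panel; a few-hundred-bp repeat would be dominated by
  Poisson counting noise at the young end.
* **Nascent sequence** is drawn as truncated, lightly mutated copies
  of a small set of donor families, so its k-mers are *abundant* —
  the property the origin classifier relies on, and the property real
  TE-driven nascent sequence has. Lost intervals are unique backbone
  deleted from a subgenome; they default to 24 intervals of 8–16 kb
  per subgenome (~6% of the subgenome), matching the proportion seen
  in cotton, where lost sequence comes in long blocks. Small planted
  losses also arise from gene-fate deletions (1–2.5 kb).
* **Gene fates**: balanced, lost-in-both, reverted-to-single (split
  between TE-disruption, annotation-omission and clean deletion
  mechanisms) and gained (an extra subgenome copy). A TE-disrupted
  gene keeps its sequence but receives a young LTR element mid-gene
  and loses its annotation; an annotation-omission gene keeps its
  sequence untouched; a deletion loses the gene body.
* **The accession panel** assigns group labels in the proportions of
  the real panel (~64% CHN, 15% South Asia, 8% US, 13% other), makes
  80% of families core, draws dispensable presence frequencies from a
  uniform spectrum, and enriches a tenth of dispensable genes in the
  largest group.

What the generator does *not* emulate: read-level sequencing error
(depth tables are summaries by construction), indels and
rearrangements, nested/truncated TE copies, gene family expansion
beyond single copies, and realistic inter-genome divergence. The
backbone divergence between a diploid and its subgenome defaults to
0.5%; real A2-versus-At divergence is several times higher. The
built-in exact-seed fragment mapper (31-mer seeds, mapped when at
least half of a fragment's seeds occur in the target) is only
meaningful at that modest divergence — at real divergence one maps
fragments with a real aligner and feeds the mapped/unmapped flags in
directly. Consequently, passing the planted-truth tests demonstrates
the *logic* of the pipeline (filters, thresholds, bookkeeping,
estimators), not robustness to the full noise structure of real data.

# Thresholds and conventions

All thresholds sit in `pipeline_config()` with their standard
defaults: 500 bp contig filter, 300 bp / 90% alignment filter, 500 bp
unaligned-region filter, 80% exon-coverage presence rule at depth 2,
99%/95%/1% occupancy quantiles, twofold k-mer abundance ratio with a
count threshold scaled as `max(2, round(100 * genome_len / 1.6e9))`
(so "count > 100" at cotton scale maps onto toy genomes), 1 kb
fragmentation, 50 bp mask-gap joining, 20% lost cutoff, 90%
single-alignment rule and 25 kb gap rule for TE tracing, 90/90
clustering, 5th–95th percentile lifespans, fold-change 2 / FDR 0.001
for the frequency scan, and `r = 9e-9`.

Inequalities are strict wherever the source convention says "longer
than", "higher than", "more than": a 500 bp contig is discarded, a
masked fraction of exactly 20% is *nascent*, a presence count of
exactly `floor(0.99 n)` is soft-core, and exactly 80% exon coverage is
absent. Internally every interval is 0-based half-open; GFF3 is
emitted and read 1-based inclusive, BED passes through unchanged.
Empirical p-values use the add-one correction `(1 + k)/(n + 1)` and
can never be zero. Percentiles are linear-interpolation (R type 7).
The occupancy thresholds reproduce the published boundaries at
n = 341 (337/324/4) exactly.

Decisions where the sources were ambiguous, resolved once:

* The presence rule ">80% of exon regions covered" is primary; the
  alternative lost-fraction parameterisation (`lostCutoff = 0.2`) is
  the same decision expressed on the complementary scale and is not a
  separate mode.
* The masked fraction is computed *after* gap joining (joining is a
  prior step in the procedure).
* "Count > 100" k-mer retention applies to the maximum across
  genomes, and relative abundance normalizes by the genome's total
  retained k-mer count.
* In the specificity decision tree, rule 3 fires when *exactly one*
  genome contributes less than 10% of members; labels join genome
  names in the fixed order A2, D5, At, Dt.
* The 25 kb TE-tracing rule is applied to the gap between consecutive
  alignment target spans, inclusively.
* A 2+0 tetraploid split of a single-copy family is flagged
  `unbalanced_retention`, not balanced.
* Interval-subtraction remnants must be strictly longer than 500 bp,
  consistent with the extraction filters.
* The terminal fragment of a chromosome shorter than the 1 kb window
  is kept as its own fragment.
* Exact tests (Fisher) with BH adjustment back the frequency scan;
  when a 2x2 cell is zero, 0.5 is added to all four cells (Haldane)
  for the fold change only, never for the test.
* K-mer pattern clustering z-scales each k-mer's relative-abundance
  profile across genomes (row-wise), so families of different copy
  number but the same genome pattern cluster together; column
  z-scaling would cluster by magnitude instead.
* Redundancy removal and LTR 90/90 clustering share one greedy
  length-sorted centroid pass; identity is estimated per 250 bp
  window as `containment^(1/k)` (the expected k-mer survival under
  substitution divergence), a window aligns when that estimate
  reaches the identity cutoff, and the pair joins when the aligned
  window fraction reaches the coverage cutoff. This is deterministic,
  alignment-free, and separates a few percent of divergence from 25%
  unambiguously.
* Equal-length terminal repeats are compared positionally in
  `date_ltr()`; a shrinking local alignment would silently
  underestimate divergence for saturated pairs. Unequal-length pairs
  are aligned globally with free end gaps and gap columns are
  excluded from `p`. `p >= 0.75` is a saturation error, not a number.

# Statistical components

**Pan/core curves** draw accessions without replacement, by default
independently per size; `nested = TRUE` evaluates prefixes of one
permutation per draw, which makes monotonicity exact per sampling and
is the mode the monotonicity property test uses. Reported intervals
are the 0.5 and 99.5 percentiles over samplings.

**The distance permutation test** places length-matched intervals
uniformly (chromosomes weighted by length) and compares the observed
mean nearest-gene distance against the permutation distribution, both
tails reported. Distances use the same semantics as
`GenomicRanges::distanceToNearest` (0 for overlap or book-ending); an
internal vectorized routine is used inside the permutation loop for
speed and is cross-checked against GenomicRanges in the test suite.

**The spacing conservation test** bins log2 ratios of tetraploid to
diploid adjacent-homolog spacings, builds the null by permuting the
spacing multisets within each genome (order preserved, distances
randomized), Laplace-smooths the null bin proportions, and applies a
chi-square goodness-of-fit test.

**Retention rates** are `retained / alignment length` per genome per
homologous locus; the CV cutoff restricts to loci whose four retained
lengths vary (CV = sd/mean at or above the cutoff), which is where
differential deletion is visible. Pairwise t-tests compare genomes
within a cutoff.

**Distance–age regression** is ordinary least squares of nearest-gene
distance (kb) on insertion age (Myr), per superfamily, with the
slope's 95% CI; only the fit method is a choice here, and OLS is the
default anyone would reach for.

# Problem sizes

The default simulation is 4 chromosomes of 1 Mb per genome, 200 gene
families, ~214 LTR elements across the four genomes, and 60
accessions; every stage completes in seconds to a couple of minutes
on one CPU. The test suite reuses one cached quartet for the
expensive end-to-end checks; oracle-equivalence tests enumerate all
10,625 specificity compositions with total at most 20, all 45
accession pairs for the rarefaction check, and 1000 random orthogroup
tables; null-calibration checks use 50–100 replicate panels and
assert, via a one-sided binomial test, that observed false-positive
rates are not above nominal — an exact match to nominal cannot be
asserted at finite replicate counts.

# Known limitations

Beyond the generator's simplifications listed above: the toy fragment
mapper has no concept of secondary loci beyond best-diagonal support,
so segmental duplications at real scale require external alignments;
the greedy clustering depends on visit order (by length) as any
CD-HIT-style method does; the k-mer machinery holds profiles in
memory and is sized for genomes up to tens of Mb, not Gb (the real
study's scale needs disk-backed counting); and the frequency scan
assumes accessions are exchangeable within groups — population
structure within a group will inflate its false-positive rate on real
panels.
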