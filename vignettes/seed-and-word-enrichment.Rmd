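---
title: "Seed-site and word enrichment analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-site and word enrichment analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedwords)
```

# The problem

Overexpressing a microRNA and profiling the transcriptome is a standard
route to candidate targets: transcripts that carry a binding site for the
miRNA should, on average, go down. `seedwords` implements the
computational side of that experiment as a reusable, tested pipeline with
four stages:

1. **Expression-defined gene sets.** Per-gene differential statistics
   (log2 fold-change, Welch t-test p-value, Benjamini–Hochberg FDR)
   partition genes into *up*, *down* and *no-change* sets.
2. **Hierarchical seed-site enrichment.** The canonical seed-match words
   of the miRNA are counted in each gene's 3′UTR (and other regions), and
   site prevalence is compared between sets with a two-proportion test.
3. **Unbiased word analysis.** Without assuming the seed is what
   matters, *every* k-mer is scored for overrepresentation in each
   sequence against a mononucleotide-shuffle null; a running sum over the
   logFC-ranked sequence list gives each word an enrichment statistic,
   standardized and FDR-controlled by ranked-list permutations.
4. **Secondary effects.** If a transcription factor is itself a target,
   its regulon shifts coordinately. JASPAR-style count matrices are
   turned into PSSMs and promoter hit prevalence is compared between
   sets, with column-shuffled matrices as negative controls.

A synthetic-data generator with complete ground truth
(`simulate_experiment()`) drives validation of every stage.

# Models and statistics

## Seed words and hierarchical counting

For a mature miRNA (5′→3′), the target-strand DNA words are the reverse
complement of positions 2–7 (**6mer**), of positions 2–8 (**7mer-m8**),
the 6mer followed by an `A` opposite position 1 (**7mer-1A**), and the
7mer-m8 followed by that `A` (**8mer**). Counting is *hierarchical*:
every raw occurrence of the 6mer core is assigned to exactly one class by
its flanking bases, so an 8mer is never also counted as a 7mer or 6mer,
and the class counts always sum to the raw (overlapping) core count.
Sequence ends and `N` act as non-matching flanks; windows containing `N`
never match. Scanning is sense-strand only, since miRNA targeting reads
the mRNA.

## Set-level enrichment

Three metrics compare the down set against the up and no-change sets:
the percentage of genes with at least one site; sites per kilobase
(denominators use valid start positions, `len − k + 1`, a deliberate
pin-down that matters only for very short sequences); and raw counts
after subsampling all sets to the smallest set's size (seeded, so
reproducible). All use a two-sided pooled two-proportion z-test without
continuity correction; a degenerate pooled proportion gives p = 1. A
*pooled* site category (7mer-m8 + 7mer-1A + 8mer) accompanies the four
exclusive classes; the 6mer is excluded from the pool because it is both
the weakest class and the one most contaminated by chance matches.

## Word overrepresentation and the running sum

For one sequence and one k-mer with observed count *m*, the null is the
sequence's own mononucleotide composition: B random permutations of its
characters (default B = 5000). With N(m) the number of shuffles
containing the word at least *m* times, the score is

    score = −log10( (N(m) + 1) / (B + 1) )

The +1 is a crude finite-sampling correction that also avoids log(0).
Scores are non-negative, zero for absent words, and depend only on the
sequence content and the seed (duplicate sequences share one null
estimation). The exact log transform is a monotone choice; any monotone
variant ranks words identically.

Per word, scores along the logFC-ranked sequence list (most
down-regulated first) are centered by their mean and accumulated; the
word's statistic is the maximum of this running sum, a one-tailed choice
that targets enrichment among down-regulated sequences. Because the
centered sum returns to zero at the end, the maximum is non-negative; it
is clamped at zero against floating-point summation noise.

z-scores standardize the observed statistic against P random permutations
of the ranking (plug-in mean and standard deviation; sd = 0 gives z = 0,
which also covers words absent from every sequence). The FDR of a word
with z-score *z* is the pooled-null ratio

    FDR(z) = [fraction of all P·4^k permutation z-values ≥ z] /
             [fraction of observed z-values ≥ z]

clipped to [0, 1]. The raw ratio can wiggle non-monotonically through
ties and sparse tails, so a running maximum down the z-ranking enforces
monotonicity (a word never has a smaller FDR than a higher-scoring one).
The resolution floor is 1/(P·4^k): planted-signal FDRs of exactly 0 mean
"below resolution", consistent with reporting bounds like "< 0.002".

Words are annotated against the seed lexicon: exact class matches, or a
shared substring of at least 5 nt with the 8mer seed word ("partial").

## PSSM scanning and regulon enrichment

Count matrices become log2-ratio weight matrices with Laplace smoothing:
`weight(b, j) = log2(((count + 1) / (n_j + 4)) / 0.25)` at the default
pseudocount 1 and uniform 25% background. A window is a hit when its
*relative* score, `(s − s_min) / (s_max − s_min)`, reaches the threshold
(default 0.8). Relative scoring is the only interpretation under which a
single cutoff is meaningful across matrices of different lengths and
information content; for a matrix with equal per-column mismatch costs it
admits matches with at most `floor(0.2 L)` mismatches. Both strands are
scanned by default (promoters are double-stranded), minus-strand hits
being reported in the input frame; plus-only scanning is available and is
what the synthetic benchmarks use when the planted orientation is known.
Only hit presence/absence per promoter enters the set comparison, again
via the two-proportion test.

`shuffle_matrix()` provides the negative control: a uniformly random
non-identity column permutation, additionally resampled if duplicated
columns make the permuted matrix identical to the original. Shuffling
preserves column contents and total information content but destroys the
positional pattern.

One caveat the synthetic experiments make vivid: if a motif's letter
composition differs strongly from the promoter background (a GC-rich
motif in AT-rich promoters), planted instances are *compositional
islands* and even a shuffled matrix shows residual enrichment — shuffled
controls bound pattern-specificity, not composition effects. The shipped
`SYN_MIXED` motif has background-matched composition precisely so that
the shuffled control isolates the positional signal; `SYN_GCRICH`
deliberately does not, and is used where background hits are wanted.

# The synthetic-data generator

`simulate_experiment()` emulates the statistical structure such a study
rests on, not its biology:

- **Sequences.** Region lengths are log-normal (3′UTR median 1000 nt,
  σ = 0.6; CDS 1300; 5′UTR 200; promoters fixed at 2000 nt upstream of
  the TSS) with genome-like AT-rich composition (41% GC).
- **Sites.** A `target_fraction` (default 0.15) of genes receives
  effective planted sites per category (independent probabilities
  `site_spec`; a target drawing none gets a 7mer-m8). A further
  `background_prob` (default 0.1) of non-targets receives one
  *nonfunctional* site — real 3′UTRs are full of seed matches that do
  nothing, and set-level statistics must survive that. Generated 3′UTRs
  are first scrubbed of chance seed cores so the emitted site content
  equals the bookkept ground truth exactly, making truth verifiable by
  an independent scanner.
- **Expression.** Control replicates are gene baseline plus N(0,
  noise_sd²) noise (default 0.25); treated replicates add the gene's
  true shift — the sum of its planted categories' effects (defaults
  −0.6, −0.4, −0.3, −0.1 for 8mer, 7mer-m8, 7mer-1A, 6mer, following the
  canonical site-efficacy hierarchy; magnitudes are free parameters) —
  plus a condition-wide `global_shift` (default +0.226 log2 units)
  emulating the array-wide displacement such experiments show as a
  technical artefact. Replicates default to 4 vs 4; 4 vs 3 reproduces a
  removed array.
- **Regulon.** Optionally, a member fraction of genes gets a motif
  consensus planted in its promoter with high probability (background
  genes with low probability) and a coordinated expression shift.

What the generator does **not** emulate: probe-level array artifacts,
sequence conservation, 3′UTR secondary structure, site context (AU
flanking content, position within the UTR), or correlated expression
between genes. Passing tests therefore demonstrate that the statistics
behave correctly under their own assumptions, not that those assumptions
hold in any particular real dataset.

# Numerical and design choices

- **Differential statistic.** Welch's t with Benjamini–Hochberg
  correction stands in for a moderated-variance model; with several
  replicates per condition and the permissive FDR thresholds used for
  set definition (0.25 / 0.8) moderation changes little, and the
  `read_diff_table()` path accepts externally computed statistics.
- **Set thresholds.** FDR < 0.25 with the logFC sign defines up/down;
  FDR > 0.8 defines no-change; the band in between stays *unassigned*
  and is reported, never silently dropped. The measure-zero case
  FDR < 0.25 with logFC = 0 is unassigned.
- **Variance filter.** Strictly-less-than removes: a gene at exactly the
  cutoff is kept. The boundary is arbitrary but must be pinned for
  reproducibility.
- **Functional export cutoff.** `functional_set()` defaults to
  |logFC| > log2(1.1) (the fold-change reading) and is configurable to a
  literal 1.1 log2 units; both readings appear in the field and the
  package refuses to guess which was meant.
- **Isoform tie-break.** Equal-length isoforms resolve to the
  lexicographically smallest sequence — determinism over biology, since
  no biological rule exists.
- **Randomness.** Every stochastic operation takes a `seed` and runs
  under `withr::with_seed`, leaving the caller's RNG untouched. One
  seeded stream is consumed sequentially within an operation (shuffles,
  then permutations, in `word_analysis()`); a single seed therefore
  reproduces any result bit-for-bit, which the tests assert.
- **Resource guard.** `word_analysis()` restricts k to 4–8 by default
  (4^k score columns are materialized); the bound is a configurable
  argument, not a hard limit.

# Validation problem sizes

The shipped test-suite exercises the pipeline at sizes chosen to make
the statistical assertions sharp while staying desk-scale: the seed
counter against a brute-force classifier on 1,000 random sequences of
50–3,000 nt; shuffle-null tails against exhaustive multiset enumeration
for sequences up to 8 nt at B = 5,000; planted-word recovery on 2,000
ranked sequences (7mer planted at 60% prevalence in the top 300 versus
10% background, B = 200, P = 100); the proportion test against a
chi-square oracle on 10,000 random tables; PSSM scanning against a
brute-force scorer on 200 random fixtures; the regulon contrast
(70% vs 51% planting, 500 promoters of 2,000 nt per set) and the full
simulate→sets→enrichment pipeline over 100 seeds each. The generator's
defaults (2,000 genes, 4 vs 4 replicates, noise 0.25, global shift
0.226) are the simulated study conditions throughout.

# Known limitations

- The word-analysis score matrix is dense (sequences × 4^k); k = 8 with
  tens of thousands of sequences is memory-hungry.
- Permutation FDRs cannot resolve below 1/(P·4^k); P ≥ 100 is advised
  before interpreting small FDRs.
- The two-proportion z-test is asymptotic; with very small sets or
  near-0/1 prevalences its calibration degrades (the test-suite checks
  calibration at moderate sizes only).
- Set definitions assume the differential table's FDR is trustworthy;
  with strong global displacement and few replicates the no-change set
  is a mixture, which the generator reproduces on purpose.
- Shuffled-matrix controls do not control for motif composition (see
  above); conclusions about a compositionally extreme motif need a
  composition-matched null as well.
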