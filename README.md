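# seedwords

Identify candidate microRNA targets from a perturbation experiment: when
a miRNA is overexpressed and the transcriptome profiled, its direct
targets are enriched among the down-regulated transcripts, and that
enrichment is detectable in sequence space. `seedwords` implements the
complete computational pipeline for this design — expression-defined
gene sets, hierarchical seed-site enrichment, an unbiased ranked-list
k-mer analysis, and promoter motif scanning for secondary
transcription-factor effects — together with a ground-truth synthetic
data generator that validates every stage.

It is written for computational biologists analysing miRNA
overexpression/inhibition microarray or RNA-seq experiments, and for
method developers who need a tested reference implementation of
ranked-list word statistics.

## The statistics at the core

**Seed sites.** For a mature miRNA, the target words are the reverse
complements of seed positions 2–7 (6mer) and 2–8 (7mer-m8), plus the
A-anchored variants (7mer-1A = 6mer + `A`, 8mer = 7mer-m8 + `A`).
Counting is hierarchical: each occurrence of the 6mer core is assigned
to exactly one class by its flanking bases, so
`n8 + n7m8 + n7a1 + n6` equals the raw core count. Site prevalence in
the down- vs no-change gene sets (FDR < 0.25 with logFC sign; FDR > 0.8)
is compared with a pooled two-proportion z-test.

**Unbiased word analysis.** For every k-mer *w* and sequence with
observed count *m*, the overrepresentation score is

    score(w) = −log10( (N(m) + 1) / (B + 1) )

where N(m) counts mononucleotide shuffles (of B, default 5000) of that
sequence containing *w* at least *m* times. Scores are mean-centered per
word and accumulated along the logFC-ranked sequence list; the word's
statistic is the maximum of this running sum, standardized against P
permutations of the ranking (z-score), with FDR from the pooled
permutation null.

**Promoter motifs.** JASPAR count matrices become log2-ratio PSSMs
(pseudocount 1, 25% background); windows with relative score
`(s − s_min)/(s_max − s_min) ≥ 0.8` are hits, and per-set promoter hit
percentages are compared with the same proportion test, with
column-shuffled matrices as negative controls.

## Worked example

Simulate a miR-145 overexpression experiment (2,000-gene default scaled
to 1,000 here), define sets, and test seed-site enrichment:

```r
library(seedwords)

lex <- seed_words("GUCCAGUUUUCCCAGGAAUCCCU", "hsa-miR-145")
lex
#> <seed_lexicon> hsa-miR-145 (GUCCAGUUUUCCCAGGAAUCCCU)
#>   6mer:    ACTGGA
#>   7mer-m8: AACTGGA
#>   7mer-1A: ACTGGAA
#>   8mer:    AACTGGAA

exp  <- simulate_experiment(simulation_config(n_genes = 1000, seed = 42), lex)
sets <- assign_sets(exp$diff)
glance(sets)
#> # A tibble: 1 × 8
#>   n_genes  n_up n_down n_nochange n_unassigned fdr_regulated fdr_nochange ...
#> 1    1000   135     41        185          639          0.25          0.8

utr3 <- dplyr::filter(exp$sequences, region == "utr3")
seed_enrichment(sets, utr3, lex)
#> # A tibble: 5 × 6
#>   category    up  down no_change p_dn_vs_up p_dn_vs_nc
#> 1 site8     2.22  56.1      1.08   1.67e-17   2.95e-24
#> 2 site7m8   2.22  70.7     10.3    2.25e-23   1.09e-17
#> 3 site7a1   2.96  53.7      7.03   1.13e-15   8.19e-14
#> 4 site6     2.96  19.5      1.08   2.31e- 4   2.08e- 7
#> 5 pooled    7.41  95.1     18.4    5.07e-28   1.95e-21
```

95% of down-regulated genes carry a 7mer/7mer-1A/8mer site versus 18% of
unchanged genes (p ≈ 2·10⁻²¹): the planted targeting signal is recovered.
The unbiased analysis finds the same signal with no prior knowledge of
the seed:

```r
ranked <- dplyr::inner_join(utr3, exp$diff[, c("gene_id", "logFC")],
                            by = c(seq_id = "gene_id"))
words <- word_analysis(ranked, k = 7, B = 200, P = 50, seed = 43, lexicon = lex)
head(tidy(words), 5)
#> # A tibble: 5 × 6
#>    rank word    statistic z_score   fdr annotation
#> 1     1 ACTGGAC     111.    21.2      0 hsa-miR-145 partial
#> 2     2 AACTGGA     111.    20.6      0 hsa-miR-145 7mer-m8
#> 3     3 CACTGGA      78.7   16.8      0 hsa-miR-145 partial
#> 4     4 ACTGGAA      83.1   16.4      0 hsa-miR-145 7mer-1A
#> 5     5 CTGGACT      37.8    8.12     0 hsa-miR-145 partial
```

The top-ranked 7mers are the seed match and its overlapping variants
(FDR 0 = below the 1/(P·4^k) permutation resolution).
`autoplot(word_profile(...))` draws the running-sum profile;
`promoter_enrichment()` and `cmd_tfbs()` cover the transcription-factor
stage. A thin command-line wrapper with `simulate | seedscan | wordscan |
tfbs` subcommands ships in `inst/scripts/seedwords.R`.

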