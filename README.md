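# varcis

Variant catalogs and cis-eQTL mapping for panels of fully inbred lines.

## The problem

Dense panels of wild-derived, fully inbred lines (each line effectively a
single homozygous haplotype) make it possible to catalogue *all* classes of
sequence variation — SNPs, insertions, deletions, balanced multi-nucleotide
substitutions (MNS) and complex variants — and to ask how those variants
shape gene expression in cis. varcis implements that analysis end to end for
anyone who wants to study, teach or stress-test the machinery on data with
known truth:

* a **seeded synthetic-data generator**: reference genome, gene models with
  clean ORFs, a planted variant panel with a controlled allele-frequency
  spectrum, paired-end reads, log2 expression (lines × sex × replicates)
  with planted cis effects, and F1 allele-specific counts with planted
  imbalance;
* **indel normalization and rule-based classification** (homopolymer /
  microsatellite / tandem-repeat context, MNS, inversions, segmental
  duplications by seeded homology search);
* a **vote-based genotyper**: reads are scored against every population
  allele of a site jointly; a read's unique best allele gets one positive
  vote and every other allele one negative vote; a new call needs
  `pos >= neg + 1`, an existing call is removed when `pos <= neg / 2`;
* **genomic-context statistics**: SNP density around variant breakpoints
  with a non-carrier-line control, di/tri-nucleotide adjacency excess versus
  a within-window re-placement simulation, density correlations, LD r²,
  strand-oriented TSS/TES profiles, coding consequences, and the coding
  indel size spectrum;
* **multi-allelic cis-eQTL mapping**: overlapping variants grouped into
  sites whose alleles are local haplotypes; Kruskal-Wallis allele
  association and rank-regression on alignment scores `max(ni, nd)`; the
  per-transcript adjusted threshold is the `round(alpha * n_perm)`-th
  order statistic of the permutation minima (with 10,000 permutations at
  nominal 0.05: the 500th); FDR is estimated as
  `alpha * transcripts tested / transcripts passing` with a 10% operating
  point; sex-specificity is classified at the operating threshold;
* **F1 allelic imbalance**: two-sided exact binomial tests at >= 20
  informative reads, BH correction, significance required in both reciprocal
  crosses, plus variant TP/FP validation from parental allele support and a
  permutation test for how the validated fraction scales with eQTL effect
  size.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` methods on fitted objects, `autoplot()` methods on every result
type.

## Worked example

```r
library(varcis)
library(dplyr)

cfg <- sim_config(seed = 11, genome_length = 60000, n_lines = 39,
                  n_transcripts = 10)
g0     <- sim_genome(cfg)
genes  <- sim_transcripts(g0, cfg)          # writes ORFs into the genome
panel  <- sim_variants(genes$genome, cfg) |>
  normalize_variants(genes$genome)
sites  <- group_alleles(panel, genes$transcripts)
expr   <- sim_expression(panel, genes$transcripts, cfg, sites = sites)
fit    <- map_cis_eqtl(expr$expression, sites,
                       eqtl_config(seed = 5, n_perm = 1000))
glance(fit)
```

```
#> # A tibble: 4 × 8
#>   sex   method n_transcripts n_sites_tested n_significant_sites
#>   <chr> <chr>          <int>          <int>               <int>
#> 1 F     allele            10            362                   3
#> 2 F     score             10            362                   3
#> 3 M     allele            10            362                   3
#> 4 M     score             10            362                   3
#>   n_significant_transcripts operating_alpha operating_fdr
#> 1                         3           0.025        0.0833
```

All ten transcripts have a testable site (at least two alleles with three or
more carrier lines) within 10 kb, giving 362 site-transcript tests per sex
and method; three transcripts — exactly the three with planted two-fold
effects (`expr$truth`: tx001, tx009, tx010) — are called significant by both
association methods in both sexes, at an operating nominal alpha of 0.025
where the estimated FDR is 8.3%. `tidy(fit)` returns one row per tested site
with its raw p-value, per-transcript adjusted threshold and allelic effect
size, and `autoplot(fit)` plots effect against significance.

The same world feeds the downstream stages:

```r
f1  <- sim_f1_counts(panel, genes$transcripts, cfg)   # two reciprocal crosses
ase <- combine_crosses(f1$counts)
ase
#> <ase_result> 6 transcripts tested; 0 imbalanced in both crosses at 10% FDR
```

Six transcripts are informative for the default cross (the parents differ at
an exonic variant) and none shows imbalance in both crosses — as planted:
the default config leaves these transcripts' imbalance fraction small.

or run every stage at once with `run_pipeline(cfg)`, which also writes
FASTA/FASTQ/VCF/GFF3/TSV/JSON artifacts and a manifest of stage digests
(re-running with the same config reproduces them byte for byte).

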