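---
title: "Methods: variant catalogs and cis-eQTL mapping in inbred line panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant catalogs and cis-eQTL mapping in inbred line panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varcis)
library(dplyr)
```

varcis studies how sequence variants of all classes — SNPs, insertions,
deletions, balanced multi-nucleotide substitutions (MNS) and unbalanced
complex variants — shape gene expression in a panel of fully inbred lines.
Because each line is homozygous (one haplotype per line), a variant's
genotype across the panel is a simple carrier set, and cis-regulatory effects
can be read directly from line-level expression differences. This vignette
explains the models behind each stage, the tunable parameters that matter,
and the design decisions taken where more than one reasonable choice existed.

## The synthetic panel

Every analysis stage consumes inputs that the package can generate with
planted ground truth, so the whole pipeline is testable without external
data. The generator ([`sim_config()`] and the `sim_*` functions) emulates:

* **A reference contig** of i.i.d. bases at a configurable GC fraction
  (default 0.42, typical of a fly euchromatic arm). One autosome-like contig
  is the default; nothing in the tested statistics needs more.
* **Gene models** with a 5' UTR, a clean open reading frame (ATG start, no
  internal stop, terminal stop), a 3' UTR and one intron with canonical
  GT..AG dinucleotides, on both strands. ORFs are written into the returned
  genome so that coding-consequence calls can be verified by honest
  translation.
* **A variant panel**: per-bp rates per class (defaults mirror the relative
  abundances seen in dense natural panels — SNPs several-fold more common
  than indels, balanced MNS the most common complex class, scaled to desk
  size). Carrier counts come from the standard neutral allele-frequency
  spectrum (P(count = i) proportional to 1/i), whose *folded* form is the
  analytic expectation that [`variant_spectrum()`] plots and tests;
  `fixed_counts` pins every variant to a chosen carrier count instead.
  Variants are planted non-overlapping so the truth is unambiguous, except
  that a configurable fraction of multi-bp deletions receives a second,
  overlapping allele (a SNP inside the deleted span carried by other lines)
  to create genuinely multi-allelic sites.
* **Paired-end reads** with uniform fragment starts, Gaussian insert sizes
  and i.i.d. per-base substitution errors; each read carries its true origin.
* **Expression**: for transcript *t*, line *l*, sex *s*, replicate *r*,
  `value = baseline_t + line_effect_tl + effect * carrier_l * [s in scope] +
  noise`, all in log2 units, two replicates per line and sex by default.
  Planted cis effects sit at a testable site within 10 kb of the transcript;
  the effect size (default 1.0 = two-fold) may be a vector sampled per eQTL,
  and effects can be male-only, female-only or shared.
* **F1 counts**: for a cross between two panel lines, a transcript is
  informative when the parents differ at an exonic variant; informative
  depth is Poisson (mean 200 reads), and the count supporting parent A is
  binomial with success probability `fold / (1 + fold)`.

What the generator does **not** emulate: linkage blocks from recombination
history (carrier sets are drawn independently per variant, so background LD
is weaker than in a real panel), sequence-context mutation biases,
microarray probe-level effects (expression arrives already normalized, with
detection flags), X-chromosome dosage, and base-quality structure in reads.
Passing tests therefore demonstrate correctness of the statistical machinery
under the stated generative model, not robustness to every artefact of real
data.

## Variant representation and classification

Variants are stored 1-based: `pos` is the first affected reference base
(for insertions, the base before which new sequence is inserted), `ref` the
deleted sequence (nd bases) and `alt` the inserted sequence (ni bases).
1-based closed intervals are the native convention of the R/Bioconductor
ecosystem this package lives in; conversion to VCF (anchor-base convention
for pure indels) and GFF3 happens only at the file boundary and is exact.

[`normalize_variants()`] trims shared suffixes then prefixes and left-aligns
pure indels through repeated sequence — the canonical representation used by
VCF tooling — and is idempotent.

[`classify_variants()`] assigns exactly one top-level class from (nd, ni):
SNP (nd = ni = 1), insertion (nd = 0), deletion (ni = 0), complex (both
positive). Subtypes evaluate the allele against its flanking context:
homopolymer (unit size 1, resulting run at least 3), microsatellite (unit
2–4, resulting full units at least 4), tandem repeat (unit > 4, at least 2
units), balanced MNS (nd = ni > 1), inversion (nd = ni >= 4 and the
alternative is the exact reverse complement), and segmental duplication
(allele of at least 100 bp homologous elsewhere). Two decisions here were
genuinely open:

* *"Resulting" repeat counts* are evaluated on the post-insertion sequence
  for insertions and on the reference sequence for deletions, counting only
  whole units in the allele's own phase. Partial terminal units do not
  count; the unit is the smallest period that tiles the allele exactly.
* *Homology search* uses exact k-mer seeds (k = 16) grouped by diagonal and
  verified by gapless full-length comparison, reporting a hit at >= 90%
  identity over >= 90% of the allele, on either strand, excluding a
  deletion's own locus. This replaces an external aligner; an
  alignment-score cutoff tied to a specific tool is dropped in favour of the
  reproducible identity/length criteria.

## Vote-based genotyping

Candidate sites come from the population-wide call set, merged into
multi-allelic sites by [`candidate_sites()`]: all overlapping variants of a
locus are competed **jointly**, each allele spelled out as an explicit
sequence in identical reference flanks. This matters: genotyping a SNP in
isolation inside a span that other lines carry as a deletion misattributes
deletion reads to the SNP allele.

Reads are placed on the reference by exact k-mer seeding (three seed
offsets, both strands) plus gapless mismatch extension; reads with more than
one equally good locus are ambiguous and never vote. Placement tolerates up
to 45% mismatches — a read spanning an indel disagrees with the reference at
up to half its length under gapless alignment — while allele scoring keeps a
strict cap of 10% of the read length, so reads that fit no candidate allele
cannot vote. Each read then scores every candidate allele (minimum Hamming
distance over all offsets); a unique best allele receives one positive vote
and every other allele one negative vote; ties abstain. A new allele is
called when positive votes exceed negative votes by at least one; an
existing call is removed when positive votes are not greater than half the
negative votes (real-valued halving). With zero votes of either sign nothing
changes: removal requires actual negative evidence.

## Genomic-context statistics

* [`snp_density_around()`] profiles SNP observations per carrier line around
  variant breakpoints (the normalized variant start; the insertion point for
  insertions), with a control computed at the same loci in the lines that
  lack the focal variant — the comparison that separates locus-level
  mutation-proneness from population-level haplotype structure.
* [`adjacency_excess()`] decomposes SNPs and balanced MNS into substituted
  base positions per line and 1 kb window, counts maximal runs of exactly 2
  (di) and 3 (tri) adjacent substitutions, and re-places each window's
  substitutions uniformly `n_sim` times for the chance expectation. Whether
  the expectation should condition on window base composition is unstated in
  the underlying method; uniform re-placement within the window is used.
* [`density_correlation()`] (Spearman with midranks), [`ld_r2()`] (squared
  Pearson correlation of 0/1 carrier indicators), and [`feature_profile()`]
  (TSS/TES metagene profiles, minus-strand transcripts flipped so
  transcription always runs rightward) follow their textbook definitions.
* [`variant_consequence()`] classifies with precedence gene disruption >
  splice-site disruption (the 2 terminal bases of an intron) > coding > UTR,
  with intron-only overlaps reported as `intron` outside the functional
  classes. In-frame coding variants are screened for created stops by
  editing the CDS in transcript space and scanning codons; stop loss is only
  evaluated when the variant overlaps the annotated stop codon. A
  brute-force oracle that rebuilds the mutant CDS from the mutated genome
  and translates it backs this logic in the test suite.

## Multi-allelic cis-eQTL mapping

Overlapping variants are grouped into sites whose alleles are the distinct
local haplotypes; the reference allele is the empty combination
([`group_alleles()`]). Each allele carries an alignment score
`max(total ni, total nd)` (reference 0). Sites are tested against every
transcript whose either end lies within 10 kb. Alleles carried by fewer than
3 lines are excluded along with their lines — the chi-square approximation
of the Kruskal-Wallis test needs group sizes of at least 3, and the
"present in at least three lines" filter is read per allele group.

Two association statistics are available per site and sex, on
replicate-averaged line expression (associations act at line level, so
averaging before ranking loses nothing and stabilises the ranks):

* **allele association** — Kruskal-Wallis on expression ranks grouped by
  allele (midranks, classical tie correction, chi-square with groups − 1 df);
* **score association** — linear regression of expression ranks on
  alignment-score ranks, slope t-test; this associates variant *size* rather
  than identity, which matters when several alleles have different lengths.

Multiplicity over the many sites of a transcript is handled by permutation:
the same `n_perm` permutations of line labels (one seeded stream per
transcript and sex, applied jointly to all sites so between-site linkage is
preserved) give a vector of per-permutation minimum p-values; the adjusted
threshold at nominal level alpha is the element at 1-based index
`round(alpha * n_perm)` of the ascending-sorted vector — with 10,000
permutations and nominal 0.05, the 500th element. The FDR at alpha is
`alpha * transcripts tested / transcripts passing`, and the operating point
is the largest grid alpha with FDR at or below the target (default 10%).
The two methods are corrected independently; on bi-allelic sites they agree
on significance for the vast majority of transcripts (tested at 95%).
A transcript with significant eQTLs in both sexes is "shared"; otherwise it
is specific to the sex in which it is significant — at the operating
threshold only, with no secondary lenient threshold, so near-misses in the
other sex still count as sex-specific.

Numerical notes: permuted p-values are computed by the same vectorised code
path as the observed ones (exchangeability by construction), and that code
is unit-tested for exact equality with `kruskal.test()` and `cor.test()`.
At panel sizes of 10 lines and below the chi-square approximation deviates
from the exhaustive permutation distribution of H by up to ~0.2 in the
mid-range — the discreteness step of an exact distribution with as few as 10
atoms — while ordering datasets identically; the acceptance suite asserts
both facts.

## F1 allelic imbalance and validation

[`build_haplotype_transcriptomes()`] applies each parent's variants to the
reference, lifts exon coordinates through the indel shifts and splices per
haplotype. [`assign_reads()`] aligns each read to both transcriptomes:
reads placeable at more than one *genomic* location are discarded
(transcript-level multiplicity from overlapping isoforms does not discard);
equal-mismatch reads are uninformative; otherwise the read supports the
haplotype with fewer mismatches, and single-haplotype aligners support that
haplotype. Error-free reads spanning a differing base never support the
wrong haplotype (property-tested).

[`ase_test()`] is the two-sided exact binomial test against 0.5, computed as
`min(1, 2 x smaller tail)` — identical to the conventional exact test at
p = 0.5; mid-p is not used. Transcripts need at least 20 informative reads
to be tested; the filter is applied before Benjamini-Hochberg correction
(only covered transcripts count toward m), and a transcript is significantly
imbalanced only when it passes 10% FDR in **both** reciprocal crosses, with
no pooling of counts. The Spearman concordance of log2 allele ratios between
the crosses is reported as QC, not used as a gate.

For validating DNA-level calls from parental RNA-seq,
[`validate_variants()`] marks a variant true positive when all aligned reads
support it or support is significant at p < 0.05 (two-tailed binomial),
false positive symmetrically for the reference, and unresolved otherwise.
[`eqtl_validation_rate()`] measures, per effect-size cutoff, the fraction of
eligible eQTL transcripts (parents carrying different alleles) that show
significant imbalance, against an empirical null of 1,000 same-size random
draws from all ASE-tested transcripts; the empirical p counts random sets
scoring at least as high as the real one.

## Problem sizes and reproducibility

All randomness flows from one root seed through named substreams per stage,
so any stage can be re-run in isolation and the full pipeline reproduces
byte-identical outputs ([`run_pipeline()`] records stage digests in its
manifest). The shipped checks use desk-scale problem sizes chosen to give
each statistic enough events to be sharp while staying comfortably
interactive: null calibration uses 500 transcripts x 39 lines x 1,000
permutations; planted-effect recovery 200 transcripts (30% carrying a
two-fold effect); genotyping 200 planted variants on a 100 kb genome at
20-fold coverage; ASE power 2,000 transcripts at depth 200; the classifier
partition 100,000 random variants. Known limitations worth repeating: the
recovery rate of planted eQTLs is dominated by sites with minor allele
count 3, where a rank test over 3-vs-36 lines simply cannot reach very small
p-values against a multiplicity-adjusted threshold — a real property of the
design, not an implementation artefact; and because carrier sets are drawn
independently, the generator's LD is weaker than in real panels, making the
permutation correction mildly conservative relative to field data.
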