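---
title: "Methods: dissecting 90-bp exon array LRR gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting 90-bp exon array LRR gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrrscape)
```

# The biological setting

Ciliates of the genus *Tetrahymena* carry large, fast-evolving families of
leucine-rich repeat (LRR) genes with an architecture that is, to our
knowledge, unique: runs of CDS exons that are *exactly* 90 bp long, separated
by phase-2 introns. Because 90 is divisible by 3 and every flanking intron
interrupts a codon after its second nucleotide, each exon's first nucleotide
completes the junction codon begun by the previous exon, and its last two
nucleotides begin the junction codon completed by the next one. A 90-bp exon
therefore contributes 29 complete codons of its own (nucleotides 2–88) and
touches 31 amino acids in total; the whole array translates as an interlocked
unit, and all exons are "naturally aligned" without any alignment algorithm.

This package quantifies that architecture and everything the field hangs on
it: exon/intron length landscapes, intron-phase bias, age-group
classification from repeat masking, per-position conservation profiles,
near-identity exon clustering (a signature of ectopic recombination),
ortholog/tandem-duplication statistics, germline chromosome maps in
IES-omitted coordinates, and the colocalization of a non-LTR retrotransposon
(REP) with LRR repeat units.

# Coordinate and sequence conventions

* Internal coordinates are **0-based half-open** everywhere. GFF3 (1-based
  inclusive) and RepeatMasker `.out` (1-based) are converted at the parser
  boundary and back at the writer, which keeps the round trip the identity.
* "Exon" always means **CDS segment**: phases and translation are undefined
  on UTRs, and none of the analyses use them.
* Multi-transcript genes collapse to the transcript with the longest total
  CDS (ties: lexicographically smallest transcript id). Annotation dialects
  contain partial models, so genes whose CDS length is not divisible by 3
  are excluded with a warning rather than aborting the run.
* Translation defaults to the **ciliate nuclear code** (NCBI table 6:
  TAA/TAG encode glutamine, only TGA terminates). The standard code is
  available but would introduce spurious internal stops in ciliate data.
  In amino-acid profiles, Q from TAA/TAG is reported simply as Q.

# Key statistics and their parameters

## Intron phases and exon arrays

The phase of intron *i* is the cumulative length of exons 1..*i* modulo 3.
An *array* is a maximal run of consecutive exons each exactly
`target_len = 90` bp; only runs of `min_run = 3` or more are reported, and
the match is exact (90 means 90, not 89–91) — the sharp inset peak of the
exon length distribution motivates strictness. `phase_bias_report()`
tallies phases in four strata (introns preceding 90-bp exons in LRR genes,
introns in LRR genes without 90-bp exons, introns preceding 90-bp exons in
non-LRR genes, all introns); "preceding" means immediately 5′ in
transcription order, with following-intron phases emitted as an extra
column for reference.

## Length histograms and peak detection

Histograms use 1-bp bins. Peaks are local maxima of a centered moving
average (window 5 bp) whose topographic prominence is at least 10% of the
global smoothed maximum; each peak is then refined to the raw-count mode
within the smoothing window so that sharp modes (90, 56, 257, 122 bp) are
reported at their exact value. The procedure is deterministic and
permutation-invariant; it is a package design choice, since the source
analyses present peaks graphically.

## Age groups from repeat masking

A gene is *masked* when the union of a single repeat family's hits covers at
least `min_masked_bp = 50` bp of its CDS+intron span — below one repeat
unit's exon length, an isolated spurious hit should not trigger a group III
call. Group I = no 90-bp exon and not masked; group II = 90-bp exon(s), not
masked; group III = 90-bp exon(s) and masked. Masked genes without 90-bp
exons do not fit the three-group scheme and are surfaced as `unclassified`
rather than forced. The *best family* of a group III gene is the family with
the largest sum of overlapping hit scores (RepeatMasker-style alignment
scores), ties broken by masked bp then family id — an explicit
operationalization of "highest masking score".

## Conservation profiles and the two-sample logo

The amino-acid view of a 90-bp exon matrix drops nucleotide 1 and
nucleotides 89–90 (the junction nucleotides) and translates the remaining 29
codons; codon *k* spans exon nucleotides 3k−1..3k+1, so the conserved
leucine codon centers 36, 48, 66, 75, 81, 87 map to residues 12, 16, 22, 25,
27, 29. A position is *conserved* for a symbol when its frequency reaches
`min_freq = 0.5`.

The two-sample comparison tests, per column and symbol, the count in sample
A against a null frequency taken from sample B, one-sided in each direction
(binomial tails), calling at `alpha = 1e-5`. The null frequency is clamped
to [1/(|B|+2), 1−1/(|B|+2)]: a pseudo-frequency floor that avoids degenerate
p-values when a symbol is absent or fixed in B. B-only (rather than pooled)
null frequencies are a package choice; the original tool's exact handling is
unspecified. Samples under 20 sequences warn as underpowered but are still
computed.

## Near-identity exon clustering

"Identity ≥ 97%" over 90 bp is exactly "Hamming distance ≤ 2" (lengths are
identical by construction, so no alignment or gap handling is needed).
Clusters are single-linkage connected components — the connected-component
reading of "clustering", and the one that is oracle-checkable. The
implementation finds candidate pairs with an exact-segment pigeonhole index
(any pair within 2 mismatches shares one of 3 equal thirds) and is tested
for equality against an all-pairs components oracle; it scales to tens of
thousands of exons.

## Ortholog categories, expansions, tandem groups

A cluster's category is the number of species with at least one member
(rendered I–X when 10 species are analyzed; internally an integer so any
species count works). The inparalog-expansion test models a species' count
k in a cluster of size N spanning S species as Binomial(N, 1/S), takes the
upper tail, Bonferroni-corrects over the S species tested within the
cluster, and flags at `alpha = 0.01`; clusters with N < 5 or a single
species are skipped. The exact test used by the original analysis is not
recoverable from the text, so this form is stated, configurable, and
calibrated by a type-I property test (≤ α family-wise flags on 10⁴
multinomial-uniform clusters). Species-specific genes are the union of
singletons, category-I members, and members of clusters where their species
is flagged expanded.

Tandem linkage counts intervening *genes* in annotation order (strand
ignored): `max_gap = 0` is the strict criterion, `max_gap = 3` the relaxed
one. Singletons link to other singletons under the same rule. Strict groups
are, provably, contiguous intervals of the gene order.

## Chromosome landscape

MDS ("MAC-destined sequence") coordinates subtract all IES bp strictly
upstream; positions inside an IES collapse to its left edge and are flagged
(and excluded from bin tracks). Bin tracks tile the IES-omitted chromosome
with 1-Mb bins (last bin short). Regions are *pericentromeric* within 1 Mb
of the centromere midpoint (computed in MDS coordinates), *subtelomeric*
within 1 Mb of either end, *arm* otherwise; the extents are working
definitions, configurable, with pericentromeric taking precedence.
Enrichment uses a chi-squared test on the subset × region table; per-gene
values (e.g. Ka/Ks) compare between regions by two-sided Mann–Whitney.

## REP tail scanning and colocalization

The conserved 54-bp 3′ tail is searched as Hamming windows on both strands
(no indels) at `max_mismatch = 5` (~90% identity over 54 bp) — a tolerance
choice balancing "highly conserved" against neutral divergence; overlapping
same-strand hits keep the lowest-mismatch window. "Flanking" is edge-to-edge
distance ≤ 1000 bp, swept over {250, 500, 1000, 2000} in a sensitivity
report because the source analyses use the word without a number. A copy is
*functional* iff both ORFs are intact; intactness is taken from annotations,
with an optional helper that checks for an uninterrupted reading frame under
the ciliate code.

# The synthetic data generator

`generate_bundle()` emits, per species, a germline-like genome of 5
chromosomes with centromere and IES annotations, gene models (GFF3), repeat
mask hits, REP elements, domain/ortholog/expression/Ka-Ks tables and truth
tables. It emulates:

* background genes with ~56 ± 8 bp introns and AT-rich codon usage;
* group I LRR genes (no 90-bp exons, short introns);
* group II/III array genes: a lead exon, Poisson(10)-truncated-to-[3,15]
  exactly-90-bp exons built from a per-species template with leucine codons
  at nucleotide centers {36, 48, 66, 75, 81, 87}, GT..AG introns, and a tail
  exon ending in TGA. With probability `phase2_prob = 0.99` the lead exon
  length is ≡ 2 (mod 3), making every intron that precedes an array exon
  phase 2 (the gene-level Bernoulli mirrors how a single ancestral frame
  propagates through an array); off-frame genes are built with template-free
  exon content in a shifted frame.
* the conservation gradient: leucine retention 0.95 (group III) vs 0.85
  (group II), background substitution rate 0.01 vs 0.05, with substitutions
  never creating an in-frame TGA and junction nucleotides held fixed;
* species-characteristic group III intron modes (257 bp for the focal
  *thermophila*-like profile, 232 and 200 bp for the others) and a 122-bp
  secondary mode carried by a CRS1-attributed 10% subset of focal group III
  genes;
* mask hits written directly by the generator with plausible scores (the
  best family is the gene's true family), so group recovery is testable
  hermetically without running a masking tool;
* placement on a 10-kb slot grid with region weights 5:5:1
  (pericentromeric : subtelomeric : arm) for group III genes and REP copies,
  4:4:1 for intergenic IESs, uniform for everything else; one strict tandem
  run (17 genes) plus a relaxed chain grown from the focal species'
  61-inparalog expansion cluster;
* REP copies with two ORFs, a spacer and the 54-bp tail (0–2 planted
  mismatches), adjacent to a group III gene with probability 0.8 at an edge
  gap of 100–800 bp, otherwise placed in their own region-weighted slots;
* ortholog structure by label (conserved clusters pairing the k-th gene of
  each species, species-specific clusters, singletons, one expansion
  cluster, optional partial-span clusters for intermediate categories) —
  deliberately independent of sequence similarity so the ortholog module is
  tested on its own;
* log-normal FPKM with a lower median for species-specific genes, and
  region-dependent Ka/Ks (higher pericentromeric/subtelomeric).

What it does **not** emulate: tree-aware sequence evolution along a
phylogeny, IES excision machinery, splice-site signals beyond GT..AG,
assembly gaps, or annotation errors other than the frame checks exercised in
the parsers. Passing tests on synthetic data therefore demonstrate the
correctness and calibration of the *computations*, not the biological
fidelity of any particular genome.

Intron sequences are random at 75% AT (matching the genus' AT richness) with
GT/AG forced. Intergenic sequence is random with the same composition.
Regeneration with the same spec and seed is byte-identical; fixtures are
cached per session.

# Problem sizes and numerical choices

The package's reference conditions are three fixtures: `toy` (2 species,
~46 genes — used by most integration tests), `default` (3 species, 5 × 6-Mb
chromosomes each, 750 LRR + 500 background genes per species, 400 REP
copies — ~2,250 LRR genes in total, the scale at which the statistical
summaries stabilize while a full generation stays around a minute), and
`stress` (10 small species, exercising ortholog categories I–X). Calibration
tests use 10⁴ null clusters for the expansion test and 90 × 4 = 360 binomial
tests for the logo comparison.

Tie-breaking is deterministic throughout: consensus ties resolve by fixed
symbol order (A<C<G<T, alphabetical for amino acids), best-family ties by
masked bp then family id, histogram peak ties by raw count. Degenerate
inputs (empty strata, empty categories, single-region chromosomes,
zero-row matrices) return NA-marked rows or explicit errors naming the
offending filter rather than silently propagating.

# Known limitations

* The expansion test and the masking threshold are explicit stand-ins for
  procedures the source analyses do not fully specify; both are
  configurable, and conclusions that depend on them should be checked at
  neighboring settings.
* Near-identity clustering is single-linkage by design; it answers "which
  exons are connected by chains of ≥97% identity", not "which exons form
  tight cliques".
* The landscape module assumes one centromere interval per chromosome and
  non-overlapping IESs; scaffolded (non-chromosomal) assemblies can use the
  binning but not the region calls.
* ORF-intactness of REP copies is trusted from annotations; the built-in
  checker is a coarse reading-frame scan, not a gene model.
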