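# lrrscape

Comparative-genomic analysis of rapidly evolving **leucine-rich repeat (LRR)
gene families in ciliates**, built around the peculiar gene architecture found
in *Tetrahymena*: tandem arrays of CDS exons that are **exactly 90 bp** long,
separated by **phase-2 introns**, each exon encoding one LRR unit. The package
is aimed at genome scientists who want to dissect such repeat-driven gene
family expansions — from raw annotation files to age-group classification,
conservation profiling, duplication statistics and chromosomal mapping —
entirely in R.

## What it computes

For a set of annotated genomes (FASTA + GFF3 + RepeatMasker-style hits +
OrthoMCL-style clusters), the package provides:

* **Gene architecture** — intron phases (phase of intron *i* =
  cumulative CDS length of exons 1..*i* mod 3), exact-length exon arrays
  (≥3 consecutive 90-bp exons), exon/intron length histograms with peak
  detection, repeat-unit lengths (90-bp exon + following intron), GC content
  and leucine codon usage under the ciliate nuclear code (TAA/TAG → Gln).
* **Age grouping** — LRR genes sorted into group I (no 90-bp exons, not
  masked), group II (90-bp exons, not masked) and group III (90-bp exons,
  masked by a repeat-family consensus), with exclusive best-family assignment
  by highest masking score.
* **Conservation profiles** — naturally aligned N×90 exon matrices; position
  frequency profiles in nucleotide space and in the 29-residue frame obtained
  by dropping the junction nucleotides (positions 1, 89, 90); consensus
  calls; two-sample logo comparison by one-sided binomial tests
  (p < 10⁻⁵); single-linkage clustering of exons at ≥97% identity (Hamming
  distance ≤ 2 of 90).
* **Ortholog categories and tandem duplication** — cluster categories I–X
  (number of species present), binomial inparalog-expansion tests,
  species-specific gene sets (singletons ∪ category I ∪ flagged expansions),
  strict (0 intervening genes) and relaxed (≤3) tandem groups.
* **Chromosome landscape** — IES-omitted (MDS) coordinates, 1-Mb bin tracks,
  pericentromeric / subtelomeric / arm region calls with chi-squared
  enrichment and Mann–Whitney value comparisons, IES–gene association.
* **Retrotransposon colocalization** — Hamming-window scanning for the
  conserved 54-bp REP tail on both strands, nearest-flanking-family ranking,
  and the fraction of REP copies colocalized with LRR repeat units.
* **Synthetic data** — a fully parameterized generator
  (`synthetic_spec()` / `generate_bundle()`) that emits multi-species
  annotated genomes with known ground truth for every quantity above, so the
  whole pipeline is testable without downloads.

## Worked example

```r
library(lrrscape)

b <- make_fixture("toy")               # 2 species, ~46 genes, deterministic
g <- b$genes$thermophila[["tth_g30001"]]
g
#> <gene_model> tth_g30001 (thermophila) tth_chr2:-, 12 exon(s), CDS 1002 bp

intron_phases(g)
#>  [1] 2 2 2 2 2 2 2 2 2 2 2

find_exact_length_arrays(g)
#>   start_exon run_length
#> 1          2         10

repeat_unit_lengths(g)
#>  [1] 343 348 358 348 349 344 348 344 355 352

length_histogram(unlist(lapply(b$genes$thermophila, exon_lengths)))
#> <length_histogram> n=183, primary peak 90
```

Every intron of this array gene is phase 2, its ten internal exons are
exactly 90 bp, and its repeat units are ~347 bp (90-bp exon plus a ~257-bp
intron) — the signature this package is built to detect and quantify. The
full pipeline runs the same way:

```r
cfg <- run_config(bundle_dir = b$dir, out_dir = "toy_run",
                  focal_species = "thermophila",
                  bin_width = 5e4, peri_half_width = 5e4, subtel_len = 5e4)
run_pipeline("all", cfg)    # architecture -> classify -> profiles ->
                            # orthologs -> landscape -> te -> report.json
```

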