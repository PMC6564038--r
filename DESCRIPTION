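Package: lrrscape
Title: Architecture, Age Grouping and Chromosomal Landscape of Ciliate
    Leucine-Rich-Repeat Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting rapidly evolving leucine-rich-repeat (LRR)
    gene families in ciliate genomes: intron-phase and exon-length landscapes,
    detection of exact-90-bp exon arrays and their phase-2 intron bias,
    classification of LRR genes into three age groups from repeat masking,
    naturally aligned 90-bp exon matrices with position profiles, consensus
    calls and two-sample binomial logo comparisons, near-identity exon
    clustering, ortholog category and tandem-duplication statistics,
    germline-chromosome binning with IES-aware coordinates, and non-LTR
    retrotransposon colocalization. Includes a synthetic annotated-genome
    generator that reproduces the statistical structure the analyses assume,
    so every stage can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
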