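#' Species profile for the synthetic genome generator
#'
#' Describes one simulated species: how many background and LRR genes of
#' each age group it carries, its intron-length distributions, and the
#' parameters of the 90-bp exon model. The defaults emulate the
#' *T. thermophila*-like focal species: background introns around 56 bp,
#' group III array introns around a species-characteristic primary mode
#' (257 bp) with an optional sharp secondary mode (122 bp) carried by a
#' subset of genes attributed to one repeat family, array sizes around 10
#' exons, a 0.99 probability that introns preceding 90-bp exons are phase 2,
#' and leucine-template codons centered at exon nucleotide positions 36, 48,
#' 66, 75, 81 and 87 retained with high probability (group III more
#' faithfully than group II, creating the conservation gradient).
#'
#' @param name Species name.
#' @param abbrev Short tag used in gene/scaffold ids.
#' @param n_background,n_group1,n_group2,n_group3 Gene counts.
#' @param background_intron_mean,background_intron_sd Discretized normal for
#'   background/group I/II intron lengths (bp).
#' @param group3_intron_primary,group3_intron_sd Primary group III intron
#'   mode (bp) and spread.
#' @param group3_intron_secondary,group3_secondary_weight Secondary intron
#'   mode and the per-gene probability of belonging to the secondary
#'   (most recently expanded, family `CRS1`) subset; `NA`/0 disables it.
#' @param exon_count_mean,exon_count_min,exon_count_max Truncated Poisson for
#'   the number of 90-bp exons per array gene.
#' @param phase2_prob Probability that a gene's array introns are phase 2.
#' @param leucine_centers Exon nucleotide positions (1-based) of the six
#'   conserved leucine codon centers.
#' @param leucine_retention_g3,leucine_retention_g2 Per-position probability
#'   that the template leucine codon is retained.
#' @param sub_rate_g3,sub_rate_g2 Per-site background substitution
#'   probability applied to array exons (group III < group II).
#' @param specific_fraction Named fractions of species-specific genes per
#'   class (`bg`, `g1`, `g2`, `g3`).
#' @param n_crs Number of repeat families (`CRS1..CRSn`) masking group III.
#' @param n_rep Number of REP retrotransposon copies to plant.
#' @param ies_in_intron_prob Probability a group III gene carries an IES
#'   within one of its introns.
#' @return List of class `species_profile`.
#' @export
species_profile <- function(name = "thermophila", abbrev = "tth",
                            n_background = 500L, n_group1 = 150L,
                            n_group2 = 200L, n_group3 = 400L,
                            background_intron_mean = 56, background_intron_sd = 8,
                            group3_intron_primary = 257, group3_intron_sd = 5,
                            group3_intron_secondary = 122,
                            group3_secondary_weight = 0.1,
                            exon_count_mean = 10, exon_count_min = 3L,
                            exon_count_max = 15L,
                            phase2_prob = 0.99,
                            leucine_centers = c(36L, 48L, 66L, 75L, 81L, 87L),
                            leucine_retention_g3 = 0.95,
                            leucine_retention_g2 = 0.85,
                            sub_rate_g3 = 0.01, sub_rate_g2 = 0.05,
                            specific_fraction = c(bg = 0.2, g1 = 0.12,
                                                  g2 = 0.35, g3 = 0.8),
                            n_crs = 8L, n_rep = 0L,
                            ies_in_intron_prob = 0.1) {
  p <- as.list(environment())
  probs <- c(p$group3_secondary_weight, p$phase2_prob, p$leucine_retention_g3,
             p$leucine_retention_g2, p$sub_rate_g3, p$sub_rate_g2,
             p$specific_fraction, p$ies_in_intron_prob)
  if (any(is.na(probs) | probs < 0 | probs > 1))
    stop("species_profile: probabilities must lie in [0, 1]")
  if (any(c(p$n_background, p$n_group1, p$n_group2, p$n_group3) < 0))
    stop("species_profile: counts must be non-negative")
  structure(p, class = "species_profile")
}

#' Chromosome layout for the synthetic generator
#'
#' @param n_chrom Number of germline chromosomes.
#' @param chrom_length Chromosome length (bp, including IESs).
#' @param slot_width Width of the placement grid cells (bp); each gene, REP
#'   element or intergenic IES occupies one cell.
#' @param centromere_halfwidth Half-width of the centromere interval.
#' @param peri_half_width,subtel_len Region definition used for placement
#'   (same meaning as in [region_of()]).
#' @param placement_weights Region sampling weights
#'   (pericentromeric, subtelomeric, arm) for group III genes and REP copies.
#' @param ies_weights Region weights for intergenic IES placement.
#' @param n_ies Intergenic IES count per species.
#' @param ies_len_range Intergenic IES length range (bp).
#' @return List of class `chromosome_layout`.
#' @export
chromosome_layout <- function(n_chrom = 5L, chrom_length = 6e6,
                              slot_width = 1e4, centromere_halfwidth = 5e4,
                              peri_half_width = 1e6, subtel_len = 1e6,
                              placement_weights = c(5, 5, 1),
                              ies_weights = c(4, 4, 1),
                              n_ies = 300L, ies_len_range = c(500L, 3000L)) {
  structure(as.list(environment()), class = "chromosome_layout")
}

#' REP retrotransposon model
#'
#' @param orf1_codons,orf2_codons ORF lengths (codons) of the two open
#'   reading frames of a functional copy.
#' @param spacer Spacer between ORF2 and the 54-bp tail (bp).
#' @param adjacency_prob Probability that a copy is planted adjacent to a
#'   group III LRR gene (edge gap drawn from `gap_range`).
#' @param functional_fraction Fraction of copies with both ORFs intact.
#' @param tail_mismatch_max Maximum mismatches planted into each copy's tail.
#' @param gap_range Edge distance range between gene and adjacent copy (bp).
#' @return List of class `rep_model`.
#' @export
rep_model <- function(orf1_codons = 200L, orf2_codons = 400L, spacer = 50L,
                      adjacency_prob = 0.8, functional_fraction = 0.5,
                      tail_mismatch_max = 2L, gap_range = c(100L, 800L)) {
  if (adjacency_prob < 0 || adjacency_prob > 1)
    stop("adjacency_prob must lie in [0, 1]")
  structure(as.list(environment()), class = "rep_model")
}

#' Full synthetic genome specification
#'
#' @param species List of [species_profile()]s; gene counts must be identical
#'   across species (ortholog clusters are built by pairing the k-th
#'   conserved gene of each species).
#' @param layout A [chromosome_layout()].
#' @param rep A [rep_model()].
#' @param expansion_size Inparalog count of the focal species in the single
#'   significantly expanded cluster (0 disables it).
#' @param tandem_strict_run,tandem_relaxed_extra Size of the strict tandem
#'   run carved out of the expanded cluster and the number of additional
#'   members appended with one intervening background gene each.
#' @param partial_spans Integer vector; for each k a background ortholog
#'   cluster spanning species 1..k is created (exercises intermediate
#'   ortholog categories).
#' @param specific_cluster_size Size of species-specific inparalog clusters.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(species = list(
                             species_profile("thermophila", "tth", n_rep = 400L),
                             species_profile("malaccensis", "tma",
                                             group3_intron_primary = 232,
                                             group3_intron_secondary = NA,
                                             group3_secondary_weight = 0),
                             species_profile("elliotti", "tel",
                                             group3_intron_primary = 200,
                                             group3_intron_secondary = NA,
                                             group3_secondary_weight = 0)),
                           layout = chromosome_layout(),
                           rep = rep_model(),
                           expansion_size = 61L,
                           tandem_strict_run = 17L,
                           tandem_relaxed_extra = 20L,
                           partial_spans = integer(0),
                           specific_cluster_size = 5L) {
  counts <- vapply(species, function(p) c(p$n_background, p$n_group1,
                                          p$n_group2, p$n_group3), numeric(4))
  if (length(species) > 1L && any(apply(counts, 1L, function(x) length(unique(x)) != 1L)))
    stop("gene counts must be identical across species profiles")
  structure(as.list(environment()), class = "synthetic_spec")
}

## ---- sequence building blocks -------------------------------------------

REP_TAIL_54 <- "ATTAGCTTAAGGTTCAATTCGAAGTTACCATAGGTTCGATTAACGGATTAGCTT"

ALL_CODONS <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                    paste0), c("T", "C", "A", "G"), paste0))
# non-stop (ciliate: only TGA), non-leucine codons with AT-rich weights
ALLOWED_CODONS <- setdiff(ALL_CODONS, c("TGA", LEUCINE_CODONS))
codon_at_weight <- function(codon, p_at = 0.35, p_gc = 0.15) {
  base <- strsplit(codon, "")[[1]]
  prod(ifelse(base %in% c("A", "T"), p_at, p_gc))
}
ALLOWED_WEIGHTS <- vapply(ALLOWED_CODONS, codon_at_weight, numeric(1))

sample_codons <- function(n) {
  if (n <= 0L) return(character(0))
  ALLOWED_CODONS[sample.int(length(ALLOWED_CODONS), n, replace = TRUE,
                            prob = ALLOWED_WEIGHTS)]
}

make_intron <- function(len) {
  len <- max(10L, as.integer(len))
  paste0("GT", random_dna(len - 4L, prob = c(0.375, 0.125, 0.125, 0.375)), "AG")
}

# 29-codon template with TTA at the conserved centers; exon = "A" + codons + "TT"
make_template90 <- function(centers = c(36L, 48L, 66L, 75L, 81L, 87L)) {
  idx <- (centers - 2L) %/% 3L + 1L
  codons <- sample_codons(29L)
  codons[idx] <- "TTA"
  list(codons = codons, leu_idx = idx)
}

mutate_template <- function(tpl, n_changes) {
  free <- setdiff(seq_len(29L), tpl$leu_idx)
  pick <- sample(free, min(n_changes, length(free)))
  tpl$codons[pick] <- sample_codons(length(pick))
  tpl
}

# instantiate one 90-bp exon from a template: leucine retention, then
# per-site noise on nt 2..88 (codon-wise, never creating a TGA stop)
make_exon90 <- function(tpl, sub_rate, leu_retention) {
  codons <- tpl$codons
  lost <- tpl$leu_idx[runif(length(tpl$leu_idx)) > leu_retention]
  if (length(lost)) codons[lost] <- sample_codons(length(lost))
  if (sub_rate > 0) {
    nts <- strsplit(paste(codons, collapse = ""), "")[[1]]
    hit <- which(runif(87L) < sub_rate)
    if (length(hit)) {
      bases <- c("A", "C", "G", "T")
      for (i in hit) nts[i] <- sample(setdiff(bases, nts[i]), 1L)
      mutated <- split_codons(paste(nts, collapse = ""))
      mutated[mutated == "TGA"] <- codons[mutated == "TGA"]
      codons <- mutated
    }
  }
  paste0("A", paste(codons, collapse = ""), "TT")
}

## ---- gene builders -------------------------------------------------------

# gene body = exon/intron sequence on the coding strand, with exon intervals
# relative to the body start (transcription order)
assemble_body <- function(exon_seqs, intron_seqs) {
  n <- length(exon_seqs)
  pieces <- character(2L * n - 1L)
  rel <- matrix(0L, n, 2L, dimnames = list(NULL, c("start", "end")))
  cur <- 0L
  for (i in seq_len(n)) {
    pieces[2L * i - 1L] <- exon_seqs[i]
    rel[i, ] <- c(cur, cur + nchar(exon_seqs[i]))
    cur <- cur + nchar(exon_seqs[i])
    if (i < n) {
      pieces[2L * i] <- intron_seqs[i]
      cur <- cur + nchar(intron_seqs[i])
    }
  }
  list(seq = paste(pieces, collapse = ""), rel = rel)
}

truncated_poisson <- function(lambda, lo, hi) {
  repeat {
    x <- rpois(1L, lambda)
    if (x >= lo && x <= hi) return(x)
  }
}

group3_intron_len <- function(profile, secondary) {
  mu <- if (secondary) profile$group3_intron_secondary else profile$group3_intron_primary
  max(10L, as.integer(round(rnorm(1L, mu, profile$group3_intron_sd))))
}

#' Build one group II/III-style 90-bp exon array gene
#'
#' Constructs a lead exon, `n` exactly-90-bp exons instantiated from the
#' species/group template, GT..AG introns drawn from the profile's length
#' model, and a tail exon ending in TGA, with total CDS length divisible
#' by 3. With probability `phase2_prob` the lead exon length is congruent to
#' 2 mod 3 so that every intron preceding an array exon is phase 2 (and each
#' exon's first/last junction nucleotides stitch leucine junction codons);
#' otherwise the gene is built in a shifted frame with template-free exon
#' content.
#'
#' @param profile A [species_profile()].
#' @param template Template from the generator (list with `codons`,
#'   `leu_idx`); a fresh one is drawn when `NULL`.
#' @param group `"III"` (default) or `"II"` (uses the group II retention and
#'   substitution rate, background intron lengths).
#' @param secondary Logical: use the secondary intron mode (group III only).
#' @param n_exons Number of array exons; drawn from the profile when `NULL`.
#' @return List with `gene` (a [gene_model()] on scaffold `"unplaced"`),
#'   `sequence` (the gene body), `rel` (exon intervals relative to the body)
#'   and `phase2` (logical).
#' @export
make_group3_gene <- function(profile, template = NULL, group = "III",
                             secondary = FALSE, n_exons = NULL) {
  if (is.null(template)) template <- make_template90(profile$leucine_centers)
  if (is.null(n_exons))
    n_exons <- truncated_poisson(profile$exon_count_mean,
                                 profile$exon_count_min, profile$exon_count_max)
  retention <- if (group == "III") profile$leucine_retention_g3 else profile$leucine_retention_g2
  sub_rate <- if (group == "III") profile$sub_rate_g3 else profile$sub_rate_g2
  intron_len <- function() {
    if (group == "III") group3_intron_len(profile, secondary)
    else max(10L, as.integer(round(rnorm(1L, profile$background_intron_mean,
                                         profile$background_intron_sd))))
  }
  phase2 <- runif(1L) < profile$phase2_prob
  if (phase2) {
    k0 <- sample(10:19, 1L)
    lead <- paste0("ATG", paste(sample_codons(k0 - 1L), collapse = ""), "TT")
    exons <- vapply(seq_len(n_exons), function(i)
      make_exon90(template, sub_rate, retention), character(1))
    kt <- sample(5:20, 1L)
    tail_exon <- paste0("A", paste(sample_codons(kt), collapse = ""), "TGA")
    exon_seqs <- c(lead, exons, tail_exon)
  } else {
    lead_len <- {
      l <- sample(30:60, 1L)
      l - (l %% 3L) + sample(0:1, 1L)  # lead length != 2 (mod 3)
    }
    tail_len <- {
      t0 <- sample(30:60, 1L)
      t0 + ((3L - ((lead_len + t0) %% 3L)) %% 3L)
    }
    total <- lead_len + 90L * n_exons + tail_len
    cds <- paste0("ATG", paste(sample_codons(total %/% 3L - 2L), collapse = ""), "TGA")
    bounds <- cumsum(c(lead_len, rep(90L, n_exons), tail_len))
    starts <- c(1L, head(bounds, -1L) + 1L)
    exon_seqs <- substring(cds, starts, bounds)
  }
  intron_seqs <- vapply(seq_len(length(exon_seqs) - 1L),
                        function(i) make_intron(intron_len()), character(1))
  body <- assemble_body(exon_seqs, intron_seqs)
  gene <- gene_model("synthetic", profile$name, "unplaced", "+", body$rel)
  list(gene = gene, sequence = body$seq, rel = body$rel, phase2 = phase2)
}

# multi-exon gene with arbitrary exon lengths (background / group I)
make_plain_gene <- function(profile, exclude_len = integer(0)) {
  k <- sample(2:8, 1L)
  lens <- sample(40:200, k, replace = TRUE)
  adj <- (3L - sum(lens) %% 3L) %% 3L
  lens[1L] <- lens[1L] + adj
  while (any(lens %in% exclude_len)) {
    lens[lens %in% exclude_len] <- lens[lens %in% exclude_len] + 3L
  }
  total <- sum(lens)
  cds <- paste0("ATG", paste(sample_codons(total %/% 3L - 2L), collapse = ""), "TGA")
  bounds <- cumsum(lens)
  exon_seqs <- substring(cds, c(1L, head(bounds, -1L) + 1L), bounds)
  intron_seqs <- vapply(seq_len(k - 1L), function(i) {
    make_intron(round(rnorm(1L, profile$background_intron_mean,
                            profile$background_intron_sd)))
  }, character(1))
  assemble_body(exon_seqs, intron_seqs)
}

make_rep_copy <- function(rep, functional) {
  orf <- function(n_codons) {
    paste0("ATG", paste(sample_codons(n_codons - 2L), collapse = ""), "TGA")
  }
  body <- if (functional) {
    paste0(orf(rep$orf1_codons), orf(rep$orf2_codons))
  } else {
    random_dna(3L * (rep$orf1_codons + rep$orf2_codons))
  }
  tail <- strsplit(REP_TAIL_54, "")[[1]]
  n_mm <- sample(0:rep$tail_mismatch_max, 1L)
  if (n_mm > 0L) {
    at <- sample(54L, n_mm)
    for (i in at) tail[i] <- sample(setdiff(c("A", "C", "G", "T"), tail[i]), 1L)
  }
  seq <- paste0(body, random_dna(rep$spacer), paste(tail, collapse = ""))
  list(seq = seq, tail_offset = nchar(seq) - 54L, tail_mismatches = n_mm)
}
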