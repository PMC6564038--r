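#' Identify LRR genes from a domain annotation table
#'
#' A gene is called LRR if any of its domain annotations matches one of the
#' supplied labels: accession-like labels (no whitespace, ending in digits,
#' e.g. `PF13855`, `IPR001611`) must match exactly (case-insensitive), other
#' labels match as case-insensitive substrings of the domain name.
#'
#' @param domain_table `data.frame` with columns `gene_id`, `domain`.
#' @param lrr_labels Character vector of domain names/accessions to match.
#' @return Character vector of LRR gene ids.
#' @export
identify_lrr_genes <- function(domain_table,
                               lrr_labels = c("Leucine-rich repeat", "LRR")) {
  if (!nrow(domain_table)) {
    warning("empty domain table: no LRR genes identified")
    return(character(0))
  }
  dom <- tolower(domain_table$domain)
  hit <- rep(FALSE, nrow(domain_table))
  for (lab in lrr_labels) {
    is_accession <- !grepl("\\s", lab) && grepl("[0-9]$", lab)
    hit <- hit | if (is_accession) dom == tolower(lab) else
      grepl(tolower(lab), dom, fixed = TRUE)
  }
  sort(unique(domain_table$gene_id[hit]))
}

# per-family masked bp over [start, end): union of the family's hits
# intersected with the span
masked_bp_by_family <- function(span_start, span_end, scaffold, mask_hits) {
  h <- mask_hits[mask_hits$scaffold == scaffold &
                   mask_hits$end > span_start & mask_hits$start < span_end, ,
                 drop = FALSE]
  if (!nrow(h)) return(list(bp = numeric(0), score = numeric(0)))
  span <- IRanges::IRanges(span_start + 1L, span_end)
  fams <- sort(unique(h$family))
  bp <- vapply(fams, function(f) {
    r <- IRanges::reduce(IRanges::IRanges(h$start[h$family == f] + 1L,
                                          h$end[h$family == f]))
    sum(IRanges::width(IRanges::intersect(r, span)))
  }, numeric(1))
  score <- vapply(fams, function(f) sum(h$score[h$family == f]), numeric(1))
  list(bp = bp, score = score)
}

#' Classify LRR genes into three age groups
#'
#' Sorts LRR genes by presence of exactly-`target_len` exons and by repeat
#' masking: group I = no target-length exon and not masked; group II =
#' target-length exon(s), not masked; group III = target-length exon(s) and
#' masked. A gene is "masked" when the union of any single repeat family's
#' hits covers at least `min_masked_bp` of its CDS+intron span. Masked genes
#' without target-length exons fall outside the three-group scheme and are
#' reported as `unclassified`.
#'
#' @param lrr_genes List of [gene_model()] objects (LRR genes only).
#' @param mask_hits Mask table from [read_mask_table()], restricted to the
#'   repeat families of interest.
#' @param target_len Array exon length.
#' @param min_masked_bp Minimum single-family masked bp to call a gene masked.
#' @return `data.frame` with columns `gene_id`, `group` (`I`,`II`,`III`,
#'   `unclassified`), `best_family` (group III only), `masked_bp`,
#'   `best_family_score`.
#' @export
classify_groups <- function(lrr_genes, mask_hits, target_len = 90L,
                            min_masked_bp = 50L) {
  rows <- lapply(lrr_genes, function(g) {
    sp <- gene_span(g)
    m <- masked_bp_by_family(sp["start"], sp["end"], g$scaffold, mask_hits)
    masked <- length(m$bp) > 0 && max(m$bp) >= min_masked_bp
    has_target <- any(exon_lengths(g) == target_len)
    group <- if (has_target && masked) "III"
      else if (has_target) "II"
      else if (!masked) "I" else "unclassified"
    best <- NA_character_; best_score <- NA_real_
    if (group == "III") {
      b <- best_family_of(m)
      best <- b$family; best_score <- b$score
    }
    data.frame(gene_id = g$gene_id, group = group, best_family = best,
               masked_bp = if (length(m$bp)) max(m$bp) else 0,
               best_family_score = best_score, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

best_family_of <- function(m, families = names(m$score)) {
  fams <- families
  ord <- order(-m$score[fams], -m$bp[fams], fams)
  f <- fams[ord[1L]]
  list(family = f, score = unname(m$score[f]))
}

#' Assign the best repeat family to a masked gene
#'
#' The best family is the one with the largest sum of overlapping hit scores
#' over the gene span; ties go to the family with more masked bp, then to the
#' lexicographically smallest family id. Mirrors the exclusive
#' highest-masking-score assignment of group III genes to repeat subgroups.
#'
#' @param gene A [gene_model()].
#' @param mask_hits Mask table.
#' @return Family id (character scalar); error if no hit overlaps the gene.
#' @export
assign_best_family <- function(gene, mask_hits) {
  sp <- gene_span(gene)
  m <- masked_bp_by_family(sp["start"], sp["end"], gene$scaffold, mask_hits)
  if (!length(m$score)) stop("gene ", gene$gene_id, ": no overlapping mask hits")
  best_family_of(m)$family
}

#' Per-group summaries and pairwise composition tests
#'
#' For each group: gene count, species-specific fraction, exon/intron length
#' histograms, intron-count histogram, GC content distribution and leucine
#' codon usage; plus a chi-squared test of the species-specific/conserved
#' split for every pair of groups.
#'
#' @param assignments Output of [classify_groups()].
#' @param genes Named list of [gene_model()] objects.
#' @param genome Genome from [read_fasta()] (for GC/codon usage; optional).
#' @param species_specific Character vector of species-specific gene ids.
#' @return List with `table` (per-group `data.frame`), `histograms` (per-group
#'   list of [length_histogram()]s), `pairwise_tests` (`data.frame` of
#'   chi-squared results).
#' @export
group_summary <- function(assignments, genes, genome = NULL,
                          species_specific = character(0)) {
  groups <- c("I", "II", "III")
  per <- lapply(groups, function(gr) {
    ids <- assignments$gene_id[assignments$group == gr]
    gs <- genes[ids]
    n <- length(gs)
    spec <- sum(ids %in% species_specific)
    hist <- list(exon = NULL, intron = NULL, introns_per_gene = NULL)
    gc <- numeric(0); leu <- NULL
    if (n > 0) {
      ex <- unlist(lapply(gs, exon_lengths))
      intr <- unlist(lapply(gs, intron_lengths))
      hist$exon <- length_histogram(ex)
      if (length(intr)) hist$intron <- length_histogram(intr)
      hist$introns_per_gene <- table(vapply(gs, function(g) nrow(g$exons) - 1L, integer(1)))
      if (!is.null(genome)) {
        gc <- vapply(gs, function(g) gc_content(cds_sequence(g, genome)), numeric(1))
        leu <- leucine_codon_usage(gs, genome)
      }
    }
    list(group = gr, n = n, n_specific = spec,
         specific_fraction = if (n > 0) spec / n else NA_real_,
         histograms = hist, gc = gc, leucine_usage = leu)
  })
  names(per) <- groups
  tab <- data.frame(group = groups,
                    n = vapply(per, `[[`, numeric(1), "n"),
                    n_specific = vapply(per, `[[`, numeric(1), "n_specific"),
                    specific_fraction = vapply(per, `[[`, numeric(1), "specific_fraction"),
                    row.names = NULL)
  pairs <- utils::combn(groups, 2L)
  tests <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- per[[pairs[1L, i]]]; b <- per[[pairs[2L, i]]]
    if (a$n == 0 || b$n == 0)
      return(data.frame(group_a = a$group, group_b = b$group, p = NA_real_,
                        significant = NA))
    m <- rbind(c(a$n_specific, a$n - a$n_specific),
               c(b$n_specific, b$n - b$n_specific))
    p <- suppressWarnings(chisq.test(m)$p.value)
    data.frame(group_a = a$group, group_b = b$group, p = p,
               significant = is.finite(p) && p < 1e-5)
  })
  list(table = tab,
       histograms = lapply(per, `[[`, "histograms"),
       gc = lapply(per, `[[`, "gc"),
       leucine_usage = lapply(per, `[[`, "leucine_usage"),
       pairwise_tests = do.call(rbind, c(tests, list(make.row.names = FALSE))))
}
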