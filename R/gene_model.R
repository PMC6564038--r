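#' Gene model container
#'
#' A `gene_model` holds one gene's stranded, ordered CDS exon structure on a
#' scaffold. Exon intervals are stored in internal 0-based half-open scaffold
#' coordinates, listed in transcription (5'->3') order; for minus-strand genes
#' that means decreasing scaffold position. "Exon" throughout this package
#' means CDS segment: intron phases and translation are defined only on coding
#' sequence, and UTR structure is never used.
#'
#' @param gene_id Gene identifier.
#' @param species Species label.
#' @param scaffold Scaffold/chromosome identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons Integer matrix with columns `start`, `end` (0-based half-open),
#'   rows in transcription order.
#' @param domains Character vector of domain annotations (may be empty).
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(gene_id, species, scaffold, strand, exons, domains = character(0)) {
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1L) stop("gene ", gene_id, ": needs at least one exon")
  if (any(exons[, "end"] <= exons[, "start"]))
    stop("gene ", gene_id, ": empty or inverted exon interval")
  if (!strand %in% c("+", "-")) stop("gene ", gene_id, ": bad strand")
  # transcription order: ascending starts on +, descending on -
  ord <- if (strand == "+") order(exons[, "start"]) else order(-exons[, "start"])
  exons <- exons[ord, , drop = FALSE]
  if (nrow(exons) > 1L) {
    genomic <- exons[order(exons[, "start"]), , drop = FALSE]
    if (any(genomic[-1L, "start"] < genomic[-nrow(genomic), "end"]))
      stop("gene ", gene_id, ": overlapping exons")
  }
  if (sum(exons[, "end"] - exons[, "start"]) %% 3L != 0L)
    stop("gene ", gene_id, ": CDS length not divisible by 3")
  structure(list(gene_id = gene_id, species = species, scaffold = scaffold,
                 strand = strand, exons = exons, domains = as.character(domains)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%s, %d exon(s), CDS %d bp\n",
              x$gene_id, x$species, x$scaffold, x$strand,
              nrow(x$exons), sum(exon_lengths(x))))
  invisible(x)
}

#' Exon and intron lengths of a gene model
#'
#' Lengths are reported in transcription order. Intron lengths are genomic
#' gaps between consecutive exons (identical on either strand).
#'
#' @param gene A [gene_model()].
#' @return Integer vector.
#' @export
exon_lengths <- function(gene) {
  as.integer(gene$exons[, "end"] - gene$exons[, "start"])
}

#' @rdname exon_lengths
#' @export
intron_lengths <- function(gene) {
  n <- nrow(gene$exons)
  if (n < 2L) return(integer(0))
  if (gene$strand == "+") {
    as.integer(gene$exons[-1L, "start"] - gene$exons[-n, "end"])
  } else {
    as.integer(gene$exons[-n, "start"] - gene$exons[-1L, "end"])
  }
}

#' Genomic span of a gene model
#'
#' The `[start, end)` interval covered by the gene's CDS and introns.
#'
#' @param gene A [gene_model()].
#' @return Named integer vector `c(start =, end =)`.
#' @export
gene_span <- function(gene) {
  c(start = min(gene$exons[, "start"]), end = max(gene$exons[, "end"]))
}

#' Extract coding-strand exon sequences
#'
#' @param gene A [gene_model()].
#' @param genome A genome as returned by [read_fasta()] (named character
#'   vector of scaffold sequences).
#' @return Character vector of exon sequences, transcription order, coding
#'   strand.
#' @export
exon_sequences <- function(gene, genome) {
  if (!gene$scaffold %in% names(genome))
    stop("scaffold ", gene$scaffold, " absent from genome")
  seq <- genome[[gene$scaffold]]
  out <- substring(seq, gene$exons[, "start"] + 1L, gene$exons[, "end"])
  if (gene$strand == "-") out <- reverse_complement(out)
  out
}

#' @rdname exon_sequences
#' @export
cds_sequence <- function(gene, genome) {
  paste(exon_sequences(gene, genome), collapse = "")
}
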