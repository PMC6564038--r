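#' Read a genome FASTA
#'
#' Sequences are uppercased, `U` is mapped to `T`, and any residual
#' non-ACGTN character is mapped to `N` (the number of substitutions is
#' reported via a message). Duplicate scaffold ids and empty records are
#' errors.
#'
#' @param path FASTA file.
#' @param species Optional species label attached as an attribute.
#' @return Named character vector of scaffold sequences with attribute
#'   `species`.
#' @export
read_fasta <- function(path, species = NA_character_) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate scaffold id: ", ids[duplicated(ids)][1L])
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L))
    stop("empty FASTA record: ", ids[nchar(seqs) == 0L][1L])
  seqs <- chartr("U", "T", seqs)
  bad <- sum(vapply(seqs, function(s) {
    sum(!strsplit(s, "")[[1]] %in% c("A", "C", "G", "T", "N"))
  }, integer(1)))
  if (bad > 0L) {
    message("read_fasta: ", bad, " non-ACGTN character(s) replaced by N")
    seqs <- vapply(seqs, function(s) {
      ch <- strsplit(s, "")[[1]]
      ch[!ch %in% c("A", "C", "G", "T", "N")] <- "N"
      paste(ch, collapse = "")
    }, character(1))
  }
  structure(setNames(seqs, ids), species = species)
}

#' Write a genome FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output file.
#' @param width Line wrap width.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (id in names(genome)) {
    writeLines(paste0(">", id), con)
    s <- genome[[id]]
    n <- nchar(s)
    writeLines(substring(s, seq(1L, n, width), pmin(seq(width, n + width - 1L, width), n)), con)
  }
  invisible(path)
}

parse_gff3_attr <- function(attr, key) {
  pat <- paste0("(^|;)", key, "=[^;]*")
  m <- regexpr(pat, attr)
  res <- rep(NA_character_, length(attr))
  hit <- m > 0L
  res[hit] <- sub(paste0("^;?", key, "="), "", regmatches(attr, m))
  res
}

#' Read gene models from GFF3
#'
#' Parses `gene`/`mRNA`/`CDS` features. GFF3 coordinates (1-based inclusive)
#' are converted to internal 0-based half-open coordinates at this boundary.
#' When a gene has several mRNAs, the transcript with the longest total CDS is
#' kept (ties broken by lexicographically smallest transcript id).
#' Minus-strand exon lists are stored in transcription order. Genes whose CDS
#' length is not divisible by 3 are excluded with a warning; a CDS outside
#' scaffold bounds is an error.
#'
#' @param path GFF3 file (`##gff-version 3` header required).
#' @param genome Optional genome from [read_fasta()], used for bounds checks
#'   and to fill the species label.
#' @param species Species label for the models.
#' @return List of [gene_model()] objects, named by gene id.
#' @export
read_gff3 <- function(path, genome = NULL, species = NA_character_) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^##gff-version\\s+3", lines[1L]))
    stop("not a GFF3 file (missing ##gff-version 3 header): ", path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) return(list())
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 9L)) stop("malformed GFF3 row in ", path)
  f <- do.call(rbind, f)
  type <- f[, 3L]
  attr <- f[, 9L]
  if (is.na(species) && !is.null(genome)) species <- attr(genome, "species", exact = TRUE)

  mrna <- which(type == "mRNA")
  cds <- which(type == "CDS")
  mrna_id <- parse_gff3_attr(attr[mrna], "ID")
  mrna_parent <- parse_gff3_attr(attr[mrna], "Parent")
  cds_parent <- parse_gff3_attr(attr[cds], "Parent")
  if (anyNA(mrna_id) || anyNA(mrna_parent) || anyNA(cds_parent))
    stop("GFF3 mRNA/CDS feature lacking ID/Parent attribute")

  cds_df <- data.frame(tx = cds_parent,
                       scaffold = f[cds, 1L],
                       start = as.integer(f[cds, 4L]) - 1L,  # -> 0-based half-open
                       end = as.integer(f[cds, 5L]),
                       strand = f[cds, 7L],
                       stringsAsFactors = FALSE)
  gene_of_tx <- setNames(mrna_parent, mrna_id)
  # CDS rows attached directly to a gene (no mRNA level) are allowed
  orphan <- !(cds_df$tx %in% mrna_id)
  gene_of_tx <- c(gene_of_tx, setNames(cds_df$tx[orphan], cds_df$tx[orphan]))

  models <- list()
  skipped <- character(0)
  for (g in unique(gene_of_tx[cds_df$tx])) {
    txs <- names(gene_of_tx)[gene_of_tx == g]
    txs <- intersect(txs, cds_df$tx)
    tot <- vapply(txs, function(t) {
      r <- cds_df[cds_df$tx == t, ]
      sum(r$end - r$start)
    }, numeric(1))
    best <- txs[order(-tot, txs)][1L]
    r <- cds_df[cds_df$tx == best, ]
    if (!is.null(genome)) {
      if (!r$scaffold[1L] %in% names(genome))
        stop("scaffold ", r$scaffold[1L], " absent from genome")
      L <- nchar(genome[[r$scaffold[1L]]])
      if (any(r$start < 0L) || any(r$end > L))
        stop("gene ", g, ": CDS outside scaffold bounds")
    }
    if (sum(r$end - r$start) %% 3L != 0L) {
      skipped <- c(skipped, g)
      next
    }
    models[[g]] <- gene_model(g, species, r$scaffold[1L], r$strand[1L],
                              cbind(r$start, r$end))
  }
  if (length(skipped))
    warning("excluded ", length(skipped),
            " gene(s) with CDS length not divisible by 3: ",
            paste(head(skipped, 5L), collapse = ", "))
  if (!length(models)) return(models)
  models[order(names(models))]
}

#' Write gene models as GFF3
#'
#' Emits `gene`, `mRNA` and `CDS` rows with deterministic ordering
#' (genes sorted by scaffold then start then id). Internal 0-based half-open
#' coordinates are converted back to GFF3's 1-based inclusive convention, so
#' [read_gff3()] of the output reproduces the input models.
#'
#' @param genes List of [gene_model()] objects.
#' @param path Output file.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  key <- vapply(genes, function(g) {
    sprintf("%s|%012d|%s", g$scaffold, min(g$exons[, "start"]), g$gene_id)
  }, character(1))
  for (g in genes[order(key)]) {
    sp <- gene_span(g)
    rows <- c(
      sprintf("%s\tlrrscape\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$scaffold, sp["start"] + 1L, sp["end"], g$strand, g$gene_id),
      sprintf("%s\tlrrscape\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              g$scaffold, sp["start"] + 1L, sp["end"], g$strand, g$gene_id, g$gene_id))
    ex <- g$exons[order(g$exons[, "start"]), , drop = FALSE]
    rows <- c(rows, sprintf("%s\tlrrscape\tCDS\t%d\t%d\t.\t%s\t.\tID=%s.cds;Parent=%s.t1",
                            g$scaffold, ex[, "start"] + 1L, ex[, "end"],
                            g$strand, g$gene_id, g$gene_id))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read repeat-mask hits
#'
#' Normalizes hits to internal 0-based half-open coordinates. Two dialects
#' are supported: BED6 with the family id in column 4 and the alignment score
#' in column 5 (already 0-based half-open), and RepeatMasker `.out`
#' (1-based inclusive begin/end, Smith-Waterman score in column 1).
#'
#' @param path Input file.
#' @param dialect `"bed6+family"` or `"repeatmasker_out"`.
#' @return `data.frame` with columns `scaffold`, `start`, `end`, `family`,
#'   `score`.
#' @export
read_mask_table <- function(path, dialect = c("bed6+family", "repeatmasker_out")) {
  dialect <- match.arg(dialect)
  empty <- data.frame(scaffold = character(0), start = integer(0), end = integer(0),
                      family = character(0), score = numeric(0), stringsAsFactors = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (dialect == "bed6+family") {
    if (!length(lines)) return(empty)
    f <- do.call(rbind, strsplit(lines, "\\s+"))
    hits <- data.frame(scaffold = f[, 1L], start = as.integer(f[, 2L]),
                       end = as.integer(f[, 3L]), family = f[, 4L],
                       score = as.numeric(f[, 5L]), stringsAsFactors = FALSE)
  } else {
    # RepeatMasker .out: 3 header lines, whitespace-separated columns:
    # score div del ins query begin end (left) strand repeat class ...
    lines <- lines[!grepl("^\\s*(SW|score)\\s", lines)]
    if (!length(lines)) return(empty)
    f <- do.call(rbind, strsplit(trimws(lines), "\\s+"))
    hits <- data.frame(scaffold = f[, 5L], start = as.integer(f[, 6L]) - 1L,
                       end = as.integer(f[, 7L]), family = f[, 10L],
                       score = as.numeric(f[, 1L]), stringsAsFactors = FALSE)
  }
  if (any(hits$score < 0)) stop("negative mask score in ", path)
  hits
}

#' Read OrthoMCL-style ortholog clusters
#'
#' Input lines follow the `groups.txt` dialect:
#' `clusterID: speciesA|gene1 speciesB|gene2 ...`. Genes of the universe not
#' assigned to any cluster become singletons.
#'
#' @param path Groups file.
#' @param universe Named list: species -> character vector of all gene ids of
#'   that species.
#' @return Object of class `ortholog_clusters`: list with `clusters` (named
#'   list of named lists species -> gene ids), `universe`, and `singletons`
#'   (named list species -> gene ids in no cluster).
#' @export
read_orthomcl_groups <- function(path, universe) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  clusters <- list()
  seen <- character(0)
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    cid <- sub(":$", "", parts[1L])
    members <- parts[-1L]
    sp <- sub("\\|.*$", "", members)
    gid <- sub("^[^|]*\\|", "", members)
    if (any(!sp %in% names(universe)))
      stop("cluster ", cid, ": unknown species tag ", setdiff(sp, names(universe))[1L])
    dup <- intersect(gid, seen)
    if (length(dup)) stop("gene in two clusters: ", dup[1L])
    seen <- c(seen, gid)
    clusters[[cid]] <- split(gid, factor(sp, levels = unique(sp)))
  }
  singletons <- lapply(names(universe), function(s) {
    setdiff(universe[[s]], seen)
  })
  names(singletons) <- names(universe)
  structure(list(clusters = clusters, universe = universe, singletons = singletons),
            class = "ortholog_clusters")
}

#' @export
print.ortholog_clusters <- function(x, ...) {
  cat(sprintf("<ortholog_clusters> %d cluster(s), %d species, %d singleton(s)\n",
              length(x$clusters), length(x$universe), sum(lengths(x$singletons))))
  invisible(x)
}

#' Read a per-gene value table
#'
#' @param path TSV with columns `gene_id` and `value`.
#' @param kind One of `"ka_ks"`, `"fpkm"`, `"other"`; FPKM values must be
#'   non-negative, all values finite.
#' @return Named numeric vector with attribute `kind`.
#' @export
read_value_table <- function(path, kind = c("other", "ka_ks", "fpkm")) {
  kind <- match.arg(kind)
  df <- read_tsv(path)
  v <- setNames(as.numeric(df$value), df$gene_id)
  if (any(!is.finite(v))) stop("non-finite value in ", path)
  if (kind == "fpkm" && any(v < 0)) stop("negative FPKM in ", path)
  structure(v, kind = kind)
}

#' Chromosome landscape: lengths, centromeres and IES intervals
#'
#' @param lengths Named integer vector: chromosome -> length (bp).
#' @param centromeres `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open), one row per chromosome.
#' @param ies `data.frame` with columns `chrom`, `start`, `end`; intervals are
#'   sorted and must be pairwise disjoint and within bounds.
#' @return Object of class `chromosome_landscape`.
#' @export
chromosome_landscape <- function(lengths, centromeres, ies) {
  ies <- ies[order(ies$chrom, ies$start), , drop = FALSE]
  for (ch in unique(ies$chrom)) {
    z <- ies[ies$chrom == ch, ]
    if (any(z$start < 0L) || any(z$end > lengths[[ch]]))
      stop("IES interval out of bounds on ", ch)
    if (nrow(z) > 1L && any(z$start[-1L] < z$end[-nrow(z)]))
      stop("overlapping IES intervals on ", ch)
  }
  for (i in seq_len(nrow(centromeres))) {
    ch <- centromeres$chrom[i]
    if (centromeres$start[i] < 0L || centromeres$end[i] > lengths[[ch]])
      stop("centromere out of bounds on ", ch)
  }
  structure(list(lengths = lengths, centromeres = centromeres, ies = ies),
            class = "chromosome_landscape")
}

#' @export
print.chromosome_landscape <- function(x, ...) {
  cat(sprintf("<chromosome_landscape> %d chromosome(s), %d IES interval(s)\n",
              length(x$lengths), nrow(x$ies)))
  invisible(x)
}

read_bed3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  f <- do.call(rbind, strsplit(lines, "\\s+"))
  data.frame(chrom = f[, 1L], start = as.integer(f[, 2L]), end = as.integer(f[, 3L]),
             stringsAsFactors = FALSE)
}

write_bed <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  cols <- lapply(df, function(x) if (is.numeric(x)) format(x, trim = TRUE, scientific = FALSE) else as.character(x))
  if (nrow(df)) writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}
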