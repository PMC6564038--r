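#' Build a naturally aligned exon matrix
#'
#' Collects every exactly-`target_len` CDS exon (coding strand) of the given
#' genes into a matrix-like object. Because all rows have identical length
#' the sequences are naturally aligned with no gapping. Optional filters
#' subset by group, species or repeat family using per-gene metadata.
#'
#' @param genes Named list of [gene_model()] objects.
#' @param genome Genome from [read_fasta()].
#' @param meta Optional `data.frame` with `gene_id` and any of `group`,
#'   `species`, `family` used by the filters.
#' @param group,species,family Optional filter values (vectors allowed).
#' @param target_len Exon length (bp).
#' @return Object of class `exon_matrix`: list with `seqs` (character vector
#'   of `target_len`-nt strings) and `meta` (`data.frame`: `gene_id`,
#'   `exon_index`, `species`, `group`, `family`).
#' @export
build_exon_matrix <- function(genes, genome, meta = NULL, group = NULL,
                              species = NULL, family = NULL, target_len = 90L) {
  lookup <- function(ids, col) {
    if (is.null(meta) || is.null(meta[[col]])) return(rep(NA_character_, length(ids)))
    meta[[col]][match(ids, meta$gene_id)]
  }
  keep_ids <- names(genes)
  if (!is.null(group)) keep_ids <- keep_ids[lookup(keep_ids, "group") %in% group]
  if (!is.null(species)) keep_ids <- keep_ids[lookup(keep_ids, "species") %in% species]
  if (!is.null(family)) keep_ids <- keep_ids[lookup(keep_ids, "family") %in% family]
  seqs <- character(0)
  rows <- list()
  for (id in keep_ids) {
    g <- genes[[id]]
    len <- exon_lengths(g)
    idx <- which(len == target_len)
    if (!length(idx)) next
    s <- exon_sequences(g, genome)[idx]
    seqs <- c(seqs, s)
    rows[[id]] <- data.frame(gene_id = id, exon_index = idx,
                             species = g$species, stringsAsFactors = FALSE)
  }
  if (!length(seqs))
    stop("no ", target_len, "-bp exons match the filter (group=",
         paste(group %||% "*", collapse = ","), ", species=",
         paste(species %||% "*", collapse = ","), ", family=",
         paste(family %||% "*", collapse = ","), ")")
  m <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  m$group <- lookup(m$gene_id, "group")
  m$family <- lookup(m$gene_id, "family")
  structure(list(seqs = seqs, meta = m, target_len = as.integer(target_len)),
            class = "exon_matrix")
}

#' @export
print.exon_matrix <- function(x, ...) {
  cat(sprintf("<exon_matrix> %d x %d nt, %d gene(s)\n",
              length(x$seqs), x$target_len, length(unique(x$meta$gene_id))))
  invisible(x)
}

#' Construct an exon matrix from bare sequences
#'
#' @param seqs Character vector of equal-length nucleotide strings.
#' @param meta Optional per-row metadata `data.frame`.
#' @return An `exon_matrix`.
#' @export
exon_matrix <- function(seqs, meta = NULL) {
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("exon_matrix: rows must have identical length")
  if (is.null(meta))
    meta <- data.frame(gene_id = paste0("row", seq_along(seqs)),
                       exon_index = 1L, species = NA_character_,
                       group = NA_character_, family = NA_character_)
  structure(list(seqs = unname(seqs), meta = meta, target_len = L),
            class = "exon_matrix")
}

# character matrix view (rows x positions)
exon_char_matrix <- function(m) {
  matrix(unlist(strsplit(m$seqs, "")), nrow = length(m$seqs), byrow = TRUE)
}

#' Amino-acid view of a 90-bp exon matrix
#'
#' Because the flanking introns of array exons are phase 2, the first
#' nucleotide completes the upstream junction codon and the last two start
#' the downstream one; dropping them leaves 87 nt = 29 codons, translated
#' under the selected code (TAA/TAG fold to Q under the ciliate code).
#'
#' @param m An `exon_matrix` with 90-nt rows.
#' @param code Genetic code name.
#' @return Character matrix, rows = exons, 29 amino-acid columns.
#' @export
exon_matrix_aa <- function(m, code = "ciliate") {
  if (m$target_len != 90L) stop("amino-acid view requires 90-nt rows")
  tab <- genetic_code(code)
  core <- substring(m$seqs, 2L, 88L)
  aa <- vapply(core, function(s) {
    unname(tab[split_codons(s)])
  }, character(29L), USE.NAMES = FALSE)
  t(aa)
}

#' Position frequency profile of an exon matrix
#'
#' @param m An `exon_matrix`.
#' @param level `"nt"` (A/C/G/T columns over all positions) or `"aa"`
#'   (29-residue frame, see [exon_matrix_aa()]).
#' @param code Genetic code for the aa view.
#' @return Object of class `position_profile`: numeric matrix symbols x
#'   positions whose columns each sum to 1, with attributes `level` and `n`
#'   (sample size).
#' @export
position_profile <- function(m, level = c("nt", "aa"), code = "ciliate") {
  level <- match.arg(level)
  chars <- if (level == "nt") exon_char_matrix(m) else exon_matrix_aa(m, code)
  symbols <- if (level == "nt") c("A", "C", "G", "T") else
    sort(unique(as.vector(chars)))
  prof <- matrix(vapply(seq_len(ncol(chars)), function(j) {
    tab <- table(factor(chars[, j], levels = symbols))
    as.numeric(tab) / nrow(chars)
  }, numeric(length(symbols))), nrow = length(symbols), ncol = ncol(chars))
  rownames(prof) <- symbols
  structure(prof, level = level, n = nrow(chars), class = "position_profile")
}

#' Consensus sequence of a position profile
#'
#' Per-column argmax; ties break by fixed symbol order (A<C<G<T for
#' nucleotides, alphabetical for amino acids).
#'
#' @param profile A [position_profile()].
#' @return Consensus string.
#' @export
consensus <- function(profile) {
  syms <- rownames(profile)
  ord <- order(syms)  # tie-break order
  paste(vapply(seq_len(ncol(profile)), function(j) {
    col <- profile[ord, j]
    syms[ord][which.max(col)]
  }, character(1)), collapse = "")
}

#' Map a 90-bp exon nucleotide position to its amino-acid index
#'
#' In the 29-residue frame of a phase-2-flanked 90-bp exon (first nucleotide
#' and last two excluded), codon *k* spans nucleotides 3k-1..3k+1, so
#' nucleotide position *p* (2..88) maps to codon `floor((p-2)/3)+1`. The six
#' conserved leucine codon centers 36, 48, 66, 75, 81 and 87 map to residues
#' 12, 16, 22, 25, 27 and 29.
#'
#' @param position_1based Nucleotide position in the exon (2..88).
#' @return 1-based amino-acid index (1..29).
#' @export
codon_index_of_nt <- function(position_1based) {
  p <- as.integer(position_1based)
  if (any(p < 2L | p > 88L))
    stop("position must be in 2..88 (1, 89, 90 are junction nucleotides)")
  (p - 2L) %/% 3L + 1L
}

#' Positions with a conserved symbol
#'
#' @param profile A [position_profile()] (typically the aa view).
#' @param symbol Symbol to test (default leucine).
#' @param min_freq Minimum frequency to call a position conserved.
#' @return Ascending integer positions.
#' @export
conserved_positions <- function(profile, symbol = "L", min_freq = 0.5) {
  if (!symbol %in% rownames(profile)) return(integer(0))
  which(profile[symbol, ] >= min_freq)
}

#' Two-sample logo comparison of exon matrices
#'
#' Per position and symbol, tests whether sample A is enriched or depleted
#' relative to sample B with one-sided binomial tail tests: k = symbol count
#' in A, n = |A|, p0 = symbol frequency in B clamped to
#' \[1/(|B|+2), 1 - 1/(|B|+2)\] (a pseudo-frequency floor that avoids
#' degenerate nulls). Calls are made where p < `alpha`; the effect size is
#' freq(A) - freq(B).
#'
#' @param a,b `exon_matrix` objects (same row length).
#' @param level `"nt"` or `"aa"`.
#' @param alpha Call threshold (the original tool's cutoff, 1e-5).
#' @param code Genetic code for the aa view.
#' @return `data.frame` of calls: `position`, `symbol`, `direction`
#'   (`enriched`/`depleted`), `p`, `effect`, plus attribute `n_tests`.
#' @export
two_sample_logo <- function(a, b, level = c("nt", "aa"), alpha = 1e-5,
                            code = "ciliate") {
  level <- match.arg(level)
  na <- length(a$seqs); nb <- length(b$seqs)
  if (na < 20L || nb < 20L)
    warning("two_sample_logo: fewer than 20 sequences in a sample; underpowered")
  ca <- if (level == "nt") exon_char_matrix(a) else exon_matrix_aa(a, code)
  cb <- if (level == "nt") exon_char_matrix(b) else exon_matrix_aa(b, code)
  if (ncol(ca) != ncol(cb)) stop("matrices have different position counts")
  symbols <- if (level == "nt") c("A", "C", "G", "T") else
    sort(unique(c(as.vector(ca), as.vector(cb))))
  floor_p <- 1 / (nb + 2)
  calls <- list()
  n_tests <- 0L
  for (j in seq_len(ncol(ca))) {
    ta <- table(factor(ca[, j], levels = symbols))
    tb <- table(factor(cb[, j], levels = symbols))
    for (s in symbols) {
      k <- as.integer(ta[[s]])
      fa <- k / na; fb <- as.integer(tb[[s]]) / nb
      p0 <- min(max(fb, floor_p), 1 - floor_p)
      n_tests <- n_tests + 1L
      p_enr <- pbinom(k - 1L, na, p0, lower.tail = FALSE)
      p_dep <- pbinom(k, na, p0)
      if (p_enr < alpha || p_dep < alpha) {
        enriched <- p_enr <= p_dep
        calls[[length(calls) + 1L]] <- data.frame(
          position = j, symbol = s,
          direction = if (enriched) "enriched" else "depleted",
          p = min(p_enr, p_dep), effect = fa - fb, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(calls)) do.call(rbind, c(calls, list(make.row.names = FALSE)))
    else data.frame(position = integer(0), symbol = character(0),
                    direction = character(0), p = numeric(0), effect = numeric(0))
  attr(out, "n_tests") <- n_tests
  out
}

#' Cluster near-identical fixed-length exons
#'
#' Single-linkage connected components of the graph whose edges join rows at
#' Hamming distance at most `max_mismatch`. With 90-nt rows and the default
#' of 2 mismatches this implements clustering at >= 97% identity. Candidate
#' pairs are found by an exact-segment (pigeonhole) index: any pair within
#' `max_mismatch` mismatches shares at least one of `max_mismatch + 1` equal
#' segments, so only those pairs are verified, making the procedure practical
#' on tens of thousands of rows while remaining exactly equivalent to the
#' all-pairs computation.
#'
#' @param m An `exon_matrix`.
#' @param max_mismatch Maximum Hamming distance joined by an edge.
#' @return List with `clusters` (list of integer row-index vectors, sorted by
#'   decreasing size, ties by smallest member), `membership` (integer vector),
#'   and `largest` (`data.frame` describing the largest cluster's rows).
#' @export
cluster_near_identical <- function(m, max_mismatch = 2L) {
  n <- length(m$seqs)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  L <- m$target_len
  nseg <- max_mismatch + 1L
  bounds <- floor(seq(0L, L, length.out = nseg + 1L))
  for (s in seq_len(nseg)) {
    key <- substring(m$seqs, bounds[s] + 1L, bounds[s + 1L])
    buckets <- split(seq_len(n), key)
    for (idx in buckets) {
      if (length(idx) < 2L) next
      for (i in seq_len(length(idx) - 1L)) {
        for (j in (i + 1L):length(idx)) {
          a <- idx[i]; b <- idx[j]
          if (find(a) != find(b) &&
              hamming(m$seqs[a], m$seqs[b]) <= max_mismatch)
            union_(a, b)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  comp <- split(seq_len(n), root)
  ord <- order(-lengths(comp), vapply(comp, min, integer(1)))
  clusters <- unname(comp[ord])
  membership <- integer(n)
  for (k in seq_along(clusters)) membership[clusters[[k]]] <- k
  largest <- m$meta[clusters[[1L]], , drop = FALSE]
  list(clusters = clusters, membership = membership, largest = largest)
}

#' Distance matrix between per-group exon consensus sequences
#'
#' Builds the consensus of each (species, family) exon matrix and returns the
#' pairwise Hamming distance divided by the exon length. Groups with fewer
#' than 3 rows are excluded with a warning. Tree building itself is left to
#' external phylogenetics tools; [write_phylip_dist()] exports the matrix.
#'
#' @param matrices Named list of `exon_matrix` objects (one per group).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
family_consensus_distance_matrix <- function(matrices) {
  small <- vapply(matrices, function(m) length(m$seqs) < 3L, logical(1))
  if (any(small)) {
    warning("excluding group(s) with <3 rows: ",
            paste(names(matrices)[small], collapse = ", "))
    matrices <- matrices[!small]
  }
  if (length(matrices) < 2L) stop("need at least 2 groups")
  cons <- vapply(matrices, function(m) consensus(position_profile(m, "nt")),
                 character(1))
  k <- length(cons)
  d <- matrix(0, k, k, dimnames = list(names(cons), names(cons)))
  L <- nchar(cons[[1L]])
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    d[i, j] <- d[j, i] <- hamming(cons[[i]], cons[[j]]) / L
  }
  d
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param d Symmetric matrix with row names.
#' @param path Output file.
#' @export
write_phylip_dist <- function(d, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste0(formatC(rownames(d)[i], width = -10L),
                      paste(sprintf("%.6f", d[i, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' Export logo stack data
#'
#' Per-column symbol stacks with heights = frequency x column information
#' content (2-bit scale for nucleotides, log2(20) for amino acids), the
#' layout sequence-logo renderers expect.
#'
#' @param profile A [position_profile()].
#' @return `data.frame` with `position`, `symbol`, `freq`, `height`.
#' @export
logo_stacks <- function(profile) {
  level <- attr(profile, "level")
  max_bits <- if (identical(level, "nt")) 2 else log2(20)
  rows <- lapply(seq_len(ncol(profile)), function(j) {
    f <- profile[, j]
    h <- -sum(ifelse(f > 0, f * log2(f), 0))
    ic <- max(max_bits - h, 0)
    data.frame(position = j, symbol = rownames(profile), freq = as.numeric(f),
               height = as.numeric(f) * ic, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[out$freq > 0, , drop = FALSE]
}
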