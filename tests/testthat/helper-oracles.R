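# small construction helpers and independent oracles used across tests

# gene model with given exon lengths and intron lengths on a fresh scaffold,
# plus-strand, starting at `offset`
make_gene <- function(lengths, introns = rep(60L, length(lengths) - 1L),
                      id = "g1", scaffold = "s1", strand = "+",
                      offset = 0L, species = "spA") {
  stopifnot(length(introns) == length(lengths) - 1L)
  starts <- integer(length(lengths))
  cur <- offset
  for (i in seq_along(lengths)) {
    starts[i] <- cur
    cur <- cur + lengths[i] + if (i < length(lengths)) introns[i] else 0L
  }
  ex <- cbind(starts, starts + lengths)
  if (strand == "-") {
    # mirror so transcription order still matches `lengths`
    total <- cur - offset
    ex <- cbind(offset + total - (ex[, 2L] - offset),
                offset + total - (ex[, 1L] - offset))
  }
  gene_model(id, species, scaffold, strand, ex)
}

random_seqs <- function(n, len, templates = NULL, mut = 0L) {
  bases <- c("A", "C", "G", "T")
  if (is.null(templates))
    return(vapply(seq_len(n), function(i)
      paste(sample(bases, len, replace = TRUE), collapse = ""), character(1)))
  vapply(seq_len(n), function(i) {
    s <- strsplit(sample(templates, 1L), "")[[1]]
    k <- sample(0:mut, 1L)
    if (k > 0L) {
      at <- sample(len, k)
      for (j in at) s[j] <- sample(setdiff(bases, s[j]), 1L)
    }
    paste(s, collapse = "")
  }, character(1))
}

hamming_chr <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

# independent oracle for near-identity clustering: all-pairs distances and
# igraph connected components
oracle_clusters <- function(seqs, max_mm) {
  n <- length(seqs)
  edges <- matrix(integer(0), ncol = 2L)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (hamming_chr(seqs[i], seqs[j]) <= max_mm)
      edges <- rbind(edges, c(i, j))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$membership
}

# canonical form of a clustering: sets of sorted members, sorted
canonical_partition <- function(membership) {
  parts <- split(seq_along(membership), membership)
  parts <- lapply(parts, sort)
  unname(parts[order(vapply(parts, `[`, integer(1), 1L))])
}

# brute-force oracle for scan_tail: slide over every window on both strands
oracle_scan <- function(seq, query, max_mm) {
  L <- nchar(query)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(query)))
  hits <- list()
  for (s in seq_len(nchar(seq) - L + 1L)) {
    w <- substr(seq, s, s + L - 1L)
    for (strand in c("+", "-")) {
      q <- if (strand == "+") query else rc
      mm <- hamming_chr(w, q)
      if (mm <= max_mm)
        hits[[length(hits) + 1L]] <- data.frame(start = s - 1L, end = s + L - 1L,
                                                strand = strand, mismatches = mm)
    }
  }
  if (!length(hits)) return(NULL)
  do.call(rbind, hits)
}

# ortholog_clusters object built directly from per-cluster species counts
clusters_from_counts <- function(count_list, species) {
  clusters <- lapply(seq_along(count_list), function(i) {
    k <- count_list[[i]]
    out <- lapply(seq_along(species), function(s) {
      if (k[s] == 0L) return(NULL)
      sprintf("c%d_%s_g%d", i, species[s], seq_len(k[s]))
    })
    names(out) <- species
    out[!vapply(out, is.null, logical(1))]
  })
  names(clusters) <- sprintf("c%d", seq_along(count_list))
  universe <- lapply(species, function(s)
    unlist(lapply(clusters, function(cl) cl[[s]]), use.names = FALSE))
  names(universe) <- species
  structure(list(clusters = clusters, universe = universe,
                 singletons = setNames(rep(list(character(0)), length(species)),
                                       species)),
            class = "ortholog_clusters")
}
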