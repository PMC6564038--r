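#' Ortholog cluster categories
#'
#' The category of a cluster is the number of species with at least one
#' member; with 10 species this yields the classical categories I-X (genes
#' appearing in only one species are category I).
#'
#' @param clusters An `ortholog_clusters` object from
#'   [read_orthomcl_groups()].
#' @return `data.frame` with `cluster_id`, `category` (integer), `roman`
#'   (display label), `n_genes`, and one `n_<species>` count column per
#'   species of the universe.
#' @export
categorize <- function(clusters) {
  species <- names(clusters$universe)
  rows <- lapply(names(clusters$clusters), function(cid) {
    cl <- clusters$clusters[[cid]]
    counts <- vapply(species, function(s) length(cl[[s]] %||% character(0)),
                     integer(1))
    if (sum(counts) == 0L) stop("cluster ", cid, " has zero genes")
    cat <- sum(counts > 0L)
    df <- data.frame(cluster_id = cid, category = cat,
                     roman = as.character(utils::as.roman(cat)),
                     n_genes = sum(counts), stringsAsFactors = FALSE)
    for (s in species) df[[paste0("n_", s)]] <- counts[[s]]
    df
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Test clusters for single-species inparalog expansion
#'
#' For each cluster with at least `min_n` genes spanning at least two
#' species, each member species' count k is tested against
#' Binomial(N, 1/S) where N is the cluster size and S the number of species
#' present, with a one-sided upper tail and Bonferroni correction over the S
#' species tested within the cluster; a species is flagged expanded when the
#' corrected p-value is below `alpha`. Category-I clusters are skipped: their
#' genes are species-specific wholesale.
#'
#' @param clusters An `ortholog_clusters` object.
#' @param alpha Significance level after correction.
#' @param min_n Minimum cluster size to test.
#' @return `data.frame` with `cluster_id`, `species`, `count`, `total`, `p`
#'   (corrected), `flagged`.
#' @export
expansion_test <- function(clusters, alpha = 0.01, min_n = 5L) {
  rows <- list()
  for (cid in names(clusters$clusters)) {
    cl <- clusters$clusters[[cid]]
    counts <- lengths(cl)
    counts <- counts[counts > 0L]
    N <- sum(counts); S <- length(counts)
    if (N < min_n || S < 2L) next
    for (s in names(counts)) {
      k <- counts[[s]]
      p <- pbinom(k - 1L, N, 1 / S, lower.tail = FALSE)
      p_adj <- min(1, p * S)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = cid, species = s, count = k, total = N, p = p_adj,
        flagged = p_adj < alpha, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(cluster_id = character(0), species = character(0),
                      count = integer(0), total = integer(0), p = numeric(0),
                      flagged = logical(0)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Species-specific genes of one species
#'
#' The union of (1) the species' singletons, (2) its members of category-I
#' clusters (clusters confined to that species), and (3) its members of
#' clusters where it is flagged as significantly expanded.
#'
#' @param clusters An `ortholog_clusters` object.
#' @param categories Output of [categorize()].
#' @param calls Output of [expansion_test()].
#' @param species Species name.
#' @return Character vector of gene ids (duplicates removed).
#' @export
species_specific_genes <- function(clusters, categories, calls, species) {
  out <- clusters$singletons[[species]] %||% character(0)
  cat1 <- categories$cluster_id[categories$category == 1L]
  for (cid in cat1) {
    g <- clusters$clusters[[cid]][[species]]
    if (!is.null(g)) out <- c(out, g)
  }
  flagged <- calls$cluster_id[calls$flagged & calls$species == species]
  for (cid in flagged) out <- c(out, clusters$clusters[[cid]][[species]])
  sort(unique(out))
}

#' Tandemly duplicated gene groups
#'
#' Within each scaffold's annotation order (strand ignored), two genes of the
#' same ortholog cluster are tandem-linked when at most `max_gap` other genes
#' lie between them; tandem groups are the connected components of these
#' links, with `max_gap = 0` giving the strict criterion and `max_gap = 3`
#' the relaxed one. Singleton genes (no cluster) are linked to other
#' singletons under the same rule.
#'
#' @param gene_order Named list: scaffold -> character vector of gene ids in
#'   annotation order.
#' @param clusters An `ortholog_clusters` object.
#' @param max_gap Maximum number of intervening genes.
#' @return `data.frame` with one row per tandem gene: `scaffold`, `gene_id`,
#'   `cluster_id`, `tandem_group` (integer id); only groups of >= 2 genes are
#'   reported.
#' @export
tandem_clusters <- function(gene_order, clusters, max_gap = 0L) {
  gene2cluster <- character(0)
  for (cid in names(clusters$clusters)) {
    g <- unlist(clusters$clusters[[cid]], use.names = FALSE)
    gene2cluster[g] <- cid
  }
  singles <- unlist(clusters$singletons, use.names = FALSE)
  gene2cluster[singles] <- ".singleton"
  rows <- list()
  gid_counter <- 0L
  for (sc in names(gene_order)) {
    ids <- gene_order[[sc]]
    missing <- !ids %in% names(gene2cluster)
    if (any(missing))
      stop("gene not in cluster universe: ", ids[missing][1L])
    cl <- gene2cluster[ids]
    for (c_id in unique(cl)) {
      pos <- which(cl == c_id)
      if (length(pos) < 2L) next
      # link consecutive occurrences separated by <= max_gap other genes
      brk <- c(0L, cumsum(diff(pos) - 1L > max_gap))
      for (b in unique(brk)) {
        members <- pos[brk == b]
        if (length(members) < 2L) next
        gid_counter <- gid_counter + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          scaffold = sc, gene_id = ids[members], cluster_id = c_id,
          tandem_group = gid_counter, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(scaffold = character(0), gene_id = character(0),
                      cluster_id = character(0), tandem_group = integer(0)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Percentage of tandemly duplicated genes per ortholog category
#'
#' @param categories Output of [categorize()].
#' @param clusters An `ortholog_clusters` object.
#' @param tandem Output of [tandem_clusters()].
#' @return `data.frame` with `category`, `n_genes`, `n_tandem`, `pct_tandem`
#'   (NA for an empty category).
#' @export
percent_tandem_by_category <- function(categories, clusters, tandem) {
  tandem_genes <- unique(tandem$gene_id)
  cats <- sort(unique(categories$category))
  rows <- lapply(cats, function(k) {
    cids <- categories$cluster_id[categories$category == k]
    genes <- unlist(lapply(clusters$clusters[cids], unlist), use.names = FALSE)
    n <- length(genes)
    nt <- sum(genes %in% tandem_genes)
    data.frame(category = k, n_genes = n, n_tandem = nt,
               pct_tandem = if (n > 0) 100 * nt / n else NA_real_)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
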