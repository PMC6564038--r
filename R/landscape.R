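#' IES-omitted (MDS) coordinate of a germline position
#'
#' Maps a micronuclear (MIC) chromosome position to its coordinate after
#' omitting all internal eliminated sequences (IESs): position minus the
#' total IES bp strictly before it. Positions falling inside an IES collapse
#' to the IES's left edge and are flagged.
#'
#' @param landscape A [chromosome_landscape()].
#' @param chrom Chromosome id.
#' @param position Integer vector of 0-based positions.
#' @return `data.frame` with `mds` (IES-omitted position) and `inside_ies`
#'   (logical).
#' @export
mds_coordinate <- function(landscape, chrom, position) {
  L <- landscape$lengths[[chrom]]
  if (is.null(L)) stop("unknown chromosome: ", chrom)
  if (any(position < 0L | position >= L))
    stop("position out of bounds on ", chrom)
  ies <- landscape$ies[landscape$ies$chrom == chrom, , drop = FALSE]
  if (!nrow(ies))
    return(data.frame(mds = as.integer(position), inside_ies = FALSE))
  cum <- cumsum(ies$end - ies$start)
  # index of the last IES starting at or before the position
  idx <- findInterval(position, ies$start)
  inside <- idx > 0L & position < ies$end[pmax(idx, 1L)]
  removed_before <- ifelse(idx == 0L, 0L,
                           ifelse(inside,
                                  c(0L, cum)[idx],        # up to previous IES
                                  cum[pmax(idx, 1L)]))
  mds <- ifelse(inside,
                ies$start[pmax(idx, 1L)] - ifelse(idx <= 1L, 0L, cum[pmax(idx - 1L, 1L)]),
                position - removed_before)
  data.frame(mds = as.integer(mds), inside_ies = inside)
}

#' Total IES-omitted length of a chromosome
#'
#' @param landscape A [chromosome_landscape()].
#' @param chrom Chromosome id.
#' @return Integer: chromosome length minus total IES bp.
#' @export
mds_length <- function(landscape, chrom) {
  ies <- landscape$ies[landscape$ies$chrom == chrom, , drop = FALSE]
  as.integer(landscape$lengths[[chrom]] - sum(ies$end - ies$start))
}

#' Bin per-gene values along IES-omitted chromosomes
#'
#' Tiles each chromosome's IES-omitted length with `bin_width` bins (the last
#' bin may be short) and aggregates the items falling in each bin. Items are
#' positioned by [mds_coordinate()]; items inside an IES are excluded.
#'
#' @param landscape A [chromosome_landscape()].
#' @param items `data.frame` with `chrom`, `position` (0-based MIC), optional
#'   `value`, and for `mode = "fraction_of_bin_genes"` a logical `subset`
#'   column.
#' @param bin_width Bin width in bp of IES-omitted sequence.
#' @param mode `"count"`, `"fraction_of_bin_genes"` (subset count / all items
#'   in bin) or `"median"` (median of `value`).
#' @return `data.frame` with `chrom`, `bin` (1-based), `start`, `end` (MDS
#'   coords) and `value`.
#' @export
bin_values <- function(landscape, items, bin_width = 1e6,
                       mode = c("count", "fraction_of_bin_genes", "median")) {
  mode <- match.arg(mode)
  if (bin_width <= 0) stop("bin width must be positive")
  out <- list()
  for (ch in names(landscape$lengths)) {
    Lm <- mds_length(landscape, ch)
    n_bins <- max(1L, as.integer(ceiling(Lm / bin_width)))
    starts <- (seq_len(n_bins) - 1L) * bin_width
    ends <- pmin(starts + bin_width, Lm)
    it <- items[items$chrom == ch, , drop = FALSE]
    vals <- rep(if (mode == "count") 0 else NA_real_, n_bins)
    if (nrow(it)) {
      mc <- mds_coordinate(landscape, ch, it$position)
      keep <- !mc$inside_ies
      it <- it[keep, , drop = FALSE]
      bin <- pmin(as.integer(mc$mds[keep] %/% bin_width) + 1L, n_bins)
      for (b in unique(bin)) {
        sel <- bin == b
        vals[b] <- switch(mode,
          count = sum(sel),
          fraction_of_bin_genes = sum(it$subset[sel]) / sum(sel),
          median = median(it$value[sel], na.rm = TRUE))
      }
      if (mode == "count") vals[is.na(vals)] <- 0
    }
    out[[ch]] <- data.frame(chrom = ch, bin = seq_len(n_bins), start = starts,
                            end = ends, value = vals)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Chromosomal region of an IES-omitted position
#'
#' Labels positions as `pericentromeric` (within `peri_half_width` of the
#' centromere midpoint, computed in MDS coordinates), `subtelomeric` (within
#' `subtel_len` of either chromosome end) or `arm`. Pericentromeric takes
#' precedence where the parameters overlap. The default extents (2 Mb
#' spanning the centromere midpoint, 1 Mb per chromosome end) are working
#' definitions, not biologically sharp boundaries, and are configurable.
#'
#' @param landscape A [chromosome_landscape()].
#' @param chrom Chromosome id.
#' @param mds_position Numeric vector of IES-omitted positions.
#' @param peri_half_width Half-width of the pericentromeric region (bp).
#' @param subtel_len Length of each subtelomeric region (bp).
#' @return Character vector of region labels.
#' @export
region_of <- function(landscape, chrom, mds_position,
                      peri_half_width = 1e6, subtel_len = 1e6) {
  cen <- landscape$centromeres[landscape$centromeres$chrom == chrom, , drop = FALSE]
  if (!nrow(cen)) stop("no centromere for ", chrom)
  mid_mic <- (cen$start[1L] + cen$end[1L]) / 2
  mid <- mds_coordinate(landscape, chrom, as.integer(floor(mid_mic)))$mds
  Lm <- mds_length(landscape, chrom)
  ifelse(abs(mds_position - mid) <= peri_half_width, "pericentromeric",
         ifelse(mds_position < subtel_len | mds_position >= Lm - subtel_len,
                "subtelomeric", "arm"))
}

#' Region enrichment of a gene subset
#'
#' Cross-tabulates subset membership against the three chromosomal regions
#' and applies a chi-squared test.
#'
#' @param regions Character vector of region labels for all genes.
#' @param subset Logical vector: is the gene in the focal class.
#' @return List with `table` (2 x 3 contingency matrix) and `p`.
#' @export
region_enrichment <- function(regions, subset) {
  lv <- c("pericentromeric", "subtelomeric", "arm")
  tab <- table(factor(ifelse(subset, "subset", "complement"),
                      levels = c("subset", "complement")),
               factor(regions, levels = lv))
  if (sum(colSums(tab) > 0) < 2L) {
    warning("all genes in one region; test skipped")
    return(list(table = tab, p = NA_real_))
  }
  keep <- colSums(tab) > 0
  p <- suppressWarnings(chisq.test(tab[, keep, drop = FALSE])$p.value)
  list(table = tab, p = p)
}

#' Pairwise Mann-Whitney comparison of per-gene values between regions
#'
#' @param values Numeric vector of per-gene values.
#' @param regions Region labels parallel to `values`.
#' @return `data.frame` with `region_a`, `region_b`, `n_a`, `n_b`, `p`
#'   (two-sided Wilcoxon rank-sum).
#' @export
value_comparison <- function(values, regions) {
  lv <- intersect(c("pericentromeric", "subtelomeric", "arm"), unique(regions))
  if (length(lv) < 2L) stop("need values in at least two regions")
  pairs <- utils::combn(lv, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- values[regions == pairs[1L, i]]
    b <- values[regions == pairs[2L, i]]
    p <- if (length(a) && length(b))
      suppressWarnings(wilcox.test(a, b)$p.value) else NA_real_
    data.frame(region_a = pairs[1L, i], region_b = pairs[2L, i],
               n_a = length(a), n_b = length(b), p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' IES-gene association
#'
#' For each IES, finds the nearest gene on each side (edge-to-edge distance
#' on the MIC chromosome) and, when the IES lies wholly inside an intron, the
#' containing gene. A gene is flagged `flanked_by_ies` when some IES lies
#' between it and an adjacent gene (on either side, with no other gene
#' between) or within one of its introns.
#'
#' @param landscape A [chromosome_landscape()].
#' @param genes List of [gene_model()] objects on the landscape's
#'   chromosomes.
#' @return List with `per_ies` (`data.frame`: `chrom`, `start`, `end`,
#'   `left_gene`, `right_gene`, `containing_gene`) and `per_gene`
#'   (`data.frame`: `gene_id`, `flanked_by_ies`).
#' @export
ies_gene_association <- function(landscape, genes) {
  spans <- do.call(rbind, lapply(genes, function(g) {
    sp <- gene_span(g)
    data.frame(gene_id = g$gene_id, chrom = g$scaffold,
               start = sp[["start"]], end = sp[["end"]], stringsAsFactors = FALSE)
  }))
  flagged <- setNames(rep(FALSE, length(genes)),
                      vapply(genes, `[[`, character(1), "gene_id"))
  per_ies <- list()
  for (ch in unique(landscape$ies$chrom)) {
    ies <- landscape$ies[landscape$ies$chrom == ch, , drop = FALSE]
    gs <- spans[spans$chrom == ch, , drop = FALSE]
    gs <- gs[order(gs$start), , drop = FALSE]
    for (i in seq_len(nrow(ies))) {
      s <- ies$start[i]; e <- ies$end[i]
      left_i <- which(gs$end <= s)
      right_i <- which(gs$start >= e)
      left <- if (length(left_i)) gs$gene_id[max(left_i)] else NA_character_
      right <- if (length(right_i)) gs$gene_id[min(right_i)] else NA_character_
      containing <- NA_character_
      ov <- which(gs$start < e & gs$end > s)
      for (j in ov) {
        g <- genes[[match(gs$gene_id[j], names(flagged))]]
        ex <- g$exons[order(g$exons[, "start"]), , drop = FALSE]
        if (nrow(ex) > 1L) {
          intr_s <- ex[-nrow(ex), "end"]; intr_e <- ex[-1L, "start"]
          if (any(s >= intr_s & e <= intr_e)) {
            containing <- gs$gene_id[j]
            flagged[containing] <- TRUE
          }
        }
      }
      # IES between two adjacent genes (no gene overlaps it)
      if (!length(ov)) {
        if (!is.na(left)) flagged[left] <- TRUE
        if (!is.na(right)) flagged[right] <- TRUE
      }
      per_ies[[length(per_ies) + 1L]] <- data.frame(
        chrom = ch, start = s, end = e, left_gene = left, right_gene = right,
        containing_gene = containing, stringsAsFactors = FALSE)
    }
  }
  list(per_ies = do.call(rbind, c(per_ies, list(make.row.names = FALSE))),
       per_gene = data.frame(gene_id = names(flagged),
                             flanked_by_ies = unname(flagged),
                             stringsAsFactors = FALSE))
}
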