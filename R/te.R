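#' Scan a genome for a conserved tail sequence
#'
#' Finds every window of the query's length, on either strand, within
#' `max_mismatch` Hamming mismatches of the query (no indels). Overlapping
#' same-strand hits are merged, keeping the lowest-mismatch window (ties:
#' leftmost). Designed for the conserved 54-bp 3' tail of the ciliate REP
#' non-LTR retrotransposon; the default of 5 mismatches corresponds to about
#' 90% identity over 54 bp.
#'
#' @param genome Genome from [read_fasta()].
#' @param query Query sequence (default length 54; no N allowed).
#' @param max_mismatch Maximum Hamming distance.
#' @return `data.frame` with `scaffold`, `start`, `end` (0-based half-open),
#'   `strand`, `mismatches`.
#' @export
scan_tail <- function(genome, query, max_mismatch = 5L) {
  if (grepl("N", query, fixed = TRUE)) stop("query contains N")
  if (max_mismatch >= nchar(query)) stop("max_mismatch must be < query length")
  q_fwd <- Biostrings::DNAString(query)
  q_rev <- Biostrings::reverseComplement(q_fwd)
  rows <- list()
  for (sc in names(genome)) {
    subj <- Biostrings::DNAString(genome[[sc]])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") q_fwd else q_rev
      m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch)
      if (!length(m)) next
      st <- Biostrings::start(m) - 1L
      en <- Biostrings::end(m)
      pat_chr <- as.character(pat)
      mm <- vapply(as.character(m), hamming, integer(1), b = pat_chr,
                   USE.NAMES = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = sc, start = st, end = en, strand = strand, mismatches = mm,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0)))
  hits <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  merge_overlapping_hits(hits)
}

# keep the lowest-mismatch window per overlapping same-strand chain
merge_overlapping_hits <- function(hits) {
  out <- list()
  for (key in unique(paste(hits$scaffold, hits$strand))) {
    h <- hits[paste(hits$scaffold, hits$strand) == key, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    grp <- cumsum(c(0L, h$start[-1L] >= cummax(h$end[-nrow(h)])))
    for (g in unique(grp)) {
      hh <- h[grp == g, , drop = FALSE]
      best <- order(hh$mismatches, hh$start)[1L]
      out[[length(out) + 1L]] <- hh[best, , drop = FALSE]
    }
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[order(res$scaffold, res$start, res$strand), , drop = FALSE]
}

#' Nearest repeat families flanking REP copies
#'
#' For each REP copy, finds the nearest mask-hit family within `window` bp
#' (edge-to-edge) on each side, and summarizes per family how many copies it
#' flanks on at least one side and on both sides, split by the copies'
#' functional flag. Also reports the fraction of copies colocalized (either
#' side within `window`) with a designated LRR-repeat family.
#'
#' @param rep_copies `data.frame` with `scaffold`, `start`, `end`, optional
#'   `functional` (logical).
#' @param mask_hits Mask table from [read_mask_table()].
#' @param window Maximum edge distance (bp).
#' @param lrr_family Family id whose colocalization fraction is reported.
#' @return List with `per_copy` (`data.frame`: left/right family and
#'   distance, `colocalized`), `summary` (per-family counts), and
#'   `colocalization_fraction`.
#' @export
flanking_elements <- function(rep_copies, mask_hits, window = 1000L,
                              lrr_family = "tLRR-MIC-CRS") {
  if (window <= 0) stop("window must be positive")
  n <- nrow(rep_copies)
  left_fam <- right_fam <- rep(NA_character_, n)
  left_d <- right_d <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    h <- mask_hits[mask_hits$scaffold == rep_copies$scaffold[i], , drop = FALSE]
    if (!nrow(h)) next
    # left side: hits ending at or before the copy start
    dl <- rep_copies$start[i] - h$end
    lj <- which(dl >= 0 & dl <= window)
    if (length(lj)) {
      j <- lj[order(dl[lj], h$family[lj])][1L]
      left_fam[i] <- h$family[j]; left_d[i] <- dl[j]
    }
    dr <- h$start - rep_copies$end[i]
    rj <- which(dr >= 0 & dr <= window)
    if (length(rj)) {
      j <- rj[order(dr[rj], h$family[rj])][1L]
      right_fam[i] <- h$family[j]; right_d[i] <- dr[j]
    }
  }
  functional <- if (!is.null(rep_copies$functional)) rep_copies$functional else
    rep(NA, n)
  colocal <- (!is.na(left_fam) & left_fam == lrr_family) |
    (!is.na(right_fam) & right_fam == lrr_family)
  per_copy <- data.frame(rep_copies[, c("scaffold", "start", "end")],
                         functional = functional,
                         left_family = left_fam, left_distance = left_d,
                         right_family = right_fam, right_distance = right_d,
                         colocalized = colocal, stringsAsFactors = FALSE)
  fams <- sort(unique(stats::na.omit(c(left_fam, right_fam))))
  summary <- do.call(rbind, lapply(fams, function(f) {
    one <- (left_fam == f & !is.na(left_fam)) | (right_fam == f & !is.na(right_fam))
    both <- (left_fam == f & !is.na(left_fam)) & (right_fam == f & !is.na(right_fam))
    data.frame(family = f,
               n_one_side = sum(one),
               n_both_sides = sum(both),
               n_one_side_functional = sum(one & functional %in% TRUE),
               n_one_side_nonfunctional = sum(one & functional %in% FALSE),
               stringsAsFactors = FALSE)
  }))
  if (is.null(summary))
    summary <- data.frame(family = character(0), n_one_side = integer(0),
                          n_both_sides = integer(0),
                          n_one_side_functional = integer(0),
                          n_one_side_nonfunctional = integer(0))
  summary <- summary[order(-summary$n_one_side, summary$family), , drop = FALSE]
  rownames(summary) <- NULL
  list(per_copy = per_copy, summary = summary,
       colocalization_fraction = if (n > 0) mean(colocal) else NA_real_)
}

#' Sensitivity of the colocalization fraction to the flanking window
#'
#' @param rep_copies,mask_hits,lrr_family As in [flanking_elements()].
#' @param windows Windows to sweep (bp).
#' @return `data.frame` with `window` and `colocalization_fraction`.
#' @export
flanking_window_sweep <- function(rep_copies, mask_hits,
                                  windows = c(250L, 500L, 1000L, 2000L),
                                  lrr_family = "tLRR-MIC-CRS") {
  do.call(rbind, lapply(windows, function(w) {
    data.frame(window = w,
               colocalization_fraction =
                 flanking_elements(rep_copies, mask_hits, window = w,
                                   lrr_family = lrr_family)$colocalization_fraction)
  }))
}

#' Bin tail hits along IES-omitted chromosomes
#'
#' @param hits Output of [scan_tail()] (scaffold names must be landscape
#'   chromosomes).
#' @param landscape A [chromosome_landscape()].
#' @param bin_width Bin width (bp of IES-omitted sequence).
#' @return Bin track as from [bin_values()] with `mode = "count"`.
#' @export
tail_distribution_track <- function(hits, landscape, bin_width = 1e6) {
  items <- data.frame(chrom = hits$scaffold, position = hits$start)
  bin_values(landscape, items, bin_width = bin_width, mode = "count")
}

#' Check ORF intactness of a candidate element sequence
#'
#' Helper for REP annotations lacking curated ORF flags: reports whether the
#' sequence contains an uninterrupted reading frame of at least `min_aa`
#' codons (started anywhere, any of the three frames, forward strand) under
#' the selected genetic code.
#'
#' @param sequence Nucleotide string.
#' @param min_aa Minimum ORF length in amino acids.
#' @param code Genetic code.
#' @return Logical.
#' @export
has_intact_orf <- function(sequence, min_aa = 100L, code = "ciliate") {
  tab <- genetic_code(code)
  n <- nchar(sequence)
  for (off in 0:2) {
    len <- ((n - off) %/% 3L) * 3L
    if (len < 3L * min_aa) next
    aa <- unname(tab[split_codons(substr(sequence, off + 1L, off + len))])
    aa[is.na(aa)] <- "X"
    r <- rle(aa == "*")
    if (any(!r$values & r$lengths >= min_aa)) return(TRUE)
  }
  FALSE
}
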