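#' Intron phases of a gene model
#'
#' The phase of intron *i* (the intron following exon *i* in transcription
#' order) is the cumulative CDS length of exons 1..*i* modulo 3: phase 2 means
#' the intron interrupts a codon after its second nucleotide. Single-exon
#' genes return an empty vector.
#'
#' @param gene A [gene_model()] whose CDS length is divisible by 3.
#' @return Integer vector of phases (0/1/2), length = exon count - 1.
#' @export
intron_phases <- function(gene) {
  len <- exon_lengths(gene)
  if (length(len) < 2L) return(integer(0))
  as.integer(cumsum(len)[-length(len)] %% 3L)
}

#' Find exact-length exon arrays
#'
#' Reports maximal runs of consecutive exons (transcription order) that are
#' each exactly `target_len` bp; only runs of at least `min_run` exons are
#' returned. With the defaults this detects the 90-bp exon arrays (at least 3
#' consecutive exactly-90-bp CDS exons) characteristic of ciliate LRR genes.
#'
#' @param gene A [gene_model()].
#' @param target_len Exact exon length to match (bp).
#' @param min_run Minimum run length to report.
#' @return `data.frame` with columns `start_exon` (1-based exon index) and
#'   `run_length`.
#' @export
find_exact_length_arrays <- function(gene, target_len = 90L, min_run = 3L) {
  hit <- exon_lengths(gene) == target_len
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  data.frame(start_exon = starts[keep], run_length = r$lengths[keep])
}

# indices (2..n) of exons whose preceding intron exists; helper for strata
preceding_phase_of_exons <- function(gene) {
  ph <- intron_phases(gene)
  if (!length(ph)) return(integer(0))
  setNames(ph, seq_along(ph) + 1L)  # names = exon index the intron precedes
}

#' Phase bias across gene strata
#'
#' Tallies intron phases in four strata: (1) introns immediately preceding
#' exactly-`target_len` exons in LRR genes, (2) all introns in LRR genes that
#' lack `target_len` exons, (3) introns preceding `target_len` exons in
#' non-LRR genes, and (4) all introns. "Preceding" means immediately 5' of
#' the exon in transcription order. Phases of the intron *following* each
#' target-length exon are tallied as an extra column for reference.
#'
#' @param genes List of [gene_model()] objects.
#' @param lrr_flags Named logical vector (gene id -> is LRR).
#' @param target_len Exon length defining the focal exon class.
#' @return `data.frame` with one row per stratum: phase counts `n0`,`n1`,`n2`,
#'   total `n`, and `phase2_pct` (NA for an empty stratum).
#' @export
phase_bias_report <- function(genes, lrr_flags, target_len = 90L) {
  acc <- matrix(0L, nrow = 4L, ncol = 3L,
                dimnames = list(c("lrr_preceding_target", "lrr_no_target",
                                  "nonlrr_preceding_target", "all_introns"),
                                c("n0", "n1", "n2")))
  following <- acc
  for (g in genes) {
    ph <- intron_phases(g)
    if (!length(ph)) next
    len <- exon_lengths(g)
    is_lrr <- isTRUE(unname(lrr_flags[g$gene_id]))
    acc["all_introns", ] <- acc["all_introns", ] + tabulate(ph + 1L, 3L)
    # intron i precedes exon i+1; intron i follows exon i
    pre_target <- ph[len[-1L] == target_len]
    fol_target <- ph[len[-length(len)] == target_len]
    if (is_lrr) {
      if (any(len == target_len)) {
        acc["lrr_preceding_target", ] <- acc["lrr_preceding_target", ] +
          tabulate(pre_target + 1L, 3L)
        following["lrr_preceding_target", ] <- following["lrr_preceding_target", ] +
          tabulate(fol_target + 1L, 3L)
      } else {
        acc["lrr_no_target", ] <- acc["lrr_no_target", ] + tabulate(ph + 1L, 3L)
      }
    } else {
      acc["nonlrr_preceding_target", ] <- acc["nonlrr_preceding_target", ] +
        tabulate(pre_target + 1L, 3L)
    }
  }
  n <- rowSums(acc)
  data.frame(stratum = rownames(acc), n0 = acc[, 1L], n1 = acc[, 2L], n2 = acc[, 3L],
             n = n, phase2_pct = ifelse(n > 0, 100 * acc[, 3L] / n, NA_real_),
             following_n2 = following[, 3L], row.names = NULL)
}

#' 1-bp length histogram with peak detection
#'
#' Builds a 1-bp-bin histogram of positive integer lengths and detects peaks
#' on a centered moving-average smooth (window `smooth_window`). A peak is a
#' local maximum of the smoothed series whose topographic prominence is at
#' least 10% of the global smoothed maximum; the peak is reported at the
#' raw-count mode within its plateau. The primary peak is the highest;
#' secondary peaks are ordered by decreasing prominence.
#'
#' @param values Positive integer lengths.
#' @param smooth_window Moving-average window (odd).
#' @return Object of class `length_histogram`: list with `counts` (named
#'   vector), `n`, `primary_peak`, `secondary_peaks`.
#' @export
length_histogram <- function(values, smooth_window = 5L) {
  if (!length(values)) stop("length_histogram: empty input")
  values <- as.integer(values)
  if (any(values <= 0L)) stop("length_histogram: values must be positive")
  lo <- min(values); hi <- max(values)
  counts <- tabulate(values - lo + 1L, hi - lo + 1L)
  names(counts) <- seq(lo, hi)
  # centered moving average with zero padding
  h <- smooth_window %/% 2L
  padded <- c(rep(0, h), counts, rep(0, h))
  sm <- vapply(seq_along(counts), function(i) mean(padded[i:(i + 2L * h)]), numeric(1))
  peaks <- find_peaks(sm, counts, half_window = h)
  if (length(peaks$pos)) {
    vals <- as.integer(names(counts)[peaks$pos])
    primary <- vals[which.max(peaks$height + peaks$raw / 1e9)]
    ord <- order(-peaks$prominence)
    secondary <- setdiff(vals[ord], primary)
  } else {
    primary <- as.integer(names(which.max(counts)))
    secondary <- integer(0)
  }
  structure(list(counts = counts, n = length(values), primary_peak = primary,
                 secondary_peaks = secondary),
            class = "length_histogram")
}

# local maxima (plateau-aware) of smoothed series sm with topographic
# prominence; each peak is refined to the raw-count mode within the
# smoothing window, so sharp modes are reported at their exact value.
find_peaks <- function(sm, raw, min_prom_frac = 0.10, half_window = 2L) {
  n <- length(sm)
  if (n == 1L) return(list(pos = 1L, height = sm, prominence = sm, raw = raw))
  # plateau runs of equal smoothed value
  r <- rle(sm)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  k <- length(r$values)
  is_max <- vapply(seq_len(k), function(i) {
    left_ok <- i == 1L || r$values[i - 1L] < r$values[i]
    right_ok <- i == k || r$values[i + 1L] < r$values[i]
    left_ok && right_ok
  }, logical(1))
  idx <- which(is_max)
  pos <- vapply(idx, function(i) {
    span <- starts[i]:ends[i]
    span[which.max(raw[span])]
  }, integer(1))
  height <- sm[pos]
  # topographic prominence: height minus the key saddle toward higher ground
  prom <- vapply(seq_along(pos), function(j) {
    p <- pos[j]; hgt <- height[j]
    saddles <- numeric(0)
    hi_l <- which(sm[seq_len(p)] > hgt)
    if (length(hi_l)) saddles <- c(saddles, min(sm[max(hi_l):p]))
    hi_r <- p - 1L + which(sm[p:n] > hgt)
    if (length(hi_r)) saddles <- c(saddles, min(sm[p:min(hi_r)]))
    if (!length(saddles)) hgt else hgt - max(saddles)
  }, numeric(1))
  # refine to the raw mode within the smoothing window
  pos <- vapply(pos, function(p) {
    span <- max(1L, p - half_window):min(n, p + half_window)
    span[which.max(raw[span])]
  }, integer(1))
  keep <- prom >= min_prom_frac * max(sm) & raw[pos] > 0L
  pos <- pos[keep]; height <- height[keep]; prom <- prom[keep]
  # de-duplicate peaks refined to the same value, keeping the most prominent
  ord <- order(-prom)
  first <- !duplicated(pos[ord])
  sel <- ord[first]
  sel <- sel[order(sel)]
  list(pos = pos[sel], height = height[sel], prominence = prom[sel],
       raw = raw[pos[sel]])
}

#' @export
print.length_histogram <- function(x, ...) {
  cat(sprintf("<length_histogram> n=%d, primary peak %d", x$n, x$primary_peak))
  if (length(x$secondary_peaks))
    cat(", secondary ", paste(x$secondary_peaks, collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

#' @export
plot.length_histogram <- function(x, ...) {
  v <- as.integer(names(x$counts))
  plot(v, x$counts, type = "h", xlab = "length (bp)", ylab = "count", ...)
  abline(v = x$primary_peak, col = "red", lty = 2)
  if (length(x$secondary_peaks)) abline(v = x$secondary_peaks, col = "blue", lty = 3)
  invisible(x)
}

#' Repeat-unit lengths within exact-length exon arrays
#'
#' For each `target_len` exon inside an array (as found by
#' [find_exact_length_arrays()]) that has a following intron, the repeat unit
#' length is exon length + following intron length. In *T. thermophila*
#' group III LRR genes these units are typically 347 bp
#' (90-bp exon + 257-bp intron).
#'
#' @param gene A [gene_model()].
#' @param target_len Array exon length.
#' @return Integer vector of unit lengths (possibly empty).
#' @export
repeat_unit_lengths <- function(gene, target_len = 90L) {
  runs <- find_exact_length_arrays(gene, target_len = target_len)
  if (!nrow(runs)) return(integer(0))
  il <- intron_lengths(gene)
  n_ex <- nrow(gene$exons)
  out <- integer(0)
  for (i in seq_len(nrow(runs))) {
    ex_idx <- runs$start_exon[i]:(runs$start_exon[i] + runs$run_length[i] - 1L)
    ex_idx <- ex_idx[ex_idx < n_ex]  # need a following intron
    out <- c(out, target_len + il[ex_idx])
  }
  out
}

#' Translate a CDS
#'
#' @param gene A [gene_model()] (or a bare CDS string).
#' @param genome Genome from [read_fasta()]; ignored when `gene` is a string.
#' @param code Genetic code (see [genetic_code()]); the ciliate nuclear code
#'   (TAA/TAG = Gln) is the default.
#' @return Protein string. An internal stop under the selected code truncates
#'   the translation with a warning and sets attribute `internal_stop = TRUE`.
#' @export
translate_cds <- function(gene, genome = NULL, code = "ciliate") {
  cds <- if (is.character(gene)) gene else cds_sequence(gene, genome)
  tab <- genetic_code(code)
  codons <- split_codons(cds)
  aa <- unname(tab[codons])
  aa[is.na(aa)] <- "X"
  stop_at <- which(aa == "*")
  internal <- length(stop_at) && any(stop_at < length(aa))
  if (internal) {
    warning("internal stop codon at codon ", stop_at[1L], "; translation truncated")
    aa <- aa[seq_len(stop_at[1L] - 1L)]
  } else if (length(stop_at)) {
    aa <- aa[-length(aa)]  # trailing stop dropped
  }
  structure(paste(aa, collapse = ""), internal_stop = internal)
}

#' Codon frame of an internal exon
#'
#' Given an exon's length and the phases of its flanking introns, returns the
#' number of complete codons fully inside the exon and the number of amino
#' acids to which the exon contributes at least one nucleotide (junction
#' codons shared with the neighbouring exons included). For the canonical
#' 90-bp exon flanked by phase-2 introns this is 29 full codons (nucleotides
#' 2..88) touching 31 amino acids.
#'
#' @param length Exon length (bp).
#' @param phase_before Phase of the preceding intron (0/1/2).
#' @param phase_after Phase of the following intron (0/1/2).
#' @return Named integer vector `c(n_full_codons=, n_touched_aa=)`.
#' @export
exon_translation_frame <- function(length, phase_before, phase_after) {
  if (is.na(phase_before) || is.na(phase_after))
    stop("terminal exon: flanking intron phases undefined")
  stopifnot(phase_before %in% 0:2, phase_after %in% 0:2)
  lead <- (3L - phase_before) %% 3L   # nt completing the upstream junction codon
  if ((length - lead - phase_after) %% 3L != 0L)
    stop("inconsistent length/phase combination")
  n_full <- (length - lead - phase_after) %/% 3L
  n_touched <- n_full + (phase_before != 0L) + (phase_after != 0L)
  c(n_full_codons = n_full, n_touched_aa = as.integer(n_touched))
}

#' GC content of a sequence
#'
#' Computed as (#G + #C) / (length - #N); an all-N sequence is an error.
#'
#' @param sequence Nucleotide string.
#' @return Fraction in \[0, 1\].
#' @export
gc_content <- function(sequence) {
  ch <- utf8ToInt(toupper(sequence))
  n_n <- sum(ch == DNA_CODES["N"])
  denom <- length(ch) - n_n
  if (denom == 0L) stop("gc_content: sequence has no non-N bases")
  sum(ch == DNA_CODES["G"] | ch == DNA_CODES["C"]) / denom
}

#' Leucine codon usage
#'
#' Frequencies of the six leucine codons (TTA, TTG, CTT, CTC, CTA, CTG) among
#' all leucine codons of the genes' CDSs.
#'
#' @param genes List of [gene_model()] objects.
#' @param genome Genome from [read_fasta()].
#' @return Named numeric vector over the six codons, summing to 1 (all zero
#'   if no leucine codon occurs).
#' @export
leucine_codon_usage <- function(genes, genome) {
  counts <- setNames(numeric(6), LEUCINE_CODONS)
  for (g in genes) {
    codons <- split_codons(cds_sequence(g, genome))
    t <- table(codons[codons %in% LEUCINE_CODONS])
    counts[names(t)] <- counts[names(t)] + as.numeric(t)
  }
  tot <- sum(counts)
  if (tot > 0) counts / tot else counts
}
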