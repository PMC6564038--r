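test_that("intron phases are cumulative CDS length mod 3", {
  expect_equal(intron_phases(make_gene(c(11L, 90L, 90L, 7L))), c(2L, 2L, 2L))
  expect_equal(intron_phases(make_gene(c(9L, 9L))), 0L)
  expect_equal(intron_phases(make_gene(300L)), integer(0))
  # chain consistency on random gene models, both strands
  set.seed(5)
  for (i in 1:25) {
    k <- sample(2:9, 1L)
    lens <- sample(30:200, k, replace = TRUE)
    lens[1L] <- lens[1L] + (3L - sum(lens) %% 3L) %% 3L
    g <- make_gene(lens, strand = sample(c("+", "-"), 1L))
    ph <- intron_phases(g)
    expect_equal(ph[1L], lens[1L] %% 3L)
    if (k > 2L)
      expect_equal(ph[-1L], (ph[-(k - 1L)] + lens[2:(k - 1L)]) %% 3L)
  }
})

test_that("exact-length arrays are maximal runs of at least min_run exons", {
  r <- find_exact_length_arrays(make_gene(c(45L, 90L, 90L, 90L, 90L, 60L)))
  expect_equal(r$start_exon, 2L)
  expect_equal(r$run_length, 4L)
  r <- find_exact_length_arrays(make_gene(c(90L, 90L, 45L, 90L, 90L, 90L)))
  expect_equal(r$start_exon, 4L)
  expect_equal(r$run_length, 3L)
  r <- find_exact_length_arrays(make_gene(c(90L, 90L, 90L)))
  expect_equal(r, data.frame(start_exon = 1L, run_length = 3L))
  # maximality: extending any reported run breaks the exact-length condition
  set.seed(8)
  for (i in 1:20) {
    lens <- sample(c(90L, 90L, 90L, 45L, 120L), 12L, replace = TRUE)
    lens[1L] <- lens[1L] + (3L - sum(lens) %% 3L) %% 3L
    g <- make_gene(lens)
    r <- find_exact_length_arrays(g)
    for (j in seq_len(nrow(r))) {
      s <- r$start_exon[j]; e <- s + r$run_length[j] - 1L
      if (s > 1L) expect_false(lens[s - 1L] == 90L)
      if (e < length(lens)) expect_false(lens[e + 1L] == 90L)
    }
  }
})

test_that("phase bias report stratifies introns correctly", {
  g_lrr <- make_gene(c(11L, 90L, 90L, 7L), id = "L1")
  flags <- c(L1 = TRUE)
  pb <- phase_bias_report(list(g_lrr), flags)
  s1 <- pb[pb$stratum == "lrr_preceding_target", ]
  expect_equal(s1$n2, 2L)        # introns preceding exons 2 and 3
  expect_equal(s1$n, 2L)
  expect_equal(s1$phase2_pct, 100)
  expect_equal(pb$n[pb$stratum == "all_introns"], 3L)

  # no LRR genes: stratum 1 empty, percentage undefined
  g_bg <- make_gene(c(60L, 90L, 60L), id = "B1")
  pb <- phase_bias_report(list(g_bg), c(B1 = FALSE))
  expect_equal(pb$n[pb$stratum == "lrr_preceding_target"], 0L)
  expect_true(is.na(pb$phase2_pct[pb$stratum == "lrr_preceding_target"]))
  expect_equal(pb$n[pb$stratum == "nonlrr_preceding_target"], 1L)
})

test_that("length histograms detect primary and secondary peaks", {
  h <- length_histogram(rep(56L, 100))
  expect_equal(h$primary_peak, 56L)
  expect_length(h$secondary_peaks, 0L)

  h <- length_histogram(c(rep(257L, 80), rep(122L, 20)))
  expect_equal(h$primary_peak, 257L)
  expect_equal(h$secondary_peaks, 122L)

  h <- length_histogram(c(rep(90L, 50), rep(91L, 2), 89L))
  expect_equal(h$primary_peak, 90L)

  expect_error(length_histogram(integer(0)), "empty")

  # permutation invariance
  set.seed(3)
  v <- c(rep(347L, 60), rep(212L, 25), sample(40:60, 30, replace = TRUE))
  h1 <- length_histogram(v)
  h2 <- length_histogram(sample(v))
  expect_equal(h1$primary_peak, h2$primary_peak)
  expect_equal(h1$secondary_peaks, h2$secondary_peaks)
})

test_that("repeat units add exon and following intron lengths", {
  g <- make_gene(c(90L, 90L, 90L), introns = c(257L, 257L))
  expect_equal(repeat_unit_lengths(g), c(347L, 347L))
  g <- make_gene(c(90L, 90L, 90L), introns = c(122L, 257L))
  expect_equal(repeat_unit_lengths(g), c(212L, 347L))
  expect_equal(repeat_unit_lengths(make_gene(c(60L, 90L, 90L))), integer(0))
})

test_that("translation honours the ciliate and standard codes", {
  expect_equal(as.character(translate_cds("TTATAA")), "LQ")
  expect_warning(p <- translate_cds("TTATAATTA", code = "standard"),
                 "internal stop")
  expect_equal(as.character(p), "L")
  expect_true(attr(p, "internal_stop"))
  expect_equal(as.character(translate_cds(strrep("CTT", 30))), strrep("L", 30))
})

test_that("exon translation frame counts full and touched codons", {
  expect_equal(unname(exon_translation_frame(90L, 2L, 2L)), c(29L, 31L))
  expect_equal(unname(exon_translation_frame(90L, 0L, 0L)), c(30L, 30L))
  expect_equal(unname(exon_translation_frame(91L, 2L, 0L)), c(30L, 31L))
  expect_error(exon_translation_frame(90L, NA, 2L), "terminal exon")
  # cross-check against phases computed from a real gene model
  g <- make_gene(c(11L, 90L, 90L, 7L))
  ph <- intron_phases(g)
  fr <- exon_translation_frame(90L, ph[1L], ph[2L])
  expect_equal(unname(fr), c(29L, 31L))
})

test_that("translation is consistent exon-by-exon with computed phases", {
  # stitching junction codons with the computed phases reproduces the
  # full-CDS translation
  set.seed(21)
  for (i in 1:10) {
    k <- sample(3:6, 1L)
    lens <- sample(30:120, k, replace = TRUE)
    lens[1L] <- lens[1L] + (3L - sum(lens) %% 3L) %% 3L
    exon_seq <- vapply(lens, function(L)
      paste(sample(c("A", "C", "T"), L, replace = TRUE), collapse = ""),
      character(1))
    cds <- paste(exon_seq, collapse = "")
    full <- as.character(suppressWarnings(translate_cds(cds)))
    stitched <- character(0)
    carry <- ""
    for (j in seq_len(k)) {
      s <- paste0(carry, exon_seq[j])
      n_full <- nchar(s) %/% 3L
      stitched <- c(stitched,
                    as.character(suppressWarnings(
                      translate_cds(substr(s, 1L, 3L * n_full)))))
      carry <- substr(s, 3L * n_full + 1L, nchar(s))
    }
    expect_equal(paste(stitched, collapse = ""), full)
  }
})

test_that("gc content and leucine codon usage", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("AATT"), 0)
  expect_equal(gc_content("ANGN"), 0.5)
  expect_error(gc_content("NNN"), "no non-N")

  genome <- c(s1 = strrep("TTA", 30))
  g <- gene_model("g1", "spA", "s1", "+", cbind(0L, 90L))
  u <- leucine_codon_usage(list(g), genome)
  expect_equal(unname(u["TTA"]), 1)
  expect_equal(sum(u), 1)
})
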