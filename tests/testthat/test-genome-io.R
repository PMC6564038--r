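test_that("read_fasta normalizes case, U and ambiguity codes", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "acgt"), f)
  expect_equal(unname(read_fasta(f)["s1"]), "ACGT")

  writeLines(c(">s1", "ACRT"), f)
  expect_message(g <- read_fasta(f), "1 non-ACGTN")
  expect_equal(unname(g["s1"]), "ACNT")

  writeLines(c(">s1", "ACGU"), f)
  expect_equal(unname(read_fasta(f)["s1"]), "ACGT")

  writeLines(c(">s1", "ACGT", ">s1", "AAAA"), f)
  expect_error(read_fasta(f), "duplicate scaffold id: s1")
})

test_that("fasta round-trips through write_fasta", {
  set.seed(1)
  g <- setNames(random_seqs(3, 211), c("a", "b", "c"))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(g, f)
  back <- read_fasta(f)
  expect_equal(names(back), names(g))
  expect_equal(as.character(back), as.character(g))
})

gff_lines <- function(...) c("##gff-version 3", ...)

test_that("read_gff3 converts 1-based inclusive coordinates and strand", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff_lines(
    "s1\tx\tgene\t1\t21\t.\t+\t.\tID=gA",
    "s1\tx\tmRNA\t1\t21\t.\t+\t.\tID=gA.t1;Parent=gA",
    "s1\tx\tCDS\t1\t9\t.\t+\t.\tID=c1;Parent=gA.t1",
    "s1\tx\tCDS\t13\t21\t.\t+\t.\tID=c2;Parent=gA.t1"), f)
  g <- read_gff3(f)[["gA"]]
  expect_equal(unname(g$exons[, "start"]), c(0L, 12L))
  expect_equal(unname(g$exons[, "end"]), c(9L, 21L))
  expect_equal(exon_lengths(g), c(9L, 9L))

  # minus strand: transcription order is right-to-left
  writeLines(gff_lines(
    "s1\tx\tgene\t10\t30\t.\t-\t.\tID=gB",
    "s1\tx\tmRNA\t10\t30\t.\t-\t.\tID=gB.t1;Parent=gB",
    "s1\tx\tCDS\t10\t18\t.\t-\t.\tID=c1;Parent=gB.t1",
    "s1\tx\tCDS\t22\t30\t.\t-\t.\tID=c2;Parent=gB.t1"), f)
  g <- read_gff3(f)[["gB"]]
  expect_equal(unname(g$exons[1L, ]), c(21L, 30L))
  expect_equal(unname(g$exons[2L, ]), c(9L, 18L))
})

test_that("read_gff3 keeps the longest-CDS transcript and flags bad CDS lengths", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff_lines(
    "s1\tx\tgene\t1\t400\t.\t+\t.\tID=gA",
    "s1\tx\tmRNA\t1\t400\t.\t+\t.\tID=gA.t2;Parent=gA",
    "s1\tx\tCDS\t1\t90\t.\t+\t.\tID=c1;Parent=gA.t2",
    "s1\tx\tmRNA\t1\t400\t.\t+\t.\tID=gA.t1;Parent=gA",
    "s1\tx\tCDS\t1\t90\t.\t+\t.\tID=c2;Parent=gA.t1",
    "s1\tx\tCDS\t101\t190\t.\t+\t.\tID=c3;Parent=gA.t1"), f)
  g <- read_gff3(f)[["gA"]]
  expect_equal(sum(exon_lengths(g)), 180L)

  writeLines(gff_lines(
    "s1\tx\tgene\t1\t10\t.\t+\t.\tID=gBad",
    "s1\tx\tmRNA\t1\t10\t.\t+\t.\tID=gBad.t1;Parent=gBad",
    "s1\tx\tCDS\t1\t10\t.\t+\t.\tID=c1;Parent=gBad.t1"), f)
  expect_warning(models <- read_gff3(f), "not divisible by 3")
  expect_length(models, 0L)
})

test_that("gff3 round trip reproduces gene models exactly", {
  b <- make_fixture("toy")
  sp <- b$species[[1L]]
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(b$genes[[sp]], f)
  back <- read_gff3(f, species = sp)
  expect_identical(names(back), sort(names(b$genes[[sp]])))
  for (id in names(back)) {
    a <- b$genes[[sp]][[id]]; z <- back[[id]]
    expect_identical(unname(z$exons), unname(a$exons))
    expect_identical(z$strand, a$strand)
    expect_identical(z$scaffold, a$scaffold)
  }
})

test_that("coordinate conversion is self-inverse", {
  set.seed(99)
  start0 <- sample.int(1e6, 1e4, replace = TRUE) - 1L
  end0 <- start0 + sample.int(500, 1e4, replace = TRUE)
  gff_start <- start0 + 1L
  gff_end <- end0
  expect_identical(gff_start - 1L, start0)
  expect_identical(gff_end, end0)
  expect_true(all(gff_end - gff_start + 1L == end0 - start0))
})

test_that("read_mask_table handles both dialects and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("s1\t100\t250\tCRS3\t812\t+", f)
  h <- read_mask_table(f, "bed6+family")
  expect_equal(h$start, 100L)
  expect_equal(h$end, 250L)
  expect_equal(h$family, "CRS3")
  expect_equal(h$score, 812)

  writeLines(c("   SW   perc perc perc  query", "score  div. del. ins.  sequence", "",
               "812 12.1 0.1 0.2 s1 101 250 (100) + CRS3 Unknown 1 150 (0) 1"), f)
  h <- read_mask_table(f, "repeatmasker_out")
  expect_equal(h$start, 100L)
  expect_equal(h$end, 250L)
  expect_equal(h$score, 812)

  writeLines(character(0), f)
  expect_equal(nrow(read_mask_table(f, "bed6+family")), 0L)

  writeLines("s1\t1\t5\tCRS1\t-3\t+", f)
  expect_error(read_mask_table(f, "bed6+family"), "negative")
  expect_error(read_mask_table(f, "nope"), "arg")
})

test_that("orthomcl groups parse with singleton detection and error paths", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("c1: A|g1 A|g2 B|g3", f)
  uni <- list(A = c("g1", "g2", "g4"), B = "g3")
  cl <- read_orthomcl_groups(f, uni)
  expect_equal(length(cl$clusters), 1L)
  expect_equal(sort(unlist(cl$clusters$c1$A)), c("g1", "g2"))
  expect_equal(cl$singletons$A, "g4")
  expect_equal(cl$singletons$B, character(0))

  writeLines(c("c1: A|g1", "c2: A|g1"), f)
  expect_error(read_orthomcl_groups(f, uni), "two clusters")

  writeLines("c1: Z|g9", f)
  expect_error(read_orthomcl_groups(f, uni), "unknown species")

  writeLines(character(0), f)
  cl <- read_orthomcl_groups(f, uni)
  expect_equal(length(cl$clusters), 0L)
  expect_equal(cl$singletons$A, uni$A)
})

test_that("value tables validate their kind", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tvalue", "g1\t0.5", "g2\t2.25"), f)
  v <- read_value_table(f, "ka_ks")
  expect_equal(unname(v["g2"]), 2.25)
  writeLines(c("gene_id\tvalue", "g1\t-1"), f)
  expect_error(read_value_table(f, "fpkm"), "negative")
})

test_that("chromosome landscapes enforce interval invariants", {
  expect_error(chromosome_landscape(
    c(chr1 = 100L), data.frame(chrom = "chr1", start = 10L, end = 20L),
    data.frame(chrom = "chr1", start = c(5L, 8L), end = c(10L, 12L))),
    "overlapping IES")
  expect_error(chromosome_landscape(
    c(chr1 = 100L), data.frame(chrom = "chr1", start = 90L, end = 120L),
    data.frame(chrom = character(0), start = integer(0), end = integer(0))),
    "centromere out of bounds")
})
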