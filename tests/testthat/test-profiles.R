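test_that("exon matrices collect exactly-90-bp exons on the coding strand", {
  b <- make_fixture("toy")
  sp <- "thermophila"
  genes <- b$genes[[sp]]
  tg <- b$truth_genes
  meta <- data.frame(gene_id = tg$gene_id, group = tg$group,
                     family = tg$family, species = tg$species)
  m <- build_exon_matrix(genes, b$genomes[[sp]], meta,
                         group = c("II", "III"), species = sp)
  n_expected <- sum(vapply(genes[m$meta$gene_id[!duplicated(m$meta$gene_id)]],
                           function(g) sum(exon_lengths(g) == 90L), integer(1)))
  expect_equal(length(m$seqs), n_expected)
  expect_true(all(nchar(m$seqs) == 90L))
  # empty filter errors and names the filter
  expect_error(build_exon_matrix(genes, b$genomes[[sp]], meta,
                                 group = "nope"), "group=nope")
})

test_that("position profiles normalize and consensus breaks ties by order", {
  m <- exon_matrix(c(strrep("A", 90), strrep("A", 90)))
  p <- position_profile(m, "nt")
  expect_true(all(abs(colSums(p) - 1) < 1e-9))
  expect_equal(consensus(p), strrep("A", 90))

  m <- exon_matrix(c(strrep("A", 90), strrep("C", 90)))
  expect_equal(consensus(position_profile(m, "nt")), strrep("A", 90))

  # uniform random rows: every frequency near 0.25
  set.seed(2)
  m <- exon_matrix(random_seqs(4000, 90))
  p <- position_profile(m, "nt")
  expect_true(all(abs(p - 0.25) < 0.05))
})

test_that("amino-acid view drops junction nucleotides and folds TAA/TAG to Q", {
  row <- paste0("A", strrep("TTA", 28), "TAA", "TT")
  m <- exon_matrix(c(row, row))
  aa <- exon_matrix_aa(m)
  expect_equal(ncol(aa), 29L)
  expect_equal(unname(aa[1L, 29L]), "Q")
  expect_true(all(aa[, 1:28] == "L"))
})

test_that("codon index maps exon nucleotide positions into the 29-aa frame", {
  expect_equal(codon_index_of_nt(48L), 16L)
  expect_equal(codon_index_of_nt(2L), 1L)
  expect_equal(codon_index_of_nt(c(36L, 48L, 66L, 75L, 81L, 87L)),
               c(12L, 16L, 22L, 25L, 27L, 29L))
  expect_error(codon_index_of_nt(1L), "junction")
  expect_error(codon_index_of_nt(89L), "junction")
})

test_that("conserved positions respect the frequency threshold", {
  m <- exon_matrix(c(paste0("A", strrep("TTA", 29), "TT"),
                     paste0("A", strrep("TTA", 29), "TT")))
  p <- position_profile(m, "aa")
  expect_equal(conserved_positions(p, "L", 0.5), 1:29)
  expect_equal(length(conserved_positions(p, "L", 1.01)), 0L)
})

test_that("two-sample logo calls strong enrichment and is self-consistent", {
  set.seed(4)
  base <- random_seqs(1, 90)
  a_seqs <- random_seqs(100, 90, templates = base, mut = 0L)
  # force column 5 all-A in A, 50/50 A/C in B
  b_seqs <- a_seqs
  substr(a_seqs, 5L, 5L) <- "A"
  substr(b_seqs, 5L, 5L) <- rep(c("A", "C"), 50)
  A <- exon_matrix(a_seqs); B <- exon_matrix(b_seqs)
  calls <- two_sample_logo(A, B, "nt")
  hit <- calls[calls$position == 5L & calls$symbol == "A", ]
  expect_equal(hit$direction, "enriched")
  expect_lt(hit$p, 1e-5)
  expect_equal(hit$effect, 0.5)

  # identical samples: no calls, zero effects
  expect_equal(nrow(two_sample_logo(A, A, "nt")), 0L)

  # swapping samples swaps enrichment and depletion
  swapped <- two_sample_logo(B, A, "nt")
  s_hit <- swapped[swapped$position == 5L & swapped$symbol == "A", ]
  expect_equal(s_hit$direction, "depleted")

  # underpowered samples warn
  expect_warning(two_sample_logo(exon_matrix(a_seqs[1:5]), B, "nt"),
                 "underpowered")
})

test_that("near-identity clustering equals the all-pairs oracle", {
  set.seed(6)
  # designed cases
  s <- strrep("ACGT", 22L) |> paste0("AC")
  s2 <- s; substr(s2, 1L, 3L) <- "TTT"   # distance 3
  m <- exon_matrix(c(s, s, s2))
  cl <- cluster_near_identical(m, 2L)
  expect_equal(canonical_partition(cl$membership),
               list(c(1L, 2L), 3L))

  # chain a-b 2, b-c 2, a-c 4: single linkage joins all three
  a <- s
  b <- a; substr(b, 10L, 11L) <- "TT"
  c_ <- b; substr(c_, 30L, 31L) <- "GG"
  cl <- cluster_near_identical(exon_matrix(c(a, b, c_)), 2L)
  expect_equal(length(cl$clusters), 1L)

  # random instances against the igraph components oracle
  for (i in 1:3) {
    seqs <- random_seqs(60, 90, templates = random_seqs(4, 90), mut = 3L)
    m <- exon_matrix(seqs)
    cl <- cluster_near_identical(m, 2L)
    expect_equal(canonical_partition(cl$membership),
                 canonical_partition(oracle_clusters(seqs, 2L)))
    # permutation invariance: map the permuted clustering back to the
    # original row indices and compare partitions
    perm <- sample(length(seqs))
    cl_p <- cluster_near_identical(exon_matrix(seqs[perm]), 2L)
    back <- cl_p$membership[match(seq_along(seqs), perm)]
    expect_equal(canonical_partition(back), canonical_partition(cl$membership))
  }
})

test_that("consensus distance matrices are symmetric with zero diagonal", {
  set.seed(9)
  base <- random_seqs(1, 90)
  substr(base, 1L, 9L) <- strrep("AT", 5L) |> substr(1L, 9L)
  g1 <- exon_matrix(rep(base, 5))
  far <- base
  substr(far, 1L, 9L) <- strrep("GC", 5L) |> substr(1L, 9L)
  g2 <- exon_matrix(rep(far, 5))
  g3 <- exon_matrix(rep(base, 5))
  d <- family_consensus_distance_matrix(list(a = g1, b = g2, c = g3))
  expect_equal(dim(d), c(3L, 3L))
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "b"], 0.1)
  expect_equal(d, t(d))
  expect_warning(
    family_consensus_distance_matrix(list(a = g1, b = g2,
                                          tiny = exon_matrix(base))),
    "excluding")
  f <- withr::local_tempfile(fileext = ".phylip")
  write_phylip_dist(d, f)
  lines <- readLines(f)
  expect_match(lines[1L], "^\\s+3$")
  expect_length(lines, 4L)
})
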