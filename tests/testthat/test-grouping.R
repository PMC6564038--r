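domains <- data.frame(
  gene_id = c("g1", "g2", "g3", "g3"),
  domain = c("Leucine-rich repeat", "Protein kinase", "Protein kinase",
             "Leucine-rich repeat protein"),
  stringsAsFactors = FALSE)

test_that("LRR genes are identified by name substring or exact accession", {
  expect_equal(identify_lrr_genes(domains), c("g1", "g3"))
  expect_equal(identify_lrr_genes(
    data.frame(gene_id = "g9", domain = "PF13855"), lrr_labels = "PF13855"),
    "g9")
  # accession-like labels must match exactly
  expect_equal(identify_lrr_genes(
    data.frame(gene_id = "g9", domain = "PF138550"), lrr_labels = "PF13855"),
    character(0))
  expect_warning(r <- identify_lrr_genes(domains[0, ]), "empty domain table")
  expect_equal(r, character(0))
})

mask_hit <- function(scaffold, start, end, family, score)
  data.frame(scaffold = scaffold, start = start, end = end, family = family,
             score = score, stringsAsFactors = FALSE)

test_that("group classification follows exon presence and masking", {
  no_hits <- mask_hit(character(0), integer(0), integer(0), character(0),
                      numeric(0))
  g_i <- make_gene(c(60L, 75L), id = "a")
  g_ii <- make_gene(c(90L, 90L, 90L), id = "b")
  g_iii <- make_gene(c(90L, 90L, 90L), id = "c", scaffold = "s2")
  hits <- mask_hit("s2", 0L, 300L, "CRS2", 700)
  asn <- classify_groups(list(g_i, g_ii, g_iii), rbind(hits))
  expect_equal(asn$group, c("I", "II", "III"))
  expect_equal(asn$best_family[3L], "CRS2")
  expect_true(asn$masked_bp[3L] >= 50)

  asn <- classify_groups(list(g_i, g_ii), no_hits)
  expect_equal(asn$group, c("I", "II"))

  # masked gene without 90-bp exons is surfaced, not forced into a group
  g_u <- make_gene(c(60L, 75L), id = "d", scaffold = "s2")
  asn <- classify_groups(list(g_u), hits)
  expect_equal(asn$group, "unclassified")

  # below the masked-bp threshold a hit does not flip the group
  tiny <- mask_hit("s1", 0L, 30L, "CRS2", 900)
  asn <- classify_groups(list(g_ii), tiny)
  expect_equal(asn$group, "II")
})

test_that("best family maximizes score sum with bp and lexicographic ties", {
  g <- make_gene(c(90L, 90L, 90L), id = "x")
  hits <- rbind(mask_hit("s1", 0L, 200L, "CRS1", 500),
                mask_hit("s1", 0L, 200L, "CRS2", 700))
  expect_equal(assign_best_family(g, hits), "CRS2")

  hits <- rbind(mask_hit("s1", 0L, 100L, "CRS1", 400),
                mask_hit("s1", 120L, 220L, "CRS1", 400),
                mask_hit("s1", 0L, 200L, "CRS2", 700))
  expect_equal(assign_best_family(g, hits), "CRS1")  # 800 beats 700

  hits <- rbind(mask_hit("s1", 0L, 200L, "CRS2", 700),
                mask_hit("s1", 0L, 200L, "CRS1", 700))
  expect_equal(assign_best_family(g, hits), "CRS1")  # lexicographic tie-break

  expect_error(assign_best_family(g, mask_hit("s9", 0L, 10L, "CRS1", 5)),
               "no overlapping mask hits")
})

test_that("masking is monotone: adding hits never demotes a gene", {
  set.seed(14)
  g <- make_gene(c(90L, 90L, 90L), id = "m")
  hits <- mask_hit("s1", 0L, 300L, "CRS3", 500)
  base <- classify_groups(list(g), hits)$group
  expect_equal(base, "III")
  for (i in 1:10) {
    extra <- mask_hit("s1", sample(0:200, 1L), sample(210:400, 1L),
                      sample(paste0("CRS", 1:8), 1L), runif(1, 10, 1000))
    expect_equal(classify_groups(list(g), rbind(hits, extra))$group, "III")
  }
})

test_that("every LRR gene receives exactly one group label (toy fixture)", {
  b <- make_fixture("toy")
  lrr <- identify_lrr_genes(b$domains)
  for (sp in b$species) {
    genes <- b$genes[[sp]][intersect(names(b$genes[[sp]]), lrr)]
    mask <- b$mask[[sp]]
    asn <- classify_groups(genes, mask[grepl("^CRS", mask$family), ])
    expect_equal(nrow(asn), length(genes))
    expect_true(all(asn$group %in% c("I", "II", "III", "unclassified")))
    expect_equal(anyDuplicated(asn$gene_id), 0L)
  }
})

test_that("group summary contrasts species-specific composition", {
  genes <- c(lapply(sprintf("a%02d", 1:100), function(id)
               make_gene(c(60L, 75L), id = id)),
             lapply(sprintf("b%02d", 1:100), function(id)
               make_gene(c(90L, 90L, 90L), id = id, scaffold = "s2")))
  names(genes) <- vapply(genes, `[[`, character(1), "gene_id")
  hits <- mask_hit("s2", 0L, 600L, "CRS1", 500)
  asn <- classify_groups(genes, hits)
  expect_equal(as.integer(table(asn$group)[c("I", "III")]), c(100L, 100L))
  # 10/90 vs 80/20 species-specific split: strongly significant
  specific <- c(sprintf("a%02d", 1:10), sprintf("b%02d", 1:80))
  s <- group_summary(asn, genes, species_specific = specific)
  p <- s$pairwise_tests$p[s$pairwise_tests$group_a == "I" &
                            s$pairwise_tests$group_b == "III"]
  expect_lt(p, 1e-5)
  expect_equal(s$table$specific_fraction[s$table$group == "I"], 0.1)
  # identical compositions: no significant difference
  s2 <- group_summary(asn, genes,
                      species_specific = c(sprintf("a%02d", 1:10),
                                           sprintf("b%02d", 1:10)))
  p2 <- s2$pairwise_tests$p[s2$pairwise_tests$group_a == "I" &
                              s2$pairwise_tests$group_b == "III"]
  expect_gt(p2, 0.9)
  # empty group II yields count 0 and skipped tests
  expect_equal(s$table$n[s$table$group == "II"], 0)
  expect_true(is.na(s$pairwise_tests$p[s$pairwise_tests$group_a == "I" &
                                         s$pairwise_tests$group_b == "II"]))
})
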