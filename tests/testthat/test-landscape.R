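simple_land <- function() {
  chromosome_landscape(
    c(chr1 = 100L),
    data.frame(chrom = "chr1", start = 48L, end = 52L),
    data.frame(chrom = "chr1", start = 10L, end = 20L))
}

test_that("MDS coordinates subtract upstream IES bp and flag interior points", {
  land <- simple_land()
  expect_equal(mds_coordinate(land, "chr1", 25L)$mds, 15L)
  expect_equal(mds_coordinate(land, "chr1", 5L)$mds, 5L)
  r <- mds_coordinate(land, "chr1", 15L)
  expect_equal(r$mds, 10L)
  expect_true(r$inside_ies)
  expect_error(mds_coordinate(land, "chr1", 150L), "out of bounds")
  # monotone and length-conserving
  pos <- 0:99
  mds <- mds_coordinate(land, "chr1", pos)$mds
  expect_true(all(diff(mds) >= 0L))
  expect_equal(mds_length(land, "chr1"), 90L)
  expect_equal(max(mds[!mds_coordinate(land, "chr1", pos)$inside_ies]), 89L)
})

test_that("MDS length equals MIC length minus total IES length (toy fixture)", {
  b <- make_fixture("toy")
  for (sp in b$species) {
    land <- b$landscape[[sp]]
    for (ch in names(land$lengths)) {
      ies <- land$ies[land$ies$chrom == ch, ]
      expect_equal(mds_length(land, ch),
                   land$lengths[[ch]] - sum(ies$end - ies$start))
      pos <- as.integer(seq(0L, land$lengths[[ch]] - 1L, length.out = 200L))
      expect_true(all(diff(mds_coordinate(land, ch, pos)$mds) >= 0L))
    }
  }
})

test_that("bin tracks aggregate counts, fractions and medians", {
  land <- chromosome_landscape(
    c(chr1 = 3000000L),
    data.frame(chrom = "chr1", start = 1500000L, end = 1500100L),
    data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  items <- data.frame(chrom = "chr1",
                      position = c(100000L, 200000L, 1500000L),
                      value = c(0.1, 0.3, 0.9),
                      subset = c(TRUE, FALSE, FALSE))
  tr <- bin_values(land, items, 1e6, "count")
  expect_equal(tr$value, c(2, 1, 0))
  expect_equal(sum(tr$value), nrow(items))
  tr <- bin_values(land, items[1:2, ], 1e6, "median")
  expect_equal(tr$value[1L], 0.2)
  tr <- bin_values(land, items, 1e6, "fraction_of_bin_genes")
  expect_equal(tr$value[1L], 0.5)
  expect_error(bin_values(land, items, -5), "positive")
})

test_that("region labels partition every position", {
  land <- chromosome_landscape(
    c(chr1 = 20000000L),
    data.frame(chrom = "chr1", start = 9990000L, end = 10010000L),
    data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  expect_equal(region_of(land, "chr1", 9.5e6), "pericentromeric")
  expect_equal(region_of(land, "chr1", 0.4e6), "subtelomeric")
  expect_equal(region_of(land, "chr1", 5e6), "arm")
  pos <- seq(0, 2e7 - 1, length.out = 5000)
  reg <- region_of(land, "chr1", pos)
  expect_true(all(reg %in% c("pericentromeric", "subtelomeric", "arm")))
  expect_equal(length(reg), 5000L)
})

test_that("region enrichment detects biased placement and stays calibrated", {
  set.seed(12)
  regions <- sample(c("pericentromeric", "subtelomeric", "arm"), 600,
                    replace = TRUE)
  # biased subset: mostly pericentromeric
  subset <- ifelse(regions == "pericentromeric", runif(600) < 0.5,
                   runif(600) < 0.1)
  e <- region_enrichment(regions, subset)
  expect_lt(e$p, 0.01)
  # uniform subset: p behaves like a null p-value (rarely tiny)
  p_null <- replicate(60, {
    s <- runif(600) < 0.3
    region_enrichment(regions, s)$p
  })
  expect_gt(mean(p_null > 0.05), 0.8)
  expect_warning(region_enrichment(rep("arm", 10), rep(c(TRUE, FALSE), 5)),
                 "one region")
})

test_that("identical value distributions rarely differ by Mann-Whitney", {
  set.seed(13)
  p <- replicate(100, {
    v <- rnorm(120)
    r <- sample(c("pericentromeric", "arm"), 120, replace = TRUE)
    value_comparison(v, r)$p
  })
  expect_gte(mean(p > 0.05), 0.9)
})

test_that("IES-gene association flags intronic and flanking IESs", {
  genes <- list(
    A = make_gene(c(30L, 30L), introns = 100L, id = "A", scaffold = "chr1",
                  offset = 100L),           # span [100, 260); intron [130, 230)
    B = make_gene(c(60L), id = "B", scaffold = "chr1", offset = 500L),
    C = make_gene(c(60L), id = "C", scaffold = "chr1", offset = 900L))
  land <- chromosome_landscape(
    c(chr1 = 2000L),
    data.frame(chrom = "chr1", start = 1800L, end = 1900L),
    data.frame(chrom = "chr1",
               start = c(150L, 300L),
               end = c(200L, 400L)))       # one inside A's intron, one between A and B
  r <- ies_gene_association(land, genes)
  intronic <- r$per_ies[r$per_ies$start == 150L, ]
  expect_equal(intronic$containing_gene, "A")
  between <- r$per_ies[r$per_ies$start == 300L, ]
  expect_equal(between$left_gene, "A")
  expect_equal(between$right_gene, "B")
  flags <- setNames(r$per_gene$flanked_by_ies, r$per_gene$gene_id)
  expect_true(flags[["A"]])
  expect_true(flags[["B"]])
  expect_false(flags[["C"]])
})
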