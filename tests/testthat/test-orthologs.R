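species10 <- sprintf("sp%02d", 1:10)

test_that("cluster category counts the species present", {
  cl <- clusters_from_counts(list(c(1, 1, 1, rep(0, 7)),
                                  c(5, rep(0, 9)),
                                  rep(1, 10)), species10)
  cats <- categorize(cl)
  expect_equal(cats$category, c(3L, 1L, 10L))
  expect_equal(cats$roman, c("III", "I", "X"))
  expect_equal(cats$n_genes, c(3L, 5L, 10L))
})

test_that("expansion test flags single-species inparalog blow-ups", {
  counts <- c(61, 1, 1, rep(0, 7))
  cl <- clusters_from_counts(list(counts), species10)
  calls <- expansion_test(cl)
  expect_true(calls$flagged[calls$species == "sp01"])
  expect_false(any(calls$flagged[calls$species != "sp01"]))

  cl <- clusters_from_counts(list(c(29, rep(1, 9))), species10)
  calls <- expansion_test(cl)
  expect_true(calls$flagged[calls$species == "sp01"])

  # uniform counts are never flagged
  cl <- clusters_from_counts(list(c(2, 2, 2, rep(0, 7))), species10)
  expect_false(any(expansion_test(cl)$flagged))

  # underpowered and single-species clusters are skipped
  cl <- clusters_from_counts(list(c(2, 1, 1, rep(0, 7)), c(40, rep(0, 9))),
                             species10)
  expect_equal(nrow(expansion_test(cl)), 0L)
})

test_that("expansion test type-I error is controlled under the uniform null", {
  set.seed(31)
  n_clusters <- 2000L
  counts <- lapply(seq_len(n_clusters), function(i)
    as.vector(stats::rmultinom(1L, 20L, rep(1 / 10, 10L))))
  cl <- clusters_from_counts(counts, species10)
  calls <- expansion_test(cl, alpha = 0.01)
  fp <- length(unique(calls$cluster_id[calls$flagged]))
  expect_lte(fp / n_clusters, 0.01)
})

test_that("species-specific genes union singletons, category I and expansions", {
  f <- withr::local_tempfile()
  writeLines(c("c1: A|a1 A|a2 A|a3",                       # category I, 3 genes
               paste("c2:", paste0("A|e", 1:61, collapse = " "),
                     "B|b1 C|c1")), f)                     # expansion cluster
  uni <- list(A = c(paste0("a", 1:3), paste0("e", 1:61), "s1", "s2"),
              B = "b1", C = "c1")
  cl <- read_orthomcl_groups(f, uni)
  cats <- categorize(cl)
  calls <- expansion_test(cl)
  ids <- species_specific_genes(cl, cats, calls, "A")
  expect_length(ids, 2L + 3L + 61L)   # same gene never counted twice
  expect_true(all(c("s1", "s2", "a1", "e61") %in% ids))
  # species only in conserved clusters, never expanded: empty set
  expect_length(species_specific_genes(cl, cats, calls, "B"), 0L)
})

test_that("tandem groups respect the intervening-gene criterion", {
  f <- withr::local_tempfile()
  writeLines("c1: A|a1 A|a2 A|a3", f)
  uni <- list(A = c("a1", "a2", "a3", "b"))
  cl <- read_orthomcl_groups(f, uni)
  order1 <- list(s1 = c("a1", "a2", "b", "a3"))
  strict <- tandem_clusters(order1, cl, 0L)
  expect_equal(sort(strict$gene_id), c("a1", "a2"))
  relaxed <- tandem_clusters(order1, cl, 3L)
  expect_equal(sort(relaxed$gene_id), c("a1", "a2", "a3"))

  # 17 consecutive inparalogs form one strict group; a relaxed chain with
  # up-to-3-gene gaps extends it to 65
  members <- sprintf("m%02d", 1:65)
  fillers <- sprintf("f%02d", 1:96)
  ord <- members[1:17]
  fi <- 0L
  for (k in 18:65) {
    gap <- ((k - 18L) %% 3L) + 1L
    ord <- c(ord, fillers[fi + seq_len(gap)], members[k])
    fi <- fi + gap
  }
  f2 <- withr::local_tempfile()
  writeLines(paste("cx:", paste0("A|", members, collapse = " ")), f2)
  cl2 <- read_orthomcl_groups(f2, list(A = c(members, fillers)))
  strict <- tandem_clusters(list(s1 = ord), cl2, 0L)
  strict_sizes <- table(strict$tandem_group[strict$cluster_id == "cx"])
  expect_equal(max(strict_sizes), 17L)
  relaxed <- tandem_clusters(list(s1 = ord), cl2, 3L)
  rx <- relaxed[relaxed$cluster_id == "cx", ]
  expect_equal(length(unique(rx$tandem_group)), 1L)
  expect_equal(nrow(rx), 65L)

  # unknown gene in the order index is an error
  expect_error(tandem_clusters(list(s1 = c("a1", "zz")), cl, 0L),
               "not in cluster universe")
})

test_that("strict tandem groups are contiguous intervals of the gene order", {
  set.seed(17)
  genes <- sprintf("g%03d", 1:60)
  cluster_of <- sample(sprintf("c%d", 1:12), 60, replace = TRUE)
  f <- withr::local_tempfile()
  writeLines(vapply(unique(cluster_of), function(cid)
    paste0(cid, ": ", paste0("A|", genes[cluster_of == cid], collapse = " ")),
    character(1)), f)
  cl <- read_orthomcl_groups(f, list(A = genes))
  ord <- list(s1 = sample(genes))
  strict <- tandem_clusters(ord, cl, 0L)
  for (tg in unique(strict$tandem_group)) {
    ids <- strict$gene_id[strict$tandem_group == tg]
    pos <- sort(match(ids, ord$s1))
    expect_equal(pos, seq(min(pos), max(pos)))
  }
})

test_that("percent tandem by category", {
  f <- withr::local_tempfile()
  writeLines(c("c1: A|a1 A|a2 A|a3 A|a4 A|a5 A|a6 A|a7 A|a8 A|a9 A|a10",
               "c2: A|x1 B|y1"), f)
  uni <- list(A = c(paste0("a", 1:10), "x1"), B = "y1")
  cl <- read_orthomcl_groups(f, uni)
  cats <- categorize(cl)
  # a1..a4 tandem, rest scattered
  ord <- list(s1 = c("a1", "a2", "a3", "a4", "x1", "a5", "y1", "a6", "a7"),
              s2 = c("a8", "a9", "a10"))
  # a6,a7 and a8,a9,a10 are also adjacent runs; count them
  tand <- tandem_clusters(ord, cl, 0L)
  pct <- percent_tandem_by_category(cats, cl, tand)
  expect_equal(pct$pct_tandem[pct$category == 1L], 100 * 9 / 10)
  expect_equal(pct$pct_tandem[pct$category == 2L], 0)
})
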