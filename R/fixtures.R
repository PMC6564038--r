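#' Load a synthetic (or compatible) bundle directory
#'
#' Reads back everything [generate_bundle()] emits through the package's own
#' parsers: genomes, gene models, mask tables, REP annotations, chromosome
#' metadata, domain/ortholog/value tables and (when present) truth tables.
#'
#' @param dir Bundle directory.
#' @return List with per-species `genomes`, `genes`, `mask`, `landscape`,
#'   `rep`, plus bundle-wide `domains`, `clusters`, `fpkm`, `kaks`,
#'   `gene_order`, `truth_genes`, `truth_rep`.
#' @export
load_bundle <- function(dir) {
  fa <- list.files(dir, "\\.genome\\.fasta$", full.names = TRUE)
  if (!length(fa)) stop("no *.genome.fasta found in ", dir)
  species <- sub("\\.genome\\.fasta$", "", basename(fa))
  out <- list(dir = dir, species = species, genomes = list(), genes = list(),
              mask = list(), landscape = list(), rep = list())
  for (sp in species) {
    pre <- file.path(dir, sp)
    g <- read_fasta(paste0(pre, ".genome.fasta"), species = sp)
    out$genomes[[sp]] <- g
    out$genes[[sp]] <- read_gff3(paste0(pre, ".genes.gff3"), genome = g,
                                 species = sp)
    out$mask[[sp]] <- read_mask_table(paste0(pre, ".mask.bed"), "bed6+family")
    cen <- read_bed3(paste0(pre, ".centromeres.bed"))
    ies <- read_bed3(paste0(pre, ".ies.bed"))
    out$landscape[[sp]] <- chromosome_landscape(
      setNames(nchar(g), names(g)), cen, ies)
    rep_bed <- paste0(pre, ".rep.bed")
    if (file.exists(rep_bed)) {
      rb <- read.delim(rep_bed, header = FALSE, stringsAsFactors = FALSE)
      reps <- data.frame(rep_id = rb[[4L]], scaffold = rb[[1L]],
                         start = as.integer(rb[[2L]]), end = as.integer(rb[[3L]]),
                         strand = rb[[6L]], stringsAsFactors = FALSE)
      orf <- read_tsv(paste0(pre, ".rep_orf.tsv"))
      reps$functional <- as.logical(orf$functional[match(reps$rep_id, orf$rep_id)])
      out$rep[[sp]] <- reps
    }
  }
  out$domains <- read_tsv(file.path(dir, "domains.tsv"))
  universe <- lapply(out$genes, names)
  out$clusters <- read_orthomcl_groups(file.path(dir, "groups.txt"), universe)
  out$fpkm <- read_value_table(file.path(dir, "fpkm.tsv"), "fpkm")
  out$kaks <- read_value_table(file.path(dir, "kaks.tsv"), "ka_ks")
  out$gene_order <- gene_order_of(unlist(out$genes, recursive = FALSE,
                                         use.names = FALSE))
  tg <- file.path(dir, "truth_genes.tsv")
  if (file.exists(tg)) out$truth_genes <- read_tsv(tg)
  tr <- file.path(dir, "truth_rep.tsv")
  if (file.exists(tr)) out$truth_rep <- read_tsv(tr)
  out
}

#' Annotation order of genes along each scaffold
#'
#' @param genes List of [gene_model()] objects.
#' @return Named list: scaffold -> gene ids ordered by span start.
#' @export
gene_order_of <- function(genes) {
  df <- do.call(rbind, lapply(genes, function(g) {
    data.frame(gene_id = g$gene_id, scaffold = g$scaffold,
               start = gene_span(g)[["start"]], stringsAsFactors = FALSE)
  }))
  df <- df[order(df$scaffold, df$start), , drop = FALSE]
  split(df$gene_id, df$scaffold)
}

fixture_spec <- function(name) {
  switch(name,
    toy = list(seed = 7L, spec = synthetic_spec(
      species = list(
        species_profile("thermophila", "tth", n_background = 10L, n_group1 = 3L,
                        n_group2 = 4L, n_group3 = 6L, n_rep = 6L,
                        ies_in_intron_prob = 0.3),
        species_profile("malaccensis", "tma", n_background = 10L, n_group1 = 3L,
                        n_group2 = 4L, n_group3 = 6L,
                        group3_intron_primary = 232,
                        group3_intron_secondary = NA,
                        group3_secondary_weight = 0)),
      layout = chromosome_layout(n_chrom = 2L, chrom_length = 3e5,
                                 slot_width = 1e4, centromere_halfwidth = 5e3,
                                 peri_half_width = 5e4, subtel_len = 5e4,
                                 n_ies = 8L, ies_len_range = c(200L, 800L)),
      expansion_size = 0L, tandem_strict_run = 0L, tandem_relaxed_extra = 0L,
      specific_cluster_size = 2L)),
    default = list(seed = 42L, spec = synthetic_spec()),
    stress = list(seed = 11L, spec = synthetic_spec(
      species = lapply(seq_len(10L), function(i) {
        species_profile(sprintf("sp%02d", i), sprintf("s%02d", i),
                        n_background = 30L, n_group1 = 5L, n_group2 = 5L,
                        n_group3 = 6L,
                        group3_intron_secondary = NA,
                        group3_secondary_weight = 0)
      }),
      layout = chromosome_layout(n_chrom = 2L, chrom_length = 4e5,
                                 slot_width = 1e4, centromere_halfwidth = 5e3,
                                 peri_half_width = 5e4, subtel_len = 5e4,
                                 n_ies = 10L, ies_len_range = c(200L, 800L)),
      expansion_size = 5L, tandem_strict_run = 0L, tandem_relaxed_extra = 0L,
      partial_spans = 2:9, specific_cluster_size = 2L)),
    stop("unknown fixture '", name, "'; options: toy, default, stress"))
}

.fixture_cache <- new.env(parent = emptyenv())

#' Deterministic cached test fixtures
#'
#' `toy` (2 species, ~46 genes), `default` (3 species, ~2,250 LRR genes; the
#' reference conditions for the package's validation) and `stress`
#' (10 species, small). Bundles are generated into `tempdir()` on first use
#' and cached for the session; generation is deterministic, so repeated calls
#' (and fresh sessions) see identical data.
#'
#' @param name `"toy"`, `"default"` or `"stress"`.
#' @return Loaded bundle as from [load_bundle()].
#' @export
make_fixture <- function(name = c("toy", "default", "stress")) {
  name <- match.arg(name)
  if (!is.null(.fixture_cache[[name]])) return(.fixture_cache[[name]])
  fx <- fixture_spec(name)
  dir <- file.path(tempdir(), paste0("lrrscape_fixture_", name))
  generate_bundle(fx$spec, fx$seed, dir)
  bundle <- load_bundle(dir)
  .fixture_cache[[name]] <- bundle
  bundle
}
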