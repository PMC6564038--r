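#' Pipeline configuration
#'
#' Collects the tunable parameters of the analysis stages; all thresholds
#' must be positive. The configuration round-trips losslessly through
#' [jsonlite::write_json()]/[jsonlite::read_json()].
#'
#' @param bundle_dir Directory holding the input bundle (as produced by
#'   [generate_bundle()] or assembled from real data in the same formats).
#' @param out_dir Directory for stage outputs.
#' @param fixture Fixture name used by the `simulate` stage.
#' @param target_len Array exon length (bp).
#' @param min_masked_bp Masking threshold for group III calls.
#' @param max_mismatch Near-identity clustering threshold.
#' @param alpha_logo Two-sample logo call threshold.
#' @param alpha_expansion Expansion-test significance level.
#' @param flank_window REP flanking window (bp).
#' @param bin_width Landscape bin width (bp).
#' @param peri_half_width,subtel_len Region parameters (bp).
#' @param tail_query REP tail query sequence.
#' @param tail_max_mismatch Tail scan mismatch allowance.
#' @param seed Seed for the `simulate` stage.
#' @param focal_species Species used for the landscape/TE/profile stages
#'   (default: first species of the bundle, alphabetically).
#' @return List of class `run_config`.
#' @export
run_config <- function(bundle_dir = NULL, out_dir, fixture = "toy",
                       target_len = 90L, min_masked_bp = 50L,
                       max_mismatch = 2L, alpha_logo = 1e-5,
                       alpha_expansion = 0.01, flank_window = 1000L,
                       bin_width = 1e6, peri_half_width = 1e6,
                       subtel_len = 1e6, tail_query = REP_TAIL_54,
                       tail_max_mismatch = 5L, seed = 1L,
                       focal_species = NULL) {
  cfg <- as.list(environment())
  thresholds <- c(cfg$target_len, cfg$min_masked_bp, cfg$alpha_logo,
                  cfg$alpha_expansion, cfg$flank_window, cfg$bin_width,
                  cfg$peri_half_width, cfg$subtel_len)
  if (any(thresholds <= 0)) stop("run_config: thresholds must be positive")
  structure(cfg, class = "run_config")
}

pipeline_stages <- c("simulate", "architecture", "classify", "profiles",
                     "orthologs", "landscape", "te", "report")

require_artifact <- function(path, producer) {
  if (!file.exists(path))
    stop("missing prerequisite artifact ", basename(path),
         "; run the '", producer, "' stage first")
  path
}

#' Run analysis pipeline stages
#'
#' Orchestrates the full analysis behind a single entry point with
#' plain-file handoff between stages (TSV/BED/JSON under `out_dir`), so every
#' intermediate result is inspectable and diffable. Stage outputs are pure
#' functions of (bundle, config, seed); `report` merges the stage outputs
#' into `report.json`. Running a stage whose prerequisite has not been
#' produced raises an error naming the stage to run first.
#'
#' @param stage One of `simulate`, `architecture`, `classify`, `profiles`,
#'   `orthologs`, `landscape`, `te`, `report`, or `all`.
#' @param config A [run_config()].
#' @return Invisibly, the paths written by the stage (for `report`, the
#'   report contents).
#' @export
run_pipeline <- function(stage, config) {
  stopifnot(inherits(config, "run_config"))
  if (identical(stage, "all")) {
    for (s in pipeline_stages) run_pipeline(s, config)
    return(invisible(file.path(config$out_dir, "report.json")))
  }
  if (!stage %in% pipeline_stages)
    stop("unknown stage '", stage, "'; options: ",
         paste(c(pipeline_stages, "all"), collapse = ", "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  switch(stage,
         simulate = stage_simulate(config),
         architecture = stage_architecture(config),
         classify = stage_classify(config),
         profiles = stage_profiles(config),
         orthologs = stage_orthologs(config),
         landscape = stage_landscape(config),
         te = stage_te(config),
         report = stage_report(config))
}

pipeline_bundle <- function(config) {
  dir <- config$bundle_dir %||% file.path(config$out_dir, "bundle")
  if (!length(list.files(dir, "\\.genome\\.fasta$")))
    stop("missing prerequisite bundle in ", dir,
         "; run the 'simulate' stage first or set bundle_dir")
  load_bundle(dir)
}

stage_simulate <- function(config) {
  if (!is.null(config$bundle_dir)) return(invisible(config$bundle_dir))
  fx <- fixture_spec(config$fixture)
  out <- generate_bundle(fx$spec, config$seed, file.path(config$out_dir, "bundle"))
  invisible(out$dir)
}

lrr_flags_of <- function(bundle) {
  lrr <- identify_lrr_genes(bundle$domains)
  all_ids <- unlist(lapply(bundle$genes, names), use.names = FALSE)
  setNames(all_ids %in% lrr, all_ids)
}

stage_architecture <- function(config) {
  bundle <- pipeline_bundle(config)
  flags <- lrr_flags_of(bundle)
  rows <- list()
  for (sp in bundle$species) {
    for (g in bundle$genes[[sp]]) {
      runs <- find_exact_length_arrays(g, config$target_len)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g$gene_id, species = sp, is_lrr = unname(flags[g$gene_id]),
        n_exons = nrow(g$exons),
        n_target_exons = sum(exon_lengths(g) == config$target_len),
        n_arrays = nrow(runs), largest_array = max(0L, runs$run_length),
        stringsAsFactors = FALSE)
    }
  }
  arch <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  p1 <- write_tsv(arch, file.path(config$out_dir, "architecture.tsv"))
  all_genes <- unlist(bundle$genes, recursive = FALSE, use.names = FALSE)
  pb <- phase_bias_report(all_genes, flags, config$target_len)
  p2 <- write_tsv(pb, file.path(config$out_dir, "phase_bias.tsv"))
  lrr_exons <- unlist(lapply(all_genes[flags[vapply(all_genes, `[[`,
                                                    character(1), "gene_id")]],
                             exon_lengths))
  hist <- length_histogram(lrr_exons)
  p3 <- write_tsv(data.frame(length = as.integer(names(hist$counts)),
                             count = as.integer(hist$counts)),
                  file.path(config$out_dir, "lrr_exon_lengths.tsv"))
  invisible(c(p1, p2, p3))
}

crs_families <- function(mask) unique(mask$family[grepl("^CRS", mask$family)])

stage_classify <- function(config) {
  bundle <- pipeline_bundle(config)
  lrr <- identify_lrr_genes(bundle$domains)
  rows <- list()
  for (sp in bundle$species) {
    genes <- bundle$genes[[sp]]
    lrr_sp <- genes[intersect(names(genes), lrr)]
    if (!length(lrr_sp)) next
    mask <- bundle$mask[[sp]]
    mask <- mask[mask$family %in% crs_families(mask), , drop = FALSE]
    asn <- classify_groups(lrr_sp, mask, config$target_len, config$min_masked_bp)
    asn$species <- sp
    rows[[sp]] <- asn
  }
  asn <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  p <- write_tsv(asn, file.path(config$out_dir, "classification.tsv"))
  invisible(p)
}

stage_profiles <- function(config) {
  bundle <- pipeline_bundle(config)
  cls_path <- require_artifact(file.path(config$out_dir, "classification.tsv"),
                              "classify")
  asn <- read_tsv(cls_path)
  sp <- config$focal_species %||% bundle$species[[1L]]
  genes <- bundle$genes[[sp]]
  meta <- data.frame(gene_id = asn$gene_id, group = asn$group,
                     family = asn$best_family,
                     species = asn$species, stringsAsFactors = FALSE)
  m23 <- build_exon_matrix(genes, bundle$genomes[[sp]], meta,
                           group = c("II", "III"), species = sp,
                           target_len = config$target_len)
  prof_nt <- position_profile(m23, "nt")
  prof_aa <- position_profile(m23, "aa")
  p1 <- write_tsv(data.frame(position = rep(seq_len(ncol(prof_aa)),
                                            each = nrow(prof_aa)),
                             symbol = rep(rownames(prof_aa), ncol(prof_aa)),
                             freq = as.vector(prof_aa)),
                  file.path(config$out_dir, "profile_aa.tsv"))
  cons <- conserved_positions(prof_aa, "L", 0.5)
  jsonlite::write_json(
    list(consensus_nt = consensus(prof_nt),
         conserved_leucine_positions = cons,
         logo = logo_stacks(prof_aa)),
    file.path(config$out_dir, "profiles.json"), auto_unbox = TRUE, digits = NA)
  cl <- cluster_near_identical(m23, config$max_mismatch)
  p2 <- write_tsv(data.frame(row = seq_along(cl$membership),
                             gene_id = m23$meta$gene_id,
                             cluster = cl$membership),
                  file.path(config$out_dir, "exon_clusters.tsv"))
  # per-family consensus distances (species x family groups with >=3 exons)
  fams <- unique(stats::na.omit(m23$meta$family))
  mats <- list()
  for (f in fams) {
    keep <- which(m23$meta$family %in% f)
    if (length(keep) >= 3L)
      mats[[paste0(sp, "_", f)]] <- exon_matrix(m23$seqs[keep],
                                                m23$meta[keep, , drop = FALSE])
  }
  if (length(mats) >= 2L) {
    d <- family_consensus_distance_matrix(mats)
    write_phylip_dist(d, file.path(config$out_dir, "family_consensus.phylip"))
  }
  invisible(c(p1, p2, file.path(config$out_dir, "profiles.json")))
}

stage_orthologs <- function(config) {
  bundle <- pipeline_bundle(config)
  cats <- categorize(bundle$clusters)
  calls <- expansion_test(bundle$clusters, config$alpha_expansion)
  p1 <- write_tsv(cats, file.path(config$out_dir, "ortholog_categories.tsv"))
  p2 <- write_tsv(calls, file.path(config$out_dir, "expansion_calls.tsv"))
  spec_rows <- lapply(bundle$species, function(sp) {
    ids <- species_specific_genes(bundle$clusters, cats, calls, sp)
    if (!length(ids)) return(NULL)
    data.frame(species = sp, gene_id = ids, stringsAsFactors = FALSE)
  })
  p3 <- write_tsv(do.call(rbind, c(spec_rows, list(make.row.names = FALSE))),
                  file.path(config$out_dir, "species_specific_genes.tsv"))
  strict <- tandem_clusters(bundle$gene_order, bundle$clusters, 0L)
  relaxed <- tandem_clusters(bundle$gene_order, bundle$clusters, 3L)
  p4 <- write_tsv(strict, file.path(config$out_dir, "tandem_strict.tsv"))
  p5 <- write_tsv(relaxed, file.path(config$out_dir, "tandem_relaxed.tsv"))
  pct <- percent_tandem_by_category(cats, bundle$clusters, strict)
  p6 <- write_tsv(pct, file.path(config$out_dir, "tandem_by_category.tsv"))
  invisible(c(p1, p2, p3, p4, p5, p6))
}

stage_landscape <- function(config) {
  bundle <- pipeline_bundle(config)
  cls_path <- require_artifact(file.path(config$out_dir, "classification.tsv"),
                              "classify")
  asn <- read_tsv(cls_path)
  sp <- config$focal_species %||% bundle$species[[1L]]
  land <- bundle$landscape[[sp]]
  genes <- bundle$genes[[sp]]
  pos <- data.frame(gene_id = names(genes),
                    chrom = vapply(genes, `[[`, character(1), "scaffold"),
                    position = vapply(genes, function(g)
                      gene_span(g)[["start"]], numeric(1)),
                    stringsAsFactors = FALSE)
  pos$group <- asn$group[match(pos$gene_id, asn$gene_id)]
  tracks <- lapply(c("I", "II", "III"), function(gr) {
    tr <- bin_values(land, pos[pos$group %in% gr, , drop = FALSE],
                     config$bin_width, "count")
    tr$group <- gr
    tr
  })
  p1 <- write_tsv(do.call(rbind, tracks),
                  file.path(config$out_dir, "landscape_tracks.tsv"))
  mds <- do.call(rbind, lapply(unique(pos$chrom), function(ch) {
    z <- pos[pos$chrom == ch, , drop = FALSE]
    mc <- mds_coordinate(land, ch, z$position)
    data.frame(z, mds = mc$mds, inside = mc$inside_ies)
  }))
  mds <- mds[!mds$inside, , drop = FALSE]
  mds$region <- NA_character_
  for (ch in unique(mds$chrom)) {
    i <- mds$chrom == ch
    mds$region[i] <- region_of(land, ch, mds$mds[i],
                               config$peri_half_width, config$subtel_len)
  }
  enr <- region_enrichment(mds$region, mds$group %in% "III")
  kaks <- unname(bundle$kaks[mds$gene_id])
  ok <- !is.na(kaks)
  vc <- if (length(unique(mds$region[ok])) >= 2L)
    value_comparison(kaks[ok], mds$region[ok]) else
    data.frame(region_a = character(0), region_b = character(0), p = numeric(0))
  assoc <- ies_gene_association(land, genes)
  p2 <- write_tsv(assoc$per_gene, file.path(config$out_dir, "ies_gene_flags.tsv"))
  jsonlite::write_json(
    list(group3_region_enrichment = list(p = enr$p,
                                         table = as.data.frame.matrix(enr$table)),
         kaks_region_tests = vc),
    file.path(config$out_dir, "landscape_tests.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, file.path(config$out_dir, "landscape_tests.json")))
}

stage_te <- function(config) {
  bundle <- pipeline_bundle(config)
  sp <- config$focal_species %||% bundle$species[[1L]]
  hits <- scan_tail(bundle$genomes[[sp]], config$tail_query,
                    config$tail_max_mismatch)
  p1 <- write_bed(data.frame(hits$scaffold, hits$start, hits$end, "tail54",
                             hits$mismatches, hits$strand),
                  file.path(config$out_dir, "tail_hits.bed"))
  track <- tail_distribution_track(hits, bundle$landscape[[sp]],
                                   config$bin_width)
  p2 <- write_tsv(track, file.path(config$out_dir, "tail_track.tsv"))
  out <- list(n_tail_hits = nrow(hits))
  if (!is.null(bundle$rep[[sp]])) {
    fl <- flanking_elements(bundle$rep[[sp]], bundle$mask[[sp]],
                            config$flank_window)
    sweep <- flanking_window_sweep(bundle$rep[[sp]], bundle$mask[[sp]])
    write_tsv(fl$summary, file.path(config$out_dir, "rep_flanking_summary.tsv"))
    out$colocalization_fraction <- fl$colocalization_fraction
    out$window_sweep <- sweep
  }
  jsonlite::write_json(out, file.path(config$out_dir, "te_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, file.path(config$out_dir, "te_report.json")))
}

stage_report <- function(config) {
  out <- config$out_dir
  need <- c(architecture = "phase_bias.tsv", classify = "classification.tsv",
            orthologs = "tandem_by_category.tsv",
            landscape = "landscape_tests.json", te = "te_report.json")
  for (i in seq_along(need)) require_artifact(file.path(out, need[[i]]),
                                              names(need)[i])
  pb <- read_tsv(file.path(out, "phase_bias.tsv"))
  asn <- read_tsv(file.path(out, "classification.tsv"))
  exl <- read_tsv(file.path(out, "lrr_exon_lengths.tsv"))
  hist <- length_histogram(rep(exl$length, exl$count))
  report <- list(
    group_counts = as.list(table(asn$group)),
    phase2_pct_lrr_preceding_target =
      pb$phase2_pct[pb$stratum == "lrr_preceding_target"],
    modal_lrr_exon_length = hist$primary_peak,
    tandem_by_category = read_tsv(file.path(out, "tandem_by_category.tsv")),
    landscape = jsonlite::read_json(file.path(out, "landscape_tests.json")),
    te = jsonlite::read_json(file.path(out, "te_report.json")))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
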