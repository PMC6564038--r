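## bundle generation: placement, ortholog allocation, file emission

slot_table <- function(layout, abbrev) {
  rows <- list()
  for (ci in seq_len(layout$n_chrom)) {
    chrom <- sprintf("%s_chr%d", abbrev, ci)
    starts <- seq(0L, layout$chrom_length - layout$slot_width, by = layout$slot_width)
    mid <- starts + layout$slot_width / 2
    cen_mid <- layout$chrom_length / 2
    region <- ifelse(abs(mid - cen_mid) <= layout$peri_half_width, "pericentromeric",
                     ifelse(mid < layout$subtel_len |
                              mid >= layout$chrom_length - layout$subtel_len,
                            "subtelomeric", "arm"))
    rows[[ci]] <- data.frame(chrom = chrom, chrom_idx = ci,
                             slot = seq_along(starts), start = as.integer(starts),
                             region = region, stringsAsFactors = FALSE)
  }
  st <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  st$occupant <- NA_character_
  st
}

# sample n free slots, region-weighted (weights over peri/subtel/arm);
# falls back to uniform over all free slots when a region is exhausted
draw_slots <- function(st, n, weights = NULL) {
  out <- integer(0)
  for (i in seq_len(n)) {
    free <- which(is.na(st$occupant))
    if (!length(free)) stop("synthetic layout infeasible: out of placement slots")
    if (is.null(weights)) {
      pick <- free[sample.int(length(free), 1L)]
    } else {
      w <- setNames(weights, c("pericentromeric", "subtelomeric", "arm"))
      reg_avail <- unique(st$region[free])
      wr <- w[reg_avail] / sum(w[reg_avail])
      reg <- sample(reg_avail, 1L, prob = wr)
      cand <- free[st$region[free] == reg]
      pick <- cand[sample.int(length(cand), 1L)]
    }
    st$occupant[pick] <- "pending"
    out <- c(out, pick)
  }
  list(st = st, slots = out)
}

# reserve a run of n consecutive free slots on one chromosome
reserve_run <- function(st, n) {
  for (ci in unique(st$chrom_idx)) {
    free <- is.na(st$occupant) & st$chrom_idx == ci & st$region == "arm"
    idx <- which(free)
    if (length(idx) < n) next
    runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
    for (r in runs) {
      if (length(r) >= n) return(r[seq_len(n)])
    }
  }
  stop("synthetic layout infeasible: no free run of ", n, " slots")
}

## ortholog allocation ------------------------------------------------------

# plan per-species gene ids and cluster/tandem structure; counts are assumed
# identical across species (checked by synthetic_spec)
plan_genes <- function(spec) {
  S <- length(spec$species)
  classes <- c("bg", "g1", "g2", "g3")
  per <- list()
  for (si in seq_len(S)) {
    p <- spec$species[[si]]
    n <- c(bg = p$n_background, g1 = p$n_group1, g2 = p$n_group2, g3 = p$n_group3)
    ids <- unlist(lapply(classes, function(cl) {
      sprintf("%s_%s%04d", p$abbrev, cl, seq_len(n[[cl]]))
    }))
    cls <- rep(classes, n)
    n_spec <- round(p$specific_fraction[c("bg", "g1", "g2", "g3")] * n)
    per[[p$name]] <- data.frame(gene_id = ids, class = cls,
                                species = p$name, stringsAsFactors = FALSE)
    per[[p$name]]$conserved <- unlist(lapply(classes, function(cl) {
      k <- sum(cls == cl)
      c(rep(TRUE, k - n_spec[[cl]]), rep(FALSE, n_spec[[cl]]))
    }))
    per[[p$name]]$cluster <- NA_character_
  }
  focal <- spec$species[[1L]]$name

  cid <- 0L
  next_cid <- function() {
    cid <<- cid + 1L
    sprintf("OG%05d", cid)
  }
  # queues of conserved/specific genes per species x class
  take <- function(species, class, conserved, k) {
    d <- per[[species]]
    i <- which(d$class == class & d$conserved == conserved & is.na(d$cluster))[seq_len(k)]
    if (anyNA(i)) stop("ortholog allocation underflow: ", species, "/", class)
    i
  }
  assign_cluster <- function(species, idx, cl) per[[species]]$cluster[idx] <<- cl

  # partial-span clusters (background, species 1..k)
  for (k in spec$partial_spans) {
    cl <- next_cid()
    for (si in seq_len(k)) {
      sp <- spec$species[[si]]$name
      assign_cluster(sp, take(sp, "bg", TRUE, 1L), cl)
    }
  }
  # expansion cluster: focal contributes expansion_size specific g3 genes,
  # every other species one conserved g3 gene
  expansion_cluster <- NA_character_
  exp_n <- min(spec$expansion_size,
               sum(per[[focal]]$class == "g3" & !per[[focal]]$conserved))
  if (exp_n >= 5L && S >= 2L) {
    expansion_cluster <- next_cid()
    assign_cluster(focal, take(focal, "g3", FALSE, exp_n), expansion_cluster)
    for (si in seq_len(S)[-1L]) {
      sp <- spec$species[[si]]$name
      assign_cluster(sp, take(sp, "g3", TRUE, 1L), expansion_cluster)
    }
  }
  # conserved clusters per class: as many as every species can still fill
  for (cl_ in c("bg", "g1", "g2", "g3")) {
    n_avail <- min(vapply(per, function(d)
      sum(d$class == cl_ & d$conserved & is.na(d$cluster)), integer(1)))
    for (i in seq_len(n_avail)) {
      cl <- next_cid()
      for (sp in names(per)) assign_cluster(sp, take(sp, cl_, TRUE, 1L), cl)
    }
  }
  # species-specific inparalog clusters: half of the remaining specific genes
  # in clusters of specific_cluster_size, the rest stay singletons
  sz <- spec$specific_cluster_size
  for (sp in names(per)) {
    for (cl_ in c("bg", "g1", "g2", "g3")) {
      rem <- sum(per[[sp]]$class == cl_ & !per[[sp]]$conserved &
                   is.na(per[[sp]]$cluster))
      n_clusters <- (rem %/% 2L) %/% sz
      for (i in seq_len(n_clusters)) {
        assign_cluster(sp, take(sp, cl_, FALSE, sz), next_cid())
      }
    }
  }
  # conserved genes left unclustered by rounding become singletons, which are
  # species-specific by definition
  for (sp in names(per)) {
    left <- is.na(per[[sp]]$cluster) & per[[sp]]$conserved
    per[[sp]]$conserved[left] <- FALSE
  }
  list(per = per, expansion_cluster = expansion_cluster)
}

## main generator -----------------------------------------------------------

#' Generate a synthetic annotated genome bundle
#'
#' Writes, for each species, a genome FASTA, a GFF3 gene annotation, a
#' repeat-mask BED, REP element annotations, centromere/IES metadata, and
#' bundle-wide domain, ortholog, expression and Ka/Ks tables, plus truth
#' tables recording every gene's generated group, cluster, region and tandem
#' membership and every REP copy's adjacency status. Regenerating with the
#' same spec and seed is byte-identical.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, `files` (named paths), `truth_genes`
#'   and `truth_rep` data frames.
#' @export
generate_bundle <- function(spec, seed, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(as.integer(seed))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  layout <- spec$layout
  plan <- plan_genes(spec)
  S <- length(spec$species)
  focal <- spec$species[[1L]]$name

  truth_genes <- list()
  truth_rep <- list()
  domain_rows <- list()
  files <- list()
  universe <- list()

  for (si in seq_len(S)) {
    p <- spec$species[[si]]
    d <- plan$per[[p$name]]
    st <- slot_table(layout, p$abbrev)

    # species/group templates: group II shares an older template, group III
    # and its CRS1 subtype are progressively younger copies of it
    base_tpl <- make_template90(p$leucine_centers)
    tpl_g2 <- mutate_template(base_tpl, 3L)
    tpl_g3 <- mutate_template(base_tpl, 2L)
    tpl_crs1 <- mutate_template(tpl_g3, 2L)

    # tandem window: strict run + relaxed chain from the expansion cluster
    is_exp <- !is.na(d$cluster) & d$cluster %in% plan$expansion_cluster
    window_slots <- integer(0)
    window_genes <- character(0)
    window_tandem <- integer(0)
    if (p$name == focal && any(is_exp)) {
      exp_ids <- d$gene_id[is_exp]
      n_strict <- min(spec$tandem_strict_run, length(exp_ids))
      n_relax <- min(spec$tandem_relaxed_extra, length(exp_ids) - n_strict)
      need <- n_strict + 2L * n_relax
      if (need > 0L) {
        run <- reserve_run(st, need)
        members <- exp_ids[seq_len(n_strict + n_relax)]
        # first n_strict slots: members; then alternating background, member
        occ <- c(members[seq_len(n_strict)],
                 as.vector(rbind(rep("<bg>", n_relax),
                                 members[n_strict + seq_len(n_relax)])))
        bg_free <- d$gene_id[d$class == "bg"][seq_len(n_relax)]
        occ[occ == "<bg>"] <- bg_free
        st$occupant[run] <- occ
        window_slots <- run
        window_genes <- occ
        window_tandem <- ifelse(occ %in% members, 1L, NA_integer_)
      }
    }

    # group III genes (not already in the window): region-weighted placement
    remaining <- setdiff(d$gene_id, window_genes)
    g3_ids <- intersect(d$gene_id[d$class == "g3"], remaining)
    dw <- draw_slots(st, length(g3_ids), layout$placement_weights)
    st <- dw$st
    st$occupant[dw$slots] <- g3_ids

    # everything else uniform
    rest <- setdiff(remaining, g3_ids)
    dw <- draw_slots(st, length(rest))
    st <- dw$st
    st$occupant[dw$slots] <- rest

    # REP copies: adjacency flags; adjacent ones share a group III gene slot
    rep_plan <- NULL
    if (p$n_rep > 0L) {
      adjacent <- runif(p$n_rep) < spec$rep$adjacency_prob
      host_pool <- st$occupant[!is.na(st$occupant) & st$occupant %in% g3_ids]
      if (sum(adjacent) > length(host_pool))
        stop("synthetic layout infeasible: more adjacent REP copies than group III genes")
      hosts <- rep(NA_character_, p$n_rep)
      hosts[adjacent] <- sample(host_pool, sum(adjacent))
      free_rep <- draw_slots(st, sum(!adjacent), layout$placement_weights)
      st <- free_rep$st
      st$occupant[free_rep$slots] <- sprintf("%s_rep_slot%03d", p$abbrev,
                                             seq_len(sum(!adjacent)))
      rep_plan <- data.frame(rep_id = sprintf("%s_REP%03d", p$abbrev, seq_len(p$n_rep)),
                             adjacent = adjacent, host = hosts,
                             slot = NA_integer_, stringsAsFactors = FALSE)
      rep_plan$slot[!adjacent] <- free_rep$slots
      rep_plan$functional <- runif(p$n_rep) < spec$rep$functional_fraction
    }

    # intergenic IES slots (region-weighted)
    dw <- draw_slots(st, layout$n_ies, layout$ies_weights)
    st <- dw$st
    ies_slots <- dw$slots
    st$occupant[ies_slots] <- "IES"

    # ---- build sequences --------------------------------------------------
    gene_rows <- list()   # per gene: model info + body
    mask_rows <- list()
    ies_rows <- list()
    rep_rows <- list()
    crs_choices <- paste0("CRS", seq(2L, p$n_crs))

    slot_of_gene <- setNames(seq_len(nrow(st)), st$occupant)[d$gene_id]
    for (gi in seq_len(nrow(d))) {
      gid <- d$gene_id[gi]
      cls <- d$class[gi]
      slot <- slot_of_gene[[gid]]
      chrom <- st$chrom[slot]
      place <- st$start[slot] + 100L
      secondary <- FALSE
      family <- NA_character_
      phase2 <- NA
      has_ies_intron <- FALSE
      if (cls %in% c("g2", "g3")) {
        if (cls == "g3") {
          secondary <- !is.na(p$group3_intron_secondary) &&
            runif(1L) < p$group3_secondary_weight
          family <- if (secondary) "CRS1" else
            crs_choices[sample.int(length(crs_choices), 1L)]
          tpl <- if (secondary) tpl_crs1 else tpl_g3
        } else tpl <- tpl_g2
        gb <- make_group3_gene(p, template = tpl,
                               group = if (cls == "g3") "III" else "II",
                               secondary = secondary)
        body <- list(seq = gb$sequence, rel = gb$rel)
        phase2 <- gb$phase2
      } else {
        body <- make_plain_gene(p, exclude_len = if (cls == "g1") 90L else integer(0))
      }
      has_ies_intron <- cls == "g3" && runif(1L) < p$ies_in_intron_prob
      strand <- if (has_ies_intron) "+" else sample(c("+", "-"), 1L)
      BL <- nchar(body$seq)
      if (strand == "+") {
        exons <- cbind(place + body$rel[, "start"], place + body$rel[, "end"])
        gseq <- body$seq
      } else {
        exons <- cbind(place + BL - body$rel[, "end"], place + BL - body$rel[, "start"])
        gseq <- reverse_complement(body$seq)
      }
      span <- c(place, place + BL)
      if (has_ies_intron && nrow(body$rel) > 1L) {
        # drop an 80-bp IES annotation inside the first long-enough intron
        intr_s <- body$rel[-nrow(body$rel), "end"]
        intr_e <- body$rel[-1L, "start"]
        ok <- which(intr_e - intr_s >= 120L)
        if (length(ok)) {
          i <- ok[1L]
          ies_rows[[length(ies_rows) + 1L]] <- data.frame(
            chrom = chrom, start = place + intr_s[i] + 20L,
            end = place + intr_s[i] + 100L)
        } else has_ies_intron <- FALSE
      }
      if (cls == "g3") {
        halfway <- as.integer(span[1L] + (BL %/% 2L))
        mask_rows[[length(mask_rows) + 1L]] <- data.frame(
          chrom = chrom,
          start = c(span[1L], halfway + 10L, span[1L] + 50L),
          end = c(halfway, span[2L], span[2L] + 50L),
          family = c(family, family, "tLRR-MIC-CRS"),
          score = round(c(runif(2L, 400, 900), runif(1L, 100, 300))),
          stringsAsFactors = FALSE)
      }
      gene_rows[[gid]] <- list(gid = gid, class = cls, chrom = chrom,
                               strand = strand, exons = exons, seq = gseq,
                               span = span, family = family, phase2 = phase2,
                               secondary = secondary, slot = slot,
                               has_ies_intron = has_ies_intron)
      domain_rows[[length(domain_rows) + 1L]] <- data.frame(
        gene_id = gid,
        domain = if (cls == "bg") {
          if (gi %% 2L == 0L) "Protein kinase domain" else "hypothetical protein"
        } else "Leucine-rich repeat",
        stringsAsFactors = FALSE)
    }

    # REP sequences: adjacent after the host gene, detached in their own slot
    if (!is.null(rep_plan)) {
      for (ri in seq_len(nrow(rep_plan))) {
        rp <- make_rep_copy(spec$rep, rep_plan$functional[ri])
        rl <- nchar(rp$seq)
        if (rep_plan$adjacent[ri]) {
          host <- gene_rows[[rep_plan$host[ri]]]
          gap <- sample(seq(spec$rep$gap_range[1L], spec$rep$gap_range[2L]), 1L)
          start <- host$span[2L] + gap
          chrom <- host$chrom
        } else {
          slot <- rep_plan$slot[ri]
          start <- st$start[slot] + 200L
          chrom <- st$chrom[slot]
        }
        strand <- sample(c("+", "-"), 1L)
        seq <- if (strand == "+") rp$seq else reverse_complement(rp$seq)
        tail_start <- if (strand == "+") start + rp$tail_offset else start
        rep_rows[[length(rep_rows) + 1L]] <- data.frame(
          rep_id = rep_plan$rep_id[ri], chrom = chrom, start = start,
          end = start + rl, strand = strand, seq = seq,
          functional = rep_plan$functional[ri],
          adjacent = rep_plan$adjacent[ri],
          tail_start = tail_start, tail_end = tail_start + 54L,
          tail_mismatches = rp$tail_mismatches, stringsAsFactors = FALSE)
      }
    }

    # intergenic IESs
    for (slot in ies_slots) {
      len <- sample(seq(layout$ies_len_range[1L], layout$ies_len_range[2L]), 1L)
      ies_rows[[length(ies_rows) + 1L]] <- data.frame(
        chrom = st$chrom[slot], start = st$start[slot] + 200L,
        end = st$start[slot] + 200L + len)
    }

    # ---- assemble chromosomes and write files -----------------------------
    feats <- c(lapply(gene_rows, function(g)
                 data.frame(chrom = g$chrom, start = g$span[1L], end = g$span[2L],
                            seq = g$seq, stringsAsFactors = FALSE)),
               lapply(rep_rows, function(r)
                 data.frame(chrom = r$chrom, start = r$start, end = r$end,
                            seq = r$seq, stringsAsFactors = FALSE)))
    feats <- do.call(rbind, c(feats, list(make.row.names = FALSE)))
    genome <- setNames(vector("character", layout$n_chrom),
                       sprintf("%s_chr%d", p$abbrev, seq_len(layout$n_chrom)))
    for (ch in names(genome)) {
      f <- feats[feats$chrom == ch, , drop = FALSE]
      f <- f[order(f$start), , drop = FALSE]
      pieces <- character(0)
      cur <- 0L
      for (i in seq_len(nrow(f))) {
        pieces <- c(pieces, random_dna(f$start[i] - cur), f$seq[i])
        cur <- f$end[i]
      }
      pieces <- c(pieces, random_dna(layout$chrom_length - cur))
      genome[[ch]] <- paste(pieces, collapse = "")
    }

    models <- lapply(gene_rows, function(g)
      gene_model(g$gid, p$name, g$chrom, g$strand, g$exons))
    pre <- file.path(dir, p$name)
    files[[paste0(p$name, "_fasta")]] <- write_fasta(genome, paste0(pre, ".genome.fasta"))
    files[[paste0(p$name, "_gff3")]] <- write_gff3(models, paste0(pre, ".genes.gff3"))
    mask <- do.call(rbind, c(mask_rows, list(make.row.names = FALSE)))
    if (is.null(mask))
      mask <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                         family = character(0), score = numeric(0))
    mask$strand <- "+"
    files[[paste0(p$name, "_mask")]] <-
      write_bed(mask[order(mask$chrom, mask$start),
                     c("chrom", "start", "end", "family", "score", "strand")],
                paste0(pre, ".mask.bed"))
    cen <- data.frame(chrom = names(genome),
                      start = as.integer(layout$chrom_length / 2 - layout$centromere_halfwidth),
                      end = as.integer(layout$chrom_length / 2 + layout$centromere_halfwidth))
    files[[paste0(p$name, "_centromeres")]] <- write_bed(cen, paste0(pre, ".centromeres.bed"))
    ies <- do.call(rbind, c(ies_rows, list(make.row.names = FALSE)))
    ies <- ies[order(ies$chrom, ies$start), , drop = FALSE]
    files[[paste0(p$name, "_ies")]] <- write_bed(ies, paste0(pre, ".ies.bed"))
    if (length(rep_rows)) {
      rr <- do.call(rbind, c(rep_rows, list(make.row.names = FALSE)))
      files[[paste0(p$name, "_rep")]] <-
        write_bed(data.frame(rr$chrom, rr$start, rr$end, rr$rep_id, 0L, rr$strand),
                  paste0(pre, ".rep.bed"))
      files[[paste0(p$name, "_rep_orf")]] <-
        write_tsv(data.frame(rep_id = rr$rep_id, orf1_intact = rr$functional,
                             orf2_intact = rr$functional, functional = rr$functional),
                  paste0(pre, ".rep_orf.tsv"))
      truth_rep[[p$name]] <- data.frame(
        rr[, c("rep_id", "chrom", "start", "end", "strand", "functional",
               "adjacent", "tail_start", "tail_end", "tail_mismatches")],
        species = p$name, stringsAsFactors = FALSE)
    }

    group_label <- c(bg = "background", g1 = "I", g2 = "II", g3 = "III")
    truth_genes[[p$name]] <- do.call(rbind, c(lapply(gene_rows, function(g) {
      i <- match(g$gid, d$gene_id)
      data.frame(gene_id = g$gid, species = p$name,
                 class = g$class, group = group_label[[g$class]],
                 family = g$family %||% NA_character_,
                 cluster = d$cluster[i] %||% NA_character_,
                 conserved = d$conserved[i],
                 chrom = g$chrom, start = g$span[1L], end = g$span[2L],
                 strand = g$strand, region = st$region[g$slot],
                 phase2 = g$phase2,
                 tandem_window = g$gid %in% window_genes[!is.na(window_tandem)],
                 has_ies_intron = g$has_ies_intron, stringsAsFactors = FALSE)
    }), list(make.row.names = FALSE)))
    universe[[p$name]] <- d$gene_id
  }

  # bundle-wide tables
  tg <- do.call(rbind, c(truth_genes, list(make.row.names = FALSE)))
  tr <- if (length(truth_rep))
    do.call(rbind, c(truth_rep, list(make.row.names = FALSE))) else
    data.frame()
  dom <- do.call(rbind, c(domain_rows, list(make.row.names = FALSE)))
  files$domains <- write_tsv(dom, file.path(dir, "domains.tsv"))

  # ortholog groups file
  lines <- character(0)
  all_plan <- do.call(rbind, c(unname(lapply(plan$per, function(d)
    d[, c("gene_id", "species", "cluster")])), list(make.row.names = FALSE)))
  clustered <- all_plan[!is.na(all_plan$cluster), , drop = FALSE]
  for (cl in sort(unique(clustered$cluster))) {
    m <- clustered[clustered$cluster == cl, , drop = FALSE]
    m <- m[order(m$species, m$gene_id), , drop = FALSE]
    lines <- c(lines, paste0(cl, ": ",
                             paste(paste0(m$species, "|", m$gene_id), collapse = " ")))
  }
  con <- file(file.path(dir, "groups.txt"), open = "wb")
  writeLines(lines, con)
  close(con)
  files$groups <- file.path(dir, "groups.txt")

  # expression: species-specific genes drawn with a lower median
  specific <- !tg$conserved
  fpkm <- exp(rnorm(nrow(tg), mean = ifelse(specific, 1.8, 3.0), sd = 1.0))
  files$fpkm <- write_tsv(data.frame(gene_id = tg$gene_id,
                                     value = round(fpkm, 4)),
                          file.path(dir, "fpkm.tsv"))
  # Ka/Ks: elevated in pericentromeric/subtelomeric regions
  mu <- ifelse(tg$region == "arm", log(0.15), log(0.4))
  kaks <- exp(rnorm(nrow(tg), mean = mu, sd = 0.3))
  files$kaks <- write_tsv(data.frame(gene_id = tg$gene_id,
                                     value = round(kaks, 4)),
                          file.path(dir, "kaks.tsv"))

  files$truth_genes <- write_tsv(tg, file.path(dir, "truth_genes.tsv"))
  if (nrow(tr)) files$truth_rep <- write_tsv(tr, file.path(dir, "truth_rep.tsv"))
  files$spec <- local({
    path <- file.path(dir, "spec.yaml")
    writeLines(spec_to_yaml(spec, seed), path)
    path
  })
  invisible(list(dir = dir, files = files, truth_genes = tg, truth_rep = tr))
}

# minimal flat YAML record of the generating parameters
spec_to_yaml <- function(spec, seed) {
  lines <- c("synthetic_spec:", sprintf("  seed: %d", as.integer(seed)),
             sprintf("  n_species: %d", length(spec$species)),
             sprintf("  expansion_size: %d", spec$expansion_size))
  for (p in spec$species) {
    lines <- c(lines, sprintf("  - name: %s", p$name),
               sprintf("    genes: [%d, %d, %d, %d]", p$n_background,
                       p$n_group1, p$n_group2, p$n_group3),
               sprintf("    group3_intron_primary: %s", p$group3_intron_primary),
               sprintf("    phase2_prob: %s", p$phase2_prob))
  }
  lines
}
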