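#' Toy confinement study genome with coupled switches
#'
#' Builds the standard toy genome used by [run_toy_study()]: 8 chromosomes
#' of 8 Mb tiled by 100-kb bins, 1-Mb activity blocks cycling through the
#' eight openness levels (each level once per chromosome, so octiles are
#' balanced genome-wide), plus planted subcompartment switches: per
#' chromosome, the block at the second-most-closed baseline level opens at
#' 15 minutes of confinement and partially reverts at 4 hours, and one
#' open-baseline block closes and partially reverts, emulating the
#' partially reversible response.
#'
#' @param n_chrom Number of chromosomes.
#' @param seed Integer seed (shuffles block order per chromosome).
#' @return A list with `layout` (the [sim_genome()] object) and
#'   `switch_blocks` (tibble of planted switch blocks with their direction).
#' @export
toy_study_genome <- function(n_chrom = 8, seed = 1L) {
  set.seed(seed)
  levels8 <- seq(0, 1, length.out = 8)
  open_base <- levels8[2]    # 1/7: near-closed baseline, will open
  close_base <- levels8[7]   # 6/7: near-open baseline, will close
  chroms <- stats::setNames(rep(8e6, n_chrom), paste0("chr", seq_len(n_chrom)))
  blocks <- purrr::map_dfr(names(chroms), function(chr) {
    tibble::tibble(chrom = chr, start = seq(0, 7e6, by = 1e6),
                   end = seq(1e6, 8e6, by = 1e6),
                   activity = sample(levels8))
  })
  op <- blocks[blocks$activity == open_base, ]
  cl <- blocks[blocks$activity == close_base, ]
  switches <- dplyr::bind_rows(
    dplyr::mutate(op[, 1:3], condition = "C15m", activity = levels8[7]),
    dplyr::mutate(op[, 1:3], condition = "C4h", activity = levels8[4]),
    dplyr::mutate(cl[, 1:3], condition = "C15m", activity = levels8[2]),
    dplyr::mutate(cl[, 1:3], condition = "C4h", activity = levels8[5]))
  layout <- sim_genome(chroms, 1e5, blocks = blocks, switches = switches,
                       conditions = c("NC", "C15m", "C4h"))
  switch_blocks <- dplyr::bind_rows(
    dplyr::mutate(op[, 1:3], direction = "opening"),
    dplyr::mutate(cl[, 1:3], direction = "closing"))
  list(layout = layout, switch_blocks = switch_blocks,
       open_base = open_base, close_base = close_base)
}

#' Run the full synthetic confinement study
#'
#' End-to-end pipeline on planted synthetic data: simulates temporal
#' expression with planted clusters coupled to a toy genome whose
#' subcompartments switch under confinement, simulates triplicate Hi-C for
#' the non-confined state and two confinement timepoints, and runs every
#' analysis stage -- TEC clustering, per-replicate subcompartment calling
#' with consensus, TSS switch classification, the opening/closing versus
#' up/down Fisher association, significant-interaction calling with
#' replicate consensus, insulation TAD boundaries with cross-sample
#' consensus, coarse-bin differential contacts, interchromosomal MDS with
#' Procrustes comparison, and (optionally) a small bead-model ensemble with
#' radial statistics.
#'
#' @param seed Integer seed driving every stage.
#' @param genes_per_cluster Genes per planted expression cluster.
#' @param n_irregular Irregular background genes.
#' @param cis_scale Expected cis counts at unit distance.
#' @param replicates Hi-C replicates per condition.
#' @param n_models Bead models per condition ensemble (0 skips 3D
#'   modeling).
#' @param mc_steps Monte-Carlo steps per model.
#' @return A list of per-stage results; see the methods vignette for a
#'   walk-through.
#' @export
run_toy_study <- function(seed = 1L, genes_per_cluster = 120,
                          n_irregular = 360, cis_scale = 250,
                          replicates = 3, n_models = 5, mc_steps = 20000) {
  conditions <- c("NC", "C15m", "C4h")
  genome <- toy_study_genome(seed = seed)
  layout <- genome$layout

  ## --- genes: planted clusters coupled to activity strata -------------
  # up-regulated clusters (2, 5, 6, 7) sit in blocks that open at C15m;
  # down-regulated clusters (1, 3, 4) in blocks that close; irregular genes
  # land anywhere
  eps <- 1e-6
  coupling <- dplyr::bind_rows(
    tibble::tibble(cluster = c(2, 5, 6, 7), n_genes = genes_per_cluster,
                   min_activity = genome$open_base - eps,
                   max_activity = genome$open_base + eps),
    tibble::tibble(cluster = c(1, 3, 4), n_genes = genes_per_cluster,
                   min_activity = genome$close_base - eps,
                   max_activity = genome$close_base + eps),
    tibble::tibble(cluster = 0, n_genes = n_irregular,
                   min_activity = 0, max_activity = 1))
  genes <- sim_genes(layout, coupling, seed = seed + 1)$genes

  ## --- expression: archetype + noise per planted cluster --------------
  arch <- tec_archetypes()
  set.seed(seed + 2)
  vals <- matrix(rnorm(nrow(genes) * 4, sd = 2), ncol = 4,
                 dimnames = list(NULL, colnames(arch)))
  member <- genes$cluster > 0
  vals[member, ] <- arch[genes$cluster[member], ] +
    rnorm(sum(member) * 4, sd = 0.3)
  lfc <- dplyr::bind_cols(tibble::tibble(gene_id = genes$gene_id),
                          tibble::as_tibble(vals))

  ## --- TEC clustering --------------------------------------------------
  tecs <- tec_cluster(lfc, min_cluster_size = max(30, genes_per_cluster %/% 3),
                      deep_split = 0, silhouette_threshold = 0.1)
  profiles <- tec_profiles(lfc, tecs)
  c4h <- profiles[profiles$timepoint == "C4h" & profiles$tec != 0, ]
  up_tecs <- c4h$tec[!is.na(c4h$mean) & c4h$mean > 0]
  down_tecs <- c4h$tec[!is.na(c4h$mean) & c4h$mean <= 0]

  ## --- Hi-C: triplicates per condition with subtelomeric trans gains ---
  clique <- paste0("chr", 1:4)
  pp15 <- subtelomeric_pairs(layout, n_pairs = 24, condition = "C15m",
                             fold = 6, seed = seed + 3)
  keep <- layout$bins$chrom[pp15$bin1] %in% clique &
    layout$bins$chrom[pp15$bin2] %in% clique
  pp15 <- pp15[keep, ]
  pp4 <- dplyr::mutate(pp15, condition = "C4h", fold = 2.5)
  planted_pairs <- dplyr::bind_rows(pp15, pp4)
  hic <- sim_hic_replicates(layout, decay_exponent = 1,
                            cis_scale = cis_scale, trans_scale = 2,
                            compartment_affinity = 2,
                            replicates_per_condition = replicates,
                            planted_pairs = planted_pairs, seed = seed + 4)

  ## --- subcompartments: per replicate, then condition consensus --------
  tracks <- lapply(conditions, function(cond) {
    lapply(hic$matrices[[cond]], function(cm) {
      score <- subcompartment_rank(cm, layout$bins$activity)
      rank_to_labels(cm, score)
    })
  })
  names(tracks) <- conditions
  consensus <- lapply(tracks, consensus_labels)

  ## --- switches at gene TSSs ------------------------------------------
  switch_of <- function(cond) {
    from <- map_tss_to_label(genes, consensus$NC)$label
    to <- map_tss_to_label(genes, consensus[[cond]])$label
    dplyr::bind_cols(tibble::tibble(gene_id = genes$gene_id),
                     classify_switch(from, to))
  }
  switches <- list(C15m = switch_of("C15m"), C4h = switch_of("C4h"))
  association <- lapply(switches, switching_vs_regulation, tecs = tecs,
                        up_tecs = up_tecs, down_tecs = down_tecs)
  switch_mbp <- lapply(list(C15m = "C15m", C4h = "C4h"), function(cond)
    switch_matrix(consensus$NC, consensus[[cond]]))

  ## --- significant trans interactions with replicate consensus ---------
  sig <- lapply(conditions, function(cond) {
    calls <- lapply(hic$matrices[[cond]], function(cm)
      significant_interactions(cm, fdr = 0.01))
    replicate_consensus_interactions(calls, min_reps = 2)
  })
  names(sig) <- conditions

  ## --- balancing, chromosome profiles, MDS -----------------------------
  balanced <- lapply(conditions, function(cond)
    balance_ice(pool_replicates(hic$matrices[[cond]])))
  names(balanced) <- conditions
  profiles_cc <- lapply(balanced, chromosome_contact_profile)
  mds <- lapply(profiles_cc, function(p)
    nonmetric_mds(freq_to_dissimilarity(p, mode = "inverse"), k = 2))
  disp <- lapply(c(C15m = "C15m", C4h = "C4h"), function(cond) {
    al <- procrustes_align(mds$NC$points, mds[[cond]]$points)
    per_chrom <- sqrt(rowSums((al$aligned - al$reference)^2))
    list(disparity = al$disparity, per_chrom = per_chrom)
  })

  ## --- coarse-bin differential contacts, NC vs C15m --------------------
  mats <- c(hic$matrices$NC, hic$matrices$C15m)
  names(mats) <- c(paste0("NC_", seq_len(replicates)),
                   paste0("C15m_", seq_len(replicates)))
  pairs_tab <- bin_pair_counts(mats, coarse_bin = 2e6)
  cond_lab <- stats::setNames(rep(c("NC", "C15m"), each = replicates),
                              names(mats))
  differential <- nb_differential(pairs_tab, cond_lab)

  ## --- TADs and 3D models ----------------------------------------------
  all_mats <- unlist(hic$matrices, recursive = FALSE)
  bsets <- lapply(all_mats, function(cm) {
    cm <- balance_ice(cm)
    insulation_boundaries(cm, window = 10, delta_threshold = 0.1)
  })
  seg <- consensus_boundaries(bsets, layout$bins,
                              min_support = ceiling(length(bsets) * 5 / 9),
                              tol_bins = 1)
  models <- NULL
  radial <- NULL
  if (n_models > 0) {
    # model the 15-minute state, whose consensus interactions carry the
    # planted subtelomeric gains
    constraints <- interaction_constraints(sig$C15m, layout$bins,
                                           seg$segments)
    ens <- model_ensemble(seg$segments, constraints, n_models = n_models,
                          steps = mc_steps, seed = seed + 5)
    ens <- structure(lapply(ens, annotate_beads,
                            annotation = consensus$C15m[, c("chrom", "start",
                                                            "end", "label")]),
                     class = "bead_ensemble")
    models <- ens
    radial <- radial_stats(ens)
  }

  list(layout = layout, genes = genes, lfc = lfc, tecs = tecs,
       profiles = profiles, up_tecs = up_tecs, down_tecs = down_tecs,
       consensus = consensus, switches = switches,
       association = association, switch_mbp = switch_mbp,
       significant = sig, mds = mds, mds_displacement = disp,
       differential = differential, segmentation = seg,
       models = models, radial = radial,
       truth = list(hic = hic$truth, switch_blocks = genome$switch_blocks,
                    planted_pairs = planted_pairs,
                    gene_cluster = genes[, c("gene_id", "cluster")]))
}

#' Sum replicate contact matrices
#'
#' @param matrices List of [contact_matrix()] objects on one bin grid.
#' @return A pooled [contact_matrix()].
#' @export
pool_replicates <- function(matrices) {
  counts <- Reduce(`+`, lapply(matrices, function(m) m$counts))
  contact_matrix(matrices[[1]]$bins, counts)
}

#' Convert consensus interactions to bead attraction constraints
#'
#' Maps bin-level consensus interaction calls onto the bead segmentation:
#' each interacting bin pair becomes an attraction constraint between the
#' beads containing the two bins (pairs collapsing onto one bead or onto
#' chain neighbours are dropped).
#'
#' @param interactions Tibble with `bin1`, `bin2` (from
#'   [replicate_consensus_interactions()]).
#' @param bins Bin table of the contact matrices.
#' @param segments Bead segmentation (`chrom`, `start`, `end`).
#' @return Tibble `bead1`, `bead2`.
#' @export
interaction_constraints <- function(interactions, bins, segments) {
  if (nrow(interactions) == 0L)
    return(tibble::tibble(bead1 = integer(), bead2 = integer()))
  seg_gr <- GenomicRanges::GRanges(
    segments$chrom,
    IRanges::IRanges(start = segments$start + 1, end = segments$end))
  bin_mid <- GenomicRanges::GRanges(
    bins$chrom,
    IRanges::IRanges(start = floor((bins$start + bins$end) / 2) + 1, width = 1))
  bead_of <- GenomicRanges::findOverlaps(bin_mid, seg_gr, select = "first")
  out <- tibble::tibble(bead1 = bead_of[interactions$bin1],
                        bead2 = bead_of[interactions$bin2])
  out <- out[!is.na(out$bead1) & !is.na(out$bead2), ]
  a <- pmin(out$bead1, out$bead2); b <- pmax(out$bead1, out$bead2)
  keep <- b - a > 1 | segments$chrom[a] != segments$chrom[b]
  dplyr::distinct(tibble::tibble(bead1 = a[keep], bead2 = b[keep]))
}
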