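make_lfc <- function(x, ids = sprintf("g%04d", seq_len(nrow(x)))) {
  colnames(x) <- c("C15m", "C1h", "C4h", "C24h")
  dplyr::bind_cols(tibble::tibble(gene_id = ids), tibble::as_tibble(x))
}

test_that("Ward-D2 heights match a Lance-Williams oracle", {
  set.seed(21)
  x <- matrix(rnorm(20 * 4), ncol = 4)
  tree <- ward_linkage(make_lfc(x))
  expect_equal(sort(tree$height), ward_heights_lw(x), tolerance = 1e-9)
  expect_true(all(diff(tree$height) >= -1e-12))
})

test_that("coincident points merge at height zero first", {
  x <- rbind(c(0, 0, 0, 0), c(0, 0, 0, 0), c(9, 9, 9, 9), c(9, 9, 9, 9))
  tree <- ward_linkage(make_lfc(x))
  expect_equal(tree$height[1:2], c(0, 0))
  dup <- matrix(1, nrow = 6, ncol = 4)
  expect_equal(ward_linkage(make_lfc(dup))$height, rep(0, 5))
  expect_error(ward_linkage(make_lfc(rbind(c(1, NA, 1, 1), c(0, 0, 0, 0)))),
               "finite")
  expect_error(ward_linkage(make_lfc(matrix(1, 1, 4))), "2 genes")
})

clean_two_clusters <- function(n_each = 200, sep = 6, sd = 0.2, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(0, n_each, 4), matrix(sep, n_each, 4)) +
    rnorm(2 * n_each * 4, sd = sd)
  make_lfc(x)
}

test_that("the adaptive cut recovers two clean planted clusters completely", {
  lfc <- clean_two_clusters()
  tree <- ward_linkage(lfc)
  lab <- dynamic_tree_cut(tree, min_cluster_size = 100, deep_split = 0)
  expect_setequal(unique(lab), 1:2)
  expect_equal(unname(table(lab)), c(200L, 200L), ignore_attr = TRUE)
  # cluster identity matches the planted split
  expect_equal(length(unique(lab[1:200])), 1L)
  expect_equal(length(unique(lab[201:400])), 1L)
})

test_that("cut edge cases: oversize minimum, invalid arguments", {
  lfc <- clean_two_clusters(n_each = 30)
  tree <- ward_linkage(lfc)
  expect_true(all(dynamic_tree_cut(tree, min_cluster_size = 100) == 0))
  expect_error(dynamic_tree_cut(tree, min_cluster_size = 0), "min_cluster_size")
  expect_error(dynamic_tree_cut(tree, 10, deep_split = 5), "deep_split")
})

test_that("higher deep_split yields at least as many clusters", {
  sim <- sim_expression_lfc(genes_per_cluster = 120, n_irregular = 300,
                            seed = 13)
  tree <- ward_linkage(sim$lfc)
  ks <- vapply(0:4, function(ds)
    length(setdiff(unique(dynamic_tree_cut(tree, 40, ds)), 0L)), integer(1))
  expect_true(all(diff(ks) >= 0))
})

test_that("cluster labels are permutation equivariant", {
  sim <- sim_expression_lfc(genes_per_cluster = 80, n_irregular = 100,
                            seed = 31)
  lab <- dynamic_tree_cut(ward_linkage(sim$lfc), 40, 0)
  set.seed(5)
  p <- sample(nrow(sim$lfc))
  lab_p <- dynamic_tree_cut(ward_linkage(sim$lfc[p, ]), 40, 0)
  # compare as unordered partitions: cluster ids may swap between
  # equal-sized clusters, membership sets may not
  canon <- function(ids, lab) {
    parts <- lapply(split(ids, lab), sort)
    unname(parts[order(vapply(parts, paste, character(1), collapse = ","))])
  }
  expect_identical(canon(sim$lfc$gene_id, lab),
                   canon(sim$lfc$gene_id[p], lab_p))
})

test_that("silhouette widths match hand-computed geometry", {
  # two tight, far-separated clusters: all scores near 1
  lfc <- clean_two_clusters(n_each = 20, sep = 50, sd = 0.05, seed = 3)
  lab <- rep(1:2, each = 20)
  s <- silhouette_scores(lfc, lab)
  expect_true(all(s > 0.9))
  expect_true(all(s >= -1 & s <= 1))
  # a point equidistant between two 2-point clusters scores ~ 0:
  # cluster 1 = {0, m}, cluster 2 = {d, d}; with m midway a(m) = b(m)
  x <- rbind(c(0, 0, 0, 0), c(2, 0, 0, 0), c(4, 0, 0, 0), c(4, 0, 0, 0))
  s2 <- silhouette_scores(make_lfc(x), c(1, 1, 2, 2))
  a_mid <- 2; b_mid <- 2  # |m - 0| = 2 and mean distance to cluster 2 = 2
  expect_equal(s2[2], (b_mid - a_mid) / max(a_mid, b_mid))
  # label-0 genes are excluded, single cluster warns
  expect_warning(silhouette_scores(make_lfc(x), c(1, 1, 0, 0)),
                 "fewer than 2")
  expect_true(all(is.na(suppressWarnings(
    silhouette_scores(make_lfc(x), c(1, 1, 0, 0))[3:4]))))
})

test_that("the silhouette gate sends sub-threshold genes to TEC0 exactly", {
  lfc <- clean_two_clusters(n_each = 5, seed = 9)
  labels <- rep(1:2, each = 5)
  scores <- c(0.09, 0.10, 0.5, 0.5, 0.5, 0.10, 0.09, 0.5, 0.5, 0.5)
  tecs <- assign_tecs(lfc, labels, scores, threshold = 0.1)
  expect_equal(tecs$tec[1], 0L)  # 0.09 gated
  expect_gt(tecs$tec[2], 0L)     # 0.10 kept
  expect_equal(tecs$tec[7], 0L)
  # min silhouette among assigned respects the gate
  expect_true(min(tecs$silhouette[tecs$tec != 0]) >= 0.1)
  # threshold above the range gates everything
  all0 <- assign_tecs(lfc, labels, scores, threshold = 1.1)
  expect_true(all(all0$tec == 0L))
  # NA scores (unassigned by the cut) are TEC0
  na_tecs <- assign_tecs(lfc, c(0, labels[-1]), c(NA, scores[-1]))
  expect_equal(na_tecs$tec[1], 0L)
})

test_that("TEC profiles summarise members with conservation of counts", {
  x <- rbind(matrix(c(1, 2, 3, 4), 5, 4, byrow = TRUE),
             matrix(c(-1, 0, 1, 2), 3, 4, byrow = TRUE))
  lfc <- make_lfc(x)
  tecs <- assign_tecs(lfc, rep(c(1, 2), c(5, 3)), rep(0.5, 8))
  prof <- tec_profiles(lfc, tecs)
  p1 <- prof[prof$tec == min(prof$tec), ]
  expect_equal(p1$sd, rep(0, 4))
  expect_equal(sum(prof$n) / 4, 8)
  big <- prof[prof$n == 5, ]
  expect_equal(big$mean[big$timepoint == "C4h"], 3)
})

test_that("planted archetype means are recovered within a CLT bound", {
  sim <- sim_expression_lfc(genes_per_cluster = 150, n_irregular = 0,
                            noise_sd = 0.3, seed = 17)
  tecs <- tec_cluster(sim$lfc, min_cluster_size = 60)
  prof <- tec_profiles(sim$lfc, tecs)
  arch <- tec_archetypes()
  # map each recovered TEC to its majority planted cluster
  joined <- dplyr::inner_join(tibble::as_tibble(tecs), sim$truth, by = "gene_id")
  for (tec in setdiff(unique(joined$tec), 0L)) {
    members <- joined[joined$tec == tec, ]
    planted <- as.integer(names(which.max(table(members$cluster))))
    p <- prof[prof$tec == tec, ]
    bound <- 3 * 0.3 / sqrt(nrow(members)) + 0.05
    for (tp in colnames(arch)) {
      expect_lt(abs(p$mean[p$timepoint == tp] - arch[planted, tp]), bound)
    }
  }
})
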