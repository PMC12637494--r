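test_that("chromosome contact profiles average balanced trans pixels", {
  n <- 20
  m <- matrix(6, n, n)
  bins <- tibble::tibble(chrom = rep(c("a", "b"), each = 10),
                         start = rep(0:9 * 1e5, 2), end = rep(1:10 * 1e5, 2))
  cm <- contact_matrix(bins, m, weights = rep(1, n))
  p <- chromosome_contact_profile(cm)
  expect_equal(p["a", "b"], 6)
  expect_equal(p["a", "b"], p["b", "a"])
  expect_true(is.na(p["a", "a"]))
  # doubling one block doubles only that entry
  m2 <- m; m2[1:10, 11:20] <- 12; m2[11:20, 1:10] <- 12
  p2 <- chromosome_contact_profile(contact_matrix(bins, m2,
                                                  weights = rep(1, n)))
  expect_equal(p2["a", "b"], 12)
  expect_error(chromosome_contact_profile(contact_matrix(bins, m)),
               "weights")
})

test_that("frequency-to-dissimilarity transforms are strictly decreasing", {
  f <- matrix(c(NA, 1, 2, 1, NA, 4, 2, 4, NA), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  diag(f) <- 1
  d <- freq_to_dissimilarity(f, "inverse")
  expect_equal(d["a", "b"], 1)
  expect_equal(d["a", "c"], 0.5)
  expect_equal(d["b", "c"], 0.25)
  expect_equal(unname(diag(d)), rep(0, 3))
  dn <- freq_to_dissimilarity(f, "neglog")
  expect_equal(min(dn[row(dn) != col(dn)]), 0)
  expect_true(dn["a", "b"] > dn["a", "c"])
  zero <- matrix(0, 3, 3)
  expect_error(freq_to_dissimilarity(zero), "positive")
})

test_that("nonmetric MDS recovers monotone-transformed planar geometry", {
  set.seed(4)
  X <- matrix(runif(20), ncol = 2)
  d2 <- as.matrix(dist(X))^2   # a monotone transform of true distances
  fit <- nonmetric_mds(d2, k = 2)
  expect_lte(fit$stress, 0.05)
  expect_true(all(diff(fit$trace) <= 0))
  al <- procrustes_align(X, fit$points)
  expect_lte(sqrt(al$disparity), 0.05)
  # rank invariance: adding a constant off-diagonal leaves the solution
  d3 <- d2 + 0.3; diag(d3) <- 0
  fit3 <- nonmetric_mds(d3, k = 2)
  al3 <- procrustes_align(fit$points, fit3$points)
  expect_lte(sqrt(al3$disparity), 0.05)
  # equilateral triangle embeds exactly
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  ft <- nonmetric_mds(tri, k = 2)
  expect_lt(ft$stress, 1e-3)
  expect_equal(sd(as.numeric(dist(ft$points))), 0, tolerance = 1e-3)
  expect_error(nonmetric_mds(tri[1:2, 1:2]), "3 points")
})

test_that("final stress agrees with an independent nonmetric MDS", {
  skip_if_not_installed("MASS")
  set.seed(14)
  X <- matrix(rnorm(24), ncol = 2)
  d <- as.matrix(dist(X)) + matrix(runif(144, 0, 0.3), 12)[, ]
  d <- (d + t(d)) / 2; diag(d) <- 0
  fit <- nonmetric_mds(d, k = 2)
  ref <- MASS::isoMDS(stats::as.dist(d), k = 2, trace = FALSE)
  expect_lt(abs(fit$stress - ref$stress / 100), 0.02)
})

test_that("Procrustes alignment is invariant to rigid motion and reflection", {
  set.seed(6)
  X <- matrix(rnorm(20), ncol = 2)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- X %*% R + 3
  expect_lt(procrustes_align(X, rot)$disparity, 1e-10)
  mir <- X %*% diag(c(-1, 1))
  expect_lt(procrustes_align(X, mir)$disparity, 1e-10)
  d <- procrustes_align(X, matrix(rnorm(20), ncol = 2))$disparity
  expect_true(d >= 0 && d <= 1)
  expect_error(procrustes_align(matrix(0, 5, 2), matrix(0, 5, 2)),
               "degenerate")
})

test_that("anchors get greatest-overlap A/B labels and homotypic calls", {
  track <- tibble::tibble(chrom = "c",
                          start = c(0, 1e6, 2e6, 2.6e6),
                          end = c(1e6, 2e6, 2.6e6, 3e6),
                          label = c("A3", "B1", "A0", "B3"))
  pairs <- tibble::tibble(chrom1 = "c", start1 = c(0, 0, 2e6),
                          end1 = c(1e6, 1e6, 3e6),
                          chrom2 = "c", start2 = c(0, 1e6, 1e6),
                          end2 = c(1e6, 2e6, 2e6))
  out <- homotypic_annotation(pairs, track)
  expect_equal(out$ab1, c("A", "A", "A"))  # third anchor: 0.6 Mb A0 vs 0.4 Mb B3
  expect_equal(out$ab2, c("A", "B", "B"))
  expect_equal(out$homotypic, c(TRUE, FALSE, FALSE))
})

test_that("subtelomeric calls respect absolute and fractional windows", {
  lens <- c(c1 = 100e6)
  pairs <- tibble::tibble(chrom1 = "c1", start1 = c(0, 40e6),
                          end1 = c(1e6, 41e6),
                          chrom2 = "c1", start2 = c(96e6, 50e6),
                          end2 = c(97e6, 51e6))
  out <- subtelomere_annotation(pairs, lens, window = 5e6)
  expect_equal(out$subtelomeric, c(TRUE, FALSE))
  frac <- subtelomere_annotation(pairs, lens, window = 0.5)
  expect_true(all(frac$subtelomeric))
})

test_that("per-TEC region overlap proportions are exact", {
  genes <- tibble::tibble(gene_id = sprintf("g%02d", 1:12), chrom = "c",
                          tss = seq(0, 11) * 1e6)
  tecs <- tibble::tibble(gene_id = genes$gene_id, tec = rep(1L, 12))
  regions <- tibble::tibble(chrom = "c", start = 0, end = 2.5e6)
  out <- tec_overlap_with_regions(genes, tecs, regions)
  expect_equal(out$proportion, 25)   # 3 of 12
  all_in <- tec_overlap_with_regions(genes, tecs,
                                     tibble::tibble(chrom = "c", start = 0,
                                                    end = 12e6))
  expect_equal(all_in$proportion, 100)
  none <- tec_overlap_with_regions(genes, tecs, regions[0, ])
  expect_equal(none$proportion, 0)
})

test_that("Fisher exact matches full enumeration on random small tables", {
  expect_equal(fisher_2x2(matrix(5, 2, 2))$odds_ratio, 1)
  expect_equal(fisher_2x2(matrix(5, 2, 2))$p, 1)
  t2 <- matrix(c(10, 30, 20, 5), 2)
  out <- fisher_2x2(t2)
  expect_equal(out$odds_ratio, (10 * 5) / (20 * 30))
  expect_equal(out$p, enum_fisher_p(t2), tolerance = 1e-12)
  set.seed(33)
  for (i in 1:500) {
    tab <- matrix(rpois(4, sample(2:10, 1)), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      expect_equal(fisher_2x2(tab)$p, 1)
      next
    }
    expect_equal(fisher_2x2(tab)$p, enum_fisher_p(tab), tolerance = 1e-10)
  }
  zero_margin <- matrix(c(0, 0, 3, 4), 2)
  zm <- fisher_2x2(zero_margin)
  expect_equal(zm$p, 1)
  expect_false(zm$or_defined)
})

test_that("switch-versus-regulation association handles perfect coupling", {
  switches <- tibble::tibble(gene_id = sprintf("g%02d", 1:40),
                             direction = rep(c("opening", "closing"),
                                             each = 20))
  tecs <- tibble::tibble(gene_id = switches$gene_id,
                         tec = rep(c(2L, 1L), each = 20))
  out <- switching_vs_regulation(switches, tecs)
  expect_equal(out$table["opening", "up"], 20)
  expect_equal(out$table["closing", "down"], 20)
  expect_false(out$test$or_defined)     # infinite sample odds ratio
  expect_lt(out$test$p, 1e-8)
  # gene-set switching on the same data
  gs <- geneset_switching_test(
    dplyr::mutate(switches, direction = rep(c("opening", "stable"),
                                            each = 20)),
    gene_set = switches$gene_id[1:20])
  expect_equal(gs$table["in_set", "switched"], 20)
  expect_lt(gs$test$p, 1e-8)
  expect_error(geneset_switching_test(switches, character(0)), "non-empty")
})

test_that("track overlaps count intersected megabases with row z-scores", {
  track <- tibble::tibble(chrom = "c", start = c(0, 1e6),
                          end = c(1e6, 2e6), label = c("A3", "B3"))
  feats <- list(f1 = tibble::tibble(chrom = "c", start = 0, end = 1e6),
                f2 = tibble::tibble(chrom = "c", start = 1e6, end = 2e6))
  out <- track_overlap_matrix(track, feats)
  expect_equal(out$mbp, matrix(c(1, 0, 0, 1), 2,
                               dimnames = list(c("A3", "B3"),
                                               c("f1", "f2"))))
  # a feature fully inside one label's territory counts its full length
  part <- track_overlap_matrix(track,
                               list(f = tibble::tibble(chrom = "c",
                                                       start = 2e5,
                                                       end = 7e5)))
  expect_equal(part$mbp["A3", "f"], 0.5)
  expect_equal(part$mbp["B3", "f"], 0)
  # identical row -> z-scores all zero
  same <- track_overlap_matrix(track,
                               list(u = tibble::tibble(chrom = "c", start = 0,
                                                       end = 2e6),
                                    v = tibble::tibble(chrom = "c", start = 0,
                                                       end = 2e6)))
  expect_true(all(same$z == 0))
})

test_that("MDS detects partially reversible chromosome repositioning", {
  # one focal chromosome strengthens trans contacts with a clique at 15
  # minutes and partially reverts at 4 hours; its aligned displacement
  # should be larger at the early timepoint in nearly every simulation
  chroms <- paste0("chr", 1:8)
  # each simulation has a fixed structured baseline territory profile
  # shared by all conditions; only the focal clique gains and small
  # per-condition noise differ between conditions
  profile_for <- function(base, gain, seed) {
    set.seed(seed)
    f <- base
    f["chr1", c("chr2", "chr3", "chr4")] <- gain *
      f["chr1", c("chr2", "chr3", "chr4")]
    f[c("chr2", "chr3", "chr4"), "chr1"] <- f["chr1", c("chr2", "chr3", "chr4")]
    noise <- matrix(exp(rnorm(64, sd = 0.05)), 8)
    noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
    f <- f * noise
    diag(f) <- NA
    f
  }
  wins <- 0L
  for (s in 1:20) {
    set.seed(1000 + s)
    base <- matrix(exp(rnorm(64, sd = 0.5)), 8,
                   dimnames = list(chroms, chroms))
    base[lower.tri(base)] <- t(base)[lower.tri(base)]
    fit_nc <- nonmetric_mds(freq_to_dissimilarity(
      profile_for(base, 1, s * 3 + 1)))
    fit_15 <- nonmetric_mds(freq_to_dissimilarity(
      profile_for(base, 3, s * 3 + 2)))
    fit_4 <- nonmetric_mds(freq_to_dissimilarity(
      profile_for(base, 1.5, s * 3 + 3)))
    d15 <- procrustes_align(fit_nc$points, fit_15$points)
    d4 <- procrustes_align(fit_nc$points, fit_4$points)
    move <- function(al) sqrt(rowSums((al$aligned - al$reference)^2))["chr1"]
    if (move(d15) > move(d4)) wins <- wins + 1L
  }
  expect_gte(wins, 18)
})
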