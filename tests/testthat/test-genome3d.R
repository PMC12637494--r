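two_chrom_segments <- function(n_per = 20, len = 1e6) {
  tibble::tibble(chrom = rep(c("c1", "c2"), each = n_per),
                 start = rep((seq_len(n_per) - 1) * len, 2),
                 end = rep(seq_len(n_per) * len, 2))
}

test_that("bead initialization obeys volume and containment contracts", {
  seg <- two_chrom_segments()
  m <- init_beads(seg, nucleus_radius = 5, occupancy = 0.15, seed = 2)
  # equal segment lengths -> equal radii
  expect_equal(sd(m$beads$radius), 0)
  # total bead volume = occupancy * nuclear volume
  vol <- sum(4 / 3 * pi * m$beads$radius^3)
  expect_equal(vol, 0.15 * 4 / 3 * pi * 5^3, tolerance = 1e-6)
  # inside the nucleus
  expect_true(all(radial_distances(m) + m$beads$radius <= 5 + 1e-9))
  # deterministic
  m2 <- init_beads(seg, nucleus_radius = 5, occupancy = 0.15, seed = 2)
  expect_identical(m$beads, m2$beads)
  expect_error(init_beads(seg, occupancy = 1), "occupancy")
  # radii scale with length^(1/3)
  seg2 <- tibble::tibble(chrom = "c", start = c(0, 1e6), end = c(1e6, 9e6))
  r <- init_beads(seg2, seed = 1)$beads$radius
  expect_equal(r[2] / r[1], 2, tolerance = 1e-9)
})

test_that("Monte-Carlo optimization satisfies its contracts on a toy", {
  seg <- tibble::tibble(chrom = c("c1", "c2"), start = 0, end = 1e6)
  m0 <- init_beads(seg, occupancy = 0.01, seed = 4)
  expect_identical(mc_optimize(m0, steps = 0), m0)
  fit <- mc_optimize(m0, tibble::tibble(bead1 = 1, bead2 = 2),
                     steps = 4000, seed = 4)
  trace <- attr(fit, "trace")
  expect_true(all(diff(trace) <= 1e-12))
  expect_lte(fit$loss, model_loss(m0, tibble::tibble(bead1 = 1, bead2 = 2)))
  d <- as.numeric(dist(as.matrix(fit$beads[, c("x", "y", "z")])))
  expect_lte(d - sum(fit$beads$radius), 0.1 * sum(fit$beads$radius))
  expect_true(all(radial_distances(fit) + fit$beads$radius <= 5 + 1e-9))
  expect_error(mc_optimize(m0, tibble::tibble(bead1 = 1, bead2 = 99),
                           steps = 10), "invalid beads")
})

test_that("attraction constraints pull their pairs closer than background", {
  seg <- two_chrom_segments()
  set.seed(3)
  con <- tibble::tibble(bead1 = sample(1:20, 10),
                        bead2 = sample(21:40, 10))
  m <- init_beads(seg, occupancy = 0.1, seed = 7)
  fit <- mc_optimize(m, con, steps = 15000, seed = 7)
  xyz <- as.matrix(fit$beads[, c("x", "y", "z")])
  dmat <- as.matrix(dist(xyz))
  con_d <- dmat[cbind(con$bead1, con$bead2)]
  # background: unconstrained trans pairs
  bg <- expand.grid(a = 1:20, b = 21:40)
  bg_key <- paste(bg$a, bg$b)
  bg <- bg[!(bg_key %in% paste(con$bead1, con$bead2)), ]
  bg_d <- dmat[cbind(bg$a, bg$b)]
  expect_lt(median(con_d), median(bg_d))
})

test_that("ensembles are reproducible with distinct per-model seeds", {
  seg <- tibble::tibble(chrom = "c1", start = 0:3 * 1e6, end = 1:4 * 1e6)
  ens <- model_ensemble(seg, NULL, n_models = 2, steps = 500, seed = 11)
  expect_length(ens, 2)
  expect_false(identical(ens[[1]]$beads$x, ens[[2]]$beads$x))
  ens2 <- model_ensemble(seg, NULL, n_models = 2, steps = 500, seed = 11)
  expect_identical(ens[[2]]$beads, ens2[[2]]$beads)
})

test_that("bead annotation picks the largest overlap with declared tie rule", {
  seg <- tibble::tibble(chrom = "c", start = c(0, 1e5), end = c(1e5, 2e5))
  m <- init_beads(seg, seed = 1)
  track <- tibble::tibble(chrom = "c",
                          start = c(0, 6e4, 1e5, 1.5e5),
                          end = c(6e4, 1e5, 1.5e5, 2e5),
                          label = c("A3", "B1", "B2", "A1"))
  out <- annotate_beads(m, track)
  expect_equal(out$beads$label, c("A3", "A1"))  # 60 > 40; exact tie -> A1 < B2
  none <- annotate_beads(m, track[0, ])
  expect_true(all(is.na(none$beads$label)))
  genes <- tibble::tibble(chrom = "c", tss = c(1e4, 2e4, 7e4),
                          label = c("T1", "T1", "T2"))
  g <- annotate_beads(m, genes, by = "genes")
  expect_equal(g$beads$label[1], "T1")  # 2 genes beat 1
})

test_that("radial statistics recover planted group geometry", {
  groups <- tibble::tibble(label = c("A", "B"), mean_radius = c(3, 4),
                           sd = 0, n = 100)
  ens <- sim_bead_cloud(1, groups, seed = 5)
  rs <- radial_stats(ens)
  expect_equal(rs$summary$median[rs$summary$label == "A"], 3)
  expect_equal(rs$summary$median[rs$summary$label == "B"], 4)
  expect_lt(rs$pairwise$p_holm, 1e-10)
  # identical groups: adjusted p stays high
  same <- tibble::tibble(label = c("X", "Y"), mean_radius = 3, sd = 0.3,
                         n = 60)
  rs2 <- radial_stats(sim_bead_cloud(1, same, seed = 8))
  expect_gt(rs2$pairwise$p_holm, 0.1)
})

test_that("per-bead median shifts detect translations and nothing else", {
  groups <- tibble::tibble(label = "G", mean_radius = 3, sd = 0.3, n = 80)
  a <- sim_bead_cloud(4, groups, seed = 3)
  sh0 <- per_bead_median_shift(a, a)
  expect_true(all(sh0$shifts$delta == 0))
  expect_equal(sh0$p, 1)
  # scale every center outward so each distance grows by exactly 0.1
  b <- structure(lapply(a, function(m) {
    d <- radial_distances(m)
    f <- (d + 0.1) / d
    m$beads$x <- m$beads$x * f
    m$beads$y <- m$beads$y * f
    m$beads$z <- m$beads$z * f
    m
  }), class = "bead_ensemble")
  sh <- per_bead_median_shift(a, b)
  expect_equal(sh$shifts$delta, rep(0.1, 80), tolerance = 1e-9)
  expect_lt(sh$p, 1e-6)
  bad <- sim_bead_cloud(4, dplyr::mutate(groups, n = 70), seed = 3)
  expect_error(per_bead_median_shift(a, bad), "segmentation")
})
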