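test_that("a two-block map yields a bimodal score separating the blocks", {
  n <- 40
  mu <- matrix(3, n, n)
  mu[1:20, 1:20] <- 30
  mu[21:40, 21:40] <- 30
  cm <- toy_matrix(mu, seed = 2)
  activity <- rep(c(1, 0), each = 20)
  score <- subcompartment_rank(cm, activity)
  expect_true(min(score[1:20]) > max(score[21:40]))
  # orientation contract: flipping the covariate flips the score
  flipped <- subcompartment_rank(cm, 1 - activity)
  expect_equal(flipped, -score)
})

test_that("degenerate matrices give NA scores with a warning", {
  n <- 20
  cm <- contact_matrix(tibble::tibble(chrom = "c", start = 0:(n-1) * 1e5,
                                      end = 1:n * 1e5),
                       matrix(0, n, n))
  expect_warning(s <- subcompartment_rank(cm, runif(n)), "all-zero")
  expect_true(all(is.na(s)))
  cm2 <- contact_matrix(cm$bins, matrix(5, n, n))
  expect_warning(s2 <- subcompartment_rank(cm2, runif(n)), "degenerate")
  expect_true(all(is.na(s2)))
})

test_that("octile discretization is exact, order-preserving and NA-safe", {
  n <- 80
  bins <- tibble::tibble(chrom = "c", start = 0:(n-1) * 1e5, end = 1:n * 1e5)
  cm <- contact_matrix(bins, matrix(1, n, n))
  score <- seq(1, 0, length.out = n)   # monotone decreasing along genome
  track <- rank_to_labels(cm, score)
  expect_equal(unname(table(track$label)[subcompartment_levels()]),
               rep(10L, 8), ignore_attr = TRUE)
  expect_equal(track$label, rep(subcompartment_levels(), each = 10))
  score[5] <- NA
  track2 <- rank_to_labels(cm, score)
  expect_true(is.na(track2$label[5]))
  expect_error(rank_to_labels(cm, rep(NA_real_, n)), "at least 8")
})

test_that("replicate consensus requires two exact agreements", {
  bins <- tibble::tibble(bin = 1:3, chrom = "c", start = c(0, 1, 2) * 1e5,
                         end = c(1, 2, 3) * 1e5)
  tr <- function(labs) dplyr::mutate(bins, label = labs)
  cons <- consensus_labels(list(tr(c("A1", "A1", "A1")),
                                tr(c("A1", "A1", "B0")),
                                tr(c("A1", "B3", "B3"))))
  # bin 3 sees three distinct labels: no two replicates agree
  expect_equal(cons$label, c("A1", "A1", NA))
  none <- consensus_labels(list(tr(c("A1", NA, NA)), tr(c("B0", NA, NA)),
                                tr(c("B3", NA, NA))))
  expect_true(all(is.na(none$label)))
  # symmetric in replicate order
  perm <- consensus_labels(list(tr(c("A1", "B3", "B3")),
                                tr(c("A1", "A1", "A1")),
                                tr(c("A1", "A1", "B0"))))
  expect_equal(cons$label, perm$label)
  bad <- tr(c("A1", "A1", "A1")); bad$start <- bad$start + 1
  expect_error(consensus_labels(list(tr(c("A1", "A1", "A1")), bad,
                                     tr(c("A1", "A1", "A1")))), "identical")
})

test_that("TSS mapping uses half-open bin containment", {
  track <- tibble::tibble(chrom = "c", start = c(0, 1e5, 2e5, 3e5),
                          end = c(1e5, 2e5, 3e5, 4e5),
                          label = c("A3", "A1", NA, "B2"))
  genes <- tibble::tibble(gene_id = c("g1", "g2", "g3", "g4", "g5"),
                          chrom = c("c", "c", "c", "c", "zzz"),
                          tss = c(150000, 200000, 250000, 0, 10))
  expect_warning(out <- map_tss_to_label(genes, track), "zzz")
  expect_equal(out$label, c("A1", NA, NA, "A3", NA))
  # boundary TSS 200000 belongs to [200000, 300000), whose label is NA here;
  # check the boundary rule on a labelled bin too
  g2 <- tibble::tibble(gene_id = "g", chrom = "c", tss = 3e5)
  expect_equal(map_tss_to_label(g2, track)$label, "B2")
})

test_that("switch classification agrees with brute-force rank enumeration", {
  lv <- subcompartment_levels()
  grid <- expand.grid(from = lv, to = lv, stringsAsFactors = FALSE)
  out <- classify_switch(grid$from, grid$to)
  fac <- c("A1", "A0", "B0", "B1")
  for (k in seq_len(nrow(grid))) {
    rf <- match(grid$from[k], lv); rt <- match(grid$to[k], lv)
    expect_equal(out$direction[k],
                 if (rf == rt) "stable" else if (rt < rf) "opening" else "closing")
    expect_equal(out$facultative[k],
                 if (grid$to[k] %in% fac && !(grid$from[k] %in% fac)) "gain"
                 else if (grid$from[k] %in% fac && !(grid$to[k] %in% fac)) "loss"
                 else "none")
  }
  nas <- classify_switch(c(NA, "A1"), c("A1", NA))
  expect_true(all(is.na(nas$direction)))
  expect_error(classify_switch("A9", "B1"), "alphabet")
})

test_that("the switch matrix conserves labelled megabases", {
  bins <- tibble::tibble(chrom = "c", start = 0:3 * 1e5, end = 1:4 * 1e5)
  ta <- dplyr::mutate(bins, label = c("A1", "A1", "B3", NA))
  tb <- dplyr::mutate(bins, label = c("A1", "B0", "B3", "A0"))
  m <- switch_matrix(ta, tb)
  expect_equal(m["A1", "A1"], 0.1)
  expect_equal(m["A1", "B0"], 0.1)
  expect_equal(m["B3", "B3"], 0.1)
  expect_equal(sum(m), 0.3)  # NA bins excluded
  ident <- switch_matrix(ta, ta)
  expect_equal(sum(ident) - sum(diag(ident)), 0)
})
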