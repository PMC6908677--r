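test_that("PC1 scores separate a two-block checkerboard and follow gene density", {
  # 40-bin, two-block map: scores must split by block, oriented so the
  # gene-dense block is positive
  n <- 40
  lab <- rep(c(1, 2), each = 20)
  cb <- matrix(0.6, n, n)
  cb[outer(lab, lab, "==")] <- 2
  cb <- cb * (1 / pmax(abs(outer(1:n, 1:n, "-")), 0.5))^0.3
  m <- contact_matrix(cb, genome_bins("chrT", n * 4e4, 4e4),
                      normalized = TRUE)
  gd <- ifelse(lab == 1, 10, 2)
  tr <- pca_scores(m, gd)
  expect_true(all(tr$score[lab == 1] > 0))
  expect_true(all(tr$score[lab == 2] < 0))

  # eigendecomposition oracle: scores proportional to the leading
  # eigenvector of the O/E correlation matrix
  oe <- observed_over_expected(m)$counts
  ev <- eigen(stats::cor(oe), symmetric = TRUE)
  oracle <- ev$vectors[, 1] * sqrt(ev$values[1]) * 100
  if (stats::cor(oracle, gd) < 0) oracle <- -oracle
  expect_equal(tr$score, oracle, tolerance = 1e-9)

  # flipping gene density flips all signs
  tr_flip <- pca_scores(m, -gd + max(gd) + 1)
  expect_equal(tr_flip$score, -tr$score, tolerance = 1e-9)
})

test_that("PC1 degenerates gracefully and rejects short chromosomes", {
  u <- contact_matrix(matrix(1, 20, 20) + diag(20) * 0,
                      genome_bins("chrT", 20 * 4e4, 4e4), normalized = TRUE)
  # zero-variance O/E columns are dropped into the mask -> too few bins
  expect_error(suppressWarnings(pca_scores(u, rep(1, 20))), "too short")
  s <- random_matrix(8, seed = 1)
  expect_error(suppressWarnings(pca_scores(s, rep(1, 8))), "too short")
})

test_that("compartment calling keeps only runs of the minimum length", {
  mk <- function(scores) {
    tr <- genome_bins("chrT", length(scores) * 4e4, 4e4)
    tr$score <- scores
    tr
  }
  cc <- call_compartments(mk(c(rep(1, 6), rep(-1, 5))), min_bins = 5)
  expect_equal(nrow(cc), 2)
  expect_equal(cc$label, c("A", "B"))
  expect_equal(cc$n_bins, c(6L, 5L))
  expect_equal(cc$size_bp, c(6, 5) * 4e4)

  none <- call_compartments(mk(c(1, 1, 1, -1, 1, 1, 1)), min_bins = 5)
  expect_equal(nrow(none), 0)

  # missing and zero bins break runs
  withz <- call_compartments(mk(c(rep(1, 5), 0, rep(1, 3), NA, rep(-1, 6))),
                             min_bins = 5)
  expect_equal(withz$label, c("A", "B"))
  expect_equal(withz$n_bins, c(5L, 6L))
})

test_that("transition categories follow the sign pair and are antisymmetric", {
  g <- genome_bins("chrT", 6 * 4e4, 4e4)
  t1 <- g; t1$score <- c(1, -1, 1, -1, NA, 0)
  t2 <- g; t2$score <- c(1, 1, -1, -1, 1, 1)
  tm <- classify_transitions(t1, t2)
  expect_equal(tm$category, c("AA", "BA", "AB", "BB", NA, NA))

  # swapping conditions maps BA <-> AB and fixes AA/BB
  rev <- classify_transitions(t2, t1)
  expect_equal(rev$category, c("AA", "AB", "BA", "BB", NA, NA))

  same <- classify_transitions(t2, t2)
  expect_true(all(same$category %in% c("AA", "BB")))

  t3 <- genome_bins("chrT", 7 * 4e4, 4e4); t3$score <- rep(1, 7)
  expect_error(classify_transitions(t1, t3), "differ")
})

test_that("transition regions report maximal runs with sizes", {
  g <- genome_bins("chrT", 10 * 4e4, 4e4)
  t1 <- g; t1$score <- c(-1, -1, -1, 1, 1, -1, 1, 1, 1, 1)
  t2 <- g; t2$score <- c(1, 1, -1, 1, -1, -1, 1, 1, 1, 1)
  tm <- classify_transitions(t1, t2)
  reg <- transition_regions(tm)
  expect_equal(reg$category, c("BA", "AB"))
  expect_equal(reg$n_bins, c(2L, 1L))
  expect_equal(reg$size_bp, c(8e4, 4e4))
})

test_that("BAB flags require BA then AB and match planted truth exactly", {
  sim <- default_sim()
  b <- sim$bins
  tg <- label_track(b, b$label_growing)
  ts <- label_track(b, b$label_senescent)
  tk <- label_track(b, b$label_kd)
  tm1 <- classify_transitions(tg, ts)
  tm2 <- classify_transitions(ts, tk)
  expect_identical(classify_bab(tm1, tm2), b$bab)

  # BA then AA is not BAB; empty transitions give no flags
  expect_false(any(classify_bab(classify_transitions(tg, ts),
                                classify_transitions(ts, ts))))
})

test_that("SAHF detection thresholds scores and is monotone in threshold", {
  g <- genome_bins("chrT", 3 * 4e4, 4e4)
  g$score <- c(-25, -10, -30)
  r <- detect_sahf(g, -20)
  expect_equal(attr(r, "flags"), c(TRUE, FALSE, TRUE))
  expect_equal(nrow(r), 2)

  g$score <- c(-5, 0, 10)
  expect_equal(nrow(detect_sahf(g, -20)), 0)

  sim <- default_sim()
  f_low <- attr(detect_sahf(sim$pca_sen, -50), "flags")
  f_hi <- attr(detect_sahf(sim$pca_sen, -40), "flags")
  expect_true(all(f_hi[f_low]))   # lower threshold flags a subset
})

test_that("LVS is a proper long-range mass fraction", {
  # 60-bin toy at 40 kb: cutoff 2 Mb = 50 bins
  n <- 60
  x <- matrix(0, n, n)
  x[1, 2] <- x[2, 1] <- 10          # short-range only for bin 1
  x[5, 60] <- x[60, 5] <- 4          # 55 bins apart: long for bin 5
  x[5, 6] <- x[6, 5] <- 4
  m <- contact_matrix(x, genome_bins("chrT", n * 4e4, 4e4), normalized = TRUE)
  lv <- lvs_scores(m)
  expect_equal(lv$lvs[1], 0)
  expect_equal(lv$lvs[5], 0.5)       # exactly half the mass beyond 2 Mb
  expect_true(is.na(lv$lvs[30]))     # zero-coverage bin

  # adding long-range mass strictly increases lvs
  x2 <- x; x2[5, 58] <- x2[58, 5] <- 2
  lv2 <- lvs_scores(contact_matrix(x2, m$bins, normalized = TRUE))
  expect_gt(lv2$lvs[5], lv$lvs[5])

  sim <- default_sim()
  lvs <- lvs_scores(sim$ice_sen)
  ok <- !is.na(lvs$lvs)
  expect_true(all(lvs$lvs[ok] >= 0 & lvs$lvs[ok] <= 1))
  # long + short mass equals total cis mass exactly
  d <- abs(outer(seq_len(nrow(lvs)), seq_len(nrow(lvs)), "-"))
  off <- sim$ice_sen$counts; diag(off) <- 0
  long <- rowSums(off * (d > 50))
  short <- rowSums(off * (d <= 50 & d > 0))
  expect_equal(long + short, lvs$total_mass, tolerance = 1e-9)
})

test_that("occupancy statistics summarise compartments and transitions", {
  g <- genome_bins("chrT", 11 * 4e4, 4e4)
  t1 <- g; t1$score <- c(rep(1, 6), rep(-1, 5))
  t2 <- t1
  c1 <- call_compartments(t1)
  c2 <- call_compartments(t2)
  st <- occupancy_stats(c1, c2, classify_transitions(t1, t2))
  occA <- st$occupancy$percent[st$occupancy$condition == "condition1" &
                                 st$occupancy$label == "A"]
  expect_equal(occA, 100 * 6 / 11)
  expect_equal(st$transitions$category, c("AA", "BB"))
  # identical compartment sets: exact test p == 1
  expect_true(all(st$size_tests$p_value == 1))
})

test_that("chromosome occupancy percentages and group test behave", {
  flags <- list(chrA = rep(c(TRUE, FALSE), c(10, 90)),
                chrB = rep(FALSE, 50))
  occ <- chromosome_occupancy(flags)
  expect_equal(occ$percent, c(10, 0))
  occ2 <- chromosome_occupancy(
    list(c1 = rep(c(TRUE, FALSE), c(20, 80)),
         c2 = rep(c(TRUE, FALSE), c(22, 78)),
         c3 = rep(c(TRUE, FALSE), c(5, 95)),
         c4 = rep(c(TRUE, FALSE), c(4, 96))),
    groups = list(c("c1", "c2"), c("c3", "c4")))
  expect_true(occ2$percent[1] > occ2$percent[3])
  expect_false(is.na(attr(occ2, "group_test")$p_value))
})
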