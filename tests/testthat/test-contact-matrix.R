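bins3 <- genome_bins("chrT", 3 * 40000, 40000)

test_that("triple loader mirrors, sums duplicates, and validates input", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# header", "0 1 5"), path)
  m <- read_contacts(path, bins3)
  expect_equal(m$counts[1, 2], 5)
  expect_equal(m$counts[2, 1], 5)
  expect_equal(sum(m$counts), 10)

  writeLines(c("0 1 2", "1 0 3"), path)
  m <- read_contacts(path, bins3)
  expect_equal(m$counts[1, 2], 5)

  writeLines(c("0 1 2", "oops"), path)
  expect_error(read_contacts(path, bins3), "line 2")
  writeLines("0 7 1", path)
  expect_error(read_contacts(path, bins3), "out of range")
})

test_that("dense loader rejects asymmetric matrices", {
  path <- withr::local_tempfile(fileext = ".tsv")
  x <- matrix(1:9, 3, 3)
  utils::write.table(x, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  expect_error(read_contacts(path, bins3, format = "dense"), "not symmetric")
  utils::write.table(x + t(x), path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  m <- read_contacts(path, bins3, format = "dense")
  expect_equal(m$counts, x + t(x), ignore_attr = TRUE)
})

test_that("triple round-trip is lossless", {
  m <- random_matrix(12, seed = 5)
  path <- withr::local_tempfile(fileext = ".txt")
  write_contacts(m, path)
  m2 <- read_contacts(path, m$bins)
  expect_equal(m2$counts, m$counts)
})

test_that("ICE removes planted separable biases exactly", {
  # counts = b_i * b_j on a flat truth matrix: balancing must recover the
  # flat matrix up to a global scale, matching direct bias division
  b <- c(1, 2, 4, 1, 3, 2, 1, 2, 4, 1, 3, 2)
  n <- length(b)
  flat <- matrix(1, n, n)
  biased <- flat * outer(b, b)
  m <- contact_matrix(biased, genome_bins("chrT", n * 4e4, 4e4))
  out <- ice_normalize(m, n_iter = 60, low_coverage_quantile = 0)
  ratio <- out$counts / flat
  expect_lt(max(ratio) / min(ratio) - 1, 1e-6)
  rs <- rowSums(out$counts)
  expect_lt((max(rs) - min(rs)) / mean(rs), 1e-6)
  expect_true(out$normalized)
})

test_that("ICE is idempotent at convergence and handles degenerate input", {
  m <- random_matrix(30, seed = 11)
  m$normalized <- FALSE
  out1 <- ice_normalize(m, n_iter = 200, low_coverage_quantile = 0)
  out2 <- ice_normalize(out1, n_iter = 200, low_coverage_quantile = 0)
  b2 <- attr(out2, "biases")
  expect_lt(max(abs(b2[!is.na(b2)] - 1)), 1e-6)

  uniform <- contact_matrix(matrix(3, 10, 10) - diag(3, 10),
                            genome_bins("chrT", 10 * 4e4, 4e4))
  out <- ice_normalize(uniform, n_iter = 5, low_coverage_quantile = 0)
  expect_equal(out$counts, uniform$counts, tolerance = 1e-12)

  zero <- contact_matrix(matrix(0, 10, 10), genome_bins("chrT", 4e5, 4e4))
  expect_error(ice_normalize(zero), "no signal")
  expect_error(ice_normalize(uniform, n_iter = 0), "n_iter")
})

test_that("coarsen sums blocks, keeps partial tails, and preserves totals", {
  m <- contact_matrix(matrix(1, 4, 4), genome_bins("chrT", 16e4, 4e4))
  c2 <- coarsen(m, 2)
  expect_equal(dim(c2$counts), c(2, 2))
  expect_equal(c2$counts[1, 1], 4)
  expect_equal(nrow(c2$bins), 2)

  expect_identical(coarsen(m, 1)$counts, m$counts)

  m5 <- random_matrix(5, seed = 2)
  c5 <- coarsen(m5, 2)
  expect_equal(nrow(c5$counts), 3)                 # last from a single bin
  expect_equal(sum(c5$counts), sum(m5$counts))     # total preserved
  expect_error(coarsen(m5, 0), "factor")

  # coarse bin masked only when all constituents are masked
  mm <- contact_matrix(m5$counts, m5$bins, mask = c(0L, 1L))
  expect_equal(coarsen(mm, 2)$mask, 0L)
})

test_that("observed/expected has unit diagonal means and reveals blocks", {
  m <- random_matrix(25, seed = 3)
  oe <- observed_over_expected(m)
  d <- abs(row(oe$counts) - col(oe$counts))
  for (k in c(0, 1, 5, 10)) {
    vals <- oe$counts[d == k]
    expect_equal(mean(vals), 1, tolerance = 1e-9)
  }

  # matrix equal to its own expected profile -> O/E all 1
  prof <- 1 / (1 + abs(outer(1:20, 1:20, "-")))
  mp <- contact_matrix(prof, genome_bins("chrT", 20 * 4e4, 4e4),
                       normalized = TRUE)
  oe1 <- observed_over_expected(mp)
  expect_equal(max(abs(oe1$counts - 1)), 0, tolerance = 1e-12)

  # 2-block checkerboard: within-block O/E > 1, between-block < 1
  lab <- rep(c(1, 2), each = 10)
  cb <- matrix(0.5, 20, 20)
  cb[outer(lab, lab, "==")] <- 2
  mcb <- contact_matrix(cb, genome_bins("chrT", 20 * 4e4, 4e4),
                        normalized = TRUE)
  oecb <- observed_over_expected(mcb)
  same <- outer(lab, lab, "==")
  d <- abs(row(cb) - col(cb))
  mixed <- d > 0 & d < 10   # separations where both pair types exist
  expect_true(all(oecb$counts[same & mixed] > 1))
  expect_true(all(oecb$counts[!same & mixed] < 1))

  expect_warning(observed_over_expected(
    contact_matrix(cb, genome_bins("chrT", 20 * 4e4, 4e4))), "unnormalized")
})

test_that("decay profile is flat for uniform input and tracks 1/d", {
  u <- contact_matrix(matrix(2, 15, 15), genome_bins("chrT", 15 * 4e4, 4e4),
                      normalized = TRUE)
  p <- contact_decay_profile(u)
  expect_true(all(p$mean_contact == 2))
  expect_true(all(diff(p$distance_bp) > 0))

  inv <- 1 / pmax(abs(outer(1:30, 1:30, "-")), 0.5)
  m <- contact_matrix(inv, genome_bins("chrT", 30 * 4e4, 4e4),
                      normalized = TRUE)
  p <- contact_decay_profile(m)
  nz <- p$separation_bins > 0
  expect_equal(p$mean_contact[nz], 1 / p$separation_bins[nz],
               tolerance = 1e-12)

  masked <- contact_matrix(matrix(1, 5, 5), genome_bins("chrT", 2e5, 4e4),
                           mask = 0:4, normalized = TRUE)
  expect_equal(nrow(contact_decay_profile(masked)), 0)
})

test_that("difference maps are zero for identical or rescaled inputs", {
  m <- random_matrix(20, seed = 7)
  expect_equal(max(abs(difference_map(m, m)$counts)), 0)
  m2 <- contact_matrix(2 * m$counts, m$bins, normalized = TRUE)
  expect_equal(max(abs(difference_map(m2, m)$counts)), 0, tolerance = 1e-15)
  small <- random_matrix(10, seed = 8)
  expect_error(difference_map(m, small), "differ")
})

test_that("operations preserve symmetry and non-negativity", {
  m <- random_matrix(24, seed = 9)
  m$normalized <- FALSE
  for (out in list(ice_normalize(m), coarsen(m, 3),
                   observed_over_expected(ice_normalize(m)))) {
    expect_equal(out$counts, t(out$counts))
    expect_true(all(out$counts >= 0))
  }
})
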