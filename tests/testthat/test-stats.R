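test_that("hypergeometric overlap matches exhaustive enumeration", {
  # N=10, |set1|=4, |set2|=5, overlap 3 -> 66/252
  r <- hypergeometric_overlap(1:4, c(1, 2, 3, 9, 10), 10)
  expect_equal(r$n_overlap, 3L)
  expect_equal(r$p_value, 66 / 252, tolerance = 1e-12)
  expect_equal(r$p_value, enum_hyper_tail(10, 4, 5, 3), tolerance = 1e-12)

  for (seed in 1:10) {
    withr::with_seed(seed, {
      N <- sample(8:20, 1)
      s1 <- sample(N, sample(2:(N - 2), 1))
      s2 <- sample(N, sample(2:(N - 2), 1))
      r <- hypergeometric_overlap(s1, s2, N)
      expect_equal(r$p_value,
                   enum_hyper_tail(N, length(s1), length(s2),
                                   length(intersect(s1, s2))),
                   tolerance = 1e-12)
    })
  }
})

test_that("hypergeometric extremes and log-space tail behave", {
  # zero overlap -> upper tail at 0 is 1
  expect_equal(hypergeometric_overlap(1:3, 4:6, 10)$p_value, 1)
  # forced complete overlap -> p == 1
  expect_equal(hypergeometric_overlap(1:10, 1:10, 10)$p_value, 1)
  expect_error(hypergeometric_overlap(1:3, 1:2, 0), "population")

  # log-space tail finite and monotone up to a 75,000-bin population
  N <- 75000
  ks <- c(2000, 4000, 6000, 8000, 9990)
  lp <- vapply(ks, function(k) {
    set1 <- 1:10000
    set2 <- c(1:k, (N - (10000 - k) + 1):N)
    hypergeometric_overlap(set1, set2, N)$log10_p
  }, numeric(1))
  expect_true(all(is.finite(lp)))
  expect_true(all(diff(lp) < 0))      # bigger overlap, smaller tail
  expect_lt(lp[length(lp)], -1000)    # far beyond double underflow
})

test_that("Benjamini-Hochberg matches the hand step-up computation", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(0.04, 5)), rep(0.04, 5))
  p <- c(0.005, 0.04, 0.2, 0.8)
  adj <- benjamini_hochberg(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("GSEA scores maximal enrichment, reverses with the ranking", {
  withr::with_seed(4, {
    ranked <- tibble::tibble(gene_id = sprintf("g%04d", 1:1000),
                             score = sort(rnorm(1000), decreasing = TRUE))
  })
  top <- ranked$gene_id[1:50]
  r <- preranked_gsea(ranked, top, n_perm = 200, seed = 5)
  expect_gt(r$es, 0)
  expect_gt(r$nes, 0)
  # maximal enrichment: no null draw can match it, p sits at the
  # add-one floor (1 / (same-sign nulls + 1))
  expect_lt(r$p_value, 0.02)
  expect_equal(1 / r$p_value - 1, round(1 / r$p_value - 1),
               tolerance = 1e-9)                 # numerator is exactly 1

  flipped <- ranked
  flipped$score <- -ranked$score
  r2 <- preranked_gsea(flipped, top, n_perm = 200, seed = 5)
  expect_lt(r2$es, 0)
  expect_equal(r2$es, -r$es, tolerance = 1e-12)

  expect_error(preranked_gsea(ranked, "nope", n_perm = 200), "no overlap")
  expect_error(preranked_gsea(ranked, ranked$gene_id, n_perm = 200),
               "degenerate")
  expect_error(preranked_gsea(ranked, top, n_perm = 10), "n_perm")
})

test_that("GSEA enrichment score agrees with an independent implementation", {
  skip_if_not_installed("fgsea")
  withr::with_seed(7, {
    ranked <- tibble::tibble(gene_id = sprintf("g%04d", 1:500),
                             score = rnorm(500, sd = 2))
    gs <- sample(ranked$gene_id, 40)
  })
  ours <- preranked_gsea(ranked, gs, n_perm = 200, seed = 1)
  stats_vec <- sort(setNames(ranked$score, ranked$gene_id), decreasing = TRUE)
  ref <- suppressWarnings(
    fgsea::fgsea(list(set = gs), stats_vec, nperm = 200,
                 gseaParam = 1, scoreType = "std"))
  expect_equal(ours$es, ref$ES, tolerance = 1e-6)
})

test_that("gene-to-SAHF distances and windows follow the edge convention", {
  sahf <- tibble::tibble(chrom = "chr1", start = 1e6, end = 1.2e6)
  genes <- tibble::tibble(
    gene_id = c("far", "ring", "inside", "otherchrom"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(3e6, 1.8e6, 1.05e6, 1e6),
    end = c(3.1e6, 1.85e6, 1.1e6, 1.1e6))
  gd <- gene_sahf_distance(genes, sahf)
  expect_equal(gd$sahf_distance, c(1.8e6, 6e5, 0, NA))

  expect_equal(genes_in_distance_windows(genes, sahf, 5e5, 7e5), "ring")
  expect_equal(genes_in_distance_windows(genes, sahf, 0, 2e5), "inside")
  expect_error(genes_in_distance_windows(genes, sahf, 7e5, 5e5), "window")
})

test_that("downregulated fraction uses a strict FC < 1 rule", {
  genes <- tibble::tibble(gene_id = sprintf("g%d", 1:10),
                          fold_change = c(rep(0.5, 4), rep(2, 6)))
  expect_equal(fraction_downregulated(genes$gene_id, genes), 40)
  genes$fold_change <- rep(1, 10)
  expect_equal(fraction_downregulated(genes$gene_id, genes), 0)
  expect_true(is.na(fraction_downregulated(character(0), genes)))
})

test_that("Mann-Whitney exact branch matches enumeration", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$U), 0)
  expect_equal(r$p_value, 0.1)       # 2 / C(6,3)
  expect_true(r$exact)

  # enumeration oracle for small samples without ties
  enum_p <- function(a, b) {
    pool <- c(a, b)
    na <- length(a)
    u_obs <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    combos <- utils::combn(length(pool), na)
    us <- apply(combos, 2, function(idx) {
      x <- pool[idx]; y <- pool[-idx]
      sum(outer(x, y, ">"))
    })
    mu <- na * (length(pool) - na) / 2
    mean(abs(us - mu) >= abs(u_obs - mu))
  }
  for (seed in 1:8) {
    withr::with_seed(seed, {
      a <- sample(1:100, sample(3:6, 1))
      b <- sample(setdiff(1:100, a), sample(3:8, 1))
    })
    expect_equal(mann_whitney(a, b)$p_value, enum_p(a, b), tolerance = 1e-12)
  }

  expect_equal(mann_whitney(c(1, 5, 9), c(1, 5, 9))$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1), "nonempty")

  # p decreases with the shift between large samples
  withr::with_seed(3, {
    x <- rnorm(200)
    p1 <- mann_whitney(x, x + 0.2)$p_value
    p2 <- mann_whitney(x, x + 0.8)$p_value
  })
  expect_lt(p2, p1)
})

test_that("track summaries by category are seeded and ordered as planted", {
  g <- genome_bins("chrT", 400 * 4e4, 4e4)
  cats <- rep(c("AA", "BB", "BA", "AB"), each = 100)
  tmap <- g
  tmap$category <- cats
  const <- rep(1, 400)
  s1 <- suppressWarnings(
    summarize_track_by_category(const, tmap, n_sample = 50, seed = 2))
  expect_true(all(s1$samples$value == 1))

  track <- ifelse(cats == "BA", 5, 1) + withr::with_seed(8, rnorm(400, 0, 0.1))
  s2 <- summarize_track_by_category(track, tmap, n_sample = 50, seed = 2)
  med <- tapply(s2$samples$value, s2$samples$category, median)
  expect_gt(med[["BA"]], med[["AB"]])
  ba_ab <- s2$tests[s2$tests$category1 == "AB" & s2$tests$category2 == "BA", ]
  expect_lt(ba_ab$p_value, 1e-6)

  s3 <- summarize_track_by_category(track, tmap, n_sample = 50, seed = 2)
  expect_identical(s2$samples, s3$samples)   # same seed, same draw
})

test_that("metagene profiles are flat for constant tracks and track gene bodies", {
  bins <- genome_bins("chrT", 500 * 4e4, 4e4)
  genes <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:100),
    chrom = "chrT",
    start = seq(1e5, by = 1.9e5, length.out = 100),
    end = seq(1e5, by = 1.9e5, length.out = 100) + 1e5,
    strand = rep(c("+", "-"), 50),
    expression = 1:100)

  flat <- metagene_profile(rep(2, 500), bins, genes)
  expect_true(all(abs(flat$mean_signal - 2) < 1e-12))

  # indicator of the top decile's gene bodies: only that group's body is
  # elevated
  top <- genes[genes$expression > 90, ]
  ind <- rep(0, 500)
  for (i in seq_len(nrow(top))) {
    ind[(floor(top$start[i] / 4e4) + 1):(ceiling(top$end[i] / 4e4))] <- 1
  }
  prof <- metagene_profile(ind, bins, genes)
  body_top <- prof$mean_signal[prof$group == 10 & prof$position %in% 15:65]
  body_low <- prof$mean_signal[prof$group == 1 & prof$position %in% 15:65]
  expect_gt(mean(body_top), 0.9)
  expect_lt(mean(body_low), 0.1)

  # strand reversal mirrors a single gene's contribution
  one <- genes[1, ]
  grad <- seq_len(500)
  p_fwd <- metagene_profile(grad, bins, one, n_groups = 1)
  one$strand <- "-"
  p_rev <- metagene_profile(grad, bins, one, n_groups = 1)
  expect_equal(p_fwd$mean_signal, rev(p_rev$mean_signal), tolerance = 1e-12)
})

test_that("compartment contact-change ranking selects the weakened blocks", {
  sim <- default_sim()
  comps <- call_compartments(sim$pca_sen)
  comps_a <- comps[comps$label == "A", ]
  m1 <- sim$ice_sen
  m2 <- sim$ice_sen
  # identical inputs: all relative scores 1, ties broken by coordinate
  r0 <- rank_compartment_contact_change(m1, m2, comps_a)
  expect_true(all(abs(r0$relative_score - 1) < 1e-12))
  expect_equal(r0$start, sort(r0$start))
  expect_equal(sum(rank_compartment_contact_change(
    m1, m2, comps_a, bottom_fraction = 1)$selected), nrow(r0))

  # scale down within-compartment contacts of two chosen A compartments
  chosen <- comps_a[c(1, 2), ]
  x <- m1$counts
  for (i in seq_len(nrow(chosen))) {
    idx <- (chosen$start_bin[i] + 1):(chosen$end_bin[i] + 1)
    x[idx, idx] <- x[idx, idx] * 0.6
  }
  m_kd <- contact_matrix(x, m1$bins, mask = m1$mask, normalized = TRUE)
  r <- rank_compartment_contact_change(m_kd, m2, comps_a,
                                       bottom_fraction = 2 / nrow(comps_a))
  expect_setequal(r$start[r$selected], chosen$start)
})

test_that("linear R2 and IF quantification follow their formulas", {
  x <- 1:20
  expect_equal(linear_r2(x, 2 * x + 1), 1)
  withr::with_seed(12, {
    r2 <- linear_r2(rnorm(1000), rnorm(1000))
  })
  expect_lt(r2, 0.01)
  expect_error(linear_r2(c(1, 2), c(3, 4)), "at least 3")
  expect_warning(r <- linear_r2(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(r))

  q <- quantify_nuclear_signal(1000, 100, 2)
  expect_equal(q$signal, 800)
  expect_false(q$negative)
  expect_equal(quantify_nuclear_signal(500, 100, 0)$signal, 500)
  qn <- quantify_nuclear_signal(100, 100, 2)
  expect_equal(qn$signal, -100)
  expect_true(qn$negative)
  expect_error(quantify_nuclear_signal(-1, 1, 1), "non-negative")
})
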