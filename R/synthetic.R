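#' Configuration for the synthetic senescence Hi-C generator
#'
#' Defaults describe a compact two-chromosome genome whose architecture
#' carries every feature the analysis stages look for: alternating A/B
#' compartment blocks, small B-to-A (and fewer A-to-B) switches between the
#' growing and senescent conditions, a subset of B-to-A switches reverting
#' under condensin depletion (BAB), SAHF-like blocks inside persistent B
#' compartments with boosted >2 Mb contacts in senescent conditions, TADs
#' nested within compartment blocks, multiplicative per-bin biases, and
#' expression fold changes coupled to the planted switches.
#'
#' @param chromosomes Tibble with `chrom` and `length` (bp).
#' @param bin_size Bin width (default 40 kb).
#' @param mean_block_bp Mean compartment block length (default 1.2 Mb).
#' @param min_block_bins Minimum block length in bins (default 6).
#' @param ba_fraction Fraction of the genome switching B-to-A in the
#'   senescent condition (default 0.14).
#' @param ba_ab_ratio Ratio of B-to-A over A-to-B switched bins (default 2).
#' @param transition_bp Length range of individual switch segments
#'   (default 100-500 kb).
#' @param bab_fraction Fraction of B-to-A segments reverting to B upon
#'   depletion (default 0.5).
#' @param sahf_fraction Fraction of persistent-B blocks designated SAHF
#'   (default 0.5).
#' @param sahf_min_blocks Minimum SAHF blocks per chromosome when
#'   persistent-B blocks are available (default 2; isolated single foci
#'   give no long-range SAHF-SAHF pairs to detect).
#' @param tad_mean_bp Mean TAD size (default 400 kb).
#' @param tad_fixed_bins When set, TADs tile each block in exact chunks of
#'   this many bins instead of random sizes (useful for calibration runs).
#' @param decay_exponent Power-law exponent of contact decay (default 1.0).
#' @param checkerboard Same-state contact affinity multiplier (default 2).
#' @param cross_affinity Opposite-state affinity multiplier (default 0.6;
#'   set equal to `checkerboard` to switch compartment structure off).
#' @param a_membership,b_membership,b_membership_growing,sahf_membership
#'   Ranges of the per-bin
#'   B-state membership weight drawn for bins whose planted label is A,
#'   plain B, or SAHF-designated B. Each bin's contact profile is the
#'   mixture of an A-state and a B-state pattern weighted by its
#'   membership, emulating the continuous compartment identity (population
#'   heterogeneity, facultative heterochromatin) that makes real
#'   compartment scores graded rather than binary: A bins are nearly pure
#'   A-state, plain B bins weakly B-biased, SAHF bins almost pure B-state.
#'   Plain B is stronger in the growing condition
#'   (`b_membership_growing`) than in the senescent ones, emulating the
#'   weakening of distributed heterochromatin as it concentrates into
#'   SAHF.
#' @param pair_noise_sd SD of log-normal pair-level overdispersion on
#'   expected contacts (default 0.45), the reproducible biological
#'   variability real Hi-C shows on top of Poisson counting noise.
#' @param tad_strength Within-TAD contact multiplier (default 3).
#' @param sahf_boost Multiplier on >2 Mb contacts between SAHF bins in
#'   senescent conditions (default 3).
#' @param sahf_internal Within-block contact multiplier inside SAHF blocks
#'   in every condition (default 2): condensed heterochromatin is locally
#'   dense even though it lacks TAD substructure. Keeps SAHF bin coverage
#'   comparable to TAD-carrying bins.
#' @param bias_sd SD of log-normal per-bin biases (default 0.5).
#' @param depth Mean expected count per off-diagonal bin pair (default 50).
#' @param gene_prob_a,gene_prob_b Per-bin gene placement probability in A
#'   and B blocks (defaults 0.8 and 0.3; the imbalance provides the
#'   gene-density signal that orients compartment score signs).
#' @param expr_effect Log2 fold-change effect planted on switching bins
#'   (default 1: up in B-to-A bins, down in A-to-B bins).
#' @param expr_noise SD of log2 fold-change noise (default 0.5).
#' @param sahf_ring_shift Log2 down-shift applied to genes in the near-SAHF
#'   ring (default 0.6).
#' @param sahf_ring_bp Distance window of the near-SAHF down-shift ring
#'   (default 500-700 kb).
#' @param seed Master seed.
#' @return A named list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    chromosomes = tibble::tibble(chrom = c("chrS1", "chrS2"),
                                 length = c(4e7, 4e7)),
    bin_size = 40000L,
    mean_block_bp = 1.2e6,
    min_block_bins = 6L,
    ba_fraction = 0.14,
    ba_ab_ratio = 2,
    transition_bp = c(1e5, 5e5),
    bab_fraction = 0.5,
    sahf_fraction = 0.5,
    sahf_min_blocks = 2L,
    tad_mean_bp = 4e5,
    tad_fixed_bins = NULL,
    decay_exponent = 1.0,
    checkerboard = 2,
    cross_affinity = 0.6,
    a_membership = c(0.0, 0.15),
    b_membership = c(0.55, 0.62),
    b_membership_growing = c(0.70, 0.80),
    sahf_membership = c(0.9, 1.0),
    pair_noise_sd = 0.45,
    tad_strength = 3,
    sahf_boost = 3,
    sahf_internal = 2,
    bias_sd = 0.5,
    depth = 50,
    gene_prob_a = 0.8,
    gene_prob_b = 0.3,
    expr_effect = 1.0,
    expr_noise = 0.5,
    sahf_ring_shift = 0.6,
    sahf_ring_bp = c(5e5, 7e5),
    seed = 1L) {
  cfg <- as.list(environment())
  cfg$chromosomes <- tibble::as_tibble(cfg$chromosomes)
  stopifnot(cfg$checkerboard > 0, cfg$tad_strength > 0, cfg$sahf_boost > 0,
            cfg$ba_fraction >= 0, cfg$ba_fraction <= 1,
            cfg$bab_fraction >= 0, cfg$bab_fraction <= 1,
            all(cfg$transition_bp >= cfg$bin_size))
  class(cfg) <- "synthetic_config"
  cfg
}

#' @noRd
draw_blocks <- function(n, mean_bins, min_bins) {
  lens <- integer(0)
  while (sum(lens) < n) {
    lens <- c(lens, max(min_bins, stats::rpois(1, mean_bins)))
  }
  excess <- sum(lens) - n
  lens[length(lens)] <- lens[length(lens)] - excess
  if (lens[length(lens)] < 1L) {
    # fold the remainder into the previous block
    if (length(lens) > 1L) {
      lens[length(lens) - 1L] <- lens[length(lens) - 1L] + lens[length(lens)]
      lens <- lens[-length(lens)]
    } else {
      lens <- n
    }
  }
  lens
}

#' @noRd
plant_chrom <- function(chrom, len_bp, cfg) {
  bs <- cfg$bin_size
  n <- as.integer(ceiling(len_bp / bs))
  mean_bins <- cfg$mean_block_bp / bs
  lens <- draw_blocks(n, mean_bins, cfg$min_block_bins)
  first <- sample(c("A", "B"), 1L)
  labs <- rep(rep(c(first, setdiff(c("A", "B"), first)),
                  length.out = length(lens)), lens)
  block_id <- rep(seq_along(lens), lens)

  growing <- labs
  senescent <- growing
  tr_range <- c(max(1L, as.integer(ceiling(cfg$transition_bp[1] / bs))),
                max(1L, as.integer(floor(cfg$transition_bp[2] / bs))))
  flip_segments <- function(from_lab, target_bins, labels) {
    flipped <- logical(n)
    to_lab <- setdiff(c("A", "B"), from_lab)
    attempts <- 0L
    segs <- list()
    while (sum(flipped) < target_bins && attempts < 4000L) {
      attempts <- attempts + 1L
      L <- sample(seq(tr_range[1], tr_range[2]), 1L)
      cand <- which(labels == from_lab & !flipped)
      if (length(cand) < L) break
      s <- sample(cand, 1L)
      idx <- s:min(s + L - 1L, n)
      # keep segments separated by at least one unswitched bin so each
      # planted switch stays an individually sized region
      guard <- max(1L, s - 1L):min(n, s + L)
      if (any(labels[idx] != from_lab) || any(flipped[guard])) next
      flipped[idx] <- TRUE
      segs[[length(segs) + 1L]] <- idx
    }
    list(flipped = flipped, segments = segs)
  }
  ba_target <- round(cfg$ba_fraction * n)
  ab_target <- round(cfg$ba_fraction / cfg$ba_ab_ratio * n)
  ba <- flip_segments("B", ba_target, growing)
  senescent[ba$flipped] <- "A"
  ab <- flip_segments("A", ab_target, growing)
  senescent[ab$flipped] <- "B"

  kd <- senescent
  bab_flag <- logical(n)
  if (length(ba$segments)) {
    n_rev <- round(cfg$bab_fraction * length(ba$segments))
    if (n_rev > 0) {
      rev_idx <- sample(seq_along(ba$segments), n_rev)
      for (si in rev_idx) {
        kd[ba$segments[[si]]] <- "B"
        bab_flag[ba$segments[[si]]] <- TRUE
      }
    }
  }

  # SAHF candidates: maximal persistent-B runs (B in both conditions, no
  # planted switch) of at least 8 bins; selected foci are kept > 2 Mb apart
  # so that every focus has long-range partners to aggregate with
  pers <- growing == "B" & senescent == "B"
  r <- rle(pers)
  run_ends <- cumsum(r$lengths)
  run_starts <- run_ends - r$lengths + 1L
  cand <- which(r$values & r$lengths >= 8L)
  min_gap <- ceiling(2e6 / bs) + 5L
  run_mid <- (run_starts + run_ends) / 2
  n_sahf <- min(length(cand),
                max(cfg$sahf_min_blocks,
                    round(cfg$sahf_fraction * length(cand))))
  chosen <- integer(0)
  if (n_sahf > 0 && length(cand)) {
    for (ci in sample(cand)) {
      if (length(chosen) >= n_sahf) break
      if (!length(chosen) ||
          all(abs(run_mid[ci] - run_mid[chosen]) >= min_gap)) {
        chosen <- c(chosen, ci)
      }
    }
    if (length(chosen) < 2L && length(cand) >= 2L) {
      ord <- cand[order(run_mid[cand])]
      chosen <- unique(c(ord[1L], ord[length(ord)]))
    }
  }
  sahf <- logical(n)
  sahf_block_id <- integer(n)
  for (k in seq_along(chosen)) {
    idx <- run_starts[chosen[k]]:run_ends[chosen[k]]
    sahf[idx] <- TRUE
    sahf_block_id[idx] <- k
  }

  # TADs nested within compartment blocks; SAHF stretches are condensed,
  # TAD-free domains (tad_id 0 = no domain)
  tad_mean_bins <- cfg$tad_mean_bp / bs
  tad_id <- integer(n)
  nxt <- 1L
  for (b in seq_along(lens)) {
    idx <- which(block_id == b)
    tl <- if (!is.null(cfg$tad_fixed_bins)) {
      nb <- max(1L, length(idx) %/% cfg$tad_fixed_bins)
      out <- rep(cfg$tad_fixed_bins, nb)
      out[nb] <- length(idx) - cfg$tad_fixed_bins * (nb - 1L)
      out
    } else {
      draw_blocks(length(idx), tad_mean_bins, 4L)
    }
    tad_id[idx] <- nxt + rep(seq_along(tl), tl) - 1L
    nxt <- nxt + length(tl)
  }
  tad_id[sahf] <- 0L

  bias <- exp(stats::rnorm(n, 0, cfg$bias_sd))

  # continuous B-state membership per bin: one A-type and one B-type draw,
  # picked per condition by that condition's label; SAHF bins override with
  # the near-pure-B tier in every condition (they are persistent B)
  u_a <- stats::runif(n, cfg$a_membership[1], cfg$a_membership[2])
  u_b <- stats::runif(n, cfg$b_membership[1], cfg$b_membership[2])
  u_bg <- stats::runif(n, cfg$b_membership_growing[1], cfg$b_membership_growing[2])
  u_s <- stats::runif(n, cfg$sahf_membership[1], cfg$sahf_membership[2])
  memb <- function(lab, u_b_cond) {
    ifelse(sahf, u_s, ifelse(lab == "A", u_a, u_b_cond))
  }

  bins <- genome_bins(chrom, len_bp, bs)
  dplyr::mutate(bins,
                label_growing = growing, label_senescent = senescent,
                label_kd = kd, bab = bab_flag, sahf = sahf,
                tad_id = tad_id, sahf_block_id = sahf_block_id,
                bias = bias,
                bmem_growing = memb(growing, u_bg),
                bmem_senescent = memb(senescent, u_b),
                bmem_kd = memb(kd, u_b))
}

#' Plant a synthetic genome architecture
#'
#' Draws the ground-truth architecture — compartment labels per condition,
#' switch segments, SAHF blocks, TAD boundaries and per-bin biases — that
#' the contact and expression simulators then realise.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_truth` with `config` and `bins`
#'   (named list of per-chromosome tibbles carrying `label_growing`,
#'   `label_senescent`, `label_kd`, `bab`, `sahf`, `tad_id`, `bias`).
#' @export
plant_architecture <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  bins <- withr::with_seed(config$seed, {
    out <- purrr::map2(config$chromosomes$chrom, config$chromosomes$length,
                       plant_chrom, cfg = config)
    stats::setNames(out, config$chromosomes$chrom)
  })
  structure(list(config = config, bins = bins), class = "synthetic_truth")
}

#' @noRd
condition_labels <- function(truth, chrom, condition) {
  b <- truth$bins[[chrom]]
  switch(condition,
         growing = b$label_growing,
         senescent = b$label_senescent,
         kd = b$label_kd,
         stop("unknown condition: ", condition, call. = FALSE))
}

#' Simulate a contact matrix for one chromosome and condition
#'
#' Expected contacts follow a power-law distance decay modulated by
#' same-compartment, same-TAD and (in senescent conditions) long-range
#' SAHF-SAHF multipliers, scaled so the mean off-diagonal expectation equals
#' the configured depth, distorted by the planted per-bin biases, and
#' observed through independent Poisson draws (symmetrised).
#'
#' @param truth A `synthetic_truth` from [plant_architecture()].
#' @param chrom Chromosome name.
#' @param condition One of `"growing"`, `"senescent"`, `"kd"`.
#' @param replicate Replicate index (default 1); replicates share the
#'   planted truth and biases but redraw the pair-level overdispersion and
#'   counting noise, emulating biological replicates.
#' @param apply_bias Include the planted per-bin biases (default `TRUE`;
#'   turn off to obtain the bias-free reference realisation).
#' @return A raw [contact_matrix()].
#' @export
simulate_contacts <- function(truth, chrom, condition, replicate = 1L,
                              apply_bias = TRUE) {
  stopifnot(inherits(truth, "synthetic_truth"))
  cfg <- truth$config
  b <- truth$bins[[chrom]]
  if (is.null(b)) stop("unknown chromosome: ", chrom, call. = FALSE)
  n <- nrow(b)
  bw <- switch(condition, growing = b$bmem_growing,
               senescent = b$bmem_senescent, kd = b$bmem_kd,
               stop("unknown condition: ", condition, call. = FALSE))
  aw <- 1 - bw
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  lambda <- pmax(d, 0.5)^(-cfg$decay_exponent)
  # two-state mixture affinity: same-state pairs enriched, cross depleted
  aff <- cfg$checkerboard * (outer(aw, aw) + outer(bw, bw)) +
    cfg$cross_affinity * (outer(aw, bw) + outer(bw, aw))
  lambda <- lambda * aff
  same_tad <- outer(b$tad_id, b$tad_id, "==") & b$tad_id > 0
  lambda[same_tad] <- lambda[same_tad] * cfg$tad_strength
  same_sahf_block <- outer(b$sahf_block_id, b$sahf_block_id, "==") &
    b$sahf_block_id > 0
  lambda[same_sahf_block] <- lambda[same_sahf_block] * cfg$sahf_internal
  if (condition %in% c("senescent", "kd")) {
    sahf_pair <- outer(b$sahf, b$sahf, "&") & d > (2e6 / cfg$bin_size)
    lambda[sahf_pair] <- lambda[sahf_pair] * cfg$sahf_boost
  }
  cond_off <- match(condition, c("growing", "senescent", "kd"))
  chrom_off <- match(chrom, names(truth$bins))
  seed <- (cfg$seed + 7919L * cond_off + 104729L * chrom_off +
             15485863 * (as.integer(replicate) - 1L)) %% .Machine$integer.max
  off <- d > 0
  counts <- withr::with_seed(seed, {
    ut <- upper.tri(lambda, diag = TRUE)
    if (cfg$pair_noise_sd > 0) {
      eps <- matrix(0, n, n)
      eps[ut] <- stats::rnorm(sum(ut), 0, cfg$pair_noise_sd)
      lambda <- lambda * exp(eps + t(eps) - diag(diag(eps)))
    }
    lambda <- lambda * (cfg$depth / mean(lambda[off]))
    if (apply_bias) lambda <- lambda * outer(b$bias, b$bias)
    x <- matrix(0, n, n)
    x[ut] <- stats::rpois(sum(ut), lambda[ut])
    x + t(x) - diag(diag(x))
  })
  contact_matrix(counts, genome_bins(chrom, max(b$end), cfg$bin_size))
}

#' Planted SAHF regions of the synthetic truth
#'
#' @param truth A `synthetic_truth`.
#' @return Tibble (`chrom`, `start`, `end`) of contiguous SAHF blocks.
#' @export
truth_sahf_regions <- function(truth) {
  purrr::map_dfr(truth$bins, function(b) {
    r <- rle(b$sahf)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    tibble::tibble(chrom = b$chrom[1], start = b$start[starts[keep]],
                   end = b$end[ends[keep]])
  })
}

#' Simulate gene expression and per-bin signal tracks
#'
#' Genes are placed bin-wise with higher probability in A compartments
#' (providing the gene-density signal used to orient compartment scores).
#' Log2 expression fold changes couple to the planted architecture: up in
#' B-to-A bins, down in A-to-B bins, an additional down-shift for genes in
#' the configured near-SAHF distance ring, and (for the depletion contrast)
#' down in BAB bins; Gaussian noise is added throughout. ChIP-like tracks
#' carry H3K9me3-style enrichment on B/SAHF bins and condensin-style
#' enrichment on A and B-to-A bins.
#'
#' @param truth A `synthetic_truth`.
#' @return List with `genes` (tibble: `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `expression_growing`, `expression_senescent`,
#'   `expression_kd`, `fold_change` (senescent/growing), `log2_fc`,
#'   `fold_change_kd` (kd/senescent), `significant`, plus the planted
#'   per-gene category) and `tracks` (per-bin tibble: `chrom`, `bin`,
#'   `start`, `end`, `gene_density`, `h3k9me3`, `caph2`).
#' @export
simulate_expression_and_tracks <- function(truth) {
  cfg <- truth$config
  sahf_regions <- truth_sahf_regions(truth)
  withr::with_seed(cfg$seed + 65537L, {
    genes <- purrr::map_dfr(truth$bins, function(b) {
      p <- ifelse(b$label_growing == "A", cfg$gene_prob_a, cfg$gene_prob_b)
      has_gene <- stats::runif(nrow(b)) < p
      idx <- which(has_gene)
      cat_ois <- paste0(b$label_growing, b$label_senescent)
      glen <- stats::runif(length(idx), 2e4, 8e4)
      tibble::tibble(
        chrom = b$chrom[1],
        start = b$start[idx] + 5000,
        end = pmin(b$start[idx] + 5000 + round(glen), max(b$end)),
        strand = sample(c("+", "-"), length(idx), replace = TRUE),
        bin = b$bin[idx],
        category = cat_ois[idx],
        bab = b$bab[idx]
      )
    })
    genes$gene_id <- sprintf("G%05d", seq_len(nrow(genes)))
    genes <- gene_sahf_distance(genes, sahf_regions)
    in_ring <- !is.na(genes$sahf_distance) &
      genes$sahf_distance >= cfg$sahf_ring_bp[1] &
      genes$sahf_distance < cfg$sahf_ring_bp[2]
    mu <- cfg$expr_effect * (genes$category == "BA") -
      cfg$expr_effect * (genes$category == "AB") -
      cfg$sahf_ring_shift * in_ring
    log2_fc <- stats::rnorm(nrow(genes), mu, cfg$expr_noise)
    log2_fc_kd <- stats::rnorm(nrow(genes), -cfg$expr_effect * genes$bab,
                               cfg$expr_noise)
    base_expr <- exp(stats::rnorm(nrow(genes), 5, 1))
    genes$expression_growing <- base_expr
    genes$expression_senescent <- base_expr * 2^log2_fc
    genes$expression_kd <- genes$expression_senescent * 2^log2_fc_kd
    genes$log2_fc <- log2_fc
    genes$fold_change <- 2^log2_fc
    genes$fold_change_kd <- 2^log2_fc_kd
    genes$significant <- abs(log2_fc) > log2(1.5)

    tracks <- purrr::map_dfr(truth$bins, function(b) {
      gd <- tabulate(
        genes$bin[genes$chrom == b$chrom[1]] + 1L, nbins = nrow(b))
      tibble::tibble(
        chrom = b$chrom[1], bin = b$bin, start = b$start, end = b$end,
        gene_density = gd,
        h3k9me3 = 1 + 2 * (b$label_senescent == "B") + 1 * b$sahf +
          stats::rnorm(nrow(b), 0, 0.2),
        caph2 = 1 + 1.5 * (b$label_senescent == "A") +
          1.5 * (b$label_growing == "B" & b$label_senescent == "A") +
          stats::rnorm(nrow(b), 0, 0.2)
      )
    })
    list(genes = genes, tracks = tracks)
  })
}

#' Write the planted truth to disk
#'
#' Per-bin truth as TSV plus a JSON manifest of the generating
#' configuration; together they suffice to score recovery without
#' re-running the generator.
#'
#' @param truth A `synthetic_truth`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bins <- dplyr::bind_rows(truth$bins)
  write_tsv_prov(bins, file.path(dir, "truth_bins.tsv"))
  cfg <- truth$config
  cfg$chromosomes <- as.list(cfg$chromosomes)
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "truth_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Reload a planted truth written by [write_truth()]
#'
#' @param dir Directory containing `truth_bins.tsv` and `truth_config.json`.
#' @return A `synthetic_truth`.
#' @export
read_truth <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "truth_config.json"),
                             simplifyVector = TRUE)
  cfg$chromosomes <- tibble::as_tibble(cfg$chromosomes)
  for (k in c("transition_bp", "sahf_ring_bp", "a_membership",
              "b_membership", "b_membership_growing", "sahf_membership")) {
    cfg[[k]] <- as.numeric(cfg[[k]])
  }
  class(cfg) <- "synthetic_config"
  bins_all <- tibble::as_tibble(
    utils::read.table(file.path(dir, "truth_bins.tsv"), header = TRUE,
                      sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE))
  bins <- split(bins_all, bins_all$chrom)
  bins <- lapply(bins, function(b) {
    attr(b, "bin_size") <- cfg$bin_size
    b
  })
  structure(list(config = cfg, bins = bins[unique(bins_all$chrom)]),
            class = "synthetic_truth")
}
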