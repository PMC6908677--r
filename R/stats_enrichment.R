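#' Hypergeometric overlap test for two bin (or gene) sets
#'
#' Upper-tail probability of observing at least the given overlap between
#' two sets drawn from a common population, computed in log space so that
#' extremely small tails (down to ~1e-5000 and beyond) remain representable
#' via the `log10_p` column. Equivalent to a one-sided Fisher exact test on
#' the 2x2 membership table.
#'
#' @param set1,set2 Vectors of member identifiers (bins or gene ids).
#' @param population Population size (total bins or genes).
#' @return Tibble with `n_overlap`, `n1`, `n2`, `population`, `p_value`
#'   (0 on double underflow) and `log10_p` (always finite for valid input).
#' @export
hypergeometric_overlap <- function(set1, set2, population) {
  if (length(population) != 1L || population <= 0) {
    stop("`population` must be a positive scalar", call. = FALSE)
  }
  set1 <- unique(set1)
  set2 <- unique(set2)
  k1 <- length(set1)
  k2 <- length(set2)
  if (k1 > population || k2 > population) {
    stop("set larger than population", call. = FALSE)
  }
  ov <- length(intersect(set1, set2))
  # P(X >= ov), X ~ Hypergeometric(population, k1 white, draw k2)
  logp <- stats::phyper(ov - 1L, k1, population - k1, k2,
                        lower.tail = FALSE, log.p = TRUE)
  tibble::tibble(n_overlap = ov, n1 = k1, n2 = k2,
                 population = as.integer(population),
                 p_value = exp(logp), log10_p = logp / log(10))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjustment of a vector of nominal p-values.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' @noRd
gsea_es <- function(hit_idx, w_scores, n, sum_w) {
  # running-sum extremum evaluated at and just before each hit
  nh <- length(hit_idx)
  miss_step <- 1 / (n - nh)
  cum_w <- cumsum(w_scores[hit_idx]) / sum_w
  after <- cum_w - (hit_idx - seq_len(nh)) * miss_step
  before <- c(0, cum_w[-nh]) - (hit_idx - seq_len(nh)) * miss_step
  hi <- max(after)
  lo <- min(before)
  if (hi >= -lo) hi else lo
}

#' Pre-ranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment of a gene set within
#' a ranked gene list. Genes are ordered by decreasing score; hits advance
#' the running sum by their weighted score (`|score|^weight`, normalised),
#' misses decrement it uniformly. The enrichment score (ES) is the signed
#' extremum of the running sum. The null is built by permuting gene labels
#' (drawing random sets of the same size); the normalised score (NES)
#' divides ES by the mean magnitude of same-sign null scores, and the
#' p-value counts same-sign null scores at least as extreme, with the usual
#' add-one correction.
#'
#' @param ranked Tibble (or data frame) with columns `gene_id` and `score`
#'   (e.g. log2 expression fold change). Ties are kept in input order.
#' @param gene_set Character vector of member gene ids.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed for the permutation null.
#' @param weight Exponent on `|score|` for hit increments (default 1;
#'   0 gives the classic unweighted KS statistic).
#' @return Tibble with `es`, `nes`, `p_value`, `n_hits`, `n_perm`, `seed`.
#' @export
preranked_gsea <- function(ranked, gene_set, n_perm = 1000L, seed = 1L,
                           weight = 1) {
  stopifnot(all(c("gene_id", "score") %in% names(ranked)))
  if (n_perm < 100L) stop("`n_perm` must be >= 100", call. = FALSE)
  ord <- order(ranked$score, decreasing = TRUE)
  ids <- ranked$gene_id[ord]
  scores <- ranked$score[ord]
  n <- length(ids)
  hit_idx <- sort(which(ids %in% gene_set))
  nh <- length(hit_idx)
  if (nh == 0L) stop("gene set has no overlap with the ranked list", call. = FALSE)
  if (nh == n) stop("degenerate set: contains every ranked gene", call. = FALSE)
  w_scores <- abs(scores)^weight
  if (all(w_scores[hit_idx] == 0)) w_scores <- rep(1, n)
  es <- gsea_es(hit_idx, w_scores, n, sum(w_scores[hit_idx]))
  null_es <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      h <- sort(sample.int(n, nh))
      sw <- sum(w_scores[h])
      if (sw == 0) return(0)
      gsea_es(h, w_scores, n, sw)
    }, numeric(1))
  })
  same_sign <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  nes <- if (length(same_sign) && mean(abs(same_sign)) > 0) {
    es / mean(abs(same_sign))
  } else {
    NA_real_
  }
  p <- (1 + sum(abs(same_sign) >= abs(es))) / (1 + length(same_sign))
  tibble::tibble(es = es, nes = nes, p_value = p, n_hits = nh,
                 n_perm = as.integer(n_perm), seed = as.integer(seed))
}

#' Distance from gene bodies to the nearest SAHF region
#'
#' Gap in bp between each gene body and the nearest SAHF interval edge on
#' the same chromosome; 0 when they overlap, `NA` on chromosomes without
#' SAHF.
#'
#' @param genes Gene table with `gene_id`, `chrom`, `start`, `end`.
#' @param sahf SAHF region table with `chrom`, `start`, `end` (e.g. from
#'   [detect_sahf()]).
#' @return `genes` with an added `sahf_distance` column.
#' @export
gene_sahf_distance <- function(genes, sahf) {
  dist_one <- function(gs, ge, ss, se) {
    if (!length(ss)) return(NA_real_)
    min(pmax(0, pmax(ss - ge, gs - se)))
  }
  d <- vapply(seq_len(nrow(genes)), function(i) {
    same <- sahf$chrom == genes$chrom[i]
    dist_one(genes$start[i], genes$end[i], sahf$start[same], sahf$end[same])
  }, numeric(1))
  dplyr::mutate(genes, sahf_distance = d)
}

#' Genes within a distance window of SAHF regions
#'
#' @param genes Gene table (`gene_id`, `chrom`, `start`, `end`).
#' @param sahf SAHF region table (`chrom`, `start`, `end`).
#' @param window_start,window_end Half-open distance window `[start, end)`
#'   in bp from the nearest SAHF edge.
#' @return Character vector of gene ids in the window.
#' @export
genes_in_distance_windows <- function(genes, sahf, window_start, window_end) {
  if (window_start >= window_end) {
    stop("`window_start` must be < `window_end`", call. = FALSE)
  }
  gd <- gene_sahf_distance(genes, sahf)
  gd$gene_id[!is.na(gd$sahf_distance) &
               gd$sahf_distance >= window_start &
               gd$sahf_distance < window_end]
}

#' Sweep sliding or cumulative distance windows around SAHF
#'
#' Runs [genes_in_distance_windows()] over a sweep of windows — sliding
#' windows of fixed width, or cumulative windows `[0, end)` — and reports
#' the fraction of downregulated genes per window next to the genome-wide
#' control fraction.
#'
#' @param genes Gene table with `fold_change` for the contrast of interest.
#' @param sahf SAHF region table.
#' @param width Window width in bp (default 200 kb).
#' @param max_distance Largest window end (default 2 Mb).
#' @param mode `"sliding"` or `"cumulative"`.
#' @param fc_col Name of the fold-change column (default `"fold_change"`).
#' @return Tibble (`window_start`, `window_end`, `n_genes`,
#'   `pct_downregulated`, `control_pct`).
#' @export
sahf_window_sweep <- function(genes, sahf, width = 2e5, max_distance = 2e6,
                              mode = c("sliding", "cumulative"),
                              fc_col = "fold_change") {
  mode <- match.arg(mode)
  starts <- if (mode == "sliding") seq(0, max_distance - width, by = width)
            else rep(0, length(seq(width, max_distance, by = width)))
  ends <- if (mode == "sliding") starts + width else seq(width, max_distance, by = width)
  control <- fraction_downregulated(genes$gene_id, genes, fc_col = fc_col)
  purrr::map2_dfr(starts, ends, function(ws, we) {
    ids <- genes_in_distance_windows(genes, sahf, ws, we)
    tibble::tibble(
      window_start = ws, window_end = we, n_genes = length(ids),
      pct_downregulated = fraction_downregulated(ids, genes, fc_col = fc_col),
      control_pct = control
    )
  })
}

#' Percent of genes downregulated in a contrast
#'
#' A gene counts as downregulated when its fold change is strictly below 1.
#'
#' @param gene_ids Gene ids to evaluate.
#' @param genes Gene table containing them.
#' @param fc_col Name of the fold-change column.
#' @return Percent in `[0, 100]`, or `NA` for an empty list.
#' @export
fraction_downregulated <- function(gene_ids, genes, fc_col = "fold_change") {
  if (!length(gene_ids)) return(NA_real_)
  fc <- genes[[fc_col]][match(gene_ids, genes$gene_id)]
  fc <- fc[!is.na(fc)]
  if (!length(fc)) return(NA_real_)
  100 * mean(fc < 1)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact enumeration when the smaller sample has at most 8 observations and
#' there are no ties; normal approximation with tie correction otherwise.
#'
#' @param a,b Numeric samples.
#' @return Tibble with `U` (statistic for sample `a`), `p_value`, `exact`.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be nonempty", call. = FALSE)
  if (stats::sd(c(a, b)) == 0) {
    # all observations identical: no evidence of a shift
    return(tibble::tibble(U = length(a) * length(b) / 2, p_value = 1,
                          exact = FALSE))
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- min(length(a), length(b)) <= 8L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = use_exact, correct = !use_exact)
  )
  tibble::tibble(U = unname(wt$statistic), p_value = wt$p.value,
                 exact = use_exact)
}

#' Summarise a signal track by compartmental transition category
#'
#' For each transition category, samples up to `n_sample` bins without
#' replacement (seeded) and collects the track values; categories are then
#' compared pairwise with two-sided Mann-Whitney U tests.
#'
#' @param track_values Numeric per-bin signal (e.g. ChIP enrichment).
#' @param tmap Transition map from [classify_transitions()].
#' @param n_sample Bins sampled per category (default 500).
#' @param seed Integer seed.
#' @return List with `samples` (tibble `category`, `bin`, `value`) and
#'   `tests` (pairwise Mann-Whitney results).
#' @export
summarize_track_by_category <- function(track_values, tmap, n_sample = 500L,
                                        seed = 1L) {
  stopifnot(length(track_values) == nrow(tmap))
  cats <- sort(unique(stats::na.omit(tmap$category)))
  samples <- withr::with_seed(seed, {
    purrr::map_dfr(cats, function(ct) {
      idx <- which(!is.na(tmap$category) & tmap$category == ct &
                     !is.na(track_values))
      if (!length(idx)) {
        warning("category ", ct, " has no bins; skipped")
        return(tibble::tibble(category = character(), bin = integer(),
                              value = numeric()))
      }
      if (length(idx) < n_sample) {
        warning("category ", ct, " has only ", length(idx),
                " bins; using all of them")
      } else {
        idx <- sort(sample(idx, n_sample))
      }
      tibble::tibble(category = ct, bin = tmap$bin[idx],
                     value = track_values[idx])
    })
  })
  pairs <- utils::combn(unique(samples$category), 2L, simplify = FALSE)
  tests <- purrr::map_dfr(pairs, function(pr) {
    a <- samples$value[samples$category == pr[1]]
    b <- samples$value[samples$category == pr[2]]
    mw <- mann_whitney(a, b)
    tibble::tibble(category1 = pr[1], category2 = pr[2],
                   median1 = stats::median(a), median2 = stats::median(b),
                   U = mw$U, p_value = mw$p_value)
  })
  list(samples = samples, tests = tests)
}

#' Metagene signal profiles by expression group
#'
#' Genes are split into `n_groups` expression quantile groups; each gene
#' body is rescaled to `n_points` positions running TSS to TES (strand
#' aware), flanked by a fixed number of bp on each side, and the per-bin
#' signal track is averaged pointwise within each group.
#'
#' @param track_values Numeric per-bin signal.
#' @param bins Bin table from [genome_bins()] matching `track_values`.
#' @param genes Gene table with `chrom`, `start`, `end`, `strand` and an
#'   expression column.
#' @param expr_col Expression column used for grouping.
#' @param n_groups Number of expression groups (default 10 deciles; group 1
#'   is the lowest-expressed).
#' @param n_points Points across the gene body (default 50).
#' @param flank_bp Flank on each side in bp (default 200 kb).
#' @param n_flank_points Points across each flank (default 10).
#' @return Tibble (`group`, `position`, `mean_signal`, `n_genes`);
#'   `position` runs 1..(2*n_flank_points + n_points) from upstream flank to
#'   downstream flank. Genes shorter than one bin are skipped (count in
#'   attribute `n_skipped`).
#' @export
metagene_profile <- function(track_values, bins, genes, expr_col = "expression",
                             n_groups = 10L, n_points = 50L,
                             flank_bp = 2e5, n_flank_points = 10L) {
  stopifnot(length(track_values) == nrow(bins))
  bs <- bins_bin_size(bins)
  genes <- genes[genes$chrom == bins$chrom[1], , drop = FALSE]
  glen <- genes$end - genes$start
  skipped <- sum(glen < bs)
  genes <- genes[glen >= bs, , drop = FALSE]
  expr <- genes[[expr_col]]
  grp <- if (n_groups == 1L) rep(1L, nrow(genes)) else {
    as.integer(cut(rank(expr, ties.method = "first"),
                   breaks = n_groups, labels = FALSE))
  }
  total_pts <- 2L * n_flank_points + n_points
  value_at <- function(pos_bp) {
    idx <- pmin(pmax(floor(pos_bp / bs) + 1, 1), nrow(bins))
    track_values[idx]
  }
  prof <- matrix(0, nrow = n_groups, ncol = total_pts)
  cnt <- integer(n_groups)
  for (g in seq_len(nrow(genes))) {
    s <- genes$start[g]; e <- genes$end[g]
    body <- seq(s, e, length.out = n_points)
    up <- seq(s - flank_bp, s, length.out = n_flank_points + 1L)[-(n_flank_points + 1L)]
    down <- seq(e, e + flank_bp, length.out = n_flank_points + 1L)[-1L]
    pos <- c(up, body, down)
    if (identical(genes$strand[g], "-")) pos <- rev(pos)
    vals <- value_at(pos)
    prof[grp[g], ] <- prof[grp[g], ] + vals
    cnt[grp[g]] <- cnt[grp[g]] + 1L
  }
  out <- purrr::map_dfr(seq_len(n_groups), function(gi) {
    tibble::tibble(group = gi, position = seq_len(total_pts),
                   mean_signal = if (cnt[gi] > 0) prof[gi, ] / cnt[gi] else NA_real_,
                   n_genes = cnt[gi])
  })
  attr(out, "n_skipped") <- skipped
  out
}

#' Rank compartments by relative within-compartment contact change
#'
#' For each compartment, averages the within-compartment observed/expected
#' contact score in two conditions (on the matrices' own grid, typically
#' coarsened to 200 kb) and forms the ratio condition1/condition2.
#' Compartments are ranked ascending by the ratio — the bottom fraction are
#' those losing the most internal contact in condition 1 — with coordinate
#' order breaking ties.
#'
#' @param m1,m2 Balanced [contact_matrix()] objects on the same (coarse)
#'   grid, e.g. condensin-depleted vs senescent.
#' @param comps Compartment table from [call_compartments()] (coordinates in
#'   bp; mapped onto the coarse grid).
#' @param bottom_fraction Fraction of compartments to select from the bottom
#'   of the ranking (default 0.10).
#' @return Tibble (`chrom`, `start`, `end`, `label`, `oe1`, `oe2`,
#'   `relative_score`, `rank`, `selected`); compartments spanning no full
#'   coarse bin are dropped.
#' @export
rank_compartment_contact_change <- function(m1, m2, comps,
                                            bottom_fraction = 0.10) {
  stopifnot(inherits(m1, "contact_matrix"), inherits(m2, "contact_matrix"))
  if (n_bins(m1) != n_bins(m2)) stop("grids differ", call. = FALSE)
  oe1 <- observed_over_expected(m1)$counts
  oe2 <- observed_over_expected(m2)$counts
  bs <- bins_bin_size(m1$bins)
  rows <- purrr::pmap_dfr(
    list(comps$start, comps$end, comps$label),
    function(s, e, lab) {
      lo <- floor(s / bs) + 1L
      hi <- ceiling(e / bs)
      if (hi < lo || hi - lo + 1L < 1L) return(NULL)
      idx <- lo:hi
      idx <- idx[idx >= 1 & idx <= nrow(oe1)]
      if (length(idx) < 1L) return(NULL)
      block1 <- oe1[idx, idx]
      block2 <- oe2[idx, idx]
      tibble::tibble(chrom = comps$chrom[1], start = s, end = e, label = lab,
                     oe1 = mean(block1), oe2 = mean(block2))
    }
  )
  rows <- rows[rows$oe2 > 0, , drop = FALSE]
  rows$relative_score <- rows$oe1 / rows$oe2
  ord <- order(rows$relative_score, rows$start)
  rows <- rows[ord, ]
  rows$rank <- seq_len(nrow(rows))
  n_sel <- ceiling(bottom_fraction * nrow(rows))
  rows$selected <- rows$rank <= n_sel
  rows
}

#' Genes contained in a set of genomic intervals
#'
#' @param genes Gene table (`gene_id`, `chrom`, `start`, `end`).
#' @param intervals Interval table (`chrom`, `start`, `end`).
#' @return Character vector of ids of genes overlapping any interval.
#' @export
genes_in_intervals <- function(genes, intervals) {
  hit <- vapply(seq_len(nrow(genes)), function(i) {
    same <- intervals$chrom == genes$chrom[i]
    any(same & intervals$start < genes$end[i] & intervals$end > genes$start[i])
  }, logical(1))
  genes$gene_id[hit]
}

#' Coefficient of determination of a simple linear fit
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`.
#' @return R-squared of the ordinary least-squares fit of `y` on `x`, or
#'   `NA` (with a warning) when either variable has zero variance.
#' @export
linear_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need at least 3 paired observations", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; R^2 undefined")
    return(NA_real_)
  }
  stats::cor(x, y)^2
}

#' Background-corrected nuclear immunofluorescence signal
#'
#' Subtracts the expected background contribution (nuclear area times the
#' average background signal density) from the total nuclear signal.
#'
#' @param total_nuclear Total nuclear IF signal (>= 0).
#' @param nuclear_area_px Nuclear area in pixels (>= 0).
#' @param background_density Mean background signal per pixel (>= 0).
#' @return Tibble with `signal` (may be negative) and `negative` flag.
#' @export
quantify_nuclear_signal <- function(total_nuclear, nuclear_area_px,
                                    background_density) {
  if (any(c(total_nuclear, nuclear_area_px, background_density) < 0)) {
    stop("inputs must be non-negative", call. = FALSE)
  }
  s <- total_nuclear - nuclear_area_px * background_density
  tibble::tibble(signal = s, negative = s < 0)
}
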