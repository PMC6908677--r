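#' Principal-component compartment scores
#'
#' Computes per-bin compartment scores from a balanced contact matrix:
#' the matrix is transformed to observed/expected, the Pearson correlation
#' matrix of its columns is formed (masked and zero-variance bins excluded),
#' and the leading eigenvector is extracted. The per-bin score is the unit
#' eigenvector entry scaled by `sqrt(eigenvalue) * 100`, so that magnitudes
#' land in the tens. The overall sign is oriented so the score correlates
#' positively with gene density — positive scores mark the gene-rich,
#' euchromatic A state, negative scores the heterochromatic B state.
#'
#' @param m A balanced [contact_matrix()] (typically at 40 kb resolution).
#' @param gene_density Numeric per-bin track (length `n_bins`), e.g. genes
#'   per bin, used only to fix the sign.
#' @param use_oe Correlate the O/E matrix (default) or the balanced matrix
#'   directly.
#' @return A tibble (`chrom`, `bin`, `start`, `end`, `score`) with masked
#'   bins `NA`; attributes `eigenvalue_fraction` (share of total positive
#'   eigenvalue mass carried by PC1) and `mask`.
#' @export
pca_scores <- function(m, gene_density, use_oe = TRUE) {
  stopifnot(inherits(m, "contact_matrix"))
  n <- n_bins(m)
  if (length(gene_density) != n) {
    stop("`gene_density` must have one value per bin", call. = FALSE)
  }
  base <- if (use_oe) observed_over_expected(m) else m
  live <- unmasked_idx(base)
  sub <- base$counts[live, live, drop = FALSE]
  sds <- apply(sub, 2L, stats::sd)
  keep <- which(is.finite(sds) & sds > 0)
  if (length(keep) < 10L) {
    stop("chromosome too short: fewer than 10 informative bins", call. = FALSE)
  }
  live <- live[keep]
  cc <- stats::cor(base$counts[live, live, drop = FALSE])
  ev <- eigen(cc, symmetric = TRUE)
  lambda <- ev$values
  pos <- sum(pmax(lambda, 0))
  efrac <- if (pos > 0) max(lambda[1], 0) / pos else 0
  v <- ev$vectors[, 1L]
  score_live <- v * sqrt(max(lambda[1], 0)) * 100
  gd <- gene_density[live]
  if (stats::sd(gd) > 0 && stats::sd(score_live) > 0 &&
      stats::cor(score_live, gd) < 0) {
    score_live <- -score_live
  }
  if (efrac < 0.1) {
    warning("PC1 explains a small eigenvalue fraction (",
            signif(efrac, 3), "); compartment separation may be weak")
  }
  score <- rep(NA_real_, n)
  score[live] <- score_live
  out <- m$bins
  out$score <- score
  attr(out, "eigenvalue_fraction") <- efrac
  attr(out, "mask") <- setdiff(seq_len(n), live) - 1L
  attr(out, "bin_size") <- bins_bin_size(m$bins)
  out
}

#' @noRd
score_runs <- function(score) {
  sign_vec <- ifelse(is.na(score) | score == 0, 0L, ifelse(score > 0, 1L, -1L))
  r <- rle(sign_vec)
  ends <- cumsum(r$lengths)
  tibble::tibble(
    start_bin = ends - r$lengths + 1L,   # 1-based
    end_bin = ends,
    sign = r$values,
    n_bins = r$lengths
  )
}

#' Call A/B compartments from compartment scores
#'
#' A compartments are maximal runs of at least `min_bins` consecutive bins
#' with positive score; B compartments likewise with negative score. Shorter
#' runs and missing/zero bins remain unassigned.
#'
#' @param track A score track from [pca_scores()].
#' @param min_bins Minimum run length in bins (default 5).
#' @return Tibble of compartments: `chrom`, `start_bin`, `end_bin` (0-based,
#'   inclusive), `start`, `end` (bp), `label` (`"A"`/`"B"`), `n_bins`,
#'   `size_bp`.
#' @export
call_compartments <- function(track, min_bins = 5L) {
  if (min_bins < 1L) stop("`min_bins` must be >= 1", call. = FALSE)
  bs <- bins_bin_size(track)
  runs <- score_runs(track$score)
  runs <- runs[runs$sign != 0L & runs$n_bins >= min_bins, , drop = FALSE]
  tibble::tibble(
    chrom = track$chrom[1],
    start_bin = runs$start_bin - 1L,
    end_bin = runs$end_bin - 1L,
    start = track$start[runs$start_bin],
    end = track$end[runs$end_bin],
    label = ifelse(runs$sign > 0L, "A", "B"),
    n_bins = runs$n_bins,
    size_bp = runs$n_bins * as.numeric(bs)
  )
}

#' Classify per-bin compartment transitions between two conditions
#'
#' Each bin is labelled by the compartment state in the first then the
#' second condition: `AA`, `BB`, `BA` (B-to-A switch), `AB` (A-to-B switch),
#' or `NA` when either score is missing or exactly zero.
#'
#' @param t1,t2 Score tracks from [pca_scores()] on identical bins
#'   (condition 1 and condition 2).
#' @return A tibble (`chrom`, `bin`, `start`, `end`, `category`).
#' @export
classify_transitions <- function(t1, t2) {
  if (nrow(t1) != nrow(t2) || any(t1$bin != t2$bin) ||
      t1$chrom[1] != t2$chrom[1]) {
    stop("bin grids differ between conditions", call. = FALSE)
  }
  s1 <- t1$score
  s2 <- t2$score
  lab <- function(s) ifelse(is.na(s) | s == 0, NA_character_,
                            ifelse(s > 0, "A", "B"))
  l1 <- lab(s1); l2 <- lab(s2)
  category <- ifelse(is.na(l1) | is.na(l2), NA_character_, paste0(l1, l2))
  out <- tibble::tibble(chrom = t1$chrom, bin = t1$bin,
                        start = t1$start, end = t1$end, category = category)
  attr(out, "bin_size") <- bins_bin_size(t1)
  out
}

#' Maximal runs of a transition category as switch regions
#'
#' @param tmap Transition map from [classify_transitions()].
#' @param categories Categories to report (default the switches `BA`, `AB`).
#' @return Tibble of regions with `chrom`, `start`, `end`, `category`,
#'   `n_bins`, `size_bp`.
#' @export
transition_regions <- function(tmap, categories = c("BA", "AB")) {
  cat_vec <- tmap$category
  cat_vec[is.na(cat_vec)] <- "NA"
  r <- rle(cat_vec)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values %in% categories
  bs <- bins_bin_size(tmap)
  tibble::tibble(
    chrom = tmap$chrom[1],
    start = tmap$start[starts[keep]],
    end = tmap$end[ends[keep]],
    category = r$values[keep],
    n_bins = r$lengths[keep],
    size_bp = r$lengths[keep] * as.numeric(bs)
  )
}

#' Flag B-A-B reversal bins across three conditions
#'
#' A bin is a BAB bin when it switches B-to-A in the first contrast (e.g.
#' growing to senescent) and A-to-B in the second (e.g. senescent to
#' condensin-depleted).
#'
#' @param trans_1 Transition map for the first contrast.
#' @param trans_2 Transition map for the second contrast.
#' @return Logical vector, one flag per bin.
#' @export
classify_bab <- function(trans_1, trans_2) {
  if (nrow(trans_1) != nrow(trans_2) || any(trans_1$bin != trans_2$bin)) {
    stop("bin grids differ between transition maps", call. = FALSE)
  }
  out <- !is.na(trans_1$category) & trans_1$category == "BA" &
    !is.na(trans_2$category) & trans_2$category == "AB"
  out
}

#' Detect SAHF-like bins from compartment scores
#'
#' Senescence-associated heterochromatic foci correspond to bins with
#' strongly negative compartment scores; bins scoring below `threshold`
#' are flagged and contiguous flagged runs are reported as regions. The
#' default threshold of -20 is calibrated to this package's score scaling
#' (eigenvector entry times `sqrt(eigenvalue) * 100`).
#'
#' @param track Score track from [pca_scores()].
#' @param threshold Score threshold (default -20); bins with
#'   `score < threshold` are flagged.
#' @return Tibble of SAHF regions (`chrom`, `start`, `end`, `start_bin`,
#'   `end_bin`, `n_bins`, `size_bp`), with the per-bin logical flag vector in
#'   attribute `flags`.
#' @export
detect_sahf <- function(track, threshold = -20) {
  flags <- !is.na(track$score) & track$score < threshold
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  bs <- bins_bin_size(track)
  out <- tibble::tibble(
    chrom = track$chrom[1],
    start = track$start[starts[keep]],
    end = track$end[ends[keep]],
    start_bin = starts[keep] - 1L,
    end_bin = ends[keep] - 1L,
    n_bins = r$lengths[keep],
    size_bp = r$lengths[keep] * as.numeric(bs)
  )
  attr(out, "flags") <- flags
  attr(out, "threshold") <- threshold
  out
}

#' Long-versus-short (LVS) contact scores
#'
#' For each bin, the fraction of its cis contact mass (diagonal excluded)
#' carried by partners more than `distance_cutoff` bp away. High LVS marks
#' bins engaged in the long-range heterochromatic contacts typical of SAHF.
#'
#' @param m A balanced [contact_matrix()].
#' @param distance_cutoff Separation defining "long" (default 2 Mb).
#' @return Tibble (`chrom`, `bin`, `start`, `end`, `lvs`, `total_mass`);
#'   `lvs` is `NA` for masked or zero-coverage bins.
#' @export
lvs_scores <- function(m, distance_cutoff = 2e6) {
  stopifnot(inherits(m, "contact_matrix"))
  n <- n_bins(m)
  bs <- bins_bin_size(m$bins)
  cut_bins <- distance_cutoff / bs
  d <- abs(row(m$counts) - col(m$counts))
  off <- m$counts
  diag(off) <- 0
  long_mat <- off * (d > cut_bins)
  total <- rowSums(off)
  long <- rowSums(long_mat)
  lvs <- ifelse(total > 0, long / total, NA_real_)
  lvs[m$mask + 1L] <- NA_real_
  out <- m$bins
  out$lvs <- lvs
  out$total_mass <- total
  attr(out, "distance_cutoff") <- distance_cutoff
  attr(out, "bin_size") <- bs
  out
}

#' Compartment occupancy and size statistics for two conditions
#'
#' Summarises, per condition, the percent of assigned genome in A and B
#' compartments, compartment counts and size distributions, and per
#' transition category the percent of classified genome and region sizes.
#' Size distributions are compared between conditions with a two-sided
#' Mann-Whitney U test.
#'
#' @param c1,c2 Compartment tables from [call_compartments()] for the two
#'   conditions.
#' @param tmap Transition map from [classify_transitions()].
#' @return A list of tibbles: `occupancy` (per condition/label percent of
#'   compartment-assigned bins), `sizes` (one row per compartment),
#'   `transitions` (per category bin counts and percent of classified bins),
#'   `size_tests` (Mann-Whitney p for A-vs-A and B-vs-B size comparisons
#'   across conditions).
#' @export
occupancy_stats <- function(c1, c2, tmap) {
  comp <- dplyr::bind_rows(
    dplyr::mutate(c1, condition = "condition1"),
    dplyr::mutate(c2, condition = "condition2")
  )
  occupancy <- comp |>
    dplyr::group_by(.data$condition, .data$label) |>
    dplyr::summarise(n_compartments = dplyr::n(),
                     n_bins = sum(.data$n_bins),
                     total_bp = sum(.data$size_bp), .groups = "drop_last") |>
    dplyr::mutate(percent = 100 * .data$n_bins / sum(.data$n_bins)) |>
    dplyr::ungroup()
  sizes <- comp |>
    dplyr::select("condition", "label", "size_bp", "n_bins")
  tcounts <- tmap |>
    dplyr::filter(!is.na(.data$category)) |>
    dplyr::count(.data$category, name = "n_bins") |>
    dplyr::mutate(percent = 100 * .data$n_bins / sum(.data$n_bins))
  size_tests <- purrr::map_dfr(c("A", "B"), function(lb) {
    a <- c1$size_bp[c1$label == lb]
    b <- c2$size_bp[c2$label == lb]
    p <- if (length(a) && length(b)) mann_whitney(a, b)$p_value else NA_real_
    tibble::tibble(label = lb, n1 = length(a), n2 = length(b),
                   median1 = stats::median(a), median2 = stats::median(b),
                   p_value = p)
  })
  list(occupancy = occupancy, sizes = sizes, transitions = tcounts,
       size_tests = size_tests)
}

#' Percent of each chromosome covered by a flagged bin set
#'
#' @param flags Named list: one logical per-bin vector per chromosome.
#' @param groups Optional named list of two character vectors of chromosome
#'   names; when given, the per-chromosome percentages of the two groups are
#'   compared with a two-sided Mann-Whitney U test.
#' @return Tibble (`chrom`, `n_bins`, `n_flagged`, `percent`); if `groups`
#'   is given, attribute `group_test` holds the comparison.
#' @export
chromosome_occupancy <- function(flags, groups = NULL) {
  out <- purrr::imap_dfr(flags, function(f, nm) {
    tibble::tibble(chrom = nm, n_bins = length(f), n_flagged = sum(f),
                   percent = 100 * sum(f) / length(f))
  })
  if (!is.null(groups)) {
    stopifnot(length(groups) == 2L)
    a <- out$percent[out$chrom %in% groups[[1]]]
    b <- out$percent[out$chrom %in% groups[[2]]]
    attr(out, "group_test") <- mann_whitney(a, b)
  }
  out
}
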