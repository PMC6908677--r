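#' Insulation-based TAD border strength
#'
#' For each bin with at least `window_bins` bins on both sides, contacts are
#' summed within the upstream window (unordered pairs among the
#' `window_bins` bins immediately left of the bin), within the downstream
#' window likewise, and between the two windows (all upstream-by-downstream
#' pairs). The raw score is
#' `R = (within_up + within_down) / between`; a small epsilon
#' (`1e-6` times the genome-mean contact) guards the denominator on
#' perfectly insulated toy inputs. Raw scores are standardised genome-wide
#' to z-scores (mean subtracted, divided by the SD over defined bins).
#' Insulating borders score high: their flanking windows are dense while
#' cross-window contacts are depleted.
#'
#' On a uniform matrix every interior bin scores `156/169` with the default
#' 13-bin window (78 within-pairs on each side over 169 between-pairs).
#'
#' @param m A balanced [contact_matrix()] at working resolution.
#' @param window_bins Window width in bins (default 13).
#' @return Tibble (`chrom`, `bin`, `start`, `end`, `raw_R`, `z`); bins too
#'   close to the chromosome edge are `NA`.
#' @export
border_strength <- function(m, window_bins = 13L) {
  stopifnot(inherits(m, "contact_matrix"))
  w <- as.integer(window_bins)
  if (is.na(w) || w < 1L) stop("`window_bins` must be >= 1", call. = FALSE)
  counts <- m$counts
  n <- nrow(counts)
  raw <- rep(NA_real_, n)
  live <- rep(TRUE, n)
  live[m$mask + 1L] <- FALSE
  live_mean <- mean(counts[counts > 0])
  if (!is.finite(live_mean)) live_mean <- 1
  eps <- 1e-6 * live_mean
  n_within_full <- w * (w - 1) / 2
  n_between_full <- w * w
  # masked bins are excluded from the pair sums, which are rescaled to the
  # full pair counts so masked bins do not depress (and displace) the score
  win_sum <- function(block, tri) {
    vals <- if (tri) block[upper.tri(block)] else block
    s <- sum(vals[!is.na(vals)])
    k <- sum(!is.na(vals))
    full <- if (tri) n_within_full else n_between_full
    if (k == 0L) return(NA_real_)
    s * full / k
  }
  na_counts <- counts
  na_counts[!live, ] <- NA
  na_counts[, !live] <- NA
  for (b in seq_len(n)) {
    if (b - w < 1L || b + w > n) next
    up <- (b - w):(b - 1L)
    down <- (b + 1L):(b + w)
    within_up <- win_sum(na_counts[up, up, drop = FALSE], tri = TRUE)
    within_down <- win_sum(na_counts[down, down, drop = FALSE], tri = TRUE)
    between <- win_sum(na_counts[up, down, drop = FALSE], tri = FALSE)
    if (is.na(within_up) || is.na(within_down) || is.na(between)) next
    raw[b] <- (within_up + within_down) / max(between, eps)
  }
  out <- m$bins
  out$raw_R <- raw
  out$z <- standardize_scores(raw)
  attr(out, "window_bins") <- w
  attr(out, "bin_size") <- bins_bin_size(m$bins)
  out
}

#' Standardise raw border scores genome-wide
#'
#' Pools raw R values across one or more chromosomes, subtracts the mean and
#' divides by the SD over defined bins. If the SD is zero the z-scores are
#' set to 0 with a warning.
#'
#' @param raw Numeric vector of raw R values (NA where undefined).
#' @return z-scores of the same length.
#' @export
standardize_scores <- function(raw) {
  ok <- !is.na(raw)
  if (!any(ok)) return(raw)
  mu <- mean(raw[ok])
  sdv <- stats::sd(raw[ok])
  z <- rep(NA_real_, length(raw))
  if (!is.finite(sdv) || sdv == 0) {
    warning("zero variance in border scores; z-scores set to 0")
    z[ok] <- 0
  } else {
    z[ok] <- (raw[ok] - mu) / sdv
  }
  z
}

#' Re-standardise border tracks jointly across chromosomes
#'
#' @param tracks List of [border_strength()] tibbles (one per chromosome).
#' @return The list with `z` recomputed from the pooled raw values.
#' @export
pool_border_z <- function(tracks) {
  raw <- unlist(lapply(tracks, function(t) t$raw_R))
  z <- standardize_scores(raw)
  off <- 0L
  lapply(tracks, function(t) {
    t$z <- z[off + seq_len(nrow(t))]
    off <<- off + nrow(t)
    t
  })
}

#' Call TAD borders from a border-strength track
#'
#' Border bins are local maxima of the z-score — strictly greater than both
#' neighbouring defined values, with plateaus resolved to their leftmost bin
#' — that reach at least `z_min`. TAD segments between consecutive borders
#' are reported with sizes.
#'
#' @param track A [border_strength()] tibble.
#' @param z_min Minimum z to call a border (default 1.0).
#' @return Tibble of border bins (`chrom`, `bin`, `start`, `end`, `z`);
#'   attribute `tads` holds the derived segments between consecutive borders.
#' @export
call_tad_borders <- function(track, z_min = 1.0) {
  z <- track$z
  n <- length(z)
  is_border <- logical(n)
  i <- 1L
  while (i <= n) {
    if (is.na(z[i]) || z[i] < z_min) { i <- i + 1L; next }
    # plateau [i, j] of equal z
    j <- i
    while (j < n && !is.na(z[j + 1L]) && z[j + 1L] == z[i]) j <- j + 1L
    left_ok <- i == 1L || is.na(z[i - 1L]) || z[i - 1L] < z[i]
    right_ok <- j == n || is.na(z[j + 1L]) || z[j + 1L] < z[i]
    if (left_ok && right_ok) is_border[i] <- TRUE  # leftmost plateau bin
    i <- j + 1L
  }
  idx <- which(is_border)
  borders <- tibble::tibble(
    chrom = track$chrom[idx], bin = track$bin[idx],
    start = track$start[idx], end = track$end[idx], z = z[idx]
  )
  bs <- bins_bin_size(track)
  tads <- if (length(idx) >= 2L) {
    tibble::tibble(
      chrom = track$chrom[1],
      start = track$end[idx[-length(idx)]],
      end = track$start[idx[-1]],
      n_bins = diff(idx) - 1L,
      size_bp = (diff(idx) - 1L) * as.numeric(bs)
    )
  } else {
    tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                   n_bins = integer(), size_bp = numeric())
  }
  attr(borders, "tads") <- tads
  attr(borders, "bin_size") <- bs
  borders
}

#' @noRd
present_within <- function(pos, set, tol) {
  if (!length(set)) return(rep(FALSE, length(pos)))
  vapply(pos, function(p) any(abs(set - p) <= tol), logical(1))
}

#' Classify TAD borders by replicate specificity
#'
#' Borders are matched across replicates allowing a positional shift of up
#' to `tolerance_bins`. A border is condition-1-specific when present in all
#' condition-1 replicates and no condition-2 replicate; condition-2-specific
#' when present in at least two condition-2 replicates and no condition-1
#' replicate; remaining borders found in at least two datasets are
#' non-specific; anything else is unclassified.
#'
#' @param reps1 List (>= 2) of border-bin integer vectors for condition 1
#'   (e.g. growing-cell replicates).
#' @param reps2 List (>= 2) of border-bin integer vectors for condition 2
#'   (e.g. senescent replicates).
#' @param tolerance_bins Matching tolerance (default 1 bin).
#' @param labels Labels for the two specificity classes (defaults
#'   `"G-specific"`, `"OIS-specific"`).
#' @return Tibble (`bin`, `n_reps1`, `n_reps2`, `class`), one row per
#'   distinct border position in the union of all replicates.
#' @export
classify_border_specificity <- function(reps1, reps2, tolerance_bins = 1L,
                                        labels = c("G-specific", "OIS-specific")) {
  if (length(reps1) < 2L || length(reps2) < 2L) {
    stop("at least two replicates are required per condition", call. = FALSE)
  }
  reps1 <- lapply(reps1, as.integer)
  reps2 <- lapply(reps2, as.integer)
  all_pos <- sort(unique(c(unlist(reps1), unlist(reps2))))
  # collapse positions within tolerance into clusters; keep leftmost as anchor
  anchors <- integer(0)
  for (p in all_pos) {
    if (!length(anchors) || p - anchors[length(anchors)] > tolerance_bins) {
      anchors <- c(anchors, p)
    }
  }
  n1 <- vapply(anchors, function(a) {
    sum(vapply(reps1, function(r) any(abs(r - a) <= tolerance_bins), logical(1)))
  }, integer(1))
  n2 <- vapply(anchors, function(a) {
    sum(vapply(reps2, function(r) any(abs(r - a) <= tolerance_bins), logical(1)))
  }, integer(1))
  cls <- rep("unclassified", length(anchors))
  cls[n1 == length(reps1) & n2 == 0L] <- labels[1]
  cls[n2 >= 2L & n1 == 0L] <- labels[2]
  remaining <- cls == "unclassified" & (n1 + n2) >= 2L
  cls[remaining] <- "non-specific"
  tibble::tibble(bin = anchors, n_reps1 = n1, n_reps2 = n2, class = cls)
}

#' Compartment borders from a compartment table
#'
#' A compartment border is the first bin of a compartment whose label
#' differs from the nearest preceding compartment's label.
#'
#' @param comps Compartment table from [call_compartments()].
#' @return Integer vector of 0-based border bins.
#' @export
compartment_borders <- function(comps) {
  if (nrow(comps) < 2L) return(integer(0))
  comps <- comps[order(comps$start_bin), ]
  diff_lab <- comps$label[-1] != comps$label[-nrow(comps)]
  as.integer(comps$start_bin[-1][diff_lab])
}

#' Condition-specific borders by tolerant set difference
#'
#' @param borders1,borders2 Integer border-bin vectors.
#' @param tolerance_bins Matching tolerance (default 1).
#' @return Bins of `borders1` with no match in `borders2` within tolerance.
#' @export
specific_borders <- function(borders1, borders2, tolerance_bins = 1L) {
  borders1[!present_within(borders1, borders2, tolerance_bins)]
}

#' Overlap of TAD borders with compartment borders
#'
#' Fraction of TAD borders lying within `tolerance_bins` of any compartment
#' border, with a hypergeometric enrichment p-value over the bin population
#' (compartment borders dilated by the tolerance).
#'
#' @param tad_borders Integer vector of TAD border bins.
#' @param comp_borders Integer vector of compartment border bins.
#' @param n_bins_total Number of bins in the population.
#' @param tolerance_bins Matching tolerance (default 1).
#' @return Tibble with `fraction`, `n_overlap`, `n_borders`, `p_value`,
#'   `log10_p`.
#' @export
border_overlap_fraction <- function(tad_borders, comp_borders, n_bins_total,
                                    tolerance_bins = 1L) {
  tad_borders <- unique(as.integer(tad_borders))
  comp_borders <- unique(as.integer(comp_borders))
  if (!length(tad_borders)) {
    return(tibble::tibble(fraction = NA_real_, n_overlap = 0L,
                          n_borders = 0L, p_value = NA_real_,
                          log10_p = NA_real_))
  }
  hit <- present_within(tad_borders, comp_borders, tolerance_bins)
  dilated <- unique(unlist(lapply(comp_borders, function(b) {
    (b - tolerance_bins):(b + tolerance_bins)
  })))
  dilated <- dilated[dilated >= 0 & dilated < n_bins_total]
  hg <- hypergeometric_overlap(tad_borders, dilated, n_bins_total)
  tibble::tibble(fraction = mean(hit), n_overlap = sum(hit),
                 n_borders = length(tad_borders),
                 p_value = hg$p_value, log10_p = hg$log10_p)
}
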