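#' Construct a per-chromosome contact matrix
#'
#' A `contact_matrix` holds a symmetric, non-negative matrix of cis contact
#' counts (or balanced contact scores) on a uniform bin grid, together with a
#' mask of excluded bins. Masked rows and columns are held at zero.
#'
#' @param counts Symmetric numeric `n x n` matrix, non-negative unless
#'   `signed = TRUE` (difference maps).
#' @param bins A bin table from [genome_bins()] with `n` rows.
#' @param mask Integer vector of 0-based bin indices to exclude.
#' @param normalized Logical flag: has the matrix been balanced?
#' @param signed Allow negative entries (used internally for difference maps).
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(counts, bins, mask = integer(),
                           normalized = FALSE, signed = FALSE) {
  counts <- as.matrix(counts)
  n <- nrow(bins)
  if (!is.numeric(counts) || nrow(counts) != n || ncol(counts) != n) {
    stop("`counts` must be a numeric ", n, "x", n,
         " matrix matching `bins`", call. = FALSE)
  }
  if (max(abs(counts - t(counts))) > 1e-8 * max(1, max(abs(counts)))) {
    stop("matrix not symmetric", call. = FALSE)
  }
  if (!signed && any(counts < 0)) {
    stop("contact counts must be non-negative", call. = FALSE)
  }
  mask <- sort(unique(as.integer(mask)))
  if (length(mask) && (min(mask) < 0L || max(mask) >= n)) {
    stop("mask indices out of range", call. = FALSE)
  }
  if (length(mask)) {
    counts[mask + 1L, ] <- 0
    counts[, mask + 1L] <- 0
  }
  dimnames(counts) <- NULL
  structure(
    list(counts = counts, bins = bins, mask = mask,
         normalized = isTRUE(normalized), signed = isTRUE(signed)),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  n <- nrow(x$counts)
  cat(sprintf(
    "<contact_matrix> %s: %d bins x %d bp (%d masked)%s, total %.4g\n",
    x$bins$chrom[1], n, bins_bin_size(x$bins), length(x$mask),
    if (x$normalized) ", balanced" else ", raw",
    sum(x$counts)
  ))
  invisible(x)
}

#' @noRd
n_bins <- function(m) nrow(m$counts)

#' @noRd
unmasked_idx <- function(m) setdiff(seq_len(n_bins(m)), m$mask + 1L)

#' Read a contact matrix from sparse-triple or dense text
#'
#' The sparse triple format is whitespace-separated `bin_i bin_j count` with
#' optional `#` header lines; entries are mirrored across the diagonal and
#' duplicate pairs (in either orientation) are summed. The dense format is a
#' tab-separated `n x n` matrix, which must already be symmetric.
#'
#' @param path Path to the text file.
#' @param bins Bin table defining the grid.
#' @param format `"triple"` or `"dense"`.
#' @return A raw [contact_matrix()].
#' @export
read_contacts <- function(path, bins, format = c("triple", "dense")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  n <- nrow(bins)
  if (format == "triple") {
    lines <- readLines(path)
    keep <- !grepl("^\\s*(#|$)", lines)
    counts <- matrix(0, n, n)
    ln <- which(keep)
    if (length(ln)) {
      fields <- strsplit(trimws(lines[keep]), "\\s+")
      bad <- which(lengths(fields) != 3L)
      if (length(bad)) {
        stop("parse error at line ", ln[bad[1]], ": expected 'bin_i bin_j count'",
             call. = FALSE)
      }
      rec <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                    ncol = 3L, byrow = TRUE)
      bad <- which(apply(rec, 1L, function(r) anyNA(r)))
      if (length(bad)) {
        stop("parse error at line ", ln[bad[1]], ": non-numeric field",
             call. = FALSE)
      }
      if (any(rec[, 1] < 0 | rec[, 1] >= n | rec[, 2] < 0 | rec[, 2] >= n)) {
        stop("bin index out of range [0, ", n, ")", call. = FALSE)
      }
      i <- pmin(as.integer(rec[, 1]), as.integer(rec[, 2])) + 1L
      j <- pmax(as.integer(rec[, 1]), as.integer(rec[, 2])) + 1L
      agg <- rowsum(rec[, 3], (j - 1) * n + i)        # sum duplicate pairs
      key <- as.numeric(rownames(agg))
      ii <- as.integer((key - 1) %% n) + 1L
      jj <- as.integer((key - 1) %/% n) + 1L
      counts[cbind(ii, jj)] <- agg[, 1]
      counts[cbind(jj, ii)] <- agg[, 1]
    }
  } else {
    counts <- as.matrix(utils::read.table(path, sep = "\t", comment.char = "#"))
    dimnames(counts) <- NULL
    if (nrow(counts) != n || ncol(counts) != n) {
      stop("dense matrix is ", nrow(counts), "x", ncol(counts),
           ", expected ", n, "x", n, call. = FALSE)
    }
    if (max(abs(counts - t(counts))) > 0) stop("matrix not symmetric", call. = FALSE)
  }
  contact_matrix(counts, bins)
}

#' Write a contact matrix as sparse triples
#'
#' Emits upper-triangle (including diagonal) nonzero entries as
#' `bin_i bin_j count`, preceded by a provenance header. Round-trips with
#' [read_contacts()] losslessly for exactly representable values.
#'
#' @param m A [contact_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(m, path) {
  idx <- which(upper.tri(m$counts, diag = TRUE) & m$counts != 0, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(), con)
  if (nrow(idx)) {
    writeLines(sprintf("%d %d %s", idx[, 1] - 1L, idx[, 2] - 1L,
                       format(m$counts[idx], digits = 17, scientific = FALSE,
                              trim = TRUE)), con)
  }
  invisible(path)
}

#' Balance a contact matrix by iterative correction (ICE)
#'
#' Removes multiplicative per-bin biases by repeatedly dividing each entry by
#' its (normalised) marginal, driving all unmasked row sums to a common
#' value. Bins in the lowest coverage quantile are masked before iteration,
#' as are bins with zero coverage.
#'
#' @param m A raw [contact_matrix()].
#' @param n_iter Number of correction sweeps (default 30).
#' @param low_coverage_quantile Fraction of lowest-coverage bins to mask
#'   before balancing (default 0.02).
#' @return A balanced `contact_matrix` with `normalized = TRUE`. The
#'   accumulated per-bin biases are attached as attribute `biases`
#'   (`NA` on masked bins).
#' @export
ice_normalize <- function(m, n_iter = 30L, low_coverage_quantile = 0.02) {
  stopifnot(inherits(m, "contact_matrix"))
  if (n_iter < 1L) stop("`n_iter` must be >= 1", call. = FALSE)
  if (sum(m$counts) == 0) stop("no signal: matrix is all zero", call. = FALSE)
  counts <- m$counts
  n <- nrow(counts)
  cov <- rowSums(counts)
  mask1 <- m$mask + 1L                      # 1-based
  live <- setdiff(seq_len(n), mask1)
  thr <- stats::quantile(cov[live], low_coverage_quantile, names = FALSE)
  mask1 <- sort(union(mask1, live[cov[live] < thr | cov[live] == 0]))
  live <- setdiff(seq_len(n), mask1)
  if (length(live) < 2L) stop("no signal: fewer than two covered bins", call. = FALSE)
  counts[mask1, ] <- 0
  counts[, mask1] <- 0
  bias <- rep(1, n)
  for (it in seq_len(n_iter)) {
    s <- rowSums(counts)
    s_live <- s[live]
    s_live <- s_live / mean(s_live)
    s_live[s_live == 0] <- 1
    bias[live] <- bias[live] * s_live
    counts[live, live] <- counts[live, live] / outer(s_live, s_live)
  }
  # rescale so total signal matches the input (balancing is scale-free)
  tot_in <- sum(m$counts[live, live])
  tot_out <- sum(counts)
  if (tot_out > 0) counts <- counts * (tot_in / tot_out)
  bias[mask1] <- NA_real_
  out <- contact_matrix(counts, m$bins, mask = mask1 - 1L, normalized = TRUE)
  attr(out, "biases") <- bias
  out
}

#' Coarsen a contact matrix by block summation
#'
#' Aggregates `factor x factor` blocks of bins by summing counts; the
#' trailing partial block is kept. A coarse bin is masked only if every
#' constituent fine bin was masked.
#'
#' @param m A [contact_matrix()].
#' @param factor Integer coarsening factor (e.g. 5 for 40 kb to 200 kb).
#' @return A `contact_matrix` on the coarse grid.
#' @export
coarsen <- function(m, factor) {
  stopifnot(inherits(m, "contact_matrix"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("`factor` must be >= 1", call. = FALSE)
  if (factor == 1L) return(m)
  n <- n_bins(m)
  grp <- (seq_len(n) - 1L) %/% factor
  agg <- rowsum(t(rowsum(m$counts, grp)), grp)
  dimnames(agg) <- NULL
  fine_masked <- logical(n)
  fine_masked[m$mask + 1L] <- TRUE
  coarse_mask <- which(tapply(fine_masked, grp, all)) - 1L
  bs <- bins_bin_size(m$bins)
  cbins <- genome_bins(m$bins$chrom[1], max(m$bins$end), bin_size = bs * factor)
  contact_matrix(agg, cbins, mask = as.integer(coarse_mask),
                 normalized = m$normalized, signed = m$signed)
}

#' @noRd
diagonal_means <- function(counts, live) {
  n <- nrow(counts)
  keep <- matrix(FALSE, n, n)
  keep[live, live] <- TRUE
  d <- abs(row(counts) - col(counts))
  sums <- tapply(counts[keep], d[keep], sum)
  cnts <- tapply(keep[keep], d[keep], length)
  list(dist = as.integer(names(sums)), mean = as.numeric(sums) / as.numeric(cnts))
}

#' Observed/expected transformation
#'
#' Divides each contact by the mean contact over all unmasked pairs at the
#' same bin separation, removing the genomic distance-decay so that
#' compartment structure stands out. Diagonals with zero expected value are
#' set to 0.
#'
#' @param m A balanced [contact_matrix()]; a warning is issued (and the
#'   transformation still applied) on raw input.
#' @return A `contact_matrix` of O/E ratios; the per-diagonal mean of
#'   unmasked entries is 1 by construction.
#' @export
observed_over_expected <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  if (!m$normalized) warning("computing O/E on an unnormalized matrix")
  n <- n_bins(m)
  live <- unmasked_idx(m)
  dm <- diagonal_means(m$counts, live)
  expected <- numeric(n)          # indexed by distance + 1
  expected[dm$dist + 1L] <- dm$mean
  d <- abs(row(m$counts) - col(m$counts))
  exp_mat <- matrix(expected[d + 1L], n, n)
  oe <- ifelse(exp_mat > 0, m$counts / exp_mat, 0)
  oe[-live, ] <- 0
  oe[, -live] <- 0
  contact_matrix(oe, m$bins, mask = m$mask, normalized = TRUE)
}

#' Contact decay profile P(s)
#'
#' Mean contact score as a function of bin separation, over unmasked pairs.
#' Separations with no surviving pairs are omitted.
#'
#' @param m A balanced [contact_matrix()].
#' @return A tibble with columns `distance_bp`, `separation_bins`,
#'   `mean_contact`.
#' @export
contact_decay_profile <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  live <- unmasked_idx(m)
  if (!length(live)) {
    return(tibble::tibble(distance_bp = numeric(), separation_bins = integer(),
                          mean_contact = numeric()))
  }
  dm <- diagonal_means(m$counts, live)
  bs <- bins_bin_size(m$bins)
  tibble::tibble(
    distance_bp = dm$dist * as.numeric(bs),
    separation_bins = dm$dist,
    mean_contact = dm$mean
  )
}

#' Difference of contact probability maps
#'
#' Scales both matrices to unit total over the shared unmasked region
#' (turning counts into contact probabilities) and subtracts: positive
#' entries mark pairs contacting more in `m1`.
#'
#' @param m1,m2 Balanced [contact_matrix()] objects on identical bins.
#' @return A signed `contact_matrix` of probability differences, with the
#'   union of the two masks applied.
#' @export
difference_map <- function(m1, m2) {
  stopifnot(inherits(m1, "contact_matrix"), inherits(m2, "contact_matrix"))
  if (n_bins(m1) != n_bins(m2) ||
      bins_bin_size(m1$bins) != bins_bin_size(m2$bins)) {
    stop("bin grids differ between the two matrices", call. = FALSE)
  }
  mask <- union(m1$mask, m2$mask)
  live <- setdiff(seq_len(n_bins(m1)), mask + 1L)
  p1 <- m1$counts
  p2 <- m2$counts
  p1[-live, ] <- 0; p1[, -live] <- 0
  p2[-live, ] <- 0; p2[, -live] <- 0
  s1 <- sum(p1); s2 <- sum(p2)
  if (s1 > 0) p1 <- p1 / s1
  if (s2 > 0) p2 <- p2 / s2
  contact_matrix(p1 - p2, m1$bins, mask = mask, normalized = TRUE, signed = TRUE)
}
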