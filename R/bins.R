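#' Define a binned grid over a chromosome
#'
#' All per-chromosome analyses in seneschic operate on a uniform grid of
#' fixed-size bins tiling the chromosome. Coordinates are 0-based half-open:
#' bin `i` covers `[i * bin_size, (i + 1) * bin_size)`.
#'
#' @param chrom Chromosome name.
#' @param length_bp Chromosome length in bp. The final bin may be partial.
#' @param bin_size Bin width in bp (default 40 kb, the working resolution for
#'   compartment and TAD analyses).
#' @return A tibble with columns `chrom`, `bin` (0-based index), `start`,
#'   `end`, carrying the bin size in attribute `bin_size`.
#' @examples
#' genome_bins("chr1", 1e6, 2e5)
#' @export
genome_bins <- function(chrom, length_bp, bin_size = 40000L) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  bin_size <- as.integer(bin_size)
  if (is.na(bin_size) || bin_size <= 0L) {
    stop("`bin_size` must be a positive integer number of bp", call. = FALSE)
  }
  if (length_bp <= 0) stop("`length_bp` must be positive", call. = FALSE)
  n <- as.integer(ceiling(length_bp / bin_size))
  out <- tibble::tibble(
    chrom = chrom,
    bin = seq_len(n) - 1L,
    start = (seq_len(n) - 1L) * as.numeric(bin_size),
    end = pmin(seq_len(n) * as.numeric(bin_size), as.numeric(length_bp))
  )
  attr(out, "bin_size") <- bin_size
  out
}

#' @noRd
bins_bin_size <- function(bins) {
  bs <- attr(bins, "bin_size")
  if (is.null(bs)) bs <- as.integer(bins$end[1] - bins$start[1])
  as.integer(bs)
}
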