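#' @noRd
provenance_header <- function() {
  sprintf("# generated-by seneschic %s",
          as.character(utils::packageVersion("seneschic")))
}

#' Write a per-bin track as bedGraph
#'
#' Coordinates are 0-based half-open. Bins with missing values are skipped.
#'
#' @param track Tibble with columns `chrom`, `start`, `end` and one value
#'   column named by `value_col`.
#' @param path Output path.
#' @param value_col Name of the value column (default `"score"`).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, value_col = "score") {
  stopifnot(all(c("chrom", "start", "end", value_col) %in% names(track)))
  v <- track[[value_col]]
  keep <- !is.na(v)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(), con)
  writeLines(sprintf("%s\t%d\t%d\t%s",
                     track$chrom[keep], as.integer(track$start[keep]),
                     as.integer(track$end[keep]),
                     format(v[keep], digits = 10, trim = TRUE, scientific = FALSE)),
             con)
  invisible(path)
}

#' Write genomic intervals as BED
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally a
#'   `name` column (written in BED column 4).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  nm <- if ("name" %in% names(intervals)) as.character(intervals$name) else
    rep(".", nrow(intervals))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(), con)
  if (nrow(intervals)) {
    writeLines(sprintf("%s\t%d\t%d\t%s", intervals$chrom,
                       as.integer(intervals$start), as.integer(intervals$end), nm),
               con)
  }
  invisible(path)
}

#' Write a tibble as TSV with a provenance header
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_prov <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bedGraph track into a tibble
#'
#' @param path Path to a bedGraph file (optional `#` header lines).
#' @param value_col Name for the value column.
#' @return Tibble with `chrom`, `start`, `end`, and the value column.
#' @export
read_bedgraph <- function(path, value_col = "score") {
  x <- utils::read.table(path, sep = "\t", comment.char = "#",
                         col.names = c("chrom", "start", "end", "value"),
                         colClasses = c("character", "numeric", "numeric", "numeric"))
  out <- tibble::as_tibble(x)
  names(out)[4] <- value_col
  out
}
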