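#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a contact matrix into a long tibble
#'
#' @param x A [contact_matrix()].
#' @param upper_only Keep only `bin1 <= bin2` (default `TRUE`).
#' @param drop_zero Drop zero entries (default `TRUE`).
#' @param ... Unused.
#' @return Tibble with `chrom`, `bin1`, `bin2`, `count`.
#' @export
tidy.contact_matrix <- function(x, upper_only = TRUE, drop_zero = TRUE, ...) {
  keep <- if (upper_only) upper.tri(x$counts, diag = TRUE) else
    matrix(TRUE, nrow(x$counts), ncol(x$counts))
  if (drop_zero) keep <- keep & x$counts != 0
  idx <- which(keep, arr.ind = TRUE)
  tibble::tibble(chrom = x$bins$chrom[1],
                 bin1 = idx[, 1] - 1L, bin2 = idx[, 2] - 1L,
                 count = x$counts[idx])
}

#' One-row summary of a contact matrix
#'
#' @param x A [contact_matrix()].
#' @param ... Unused.
#' @return Tibble with bin counts, mask size, total signal, and flags.
#' @export
glance.contact_matrix <- function(x, ...) {
  tibble::tibble(chrom = x$bins$chrom[1], n_bins = n_bins(x),
                 bin_size = bins_bin_size(x$bins),
                 n_masked = length(x$mask), total = sum(x$counts),
                 normalized = x$normalized, signed = x$signed)
}

#' Heatmap of a contact matrix
#'
#' @param object A [contact_matrix()].
#' @param trans Transformation for the fill scale: `"log10"` (default,
#'   raw/balanced counts) or `"identity"` (difference maps).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contact_matrix <- function(object, trans = if (object$signed) "identity" else "log10", ...) {
  df <- tidy(object, upper_only = FALSE, drop_zero = FALSE)
  bs <- bins_bin_size(object$bins) / 1e6
  df$x <- df$bin1 * bs
  df$y <- df$bin2 * bs
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "position (Mb)", y = "position (Mb)",
                  title = object$bins$chrom[1])
  if (object$signed) {
    p + ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                      high = "red", name = "Δ prob")
  } else if (trans == "log10") {
    df$count[df$count <= 0] <- NA
    p %+% df + ggplot2::scale_fill_viridis_c(trans = "log10",
                                             na.value = "white",
                                             name = "contacts")
  } else {
    p + ggplot2::scale_fill_viridis_c(name = "contacts")
  }
}

#' Plot a per-bin score track along the chromosome
#'
#' Draws compartment-style bar tracks: positive (A-like) values in red,
#' negative (B-like) in blue.
#'
#' @param track Tibble with `start` and a value column.
#' @param value_col Column to plot (default `"score"`).
#' @return A ggplot object.
#' @export
plot_track <- function(track, value_col = "score") {
  df <- tibble::tibble(x = track$start / 1e6, y = track[[value_col]])
  df <- df[!is.na(df$y), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$y > 0)) +
    ggplot2::geom_col(width = diff(range(df$x)) / nrow(df)) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c23b22",
                                          `FALSE` = "#3b6fc2"),
                               guide = "none") +
    ggplot2::labs(x = "position (Mb)", y = value_col)
}

#' Plot a contact decay profile
#'
#' @param profile Tibble from [contact_decay_profile()].
#' @return A ggplot object with log-log axes.
#' @export
plot_decay <- function(profile) {
  df <- profile[profile$distance_bp > 0 & profile$mean_contact > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance_bp,
                                   y = .data$mean_contact)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "separation (bp)", y = "mean contact", title = "P(s)")
}

#' Plot a SAHF distance-window sweep
#'
#' @param sweep Tibble from [sahf_window_sweep()].
#' @return A ggplot object: per-window percent downregulated with the
#'   genome-wide control as a dashed line.
#' @export
plot_window_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$window_start / 1e3,
                                      y = .data$pct_downregulated)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$control_pct),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "window start (kb from SAHF)",
                  y = "% downregulated genes")
}
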