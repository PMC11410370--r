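#' @importFrom ggplot2 ggplot aes geom_col geom_line geom_tile autoplot
#'   labs scale_fill_viridis_c facet_wrap theme_minimal
NULL

#' Plot a relative-distance histogram
#'
#' Bar plot of the relative-distance frequencies on `[0, 0.5]`; a flat
#' profile is the no-association null, a left skew means the queries sit
#' close to the references.
#'
#' @param x A `reldist_result` from [relative_distance()].
#' @return A ggplot object.
#' @export
plot_reldist <- function(x) {
  ggplot(x$histogram, aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                          y = .data$frequency)) +
    geom_col(width = x$histogram$bin_hi[1] - x$histogram$bin_lo[1],
             fill = "grey30") +
    labs(x = "relative distance", y = "frequency") +
    theme_minimal()
}

#' @describeIn plot_reldist autoplot method.
#' @param object,... Passed through.
#' @export
autoplot.reldist_result <- function(object, ...) plot_reldist(object)

#' Heatmap and mean profile of a signal matrix
#'
#' `autoplot()` on a `profile_matrix` draws the row-by-bin heatmap (rows
#' in their current order, so apply [order_rows()] first for the sorted
#' view); `plot_profile()` draws the per-column mean metaprofile.
#'
#' @param object A `profile_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.profile_matrix <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(-"row_id", names_to = "offset", values_to = "signal") |>
    mutate(offset = as.numeric(.data$offset),
           row_id = factor(.data$row_id, levels = rev(rownames(object))))
  ggplot(df, aes(x = .data$offset, y = .data$row_id, fill = .data$signal)) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(x = "offset (bp)", y = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @rdname autoplot.profile_matrix
#' @param mat A `profile_matrix`.
#' @export
plot_profile <- function(mat) {
  ggplot(column_profile(mat), aes(x = .data$offset, y = .data$mean_signal)) +
    geom_line(linewidth = 0.8) +
    labs(x = "offset (bp)", y = "mean signal") +
    theme_minimal()
}

#' Plot motif density around reference points
#'
#' @param density Tibble from [motif_density_around_points()].
#' @return A ggplot object.
#' @export
plot_motif_density <- function(density) {
  ggplot(density, aes(x = (.data$bin_lo + .data$bin_hi) / 2, y = .data$percent)) +
    geom_col(width = density$bin_hi[1] - density$bin_lo[1], fill = "steelblue") +
    labs(x = "offset from reference point (bp)", y = "% of points with a hit") +
    theme_minimal()
}

#' Plot per-element positional histograms around the TSS
#'
#' @param hist Tibble from [element_positional_histogram()].
#' @return A ggplot object, faceted by element.
#' @export
plot_element_histogram <- function(hist) {
  ggplot(hist, aes(x = (.data$bin_lo + .data$bin_hi) / 2, y = .data$percent)) +
    geom_col(width = hist$bin_hi[1] - hist$bin_lo[1], fill = "grey30") +
    facet_wrap(~element, scales = "free_y") +
    labs(x = "offset from dominant TSS (bp)", y = "% of promoters") +
    theme_minimal()
}
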