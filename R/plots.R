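#' Heatmap of a connectivity matrix
#'
#' @param object A `connectivity_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.connectivity_matrix <- function(object, ...) {
  n <- nrow(object$values)
  df <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n))
  df$wpli <- object$values[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$wpli)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "wPLI") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = paste0("wPLI connectivity — subject ", object$subject_id,
                     ", ", object$band$name, " band"),
      x = "region", y = "region"
    ) +
    ggplot2::theme_minimal()
}

#' Permutation null distribution of an NBS result
#'
#' Histogram of the permutation null of maximum component extents with
#' the observed component extents overlaid; significant components are
#' highlighted.
#'
#' @param object An `nbs_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nbs_result <- function(object, ...) {
  null_df <- tibble::tibble(extent = object$null_max_extents)
  comp_df <- tidy.nbs_result(object)
  p <- ggplot2::ggplot(null_df, ggplot2::aes(x = .data$extent)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70",
                            colour = "grey40") +
    ggplot2::labs(
      title = paste0("NBS permutation null — ", object$design$predictor,
                     " (", object$design$direction, ")"),
      x = "maximum component extent (edges)", y = "permutations"
    ) +
    ggplot2::theme_minimal()
  if (nrow(comp_df)) {
    p <- p + ggplot2::geom_vline(
      data = comp_df,
      ggplot2::aes(xintercept = .data$extent, colour = .data$significant),
      linewidth = 0.8
    ) +
      ggplot2::scale_colour_manual(
        values = c(`TRUE` = "firebrick", `FALSE` = "steelblue"),
        name = "significant"
      )
  }
  p
}

#' Bar chart of component node degrees
#'
#' @param component A component from an `nbs_result` or
#'   [extract_components()].
#' @param atlas Optional atlas tibble for labels.
#' @param top_k Number of regions shown (default 15).
#' @return A ggplot object.
#' @export
plot_hubs <- function(component, atlas = NULL, top_k = 15) {
  hubs <- identify_hubs(node_degree(component), top_k = top_k, atlas = atlas)
  ggplot2::ggplot(hubs, ggplot2::aes(
    x = .data$degree,
    y = stats::reorder(.data$label, .data$degree))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(title = "Network hubs by degree", x = "degree",
                  y = NULL) +
    ggplot2::theme_minimal()
}
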