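#' Plot a profile map
#'
#' Heatmap of pair profiles (one row per contiguous pair, 100 positions) or
#' the per-position mean with a standard-error ribbon. The vertical guide
#' marks the interface-anchored membrane position.
#'
#' @param object a `profile_map`.
#' @param type `"map"` (heatmap) or `"mean"` (mean +/- SE curve).
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.profile_map <- function(object, type = c("map", "mean"), ...) {
  type <- match.arg(type)
  n <- ncol(object$profiles)
  mid <- (1 + n) / 2
  if (type == "map") {
    df <- tidy.profile_map(object)
    ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$pair_id,
                                     fill = .data$intensity)) +
      ggplot2::geom_raster() +
      ggplot2::geom_vline(xintercept = mid, linetype = 2, color = "white") +
      ggplot2::scale_fill_viridis_c(name = "intensity") +
      ggplot2::labs(
        x = "internuclear position",
        y = "pair",
        title = if (object$compensated) "compensated profile map" else "extracted profile map"
      ) +
      ggplot2::theme_minimal()
  } else {
    df <- tibble::tibble(position = seq_len(n), mean = object$mean,
                         se = object$se)
    ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$mean)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           alpha = 0.3) +
      ggplot2::geom_line() +
      ggplot2::geom_vline(xintercept = mid, linetype = 2) +
      ggplot2::labs(x = "internuclear position", y = "mean intensity") +
      ggplot2::theme_minimal()
  }
}

#' Plot extracted and compensated maps side by side
#'
#' @param extracted,compensated `profile_map`s of the same pairs.
#' @return A ggplot object faceted into the two panels.
#' @export
plot_profile_panels <- function(extracted, compensated) {
  df <- dplyr::bind_rows(
    dplyr::mutate(tidy.profile_map(extracted), panel = "extracted"),
    dplyr::mutate(tidy.profile_map(compensated), panel = "compensated")
  )
  df$panel <- factor(df$panel, levels = c("extracted", "compensated"))
  n <- ncol(extracted$profiles)
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$pair_id,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::geom_vline(xintercept = (1 + n) / 2, linetype = 2,
                        color = "white") +
    ggplot2::facet_wrap(~panel, ncol = 1) +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::labs(x = "internuclear position", y = "pair") +
    ggplot2::theme_minimal()
}

#' Plot a cell network
#'
#' Delaunay edges over nuclear centroids, in image coordinates (row axis
#' reversed so the origin sits top-left, matching the pixel convention).
#'
#' @param object a `cell_network`.
#' @param edge_cutoff optional cutoff; longer edges are drawn dashed.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cell_network <- function(object, edge_cutoff = NULL, ...) {
  nodes <- object$nodes
  edges <- dplyr::mutate(
    object$edges,
    row_i = nodes$row[.data$i], col_i = nodes$col[.data$i],
    row_j = nodes$row[.data$j], col_j = nodes$col[.data$j],
    kept = if (is.null(edge_cutoff)) TRUE else .data$length <= edge_cutoff
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$col_i, y = .data$row_i, xend = .data$col_j,
                   yend = .data$row_j, linetype = !.data$kept),
      color = "grey40", show.legend = FALSE
    ) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(.data$col, .data$row), size = 1.5) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "col (px)", y = "row (px)") +
    ggplot2::theme_minimal()
}

#' Plot aggregate outlines
#'
#' Traced boundary of each segmented aggregate, mirroring the outline scheme
#' used to present aggregation phenotypes.
#'
#' @param object an `aggregate_set` (or [segment_objects()] tibble with a
#'   `boundary` list-column).
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.aggregate_set <- function(object, ...) {
  df <- purrr::map_dfr(seq_len(nrow(object)), function(k) {
    b <- object$boundary[[k]]
    tibble::tibble(label = object$label[k], row = b[, 1], col = b[, 2])
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   group = .data$label)) +
    ggplot2::geom_path() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "col (px)", y = "row (px)") +
    ggplot2::theme_minimal()
}
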