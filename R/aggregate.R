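#' Segment cell aggregates from an assay image
#'
#' Delegates to [segment_objects()] with aggregate-assay defaults: a larger
#' minimum area (50 px^2 by default) excludes scattered single cells from the
#' aggregate count. Aggregates are assumed bright-on-dark; set
#' `invert = TRUE` for dark-on-bright micrographs.
#'
#' @param image single-channel matrix.
#' @param params a [segmentation_params()] list. Assay defaults:
#'   `min_area = 50` and no pre-smoothing — aggregates are large
#'   high-contrast objects, and skipping the mean filter keeps the measured
#'   area equal to the foreground pixel count without edge blurring.
#' @param invert logical; invert intensities before thresholding.
#' @return An `aggregate_set`: the [segment_objects()] tibble with an
#'   `n_below_min_area` attribute (objects filtered as single cells).
#' @export
segment_aggregates <- function(image,
                               params = segmentation_params(
                                 smoothing_radius = 0, min_area = 50),
                               invert = FALSE) {
  if (invert) image <- max(image) - image
  all_params <- params
  all_params$min_area <- 1
  all_obj <- segment_objects(image, all_params)
  keep <- all_obj$area >= params$min_area
  out <- all_obj[keep, ]
  out$label <- seq_len(nrow(out))
  attr(out, "n_below_min_area") <- sum(!keep)
  class(out) <- c("aggregate_set", class(out))
  out
}

#' Summarize an aggregate set
#'
#' @param set an `aggregate_set` (or any [segment_objects()] tibble).
#' @param include_singles logical; also report the count of sub-threshold
#'   objects (scattered single cells) recorded by [segment_aggregates()].
#' @return A one-row tibble: `n_aggregates`, `mean_area`, `median_area`,
#'   `total_area`, `n_single_cells`. An empty set yields zero counts and
#'   `NaN` means.
#' @export
assay_summary <- function(set, include_singles = TRUE) {
  n_singles <- attr(set, "n_below_min_area")
  if (is.null(n_singles) || !include_singles) n_singles <- NA_integer_
  tibble::tibble(
    n_aggregates = nrow(set),
    mean_area = if (nrow(set)) mean(set$area) else NaN,
    median_area = if (nrow(set)) stats::median(set$area) else NaN,
    total_area = sum(set$area),
    n_single_cells = n_singles
  )
}

#' Compare aggregation assays between two conditions
#'
#' Two-tailed unpaired pooled-variance Student's t on per-image mean
#' aggregate areas.
#'
#' @param group_a,group_b tibbles of [assay_summary()] rows (one per image).
#' @return A [comparison result][new_comparison_result].
#' @export
compare_assays <- function(group_a, group_b) {
  if (!is.data.frame(group_a)) group_a <- dplyr::bind_rows(group_a)
  if (!is.data.frame(group_b)) group_b <- dplyr::bind_rows(group_b)
  if (nrow(group_a) < 2 || nrow(group_b) < 2) {
    stop("each group needs >= 2 assay summaries", call. = FALSE)
  }
  res <- student_t(group_a$mean_area, group_b$mean_area)
  res$test <- "unpaired Student's t (pooled) on per-image mean aggregate area"
  res
}
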