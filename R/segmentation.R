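#' Segmentation parameters
#'
#' @param smoothing_radius radius (pixels, >= 0) of the mean-filter denoising
#'   window applied before thresholding; `0` disables smoothing.
#' @param min_area minimum object area in pixels^2 (objects below are
#'   discarded).
#' @param connectivity foreground pixel connectivity, `4` or `8` (default 8,
#'   matching the Moore neighborhood used for boundary tracing).
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(smoothing_radius = 1, min_area = 5,
                                connectivity = 8) {
  stopifnot(smoothing_radius >= 0, min_area >= 1, connectivity %in% c(4, 8))
  structure(list(smoothing_radius = smoothing_radius, min_area = min_area,
                 connectivity = connectivity),
            class = "segmentation_params")
}

#' Otsu threshold from an intensity histogram
#'
#' Exhaustively evaluates the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` at every candidate threshold (each bin value) and
#' returns the bin value maximizing it; pixels strictly above the returned
#' threshold are foreground. Ties are broken toward the smallest qualifying
#' threshold so the result is deterministic.
#'
#' @param counts nonnegative histogram counts per intensity bin.
#' @param values intensity value of each bin (defaults to `0:(K-1)`); must be
#'   strictly increasing.
#' @return The threshold intensity (one of `values`).
#' @examples
#' h <- numeric(256); h[11] <- 100; h[201] <- 100
#' otsu_threshold(h)   # separates the two spikes
#' @export
otsu_threshold <- function(counts, values = seq_along(counts) - 1) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == length(values), all(counts >= 0),
            all(diff(values) > 0))
  if (sum(counts > 0) < 2) {
    stop("flat image: histogram has fewer than two occupied bins",
         call. = FALSE)
  }
  total <- sum(counts)
  w0 <- cumsum(counts) / total
  m <- cumsum(counts * values)
  mu_t <- m[length(m)] / total
  mu0 <- ifelse(w0 > 0, m / total / w0, 0)
  w1 <- 1 - w0
  mu1 <- ifelse(w1 > 0, (mu_t - w0 * mu0) / w1, 0)
  sigma_b <- w0 * w1 * (mu0 - mu1)^2
  sigma_b <- sigma_b[-length(sigma_b)]        # threshold at last bin is void
  values[which.max(sigma_b)]                  # which.max: first max = smallest
}

#' Mean (box) filter
#'
#' Uniform smoothing over a `(2r+1) x (2r+1)` window via summed-area tables;
#' windows are clamped at the image border and normalized by the number of
#' in-image pixels, so the filter is average-preserving at the edges.
#'
#' @param image numeric matrix.
#' @param radius window radius in pixels; `0` returns the input unchanged.
#' @return Smoothed matrix of the same dimensions.
#' @export
mean_filter <- function(image, radius = 1) {
  stopifnot(is.matrix(image), radius >= 0)
  r <- as.integer(radius)
  if (r == 0) return(image)
  nr <- nrow(image); nc <- ncol(image)
  # summed-area table with a zero border row/col
  sat <- matrix(0, nr + 1, nc + 1)
  sat[-1, -1] <- apply(apply(image, 2, cumsum), 1, cumsum) |> t()
  ri <- seq_len(nr); ci <- seq_len(nc)
  r0 <- pmax(ri - r, 1); r1 <- pmin(ri + r, nr)
  c0 <- pmax(ci - r, 1); c1 <- pmin(ci + r, nc)
  sums <- sat[r1 + 1, c1 + 1, drop = FALSE] - sat[r0, c1 + 1, drop = FALSE] -
    sat[r1 + 1, c0, drop = FALSE] + sat[r0, c0, drop = FALSE]
  counts <- outer(r1 - r0 + 1, c1 - c0 + 1)
  sums / counts
}

# Label connected foreground components. Returns an integer matrix (0 =
# background); labels are assigned in raster-scan (row-major) order of each
# component's first pixel.
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)                     # column-major linear indices
  lab <- matrix(0L, nr, nc)
  if (length(fg) == 0) return(lab)
  id <- integer(nr * nc)
  id[fg] <- seq_along(fg)
  offsets <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offsets <- c(offsets, list(c(1L, 1L), c(-1L, 1L)))
  edges <- integer(0)
  row_of <- ((fg - 1L) %% nr) + 1L
  col_of <- ((fg - 1L) %/% nr) + 1L
  for (off in offsets) {
    nr2 <- row_of + off[1]; nc2 <- col_of + off[2]
    ok <- nr2 >= 1 & nr2 <= nr & nc2 >= 1 & nc2 <= nc
    nb <- (nc2[ok] - 1L) * nr + nr2[ok]
    hit <- id[nb] > 0L
    if (any(hit)) {
      edges <- c(edges, rbind(id[fg[ok]][hit], id[nb][hit]))
    }
  }
  g <- igraph::make_graph(edges, n = length(fg), directed = FALSE)
  comp <- igraph::components(g)$membership
  # order components by first pixel in row-major scan
  rm_order <- (row_of - 1L) * nc + col_of
  first_px <- tapply(rm_order, comp, min)
  relabel <- integer(length(first_px))
  relabel[order(first_px)] <- seq_along(first_px)
  lab[fg] <- relabel[comp]
  lab
}

#' Trace an object boundary (Moore-Neighbor with Jacob's stopping)
#'
#' Clockwise Moore-neighborhood contour following starting at the object's
#' leftmost-uppermost pixel. The walk terminates when the start pixel is
#' re-entered from the same direction as it was first entered (Jacob's
#' stopping criterion), which prevents premature termination on contours that
#' pass through the start pixel more than once.
#'
#' @param mask logical matrix (foreground = `TRUE`).
#' @param start `(row, col)` of a foreground boundary pixel in 0-based
#'   coordinates; by convention the first foreground pixel in row-major scan
#'   order.
#' @return An ordered matrix of 0-based `(row, col)` boundary pixels; the
#'   contour is closed (the last pixel is Moore-adjacent to the first).
#' @export
trace_boundary <- function(mask, start) {
  stopifnot(is.matrix(mask), length(start) == 2)
  s <- as.integer(start) + 1L           # to 1-based
  nr <- nrow(mask); nc <- ncol(mask)
  is_fg <- function(p) {
    p[1] >= 1 && p[1] <= nr && p[2] >= 1 && p[2] <= nc && isTRUE(mask[p[1], p[2]])
  }
  if (!is_fg(s)) stop("start pixel is not foreground", call. = FALSE)
  # Moore neighborhood in clockwise order (rows grow downward)
  moore <- matrix(c(0, -1, -1, -1, -1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1),
                  ncol = 2, byrow = TRUE)
  neighbor_dir <- function(from, to) {
    d <- to - from
    which(moore[, 1] == d[1] & moore[, 2] == d[2])
  }
  b0 <- s + c(0L, -1L)                  # raster scan enters from the west
  boundary <- list(s)
  p <- s
  b <- b0
  max_iter <- 8L * sum(mask) + 8L
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) stop("boundary tracing failed to close", call. = FALSE)
    start_dir <- neighbor_dir(p, b)
    found <- FALSE
    prev <- b
    for (k in seq_len(8)) {
      dir <- ((start_dir - 1L + k) %% 8L) + 1L
      cand <- p + moore[dir, ]
      if (is_fg(cand)) {
        if (all(cand == s) && all(prev == b0)) {
          # Jacob's criterion: start re-entered from the original direction
          out <- do.call(rbind, boundary) - 1L
          dimnames(out) <- list(NULL, c("row", "col"))
          return(out)
        }
        boundary[[length(boundary) + 1L]] <- cand
        b <- prev
        p <- cand
        found <- TRUE
        break
      }
      prev <- cand
    }
    if (!found) {                       # isolated pixel
      out <- matrix(s - 1L, ncol = 2)
      dimnames(out) <- list(NULL, c("row", "col"))
      return(out)
    }
  }
}

#' Segment labeled objects from a single-channel image
#'
#' Pipeline: mean-filter denoising, Otsu binarization (foreground strictly
#' above threshold), connected-component labeling at the configured
#' connectivity, removal of objects below `min_area`, then per-object boundary
#' tracing and centroid computation. Labels follow the raster-scan order of
#' each object's first pixel. All coordinates are 0-based `(row, col)` with
#' pixel centers at integer positions.
#'
#' @param image numeric matrix (single-channel intensities).
#' @param params a [segmentation_params()] list.
#' @return A tibble with one row per object: `label`, `area`, `centroid_row`,
#'   `centroid_col`, and list-columns `pixels` and `boundary` (matrices of
#'   0-based `(row, col)`). A flat image yields a zero-row tibble with a
#'   warning.
#' @examples
#' img <- matrix(0, 32, 32); img[8:12, 8:12] <- 1; img[20:24, 20:26] <- 1
#' segment_objects(img, segmentation_params(smoothing_radius = 0, min_area = 4))
#' @export
segment_objects <- function(image, params = segmentation_params()) {
  stopifnot(is.matrix(image))
  empty <- tibble::tibble(label = integer(), area = integer(),
                          centroid_row = numeric(), centroid_col = numeric(),
                          pixels = list(), boundary = list())
  smoothed <- mean_filter(image, params$smoothing_radius)
  rng <- range(smoothed)
  if (diff(rng) == 0) {
    warning("flat image: no objects segmented", call. = FALSE)
    return(empty)
  }
  breaks <- seq(rng[1], rng[2], length.out = 257)
  mids <- (breaks[-1] + breaks[-257]) / 2
  counts <- tabulate(
    pmin(pmax(findInterval(smoothed, breaks, all.inside = TRUE), 1L), 256L),
    nbins = 256L
  )
  thr <- otsu_threshold(counts, mids)
  mask <- smoothed > thr
  lab <- label_components(mask, params$connectivity)
  n_obj <- max(lab)
  if (n_obj == 0) return(empty)
  nr <- nrow(image)
  rows <- purrr::map(seq_len(n_obj), function(l) {
    idx <- which(lab == l)
    if (length(idx) < params$min_area) return(NULL)
    pr <- ((idx - 1L) %% nr)            # 0-based rows
    pc <- ((idx - 1L) %/% nr)           # 0-based cols
    ord <- order(pr, pc)                # row-major raster order
    px <- cbind(row = pr[ord], col = pc[ord])
    bnd <- trace_boundary(lab == l, px[1, ])
    tibble::tibble(area = length(idx),
                   centroid_row = mean(pr), centroid_col = mean(pc),
                   pixels = list(px), boundary = list(bnd))
  })
  rows <- purrr::compact(rows)
  if (length(rows) == 0) return(empty)
  out <- dplyr::bind_rows(rows)
  out$label <- seq_len(nrow(out))
  dplyr::relocate(out, "label")
}

#' Count invasive nuclei on a filter image
#'
#' Number of segmented objects in a DAPI image of the underside of an
#' invasion-assay filter. Touching nuclei merged into one connected component
#' count once (no declumping is performed; see the vignette).
#'
#' @inheritParams segment_objects
#' @return Integer count.
#' @export
count_invasive_nuclei <- function(image, params = segmentation_params()) {
  nrow(segment_objects(image, params))
}

#' Read a single-channel image from TIFF or PNG
#'
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @param channel channel index used when the file has multiple channels.
#' @return Numeric matrix of intensities.
#' @export
read_image <- function(path, channel = 1) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  if (length(dim(img)) == 3) img <- img[, , channel]
  img
}
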