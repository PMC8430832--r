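#' Build a Delaunay cell network over nuclear centroids
#'
#' Connects nuclear geometric centers by Delaunay triangulation and records
#' the resulting edges (internuclear distances) and triangles ("triplets",
#' areas by the shoelace formula). Cocircular degeneracies (e.g. four points
#' on a square) are resolved deterministically: adjacent triangle pairs whose
#' four vertices are cocircular are flipped toward the diagonal whose
#' endpoint coordinates sort lexicographically smallest, so the triangulation
#' is platform-independent.
#'
#' @param centroids a two-column matrix or data frame of `(row, col)`
#'   coordinates (e.g. `centroid_row` / `centroid_col` from
#'   [segment_objects()]), or a tibble containing those columns.
#' @return A `cell_network`: list with `nodes` (tibble `row`, `col`), `edges`
#'   (tibble `i`, `j`, `length`), `triangles` (tibble `i`, `j`, `k`, `area`).
#'   Node indices are 1-based row numbers into `nodes`.
#' @examples
#' build_network(cbind(row = c(0, 1, 0), col = c(0, 0, 1)))
#' @export
build_network <- function(centroids) {
  pts <- as_centroid_matrix(centroids)
  n <- nrow(pts)
  if (n < 3) stop("degenerate geometry: need at least 3 centroids", call. = FALSE)
  # collinearity check via the largest triangle cross product
  span <- max(abs(sweep(pts, 2, pts[1, ])))
  if (span == 0 || all_collinear(pts)) {
    stop("degenerate geometry: centroids are collinear", call. = FALSE)
  }
  dd <- deldir::deldir(x = pts[, 2], y = pts[, 1], suppressMsge = TRUE)
  tl <- deldir::triang.list(dd)
  tris <- do.call(rbind, lapply(tl, function(t) sort(t$ptNum)))
  tris <- canonicalize_cocircular(tris, pts)
  areas <- apply(tris, 1, function(t) triangle_area(pts[t, , drop = FALSE]))
  keep <- areas > 0
  tris <- tris[keep, , drop = FALSE]
  areas <- areas[keep]
  edges <- unique(rbind(tris[, c(1, 2), drop = FALSE],
                        tris[, c(1, 3), drop = FALSE],
                        tris[, c(2, 3), drop = FALSE]))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  lens <- sqrt(rowSums((pts[edges[, 1], , drop = FALSE] -
                          pts[edges[, 2], , drop = FALSE])^2))
  ord <- order(tris[, 1], tris[, 2], tris[, 3])
  structure(
    list(
      nodes = tibble::tibble(row = pts[, 1], col = pts[, 2]),
      edges = tibble::tibble(i = edges[, 1], j = edges[, 2], length = lens),
      triangles = tibble::tibble(i = tris[ord, 1], j = tris[ord, 2],
                                 k = tris[ord, 3], area = areas[ord])
    ),
    class = "cell_network"
  )
}

as_centroid_matrix <- function(centroids) {
  if (is.data.frame(centroids)) {
    if (all(c("centroid_row", "centroid_col") %in% names(centroids))) {
      pts <- cbind(centroids$centroid_row, centroids$centroid_col)
    } else if (all(c("row", "col") %in% names(centroids))) {
      pts <- cbind(centroids$row, centroids$col)
    } else {
      pts <- as.matrix(centroids[, 1:2])
    }
  } else {
    pts <- as.matrix(centroids)
  }
  storage.mode(pts) <- "double"
  colnames(pts) <- c("row", "col")
  pts
}

all_collinear <- function(pts) {
  if (nrow(pts) < 3) return(TRUE)
  v <- sweep(pts[-1, , drop = FALSE], 2, pts[1, ])
  cross <- v[, 1] * v[1, 2] - v[, 2] * v[1, 1]
  # compare against the first non-degenerate direction
  base <- which(rowSums(v^2) > 0)[1]
  if (is.na(base)) return(TRUE)
  cross <- v[, 1] * v[base, 2] - v[, 2] * v[base, 1]
  all(abs(cross) < 1e-9 * max(1, max(abs(pts))))
}

triangle_area <- function(p) {
  abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
        (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])) / 2
}

# Signed in-circle determinant: > 0 when d lies inside the circumcircle of
# (a, b, c) taken counterclockwise.
incircle_det <- function(a, b, c, d) {
  orient <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  if (orient < 0) { tmp <- b; b <- c; c <- tmp }
  m <- rbind(
    c(a[1] - d[1], a[2] - d[2], (a[1] - d[1])^2 + (a[2] - d[2])^2),
    c(b[1] - d[1], b[2] - d[2], (b[1] - d[1])^2 + (b[2] - d[2])^2),
    c(c[1] - d[1], c[2] - d[2], (c[1] - d[1])^2 + (c[2] - d[2])^2)
  )
  det(m)
}

edge_key <- function(pts, e) {
  p <- pts[e, , drop = FALSE]
  p <- p[order(p[, 1], p[, 2]), , drop = FALSE]
  c(p[1, ], p[2, ])
}

key_less <- function(a, b) {
  d <- a - b
  nz <- which(abs(d) > 1e-12)
  length(nz) > 0 && d[nz[1]] < 0
}

# Flip cocircular adjacent triangle pairs toward the lexicographically
# smallest diagonal (by sorted endpoint coordinates). Iterates to a fixed
# point; each flip strictly decreases the multiset of diagonal keys, so the
# pass terminates.
canonicalize_cocircular <- function(tris, pts) {
  for (pass in seq_len(max(50L, 5L * nrow(tris)))) {
    changed <- FALSE
    # map each edge to the triangles containing it
    ekeys <- apply(rbind(tris[, c(1, 2), drop = FALSE],
                         tris[, c(1, 3), drop = FALSE],
                         tris[, c(2, 3), drop = FALSE]), 1,
                   paste, collapse = "-")
    tri_of <- rep(seq_len(nrow(tris)), 3)
    for (key in unique(ekeys[duplicated(ekeys)])) {
      pair <- tri_of[ekeys == key]
      if (length(pair) != 2) next
      t1 <- tris[pair[1], ]; t2 <- tris[pair[2], ]
      shared <- intersect(t1, t2)
      opp <- c(setdiff(t1, shared), setdiff(t2, shared))
      if (length(shared) != 2 || length(opp) != 2) next
      quad <- pts[c(shared, opp), , drop = FALSE]
      # the in-circle determinant scales as (quad diameter)^4; compare
      # against that scale so exact cocircularity (det = 0 up to rounding)
      # is detected at any field size without misfiring on generic quads
      diam <- max(dist(quad))
      det_val <- incircle_det(pts[shared[1], ], pts[shared[2], ],
                              pts[opp[1], ], pts[opp[2], ])
      if (abs(det_val) > 1e-9 * max(1, diam)^4) next   # not cocircular
      # candidate diagonals: current (shared) vs flipped (opp); flip only if
      # the quad is convex (the alternative diagonal must cross the shared one)
      if (!segments_cross(pts[shared[1], ], pts[shared[2], ],
                          pts[opp[1], ], pts[opp[2], ])) next
      if (key_less(edge_key(pts, opp), edge_key(pts, shared))) {
        tris[pair[1], ] <- sort(c(opp, shared[1]))
        tris[pair[2], ] <- sort(c(opp, shared[2]))
        changed <- TRUE
        break                           # edge map is stale; rebuild
      }
    }
    if (!changed) return(tris)
  }
  tris
}

segments_cross <- function(a, b, c, d) {
  side <- function(p, q, r) {
    sign((q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1]))
  }
  side(a, b, c) * side(a, b, d) < 0 && side(c, d, a) * side(c, d, b) < 0
}

#' Summarize a cell network
#'
#' Counts and central tendencies of triangle areas and edge lengths, with an
#' optional edge cutoff removing border artifacts: edges longer than the
#' cutoff — and every triangle containing such an edge — are excluded before
#' summarizing. Long sliver triangles along the convex hull otherwise
#' dominate the mean in sparse fields.
#'
#' @param network a `cell_network` from [build_network()].
#' @param edge_cutoff numeric cutoff in pixels, or `NULL` for no filtering.
#'   The conventional default for border control is `1.5 *` median edge
#'   length, available as `edge_cutoff = "auto"`.
#' @return A one-row tibble: `n_nodes`, `n_edges`, `n_triangles`,
#'   `mean_triangle_area`, `median_triangle_area`, `mean_edge_length`,
#'   `median_edge_length`, `edge_cutoff` (NA when unfiltered). When the
#'   cutoff removes everything, counts are zero and the means are `NaN`.
#' @export
network_summary <- function(network, edge_cutoff = NULL) {
  stopifnot(inherits(network, "cell_network"))
  edges <- network$edges
  tris <- network$triangles
  cutoff <- NA_real_
  if (!is.null(edge_cutoff)) {
    cutoff <- if (identical(edge_cutoff, "auto")) {
      1.5 * stats::median(edges$length)
    } else {
      as.numeric(edge_cutoff)
    }
    long <- edges[edges$length > cutoff, c("i", "j")]
    edges <- edges[edges$length <= cutoff, ]
    if (nrow(long) > 0) {
      bad <- purrr::map_lgl(seq_len(nrow(tris)), function(r) {
        tri <- c(tris$i[r], tris$j[r], tris$k[r])
        any(long$i %in% tri & long$j %in% tri)
      })
      tris <- tris[!bad, ]
    }
  }
  tibble::tibble(
    n_nodes = nrow(network$nodes),
    n_edges = nrow(edges),
    n_triangles = nrow(tris),
    mean_triangle_area = if (nrow(tris)) mean(tris$area) else NaN,
    median_triangle_area = if (nrow(tris)) stats::median(tris$area) else NaN,
    mean_edge_length = if (nrow(edges)) mean(edges$length) else NaN,
    median_edge_length = if (nrow(edges)) stats::median(edges$length) else NaN,
    edge_cutoff = cutoff
  )
}

#' Compare network features between two conditions
#'
#' Two-tailed unpaired pooled-variance Student's t on per-image mean features.
#' The observation unit is the image (one network summary per image), not the
#' pooled triangles or edges, to avoid pseudo-replication.
#'
#' @param group_a,group_b tibbles of [network_summary()] rows (one per image).
#' @param feature `"triangle_area"` or `"edge_length"`.
#' @return A [comparison result][new_comparison_result].
#' @export
compare_networks <- function(group_a, group_b,
                             feature = c("triangle_area", "edge_length")) {
  feature <- match.arg(feature)
  col <- paste0("mean_", feature)
  if (!is.data.frame(group_a)) group_a <- dplyr::bind_rows(group_a)
  if (!is.data.frame(group_b)) group_b <- dplyr::bind_rows(group_b)
  if (nrow(group_a) < 2 || nrow(group_b) < 2) {
    stop("each group needs >= 2 network summaries", call. = FALSE)
  }
  res <- student_t(group_a[[col]], group_b[[col]])
  res$test <- paste0("unpaired Student's t (pooled) on per-image mean ", feature)
  res
}

#' Tidy a cell network
#'
#' @param x a `cell_network`.
#' @param what `"edges"`, `"triangles"` or `"nodes"`.
#' @param ... unused.
#' @return The requested component as a tibble.
#' @exportS3Method generics::tidy
tidy.cell_network <- function(x, what = c("edges", "triangles", "nodes"), ...) {
  what <- match.arg(what)
  x[[what]]
}

#' @export
print.cell_network <- function(x, ...) {
  cat(sprintf("cell network: %d nodes, %d edges, %d triangles\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$triangles)))
  invisible(x)
}
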