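# Independent brute-force oracles used across tests. These deliberately
# re-derive each quantity from its definition, without reusing package code
# paths.

# Otsu: evaluate the between-class variance at every threshold by explicit
# class splits.
otsu_brute_force <- function(counts, values = seq_along(counts) - 1) {
  total <- sum(counts)
  best_t <- NA_real_
  best_v <- -Inf
  for (k in seq_len(length(values) - 1)) {
    lo <- 1:k
    hi <- (k + 1):length(values)
    w0 <- sum(counts[lo]) / total
    w1 <- sum(counts[hi]) / total
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[lo] * values[lo]) / sum(counts[lo])
    mu1 <- sum(counts[hi] * values[hi]) / sum(counts[hi])
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best_v + 1e-12) {
      best_v <- v
      best_t <- values[k]
    }
  }
  best_t
}

# Wilcoxon signed-rank: exact two-tailed p by enumerating all 2^n sign
# assignments of the ranked absolute differences.
wilcoxon_brute_force <- function(differences) {
  d <- differences[differences != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Circumcircle of a triangle: center and radius from the perpendicular
# bisector intersection.
circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(center = c(ux, uy), radius = sqrt((ax - ux)^2 + (ay - uy)^2))
}

# Empty-circumcircle check straight from the Delaunay definition.
delaunay_violations <- function(network) {
  pts <- as.matrix(network$nodes)
  tris <- network$triangles
  bad <- 0
  for (t in seq_len(nrow(tris))) {
    cc <- circumcircle(pts[tris$i[t], ], pts[tris$j[t], ], pts[tris$k[t], ])
    others <- setdiff(seq_len(nrow(pts)), c(tris$i[t], tris$j[t], tris$k[t]))
    d <- sqrt((pts[others, 1] - cc$center[1])^2 +
                (pts[others, 2] - cc$center[2])^2)
    bad <- bad + sum(d < cc$radius * (1 - 1e-9))
  }
  bad
}

# Convex hull area by the shoelace formula over chull() vertices.
convex_hull_area <- function(pts) {
  h <- grDevices::chull(pts[, 2], pts[, 1])
  x <- pts[h, 2]; y <- pts[h, 1]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

default_monolayer <- function() {
  layout_params(n_cells = 25, packing = "hexagonal", mean_spacing = 20,
                jitter_sd = 1)
}

# Segment -> network -> compensated profile map for one synthetic scene.
scene_profile_map <- function(scene) {
  obj <- segment_objects(scene$nuclei_image, segmentation_params())
  net <- build_network(obj)
  compensate_profiles(extract_profiles(scene$cadherin_image, net))
}
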