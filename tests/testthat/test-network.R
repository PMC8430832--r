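test_that("a unit right triangle triangulates to one triangle", {
  net <- build_network(cbind(row = c(0, 1, 0), col = c(0, 0, 1)))
  expect_equal(nrow(net$triangles), 1)
  expect_equal(net$triangles$area, 0.5)
  expect_equal(sort(net$edges$length), c(1, 1, sqrt(2)))
})

test_that("cocircular square picks the lexicographically smallest diagonal", {
  net <- build_network(cbind(row = c(0, 0, 1, 1), col = c(0, 1, 0, 1)))
  expect_equal(nrow(net$triangles), 2)
  expect_equal(nrow(net$edges), 5)
  diag_edges <- net$edges[abs(net$edges$length - sqrt(2)) < 1e-9, ]
  expect_equal(nrow(diag_edges), 1)
  # the chosen diagonal joins (0,0) and (1,1)
  ends <- as.matrix(net$nodes)[c(diag_edges$i, diag_edges$j), ]
  expect_equal(sort(ends[, 1]), c(0, 1))
  expect_equal(unname(ends[order(ends[, 1]), 2]), c(0, 1))
})

test_that("degenerate geometry errors", {
  expect_error(build_network(cbind(c(0, 1), c(0, 1))), "at least 3")
  expect_error(build_network(cbind(c(0, 1, 2), c(0, 1, 2))), "collinear")
})

test_that("a 3x3 unit grid yields 8 half-pixel triangles", {
  g <- as.matrix(expand.grid(row = 0:2, col = 0:2))
  net <- build_network(g)
  expect_equal(nrow(net$triangles), 8)
  expect_equal(net$triangles$area, rep(0.5, 8))
  # mean edge length equals the brute-force mean over the edge set
  pts <- as.matrix(net$nodes)
  lens <- sqrt(rowSums((pts[net$edges$i, ] - pts[net$edges$j, ])^2))
  expect_equal(network_summary(net)$mean_edge_length, mean(lens))
})

test_that("triangle areas tile the convex hull", {
  set.seed(21)
  for (k in 1:25) {
    n <- sample(6:40, 1)
    pts <- cbind(row = runif(n, 0, 100), col = runif(n, 0, 100))
    net <- build_network(pts)
    expect_equal(sum(net$triangles$area), convex_hull_area(pts),
                 tolerance = 1e-9)
    s <- network_summary(net)
    expect_equal(s$mean_triangle_area,
                 sum(net$triangles$area) / s$n_triangles, tolerance = 1e-12)
  }
})

test_that("every triangle satisfies the empty-circumcircle property", {
  set.seed(33)
  for (k in 1:10) {
    n <- sample(10:50, 1)
    pts <- cbind(row = runif(n, 0, 200), col = runif(n, 0, 200))
    expect_equal(delaunay_violations(build_network(pts)), 0,
                 label = paste("point set", k))
  }
})

test_that("coordinate scaling scales lengths and areas exactly", {
  set.seed(4)
  pts <- cbind(row = runif(12, 0, 50), col = runif(12, 0, 50))
  net1 <- build_network(pts)
  net2 <- build_network(pts * 2)
  expect_equal(net2$edges$length, net1$edges$length * 2, tolerance = 1e-12)
  expect_equal(net2$triangles$area, net1$triangles$area * 4,
               tolerance = 1e-12)
})

test_that("edge cutoff removes long edges and their triangles", {
  net <- build_network(cbind(row = c(0, 1, 0), col = c(0, 0, 1)))
  s <- network_summary(net, edge_cutoff = 1.2)
  expect_equal(s$n_edges, 2)
  expect_equal(s$n_triangles, 0)
  expect_true(is.nan(s$mean_triangle_area))
  # unfiltered summary unchanged
  expect_equal(network_summary(net)$n_triangles, 1)
})

test_that("mean triangle area grows with planted spacing", {
  means <- sapply(c(15, 25, 40), function(sp) {
    lay <- layout_params(n_cells = 16, packing = "hexagonal",
                         mean_spacing = sp, jitter_sd = 1)
    sc <- generate_monolayer(lay, phenotype_diffuse(expression_level = 0),
                             noise_off(), seed = 2)
    net <- build_network(sc$truth$centers)
    network_summary(net, edge_cutoff = "auto")$mean_triangle_area
  })
  expect_true(all(diff(means) > 0))
})

test_that("network comparison uses per-image means and the pooled t", {
  a <- dplyr::bind_rows(lapply(c(1, 2, 3), function(m)
    tibble::tibble(mean_triangle_area = m, mean_edge_length = m)))
  b <- dplyr::bind_rows(lapply(c(4, 5, 6), function(m)
    tibble::tibble(mean_triangle_area = m, mean_edge_length = m)))
  res <- compare_networks(a, b, "triangle_area")
  expect_equal(round(res$statistic, 3), -3.674)
  expect_equal(res$df, 4)

  same <- compare_networks(a, a, "edge_length")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(compare_networks(a[1, ], b, "triangle_area"), ">= 2")
})
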