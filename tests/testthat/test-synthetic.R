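test_that("scene generation is bit-exact under a fixed seed", {
  lay <- default_monolayer()
  s1 <- generate_monolayer(lay, phenotype_membranous(), noise_params(), seed = 5)
  s2 <- generate_monolayer(lay, phenotype_membranous(), noise_params(), seed = 5)
  expect_identical(s1$nuclei_image, s2$nuclei_image)
  expect_identical(s1$cadherin_image, s2$cadherin_image)
  expect_identical(s1$truth$centers, s2$truth$centers)
  s3 <- generate_monolayer(lay, phenotype_membranous(), noise_params(), seed = 6)
  expect_false(identical(s1$nuclei_image, s3$nuclei_image))
})

test_that("scene generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(3)
  set.seed(123)
  invisible(generate_monolayer(default_monolayer(), phenotype_diffuse(),
                               noise_off(), seed = 9))
  expect_identical(runif(3), before)
})

test_that("empty scenes equal the background everywhere", {
  lay <- layout_params(n_cells = 0, field_size = c(32, 32))
  sc <- generate_monolayer(lay, phenotype_membranous(),
                           noise_params(background = 10, gaussian_sd = 0),
                           seed = 1)
  expect_true(all(sc$nuclei_image == 10))
  expect_true(all(sc$cadherin_image == 10))
  expect_equal(nrow(sc$truth$centers), 0)
})

test_that("cadherin intensity is conserved per cell with noise off", {
  for (ph in list(phenotype_membranous(), phenotype_perinuclear(),
                  phenotype_params(0.3, 0.3, 0.4))) {
    sc <- generate_monolayer(default_monolayer(), ph, noise_off(), seed = 3)
    n <- nrow(sc$truth$centers)
    expect_equal(sum(sc$cadherin_image), n * ph$expression_level,
                 tolerance = 1e-6)
    expect_equal(sc$truth$cell_totals, rep(ph$expression_level, n))
  }
})

test_that("planted interfaces lie on the open segment between centers", {
  sc <- generate_monolayer(default_monolayer(), phenotype_membranous(),
                           noise_off(), seed = 4)
  ifc <- sc$truth$pair_interfaces
  ctr <- sc$truth$centers
  expect_gt(nrow(ifc), 0)
  for (k in seq_len(nrow(ifc))) {
    a <- ctr[ifc$i[k], ]; b <- ctr[ifc$j[k], ]
    p <- c(ifc$interface_row[k], ifc$interface_col[k])
    t_est <- sum((p - a) * (b - a)) / sum((b - a)^2)
    expect_gt(t_est, 0); expect_lt(t_est, 1)
    # on the segment: projection residual is zero
    expect_lt(sqrt(sum((a + t_est * (b - a) - p)^2)), 1e-9)
  }
})

test_that("membrane-only scenes place the cadherin maximum at the interface", {
  sc <- generate_monolayer(default_monolayer(), phenotype_params(1, 0, 0),
                           noise_off(), seed = 12)
  ctr <- sc$truth$centers
  ifc <- sc$truth$pair_interfaces
  checked <- 0
  for (k in seq_len(nrow(ifc))) {
    a <- ctr[ifc$i[k], ]; b <- ctr[ifc$j[k], ]
    prof <- extract_profile(sc$cadherin_image, a, b)$profile
    if (max(prof) == 0) next
    checked <- checked + 1
    expect_lte(abs(which.max(prof) - 50.5), 2.5,
               label = sprintf("pair %d-%d", ifc$i[k], ifc$j[k]))
  }
  expect_gt(checked, 20)
})

test_that("perinuclear ring distance scales with the planted offset", {
  spots <- lapply(c(0.15, 0.25, 0.35), function(d) {
    sc <- generate_monolayer(default_monolayer(),
                             phenotype_perinuclear(perinuclear_offset = d),
                             noise_off(), seed = 2)
    sc$truth$perinuclear_spots
  })
  m <- sapply(spots, function(s) mean(s$distance_from_center))
  expect_true(all(diff(m) > 0))
  expect_equal(m[3] / m[1], 0.35 / 0.15, tolerance = 1e-9)
})

test_that("hexagonal scenes are segmentable back to the planted centers", {
  lay <- layout_params(n_cells = 25, packing = "hexagonal", mean_spacing = 20,
                       jitter_sd = 1)
  sc <- generate_monolayer(lay, phenotype_membranous(), noise_off(), seed = 31)
  obj <- segment_objects(sc$nuclei_image, segmentation_params())
  expect_equal(nrow(obj), 25)
  ctr <- sc$truth$centers
  err <- sapply(seq_len(nrow(obj)), function(k) {
    min(sqrt((ctr[, 1] - obj$centroid_row[k])^2 +
               (ctr[, 2] - obj$centroid_col[k])^2))
  })
  expect_lt(max(err), 1)
})

test_that("infeasible layouts are rejected", {
  expect_error(generate_monolayer(
    layout_params(n_cells = 25, mean_spacing = 20, field_size = c(40, 40)),
    phenotype_membranous(), noise_off(), seed = 1), "layout infeasible")
  expect_error(layout_params(n_cells = 5, mean_spacing = 6,
                             nucleus_radius = 4))
  expect_error(phenotype_params(0.5, 0.2, 0.2), "sum to 1")
})

test_that("aggregation scenes plant exact rasterized disk areas", {
  one <- generate_aggregation_scene(1, c(10, 0), c(100, 100), seed = 1,
                                    noise = noise_off())
  ctr <- one$truth$centers[1, ]
  brute <- 0
  for (r in 0:99) for (c in 0:99) {
    if ((r - ctr[1])^2 + (c - ctr[2])^2 <= 100) brute <- brute + 1
  }
  expect_equal(one$truth$planted_areas, brute)
  expect_equal(sum(one$nuclei_image > 0), brute)

  two <- generate_aggregation_scene(2, c(12, 1), c(128, 128), seed = 2,
                                    noise = noise_off())
  expect_length(two$truth$planted_areas, 2)

  empty <- generate_aggregation_scene(0, c(10, 0), c(64, 64), seed = 1,
                                      noise = noise_off())
  expect_true(all(empty$nuclei_image == 0))
  expect_length(empty$truth$planted_areas, 0)

  expect_error(generate_aggregation_scene(50, c(30, 0), c(128, 128), seed = 1),
               "placement failed")
})

test_that("invasion filters plant the requested count and reproduce", {
  sc <- generate_invasion_filter(50, c(384, 384), seed = 5)
  expect_equal(sc$truth$planted_count, 50)
  expect_equal(nrow(sc$truth$centers), 50)
  sc2 <- generate_invasion_filter(50, c(384, 384), seed = 5)
  expect_identical(sc$nuclei_image, sc2$nuclei_image)

  empty <- generate_invasion_filter(0, c(64, 64), seed = 1,
                                    noise = noise_off())
  expect_true(all(empty$nuclei_image == 0))
  expect_equal(empty$truth$planted_count, 0)

  expect_error(generate_invasion_filter(200, c(100, 100), seed = 1),
               "density too high")
})

test_that("scenes round-trip through TIFF + JSON + CSV", {
  dir <- withr::local_tempdir()
  sc <- generate_monolayer(layout_params(n_cells = 9, mean_spacing = 18),
                           phenotype_membranous(), noise_params(), seed = 14)
  paths <- write_scene(sc, dir, "t")
  expect_true(all(file.exists(paths)))
  dapi <- read_scene_channel(paths["dapi"], paths["truth"], "dapi")
  # 16-bit quantization error bound
  expect_lt(max(abs(dapi - sc$nuclei_image)),
            diff(range(sc$nuclei_image)) / 65535 + 1e-9)
  ctr <- read_centers(paths["centers"])
  expect_equal(as.matrix(ctr), unname(sc$truth$centers), tolerance = 1e-6,
               ignore_attr = TRUE)
})
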