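test_that("contiguous pairs filter Delaunay edges by length", {
  g <- as.matrix(expand.grid(row = 0:2, col = 0:2))
  net <- build_network(g)
  pairs <- contiguous_pairs(net, cutoff = 1.2)
  expect_equal(nrow(pairs), 12)          # only axis-aligned unit edges
  expect_true(all(pairs$length == 1))
  expect_equal(nrow(contiguous_pairs(net, cutoff = 0)), 0)
})

test_that("profile extraction matches bilinear closed forms", {
  const <- matrix(3.7, 32, 32)
  p <- extract_profile(const, c(5, 5), c(20, 25))
  expect_equal(p$profile, rep(3.7, 100))

  ramp <- matrix(rep(0:31, each = 32), 32, 32)   # intensity = column index
  p2 <- extract_profile(ramp, c(10, 2), c(10, 29))
  expect_equal(p2$profile, seq(2, 29, length.out = 100), tolerance = 1e-9)
  expect_equal(p2$profile[1], 2, tolerance = 1e-9)
  expect_equal(p2$profile[100], 29, tolerance = 1e-9)

  expect_error(extract_profile(const, c(-1, 5), c(10, 10)), "out of bounds")
})

test_that("a ridge on the perpendicular bisector peaks at the midpoint", {
  img <- matrix(0, 41, 41)
  for (r in 0:40) img[r + 1, ] <- exp(-(0:40 - 20)^2 / 8) * 100
  p <- extract_profile(img, c(20, 4), c(20, 36))
  expect_lte(abs(which.max(p$profile) - 50.5), 1)
})

test_that("profile extraction reverses exactly under center swap", {
  set.seed(8)
  img <- matrix(runif(64 * 64, 0, 100), 64, 64)
  a <- c(10.3, 12.7); b <- c(50.2, 40.8)
  expect_equal(extract_profile(img, a, b)$profile,
               rev(extract_profile(img, b, a)$profile), tolerance = 1e-12)
})

test_that("compensation is the identity at interface 0.5", {
  set.seed(2)
  prof <- list(structure(list(profile = sin(seq(0, 3, length.out = 100)) + 2,
                              pair = c(1L, 2L), internuclear_distance = 20,
                              interface_position = 0.5,
                              centers = rbind(c(0, 0), c(0, 20))),
                         class = "pair_profile"))
  map <- profile_map(prof)
  comp <- compensate_profiles(map)
  expect_equal(comp$profiles, map$profiles, tolerance = 1e-9)
  expect_equal(nrow(comp$profiles), 1)
})

test_that("compensation moves an off-center ridge to the midpoint", {
  n <- 100
  ridge_at <- function(t0) exp(-((seq(0, 1, length.out = n) - t0) / 0.04)^2)
  prof <- structure(list(profile = ridge_at(0.4), pair = c(1L, 2L),
                         internuclear_distance = 30, interface_position = 0.4,
                         centers = rbind(c(0, 0), c(0, 30))),
                    class = "pair_profile")
  map <- profile_map(list(prof))
  expect_lte(abs(which.max(map$mean) - 40.6), 1)
  comp <- compensate_profiles(map)
  expect_lte(abs(which.max(comp$mean) - 50.5), 1)
  # monotone reparameterization preserves the extremes up to resampling
  step <- max(abs(diff(prof$profile)))
  expect_lte(abs(max(comp$mean) - max(map$mean)), step)
  expect_lte(abs(min(comp$mean) - min(map$mean)), step)
  expect_error(compensate_profiles(profile_map(list(structure(
    modifyList(unclass(prof), list(interface_position = 1.2)),
    class = "pair_profile")))), "invalid interface")
})

test_that("map invariants hold: stored means match recomputation", {
  set.seed(13)
  profs <- lapply(1:5, function(k) {
    structure(list(profile = runif(100), pair = c(k, k + 1L),
                   internuclear_distance = 10 + k,
                   interface_position = 0.5,
                   centers = rbind(c(0, 0), c(0, 10))),
              class = "pair_profile")
  })
  map <- profile_map(profs)
  expect_equal(map$mean, colMeans(map$profiles), tolerance = 1e-12)
  expect_equal(nrow(map$profiles), 5)
  td <- tidy(map)
  expect_equal(nrow(td), 500)
})

test_that("profile summary finds planted peaks with prominence", {
  flat <- profile_map(list(structure(list(profile = rep(5, 100),
                                          pair = c(1L, 2L),
                                          internuclear_distance = 10,
                                          interface_position = 0.5,
                                          centers = rbind(c(0, 0), c(0, 10))),
                                     class = "pair_profile")))
  s <- profile_summary(flat, prominence_threshold = 0.1)
  expect_equal(length(s$peak_positions), 0)

  x <- seq(0, 1, length.out = 100)
  two <- 3 * exp(-((x - 0.25) / 0.05)^2) + 3 * exp(-((x - 0.75) / 0.05)^2) + 1
  mp <- profile_map(list(structure(list(profile = two, pair = c(1L, 2L),
                                        internuclear_distance = 10,
                                        interface_position = 0.5,
                                        centers = rbind(c(0, 0), c(0, 10))),
                                   class = "pair_profile")))
  s2 <- profile_summary(mp)
  expect_setequal(s2$peak_positions, c(26, 75))
  expect_lt(s2$membrane_intensity, max(two))
  expect_error(profile_summary(structure(list(profiles = matrix(0, 0, 100)),
                                         class = "profile_map")), "empty map")
})

test_that("localization rules separate the three patterns", {
  x <- seq(0, 1, length.out = 100)
  mk_map <- function(y) profile_map(list(structure(
    list(profile = y, pair = c(1L, 2L), internuclear_distance = 10,
         interface_position = 0.5, centers = rbind(c(0, 0), c(0, 10))),
    class = "pair_profile")))
  membr <- classify_localization(profile_summary(mk_map(
    10 * exp(-((x - 0.5) / 0.05)^2) + 1)))
  expect_equal(membr$label, "membranous")
  expect_gt(membr$membrane_enrichment, 1.2)

  peri <- classify_localization(profile_summary(mk_map(
    5 * exp(-((x - 0.25) / 0.05)^2) + 5 * exp(-((x - 0.75) / 0.05)^2) + 1)))
  expect_equal(peri$label, "perinuclear")
  expect_lte(peri$symmetry_score, 8)

  diff_call <- classify_localization(profile_summary(mk_map(rep(2, 100))))
  expect_equal(diff_call$label, "diffuse_absent")
})

test_that("map comparison is a signed-rank test on per-position means", {
  x <- seq(0, 1, length.out = 100)
  mk_map <- function(y) profile_map(list(structure(
    list(profile = y, pair = c(1L, 2L), internuclear_distance = 10,
         interface_position = 0.5, centers = rbind(c(0, 0), c(0, 10))),
    class = "pair_profile")))
  a <- mk_map(10 * exp(-((x - 0.5) / 0.05)^2) + 1)
  same <- compare_profile_maps(a, a)
  expect_equal(same$p_value, 1)
  expect_true("zero-variance" %in% same$flags)

  b <- mk_map(10 * exp(-((x - 0.5) / 0.05)^2) + 2)   # uniform +1 shift
  res <- compare_profile_maps(a, b)
  expect_equal(res$n_effective, 100L)
  expect_lt(res$p_value, 1e-6)
})
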