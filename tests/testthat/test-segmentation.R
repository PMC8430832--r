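test_that("Otsu equals the exhaustive between-class-variance search", {
  h <- numeric(256); h[11] <- 100; h[201] <- 100
  t0 <- otsu_threshold(h)
  expect_gte(t0, 10)
  expect_lt(t0, 200)
  expect_equal(t0, otsu_brute_force(h))

  set.seed(1)
  for (k in 1:30) {
    counts <- rpois(64, lambda = sample(c(1, 5, 50), 64, replace = TRUE))
    if (sum(counts > 0) < 2) next
    expect_equal(otsu_threshold(counts), otsu_brute_force(counts),
                 label = paste("random histogram", k))
  }
})

test_that("Otsu rejects flat histograms and breaks ties low", {
  expect_error(otsu_threshold(c(0, 10, 0)), "flat image")
  # symmetric two-spike histogram: every threshold between the spikes has
  # equal variance; the smallest must be returned
  h <- c(5, 0, 0, 0, 5)
  expect_equal(otsu_threshold(h, values = 0:4), otsu_brute_force(h, 0:4))
  expect_equal(otsu_threshold(h, values = 0:4), 0)
})

test_that("boundary tracing handles single pixels, rectangles and disks", {
  m1 <- matrix(FALSE, 5, 5); m1[3, 3] <- TRUE
  expect_equal(trace_boundary(m1, c(2, 2)),
               matrix(c(2L, 2L), 1, dimnames = list(NULL, c("row", "col"))))

  # filled 4 cols x 3 rows rectangle: perimeter = 2(w + h) - 4 = 10
  m2 <- matrix(FALSE, 8, 8); m2[2:4, 2:5] <- TRUE
  b <- trace_boundary(m2, c(1, 1))
  expect_equal(nrow(unique(b)), 10)
  # closed: consecutive (and wrap-around) pixels are Moore-adjacent
  d <- abs(diff(rbind(b, b[1, ])))
  expect_true(all(pmax(d[, 1], d[, 2]) == 1))
  # all boundary pixels are foreground
  expect_true(all(m2[b + 1]))

  # filled disk: every boundary pixel touches background
  m3 <- matrix(FALSE, 21, 21)
  for (r in 0:20) for (c in 0:20) if ((r - 10)^2 + (c - 10)^2 <= 36) m3[r + 1, c + 1] <- TRUE
  start_idx <- which(t(m3))[1] - 1
  start <- c(start_idx %/% 21, start_idx %% 21)
  b3 <- trace_boundary(m3, start)
  padded <- matrix(FALSE, 23, 23); padded[2:22, 2:22] <- m3
  dr <- c(-1, -1, -1, 0, 0, 1, 1, 1); dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  for (k in seq_len(nrow(b3))) {
    nb <- padded[cbind(b3[k, 1] + 2 + dr, b3[k, 2] + 2 + dc)]
    expect_true(any(!nb))
  }
  expect_error(trace_boundary(m2, c(0, 0)), "not foreground")
})

test_that("segment_objects recovers planted disks and filters by area", {
  img <- matrix(0, 48, 48)
  for (r in 0:47) for (c in 0:47) {
    if ((r - 12)^2 + (c - 12)^2 <= 25) img[r + 1, c + 1] <- 200
    if ((r - 34)^2 + (c - 30)^2 <= 16) img[r + 1, c + 1] <- 200
  }
  obj <- segment_objects(img, segmentation_params(smoothing_radius = 0,
                                                  min_area = 4))
  expect_equal(nrow(obj), 2)
  expect_lt(abs(obj$centroid_row[1] - 12), 0.5)
  expect_lt(abs(obj$centroid_col[1] - 12), 0.5)
  expect_lt(abs(obj$centroid_row[2] - 34), 0.5)
  expect_lt(abs(obj$centroid_col[2] - 30), 0.5)
  # labels follow raster order of first pixel
  expect_true(obj$centroid_row[1] < obj$centroid_row[2])
  # area equals pixel count, and both equal the planted rasterization
  expect_equal(obj$area[1], sum((outer(0:47, rep(1, 48)) - 12)^2 +
                                  (outer(rep(1, 48), 0:47) - 12)^2 <= 25))

  expect_warning(empty <- segment_objects(matrix(5, 16, 16)), "flat image")
  expect_equal(nrow(empty), 0)

  small <- matrix(0, 24, 24); small[10:12, 10:13] <- 200  # 12 px object
  filtered <- segment_objects(small, segmentation_params(smoothing_radius = 0,
                                                         min_area = 20))
  expect_equal(nrow(filtered), 0)
})

test_that("object areas sum to the foreground pixel count when unfiltered", {
  set.seed(5)
  img <- matrix(0, 40, 40)
  img[3:7, 3:7] <- 150
  img[20:29, 11:16] <- 180
  img[33:36, 30:38] <- 220
  obj <- segment_objects(img, segmentation_params(smoothing_radius = 0,
                                                  min_area = 1))
  expect_equal(sum(obj$area), sum(img > 0))
})

test_that("segmentation is translation-equivariant for interior shifts", {
  img <- matrix(0, 40, 40)
  img[6:10, 6:11] <- 200
  img[18:23, 20:24] <- 200
  shifted <- matrix(0, 40, 40)
  img_idx <- which(img > 0, arr.ind = TRUE)
  shifted[cbind(img_idx[, 1] + 7, img_idx[, 2] + 9)] <- 200
  p <- segmentation_params(smoothing_radius = 0, min_area = 1)
  o1 <- segment_objects(img, p)
  o2 <- segment_objects(shifted, p)
  expect_equal(o2$centroid_row, o1$centroid_row + 7)
  expect_equal(o2$centroid_col, o1$centroid_col + 9)
})

test_that("component labeling agrees with an independent labeler", {
  skip_if_not_installed("EBImage")
  set.seed(9)
  img <- matrix(0, 64, 64)
  for (k in 1:6) {
    r <- sample(5:58, 1); c <- sample(5:58, 1)
    img[(r - 2):(r + 2), (c - 2):(c + 2)] <- 200
  }
  obj <- segment_objects(img, segmentation_params(smoothing_radius = 0,
                                                  min_area = 1))
  ref <- max(EBImage::bwlabel(img > 0))
  expect_equal(nrow(obj), ref)
})

test_that("counting returns the number of segmented objects", {
  img <- matrix(0, 32, 32)
  img[4:8, 4:8] <- 200
  img[20:24, 20:24] <- 200
  expect_equal(count_invasive_nuclei(img, segmentation_params(
    smoothing_radius = 0, min_area = 4)), 2)
  expect_warning(n0 <- count_invasive_nuclei(matrix(0, 16, 16)), "flat")
  expect_equal(n0, 0)
  # touching blobs merge into one component (documented limitation)
  merged <- matrix(0, 24, 24); merged[8:12, 6:12] <- 200; merged[10:14, 12:18] <- 200
  expect_equal(count_invasive_nuclei(merged, segmentation_params(
    smoothing_radius = 0, min_area = 4)), 1)
})

test_that("mean filter preserves constants and averages locally", {
  m <- matrix(7, 10, 10)
  expect_equal(mean_filter(m, 2), m)
  img <- matrix(0, 9, 9); img[5, 5] <- 9
  sm <- mean_filter(img, 1)
  expect_equal(sm[5, 5], 1)
  expect_equal(sum(sm[4:6, 4:6]), 9)
})
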