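#' Contiguous nucleus pairs from a cell network
#'
#' Two nuclei are "contiguous" when they are Delaunay neighbors and their
#' internuclear distance does not exceed a cutoff (long hull edges connect
#' cells that are not in contact).
#'
#' @param network a `cell_network` from [build_network()].
#' @param cutoff maximum internuclear distance in pixels.
#' @return A tibble with columns `i`, `j` (`i < j`, each unordered pair once)
#'   and `length`.
#' @export
contiguous_pairs <- function(network, cutoff) {
  stopifnot(inherits(network, "cell_network"), cutoff >= 0)
  dplyr::filter(network$edges, .data$length <= cutoff)
}

# Bilinear interpolation at 0-based (row, col) positions; pixel centers sit
# at integer coordinates.
bilinear_interp <- function(image, r, c) {
  nr <- nrow(image); nc <- ncol(image)
  if (any(r < 0 | r > nr - 1 | c < 0 | c > nc - 1)) {
    stop("out of bounds: sample position outside the image", call. = FALSE)
  }
  i0 <- pmin(floor(r), nr - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(c), nc - 2); j0 <- pmax(j0, 0)
  fr <- r - i0; fc <- c - j0
  idx <- function(i, j) image[cbind(i + 1, j + 1)]
  (1 - fr) * (1 - fc) * idx(i0, j0) +
    (1 - fr) * fc * idx(i0, j0 + 1) +
    fr * (1 - fc) * idx(i0 + 1, j0) +
    fr * fc * idx(i0 + 1, j0 + 1)
}

#' Extract an internuclear intensity profile
#'
#' Samples the cadherin channel by bilinear interpolation at `n_positions`
#' equally spaced points on the closed segment joining two nuclear centers.
#' Position 1 is the geometric center of nucleus i, position `n_positions`
#' the center of nucleus j; with the default 100 positions the cell-cell
#' interface of an equidistant pair falls at the profile midpoint between
#' positions 50 and 51 (referred to as "position 50" throughout).
#'
#' @param image numeric matrix (cadherin channel).
#' @param center_i,center_j 0-based `(row, col)` nuclear centers.
#' @param n_positions number of samples (default 100).
#' @param pair optional integer pair of node ids for bookkeeping.
#' @param interface_position fractional position of the cell-cell interface
#'   along the segment, in `(0, 1)`; defaults to `0.5` (the perpendicular-
#'   bisector convention). Supply the planted or detected value when known.
#' @return A `pair_profile`: list with `profile` (length `n_positions`),
#'   `pair`, `centers`, `internuclear_distance`, `interface_position`.
#' @export
extract_profile <- function(image, center_i, center_j, n_positions = 100,
                            pair = c(NA_integer_, NA_integer_),
                            interface_position = 0.5) {
  stopifnot(is.matrix(image), length(center_i) == 2, length(center_j) == 2,
            n_positions >= 2)
  if (interface_position <= 0 || interface_position >= 1) {
    stop("invalid interface: interface_position must lie in (0, 1)",
         call. = FALSE)
  }
  t <- seq(0, 1, length.out = n_positions)
  r <- center_i[1] + t * (center_j[1] - center_i[1])
  c <- center_i[2] + t * (center_j[2] - center_i[2])
  vals <- bilinear_interp(image, r, c)
  structure(
    list(
      profile = as.numeric(vals),
      pair = pair,
      centers = rbind(i = as.numeric(center_i), j = as.numeric(center_j)),
      internuclear_distance = sqrt(sum((center_j - center_i)^2)),
      interface_position = interface_position
    ),
    class = "pair_profile"
  )
}

#' Assemble pair profiles into a profile map
#'
#' Stacks pair profiles (rows) over the shared position axis and stores the
#' per-position mean and standard error.
#'
#' @param profiles list of `pair_profile` objects with equal length.
#' @param compensated logical bookkeeping flag.
#' @return A `profile_map`: list with `profiles` (pairs x positions matrix),
#'   `pairs` (tibble `i`, `j`, `internuclear_distance`,
#'   `interface_position`), `mean`, `se`, `compensated`.
#' @export
profile_map <- function(profiles, compensated = FALSE) {
  stopifnot(length(profiles) >= 1,
            all(purrr::map_lgl(profiles, inherits, "pair_profile")))
  lens <- purrr::map_int(profiles, ~ length(.x$profile))
  stopifnot(length(unique(lens)) == 1)
  mat <- do.call(rbind, purrr::map(profiles, "profile"))
  pairs <- purrr::map_dfr(profiles, function(p) {
    tibble::tibble(i = p$pair[1], j = p$pair[2],
                   internuclear_distance = p$internuclear_distance,
                   interface_position = p$interface_position)
  })
  structure(
    list(
      profiles = mat,
      pairs = pairs,
      mean = colMeans(mat),
      se = apply(mat, 2, stats::sd) / sqrt(nrow(mat)),
      compensated = compensated
    ),
    class = "profile_map"
  )
}

#' Extract all contiguous-pair profiles of an image
#'
#' Convenience wrapper: builds profiles for every contiguous pair of a
#' network and stacks them into a [profile_map()].
#'
#' @param image cadherin-channel matrix.
#' @param network `cell_network` over the image's nuclear centroids.
#' @param cutoff contiguity cutoff in pixels (default `"auto"`: `1.5 *`
#'   median Delaunay edge length).
#' @param interface_positions optional numeric vector (one entry per
#'   contiguous pair, in the row order of [contiguous_pairs()]) of known
#'   interface positions; defaults to 0.5 everywhere.
#' @param n_positions samples per profile.
#' @return A `profile_map`.
#' @export
extract_profiles <- function(image, network, cutoff = "auto",
                             interface_positions = NULL, n_positions = 100) {
  if (identical(cutoff, "auto")) {
    cutoff <- 1.5 * stats::median(network$edges$length)
  }
  pairs <- contiguous_pairs(network, cutoff)
  if (nrow(pairs) == 0) stop("no contiguous pairs at this cutoff", call. = FALSE)
  if (is.null(interface_positions)) {
    interface_positions <- rep(0.5, nrow(pairs))
  }
  stopifnot(length(interface_positions) == nrow(pairs))
  nodes <- as.matrix(network$nodes)
  profiles <- purrr::map(seq_len(nrow(pairs)), function(k) {
    extract_profile(image, nodes[pairs$i[k], ], nodes[pairs$j[k], ],
                    n_positions = n_positions,
                    pair = c(pairs$i[k], pairs$j[k]),
                    interface_position = interface_positions[k])
  })
  profile_map(profiles)
}

# Piecewise-linear warp sending the interface coordinate to the profile
# midpoint while keeping both endpoints fixed, followed by linear resampling
# back onto the integer position grid.
warp_profile <- function(profile, interface_position) {
  n <- length(profile)
  u_int <- 1 + (n - 1) * interface_position
  u_mid <- (1 + n) / 2
  p <- seq_len(n)
  u <- ifelse(p <= u_mid,
              1 + (p - 1) * (u_int - 1) / (u_mid - 1),
              u_int + (p - u_mid) * (n - u_int) / (n - u_mid))
  stats::approx(x = seq_len(n), y = profile, xout = u)$y
}

#' Geometrically compensate a profile map
#'
#' Re-parameterizes each pair profile so that its cell-cell interface is
#' anchored exactly at the profile midpoint ("position 50" of 100) while
#' positions 1 and `n` stay fixed, then resamples to the original position
#' grid and recomputes the map mean and standard error. Profiles whose
#' interface already sits at 0.5 pass through unchanged.
#'
#' @param map a `profile_map` (or a list of `pair_profile`s).
#' @return A compensated `profile_map`.
#' @export
compensate_profiles <- function(map) {
  if (!inherits(map, "profile_map")) map <- profile_map(map)
  ifp <- map$pairs$interface_position
  if (any(ifp <= 0 | ifp >= 1)) {
    stop("invalid interface: interface_position must lie in (0, 1)",
         call. = FALSE)
  }
  mat <- map$profiles
  for (r in seq_len(nrow(mat))) {
    mat[r, ] <- warp_profile(mat[r, ], ifp[r])
  }
  out <- map
  out$profiles <- mat
  out$pairs$interface_position <- 0.5
  out$mean <- colMeans(mat)
  out$se <- apply(mat, 2, stats::sd) / sqrt(nrow(mat))
  out$compensated <- TRUE
  out
}

# Local maxima of a vector with topographic prominence. Plateaus count once
# (at their first position). Returns a tibble position/height/prominence.
find_peaks <- function(x) {
  n <- length(x)
  is_peak <- logical(n)
  k <- 1
  while (k <= n) {
    k2 <- k
    while (k2 < n && x[k2 + 1] == x[k]) k2 <- k2 + 1
    left_ok <- k == 1 || x[k - 1] < x[k]
    right_ok <- k2 == n || x[k2 + 1] < x[k]
    if (left_ok && right_ok && !(k == 1 && k2 == n)) is_peak[k] <- TRUE
    k <- k2 + 1
  }
  pos <- which(is_peak)
  prom <- purrr::map_dbl(pos, function(p) {
    h <- x[p]
    left_min <- h
    for (q in seq(p, 1)) {
      if (x[q] > h) break
      left_min <- min(left_min, x[q])
    }
    if (q == 1 && x[1] <= h) left_min <- min(x[seq_len(p)])
    right_min <- h
    for (q in seq(p, n)) {
      if (x[q] > h) break
      right_min <- min(right_min, x[q])
    }
    if (q == n && x[n] <= h) right_min <- min(x[p:n])
    # prominence relative to the higher of the two key saddles; an end
    # reached without meeting a higher value uses the minimum on that side
    h - max(left_min, right_min)
  })
  tibble::tibble(position = pos, height = x[pos], prominence = prom)
}

#' Summarize a profile map
#'
#' Finds local maxima of the per-position mean profile with topographic
#' prominence at least `prominence_threshold`, and reports the membrane
#' intensity (mean intensity at position 50, the interface-anchored
#' midpoint).
#'
#' @param map a `profile_map`.
#' @param prominence_threshold minimum peak prominence in intensity units;
#'   `NULL` (default) uses 20% of the mean profile's dynamic range.
#' @return A `profile_summary`: list with `peaks` (tibble `position`,
#'   `height`, `prominence`), `peak_positions`, `membrane_intensity`,
#'   `mean_profile`, `n_pairs`, `nucleus_proximal` (logical per peak: within
#'   the third of the axis nearest either nucleus), `prominence_threshold`.
#' @export
profile_summary <- function(map, prominence_threshold = NULL) {
  stopifnot(inherits(map, "profile_map"))
  if (nrow(map$profiles) == 0) stop("empty map", call. = FALSE)
  m <- map$mean
  n <- length(m)
  if (is.null(prominence_threshold)) {
    prominence_threshold <- 0.2 * diff(range(m))
  }
  peaks <- find_peaks(m)
  peaks <- peaks[peaks$prominence >= prominence_threshold, , drop = FALSE]
  peaks <- peaks[order(-peaks$height), , drop = FALSE]
  mid <- c(floor((n + 1) / 2))          # position "50" of 100
  structure(
    list(
      peaks = peaks,
      peak_positions = peaks$position,
      membrane_intensity = m[mid],
      mean_profile = m,
      n_pairs = nrow(map$profiles),
      nucleus_proximal = peaks$position <= n / 3 | peaks$position > 2 * n / 3,
      prominence_threshold = prominence_threshold
    ),
    class = "profile_summary"
  )
}

#' Localization classification thresholds
#'
#' @param membrane_window positions counted as "at the membrane" (default
#'   45-55 of 100).
#' @param enrichment_min minimum membrane enrichment (mean intensity inside
#'   the membrane window over the whole-profile mean) for a membranous call.
#' @param symmetry_tol maximum `|p_left + p_right - 101|` for a perinuclear
#'   peak pair to count as symmetric about the interface.
#' @param flatness_min minimum dynamic range of the mean profile relative to
#'   its mean; below this the profile is considered structureless (diffuse or
#'   absent signal).
#' @return A named list of thresholds.
#' @export
localization_thresholds <- function(membrane_window = c(45, 55),
                                    enrichment_min = 1.2,
                                    symmetry_tol = 8,
                                    flatness_min = 0.2) {
  list(membrane_window = membrane_window, enrichment_min = enrichment_min,
       symmetry_tol = symmetry_tol, flatness_min = flatness_min)
}

#' Classify cadherin localization from a profile summary
#'
#' Rule-based call: *membranous* when the dominant mean-profile peak lies in
#' the membrane window (positions 45-55) and the membrane enrichment score
#' reaches `enrichment_min`; *perinuclear* when two roughly interface-
#' symmetric off-center maxima dominate and the membrane intensity lies below
#' both; otherwise *diffuse_absent* (including structureless profiles).
#'
#' @param summary a `profile_summary`.
#' @param thresholds a [localization_thresholds()] list.
#' @return A `localization_call`: list with `label` (one of `"membranous"`,
#'   `"perinuclear"`, `"diffuse_absent"`), `membrane_enrichment`,
#'   `symmetry_score`.
#' @export
classify_localization <- function(summary,
                                  thresholds = localization_thresholds()) {
  stopifnot(inherits(summary, "profile_summary"))
  m <- summary$mean_profile
  n <- length(m)
  win <- seq(thresholds$membrane_window[1], thresholds$membrane_window[2])
  enrichment <- mean(m[win]) / max(mean(m), .Machine$double.eps)
  flatness <- diff(range(m)) / max(mean(m), .Machine$double.eps)
  peaks <- summary$peaks
  symmetry <- NA_real_
  label <- "diffuse_absent"
  if (flatness >= thresholds$flatness_min && nrow(peaks) > 0) {
    dominant <- peaks$position[1]
    in_window <- dominant >= thresholds$membrane_window[1] &&
      dominant <= thresholds$membrane_window[2]
    if (in_window && enrichment >= thresholds$enrichment_min) {
      label <- "membranous"
    } else if (nrow(peaks) >= 2) {
      off <- peaks[peaks$position < thresholds$membrane_window[1] |
                     peaks$position > thresholds$membrane_window[2], ,
                   drop = FALSE]
      if (nrow(off) >= 2) {
        p_left <- min(off$position[1:2])
        p_right <- max(off$position[1:2])
        symmetry <- abs(p_left + p_right - (n + 1))
        if (p_left < (n + 1) / 2 && p_right > (n + 1) / 2 &&
            symmetry <= thresholds$symmetry_tol &&
            summary$membrane_intensity < min(off$height[1:2])) {
          label <- "perinuclear"
        }
      }
    }
  }
  structure(
    list(label = label, membrane_enrichment = enrichment,
         symmetry_score = symmetry),
    class = "localization_call"
  )
}

#' @export
print.localization_call <- function(x, ...) {
  cat(sprintf("localization: %s (membrane enrichment %.3g, symmetry %s)\n",
              x$label, x$membrane_enrichment,
              ifelse(is.na(x$symmetry_score), "-",
                     format(x$symmetry_score))))
  invisible(x)
}

#' Compare two profile maps (Wilcoxon signed-rank)
#'
#' Two-tailed Wilcoxon signed-rank on the per-position mean intensities of
#' two maps, paired across the shared 100-position axis. Zero differences
#' are dropped; the exact sign-flip null is used for up to 25 nonzero
#' differences, a continuity-corrected normal approximation beyond.
#'
#' @param map_a,map_b `profile_map`s with the same number of positions.
#' @return A [comparison result][new_comparison_result].
#' @export
compare_profile_maps <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "profile_map"), inherits(map_b, "profile_map"),
            length(map_a$mean) == length(map_b$mean))
  res <- wilcoxon_signed_rank(map_a$mean - map_b$mean)
  res$groups <- tibble::tibble(
    group = c("A", "B"),
    n = c(nrow(map_a$profiles), nrow(map_b$profiles)),
    mean = c(mean(map_a$mean), mean(map_b$mean)),
    se = c(stats::sd(map_a$mean) / sqrt(length(map_a$mean)),
           stats::sd(map_b$mean) / sqrt(length(map_b$mean)))
  )
  res
}

#' Tidy a profile map into long format
#'
#' @param x a `profile_map`.
#' @param ... unused.
#' @return A tibble `pair_id`, `i`, `j`, `position`, `intensity`.
#' @exportS3Method generics::tidy
tidy.profile_map <- function(x, ...) {
  n_pos <- ncol(x$profiles)
  tibble::tibble(
    pair_id = rep(seq_len(nrow(x$profiles)), each = n_pos),
    i = rep(x$pairs$i, each = n_pos),
    j = rep(x$pairs$j, each = n_pos),
    position = rep(seq_len(n_pos), nrow(x$profiles)),
    intensity = as.vector(t(x$profiles))
  )
}

#' @export
print.profile_map <- function(x, ...) {
  cat(sprintf("profile map: %d pairs x %d positions (%s)\n",
              nrow(x$profiles), ncol(x$profiles),
              if (x$compensated) "compensated" else "extracted"))
  invisible(x)
}
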