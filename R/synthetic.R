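#' Monolayer layout parameters
#'
#' Geometry of a planted epithelial monolayer. `mean_spacing` must exceed
#' twice the nucleus radius so that nuclei never touch; all planted centers
#' are kept inside the field.
#'
#' @param n_cells number of cells (>= 0).
#' @param packing `"hexagonal"` (jittered triangular lattice, epithelial
#'   monolayer-like) or `"random_poisson"` (hard-core uniform placement,
#'   scattered phenotype-like).
#' @param mean_spacing mean center-to-center distance in pixels.
#' @param jitter_sd per-center Gaussian positional jitter (pixels).
#' @param field_size `(rows, cols)` in pixels, or `NULL` to size the field to
#'   the layout automatically.
#' @param nucleus_radius nominal nucleus radius in pixels (blob sd is half
#'   this value).
#' @return A list of class `layout_params`.
#' @export
layout_params <- function(n_cells = 25, packing = c("hexagonal", "random_poisson"),
                          mean_spacing = 20, jitter_sd = 1, field_size = NULL,
                          nucleus_radius = 4) {
  packing <- match.arg(packing)
  stopifnot(n_cells >= 0, mean_spacing > 2 * nucleus_radius, jitter_sd >= 0,
            nucleus_radius > 0)
  if (!is.null(field_size)) stopifnot(length(field_size) == 2, all(field_size >= 8))
  structure(list(n_cells = as.integer(n_cells), packing = packing,
                 mean_spacing = mean_spacing, jitter_sd = jitter_sd,
                 field_size = field_size, nucleus_radius = nucleus_radius),
            class = "layout_params")
}

#' Cadherin phenotype parameters
#'
#' Distribution of each cell's cadherin signal across three compartments:
#' the membrane (shared Voronoi boundary between contiguous cells), a
#' perinuclear ring (signal displaced a fraction `perinuclear_offset` of the
#' internuclear distance from the nucleus center toward each neighbor,
#' emulating endoplasmic-reticulum retention), and diffuse cytoplasm. The
#' three fractions must sum to 1.
#'
#' @param membrane_fraction,perinuclear_fraction,cytoplasm_fraction
#'   compartment fractions in `[0, 1]`, summing to 1 (tolerance 1e-9).
#' @param perinuclear_offset fraction `d` in `(0, 0.5)` of each internuclear
#'   distance at which the perinuclear signal sits.
#' @param expression_level total cadherin intensity per cell (arbitrary
#'   units, >= 0).
#' @return A list of class `phenotype_params`.
#' @export
phenotype_params <- function(membrane_fraction, perinuclear_fraction,
                             cytoplasm_fraction, perinuclear_offset = 0.25,
                             expression_level = 5000) {
  fr <- c(membrane_fraction, perinuclear_fraction, cytoplasm_fraction)
  stopifnot(all(fr >= 0), all(fr <= 1),
            perinuclear_offset > 0, perinuclear_offset < 0.5,
            expression_level >= 0)
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("compartment fractions must sum to 1", call. = FALSE)
  }
  structure(list(membrane_fraction = membrane_fraction,
                 perinuclear_fraction = perinuclear_fraction,
                 cytoplasm_fraction = cytoplasm_fraction,
                 perinuclear_offset = perinuclear_offset,
                 expression_level = expression_level),
            class = "phenotype_params")
}

#' @describeIn phenotype_params wild-type-like preset: membrane-enriched
#'   signal (70% membrane, 30% cytoplasm).
#' @export
phenotype_membranous <- function(expression_level = 5000) {
  phenotype_params(0.7, 0, 0.3, expression_level = expression_level)
}

#' @describeIn phenotype_params mutant-like preset: no membrane enrichment,
#'   perinuclear accumulation (60% perinuclear at offset 0.25, 40%
#'   cytoplasm).
#' @export
phenotype_perinuclear <- function(expression_level = 5000,
                                  perinuclear_offset = 0.25) {
  phenotype_params(0, 0.6, 0.4, perinuclear_offset = perinuclear_offset,
                   expression_level = expression_level)
}

#' @describeIn phenotype_params diffuse/absent preset: purely cytoplasmic
#'   signal.
#' @export
phenotype_diffuse <- function(expression_level = 5000) {
  phenotype_params(0, 0, 1, expression_level = expression_level)
}

#' Acquisition noise parameters
#'
#' @param background constant background offset (intensity units).
#' @param gaussian_sd additive Gaussian read-noise sd.
#' @param poisson_gain photon shot-noise gain; `0` disables shot noise, a
#'   positive value `g` replaces each pixel `v` by `g * rpois(v / g)`.
#' @return A list of class `noise_params`.
#' @export
noise_params <- function(background = 10, gaussian_sd = 2, poisson_gain = 0) {
  stopifnot(background >= 0, gaussian_sd >= 0, poisson_gain >= 0)
  structure(list(background = background, gaussian_sd = gaussian_sd,
                 poisson_gain = poisson_gain),
            class = "noise_params")
}

#' @describeIn noise_params noise-free acquisition (zero background, no
#'   read or shot noise).
#' @export
noise_off <- function() noise_params(0, 0, 0)

# Evaluate code with a private, explicitly seeded RNG stream, restoring the
# caller's RNG state afterwards.
with_scene_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

place_hexagonal <- function(n, spacing, jitter_sd, field_size, margin) {
  dy <- spacing * sqrt(3) / 2
  ncol_grid <- ceiling(sqrt(n))
  nrow_grid <- ceiling(n / ncol_grid)
  if (is.null(field_size)) {
    field_size <- ceiling(c((nrow_grid - 1) * dy + 2 * margin,
                            (ncol_grid - 0.5) * spacing + 2 * margin))
  }
  need <- c((nrow_grid - 1) * dy, (ncol_grid - 0.5) * spacing) + 2 * margin
  if (any(field_size < need)) {
    stop("layout infeasible: field too small for n_cells at mean_spacing",
         call. = FALSE)
  }
  centers <- matrix(NA_real_, n, 2)
  k <- 0
  for (r in seq_len(nrow_grid)) {
    for (c in seq_len(ncol_grid)) {
      if (k >= n) break
      k <- k + 1
      centers[k, ] <- c(margin + (r - 1) * dy,
                        margin + (c - 1) * spacing +
                          ifelse(r %% 2 == 0, spacing / 2, 0))
    }
  }
  if (jitter_sd > 0 && n > 0) {
    centers <- centers + matrix(stats::rnorm(2 * n, 0, jitter_sd), n, 2)
  }
  centers[, 1] <- pmin(pmax(centers[, 1], 1), field_size[1] - 2)
  centers[, 2] <- pmin(pmax(centers[, 2], 1), field_size[2] - 2)
  list(centers = centers, field_size = field_size)
}

place_hardcore <- function(n, min_sep, field_size, margin, max_tries = NULL) {
  if (is.null(max_tries)) max_tries <- 2000L * max(1L, n)
  lo <- c(margin, margin)
  hi <- field_size - 1 - margin
  if (any(hi <= lo)) {
    stop("placement failed: field too small", call. = FALSE)
  }
  centers <- matrix(NA_real_, n, 2)
  placed <- 0
  tries <- 0
  while (placed < n) {
    tries <- tries + 1
    if (tries > max_tries) {
      stop("placement failed: could not place objects without overlap",
           call. = FALSE)
    }
    cand <- c(stats::runif(1, lo[1], hi[1]), stats::runif(1, lo[2], hi[2]))
    if (placed > 0) {
      d2 <- (centers[seq_len(placed), 1] - cand[1])^2 +
        (centers[seq_len(placed), 2] - cand[2])^2
      if (min(d2) < min_sep^2) next
    }
    placed <- placed + 1
    centers[placed, ] <- cand
  }
  centers
}

# Additive Gaussian blob on a local window; returns the modified image.
add_blob <- function(image, center, sd, amplitude) {
  nr <- nrow(image); nc <- ncol(image)
  half <- ceiling(4 * sd)
  r0 <- max(0, floor(center[1]) - half); r1 <- min(nr - 1, ceiling(center[1]) + half)
  c0 <- max(0, floor(center[2]) - half); c1 <- min(nc - 1, ceiling(center[2]) + half)
  if (r1 < r0 || c1 < c0) return(image)
  rr <- r0:r1; cc <- c0:c1
  g <- outer(exp(-(rr - center[1])^2 / (2 * sd^2)),
             exp(-(cc - center[2])^2 / (2 * sd^2))) * amplitude
  image[rr + 1, cc + 1] <- image[rr + 1, cc + 1] + g
  image
}

apply_noise <- function(image, noise) {
  image <- image + noise$background
  if (noise$poisson_gain > 0) {
    image <- noise$poisson_gain *
      matrix(stats::rpois(length(image), pmax(image, 0) / noise$poisson_gain),
             nrow(image))
  }
  if (noise$gaussian_sd > 0) {
    image <- image + matrix(stats::rnorm(length(image), 0, noise$gaussian_sd),
                            nrow(image))
  }
  image
}

# Nearest / second-nearest planted center per pixel (0-based coordinates).
ownership_fields <- function(field_size, centers) {
  nr <- field_size[1]; nc <- field_size[2]
  rows <- matrix(rep(0:(nr - 1), nc), nr)
  cols <- matrix(rep(0:(nc - 1), each = nr), nr)
  d1 <- matrix(Inf, nr, nc); d2 <- matrix(Inf, nr, nc)
  owner <- matrix(0L, nr, nc); second <- matrix(0L, nr, nc)
  for (i in seq_len(nrow(centers))) {
    d <- sqrt((rows - centers[i, 1])^2 + (cols - centers[i, 2])^2)
    closer <- d < d1
    d2[closer] <- d1[closer]; second[closer] <- owner[closer]
    d1[closer] <- d[closer]; owner[closer] <- i
    mid <- !closer & d < d2
    d2[mid] <- d[mid]; second[mid] <- i
  }
  list(d1 = d1, d2 = d2, owner = owner, second = second)
}

#' Generate a synthetic epithelial monolayer scene
#'
#' Renders a two-channel fluorescence scene with planted ground truth: a
#' nuclei channel with one Gaussian blob per planted center, and a cadherin
#' channel distributing each cell's `expression_level` across the membrane
#' (a tent-profile ridge along shared Voronoi boundaries, peaking exactly on
#' the cell-cell interface), perinuclear spots at fractional offset `d`
#' toward each contiguous neighbor, and uniform cytoplasm over the cell's
#' Voronoi region. Each compartment is normalized so the rendered per-cell
#' total equals `expression_level` exactly before noise; a cell lacking a
#' compartment (e.g. no contiguous neighbor) re-routes that fraction to
#' cytoplasm so total intensity is conserved.
#'
#' @param layout a [layout_params()] list.
#' @param phenotype a [phenotype_params()] list.
#' @param noise a [noise_params()] list.
#' @param seed integer seed; scenes are bit-exactly reproducible for a fixed
#'   seed and parameter set.
#' @param membrane_width full width (pixels) of the membrane ridge.
#' @param nuclear_amplitude peak intensity of a nuclear blob.
#' @return A `synthetic_scene`: list with `nuclei_image`, `cadherin_image`,
#'   `truth` (planted `centers` 0-based, `cell_regions` polygons,
#'   `pair_interfaces` tibble, `perinuclear_spots` tibble, `cell_totals`,
#'   `phenotype`, `field_size`), and `seed`.
#' @export
generate_monolayer <- function(layout, phenotype, noise = noise_params(),
                               seed = 1, membrane_width = 2,
                               nuclear_amplitude = 1000) {
  stopifnot(inherits(layout, "layout_params"),
            inherits(phenotype, "phenotype_params"),
            inherits(noise, "noise_params"))
  with_scene_seed(seed, {
    margin <- layout$mean_spacing / 2 + 2
    if (layout$n_cells == 0) {
      fs <- if (is.null(layout$field_size)) c(64, 64) else layout$field_size
      nuc <- apply_noise(matrix(0, fs[1], fs[2]), noise)
      cad <- apply_noise(matrix(0, fs[1], fs[2]), noise)
      return(new_scene(nuc, cad, centers = matrix(numeric(0), 0, 2),
                       cell_regions = list(),
                       pair_interfaces = empty_interfaces(),
                       perinuclear_spots = empty_spots(),
                       cell_totals = numeric(0), phenotype = phenotype,
                       seed = seed, field_size = fs))
    }
    if (layout$packing == "hexagonal") {
      placed <- place_hexagonal(layout$n_cells, layout$mean_spacing,
                                layout$jitter_sd, layout$field_size, margin)
      centers <- placed$centers
      fs <- placed$field_size
    } else {
      fs <- layout$field_size
      if (is.null(fs)) {
        side <- ceiling(sqrt(layout$n_cells) * layout$mean_spacing + 2 * margin)
        fs <- c(side, side)
      }
      min_sep <- 2 * layout$nucleus_radius + 2
      if (layout$n_cells * (2 * min_sep)^2 > 2 * prod(fs)) {
        stop("layout infeasible: field too small for n_cells at mean_spacing",
             call. = FALSE)
      }
      centers <- place_hardcore(layout$n_cells, min_sep, fs, margin)
    }
    colnames(centers) <- c("row", "col")

    nuc <- matrix(0, fs[1], fs[2])
    for (i in seq_len(nrow(centers))) {
      nuc <- add_blob(nuc, centers[i, ], layout$nucleus_radius / 2,
                      nuclear_amplitude)
    }

    cad <- matrix(0, fs[1], fs[2])
    n <- nrow(centers)
    cell_totals <- numeric(n)
    regions <- list()
    interfaces <- empty_interfaces()
    spots <- empty_spots()
    expr <- phenotype$expression_level

    if (n >= 3) {
      dd <- deldir::deldir(x = centers[, 2], y = centers[, 1],
                           rw = c(0, fs[2] - 1, 0, fs[1] - 1),
                           suppressMsge = TRUE)
      tiles <- deldir::tile.list(dd)
      regions <- lapply(tiles, function(t) cbind(row = t$y, col = t$x))
      adj <- unique(t(apply(dd$dirsgs[, c("ind1", "ind2")], 1,
                            function(z) sort(as.integer(z)))))
      # keep only pairs whose center-to-center segment actually crosses the
      # shared Voronoi edge: the midpoint's two nearest centers must be the
      # pair itself (marginal corner-neighbors would otherwise plant an
      # interface inside a third cell's territory)
      mid_ok <- vapply(seq_len(nrow(adj)), function(k) {
        mid <- (centers[adj[k, 1], ] + centers[adj[k, 2], ]) / 2
        d <- sqrt((centers[, 1] - mid[1])^2 + (centers[, 2] - mid[2])^2)
        all(sort(order(d)[1:2]) == adj[k, ])
      }, logical(1))
      adj <- adj[mid_ok, , drop = FALSE]
      interfaces <- tibble::tibble(
        i = adj[, 1], j = adj[, 2],
        interface_row = (centers[adj[, 1], 1] + centers[adj[, 2], 1]) / 2,
        interface_col = (centers[adj[, 1], 2] + centers[adj[, 2], 2]) / 2,
        t = 0.5
      )
    } else if (n == 2) {
      interfaces <- tibble::tibble(
        i = 1L, j = 2L,
        interface_row = mean(centers[, 1]),
        interface_col = mean(centers[, 2]), t = 0.5
      )
    }

    if (expr > 0 && n > 0) {
      own <- ownership_fields(fs, centers)
      neighbor_sets <- split(c(interfaces$j, interfaces$i),
                             c(interfaces$i, interfaces$j))
      d <- phenotype$perinuclear_offset
      for (i in seq_len(n)) {
        nbrs <- neighbor_sets[[as.character(i)]]
        frac_mem <- phenotype$membrane_fraction
        frac_per <- phenotype$perinuclear_fraction
        frac_cyt <- phenotype$cytoplasm_fraction

        # membrane: tent ridge over the cell's side of shared Voronoi edges
        mem_w <- NULL
        if (frac_mem > 0) {
          sel <- own$owner == i & (own$d2 - own$d1) <= membrane_width &
            own$second > 0
          if (length(nbrs)) sel <- sel & matrix(own$second %in% nbrs, fs[1])
          if (any(sel)) {
            w <- matrix(0, fs[1], fs[2])
            w[sel] <- 1 - (own$d2[sel] - own$d1[sel]) / (membrane_width + 1e-9)
            if (sum(w) > 0) mem_w <- w
          }
          if (is.null(mem_w)) { frac_cyt <- frac_cyt + frac_mem; frac_mem <- 0 }
        }

        # perinuclear spots toward each contiguous neighbor
        per_w <- NULL
        if (frac_per > 0) {
          if (length(nbrs)) {
            w <- matrix(0, fs[1], fs[2])
            for (jn in nbrs) {
              spot <- centers[i, ] + d * (centers[jn, ] - centers[i, ])
              w <- add_blob(w, spot, sd = 1.5, amplitude = 1)
              spots <- dplyr::bind_rows(spots, tibble::tibble(
                cell = i, neighbor = jn,
                row = spot[1], col = spot[2],
                offset = d,
                distance_from_center = d * sqrt(sum((centers[jn, ] - centers[i, ])^2))
              ))
            }
            if (sum(w) > 0) per_w <- w
          }
          if (is.null(per_w)) { frac_cyt <- frac_cyt + frac_per; frac_per <- 0 }
        }

        if (!is.null(mem_w)) cad <- cad + mem_w * (expr * frac_mem / sum(mem_w))
        if (!is.null(per_w)) cad <- cad + per_w * (expr * frac_per / sum(per_w))
        if (frac_cyt > 0) {
          sel <- own$owner == i
          cad[sel] <- cad[sel] + expr * frac_cyt / sum(sel)
        }
        cell_totals[i] <- expr
      }
    }

    nuc <- apply_noise(nuc, noise)
    cad <- apply_noise(cad, noise)
    new_scene(nuc, cad, centers = centers, cell_regions = regions,
              pair_interfaces = interfaces, perinuclear_spots = spots,
              cell_totals = cell_totals, phenotype = phenotype, seed = seed,
              field_size = fs)
  })
}

empty_interfaces <- function() {
  tibble::tibble(i = integer(), j = integer(), interface_row = numeric(),
                 interface_col = numeric(), t = numeric())
}

empty_spots <- function() {
  tibble::tibble(cell = integer(), neighbor = integer(), row = numeric(),
                 col = numeric(), offset = numeric(),
                 distance_from_center = numeric())
}

new_scene <- function(nuclei_image, cadherin_image, centers, cell_regions,
                      pair_interfaces, perinuclear_spots, cell_totals,
                      phenotype, seed, field_size,
                      planted_areas = NULL, planted_count = NULL) {
  structure(
    list(
      nuclei_image = nuclei_image,
      cadherin_image = cadherin_image,
      truth = list(
        centers = centers,
        cell_regions = cell_regions,
        pair_interfaces = pair_interfaces,
        perinuclear_spots = perinuclear_spots,
        cell_totals = cell_totals,
        phenotype = phenotype,
        planted_areas = planted_areas,
        planted_count = if (is.null(planted_count)) nrow(centers) else planted_count,
        field_size = field_size
      ),
      seed = seed
    ),
    class = "synthetic_scene"
  )
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic scene: %d x %d px, %d planted objects (seed %d)\n",
              nrow(x$nuclei_image), ncol(x$nuclei_image),
              x$truth$planted_count, x$seed))
  invisible(x)
}

#' Generate a slow-aggregation assay scene
#'
#' Non-overlapping bright disks (cell aggregates) on a dark background; each
#' disk's exact rasterized pixel count is recorded as its planted area.
#'
#' @param n_objects number of aggregates (>= 0).
#' @param radius_dist `(mean, sd)` of the Gaussian radius distribution in
#'   pixels (truncated at 2 px; mean must exceed 1 px).
#' @param field_size `(rows, cols)` pixels.
#' @param seed integer seed.
#' @param noise a [noise_params()] list.
#' @param intensity disk foreground intensity.
#' @return A `synthetic_scene`; the disk image is stored in both channels
#'   and `truth$planted_areas` holds the exact pixel counts.
#' @export
generate_aggregation_scene <- function(n_objects, radius_dist = c(20, 3),
                                       field_size = c(256, 256), seed = 1,
                                       noise = noise_params(),
                                       intensity = 200) {
  stopifnot(n_objects >= 0, radius_dist[1] > 1, length(field_size) == 2)
  with_scene_seed(seed, {
    img <- matrix(0, field_size[1], field_size[2])
    centers <- matrix(numeric(0), 0, 2)
    areas <- numeric(0)
    if (n_objects > 0) {
      radii <- pmax(2, stats::rnorm(n_objects, radius_dist[1], radius_dist[2]))
      placed <- matrix(NA_real_, n_objects, 2)
      max_tries <- 2000L * n_objects
      tries <- 0; k <- 0
      while (k < n_objects) {
        tries <- tries + 1
        if (tries > max_tries) {
          stop("placement failed: could not place aggregates without overlap",
               call. = FALSE)
        }
        r <- radii[k + 1]
        cand <- c(stats::runif(1, r + 1, field_size[1] - r - 2),
                  stats::runif(1, r + 1, field_size[2] - r - 2))
        if (k > 0) {
          d <- sqrt((placed[seq_len(k), 1] - cand[1])^2 +
                      (placed[seq_len(k), 2] - cand[2])^2)
          if (min(d - radii[seq_len(k)]) < r + 3) next
        }
        k <- k + 1
        placed[k, ] <- cand
      }
      centers <- placed
      colnames(centers) <- c("row", "col")
      areas <- numeric(n_objects)
      for (i in seq_len(n_objects)) {
        r <- radii[i]
        r0 <- max(0, floor(centers[i, 1] - r)); r1 <- min(field_size[1] - 1, ceiling(centers[i, 1] + r))
        c0 <- max(0, floor(centers[i, 2] - r)); c1 <- min(field_size[2] - 1, ceiling(centers[i, 2] + r))
        rr <- r0:r1; cc <- c0:c1
        inside <- outer((rr - centers[i, 1])^2, (cc - centers[i, 2])^2, "+") <= r^2
        areas[i] <- sum(inside)
        sub <- img[rr + 1, cc + 1]
        sub[inside] <- intensity
        img[rr + 1, cc + 1] <- sub
      }
    }
    img <- apply_noise(img, noise)
    new_scene(img, img, centers = centers, cell_regions = list(),
              pair_interfaces = empty_interfaces(),
              perinuclear_spots = empty_spots(),
              cell_totals = numeric(0), phenotype = NULL, seed = seed,
              field_size = field_size, planted_areas = areas,
              planted_count = n_objects)
  })
}

#' Generate an invasion-filter scene
#'
#' Sparse, non-touching nuclear blobs emulating the DAPI-stained underside
#' of a Matrigel invasion filter; the planted count is the ground-truth
#' number of invasive nuclei.
#'
#' @param n_nuclei number of nuclei (>= 0).
#' @param field_size `(rows, cols)` pixels.
#' @param seed integer seed.
#' @param noise a [noise_params()] list.
#' @param nucleus_radius nominal nucleus radius (blob sd is half of it).
#' @param nuclear_amplitude peak blob intensity.
#' @return A `synthetic_scene` with `truth$planted_count = n_nuclei`.
#' @export
generate_invasion_filter <- function(n_nuclei, field_size = c(384, 384),
                                     seed = 1, noise = noise_params(),
                                     nucleus_radius = 4,
                                     nuclear_amplitude = 1000) {
  stopifnot(n_nuclei >= 0, length(field_size) == 2)
  with_scene_seed(seed, {
    img <- matrix(0, field_size[1], field_size[2])
    centers <- matrix(numeric(0), 0, 2)
    if (n_nuclei > 0) {
      min_sep <- 6 * nucleus_radius
      if (n_nuclei * min_sep^2 > prod(field_size)) {
        stop("placement failed: density too high for non-touching nuclei",
             call. = FALSE)
      }
      centers <- place_hardcore(n_nuclei, min_sep, field_size,
                                margin = 2 * nucleus_radius)
      colnames(centers) <- c("row", "col")
      for (i in seq_len(n_nuclei)) {
        img <- add_blob(img, centers[i, ], nucleus_radius / 2,
                        nuclear_amplitude)
      }
    }
    img <- apply_noise(img, noise)
    new_scene(img, matrix(0, field_size[1], field_size[2]), centers = centers,
              cell_regions = list(), pair_interfaces = empty_interfaces(),
              perinuclear_spots = empty_spots(), cell_totals = numeric(0),
              phenotype = NULL, seed = seed, field_size = field_size,
              planted_count = n_nuclei)
  })
}
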