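#' Write a synthetic scene to disk
#'
#' Writes the two channels as single-channel 16-bit TIFFs
#' (`<prefix>_dapi.tif`, `<prefix>_cadh.tif`), the ground truth as JSON
#' (`<prefix>_truth.json`) and the planted centers as CSV
#' (`<prefix>_centers.csv`, header `row,col`, 0-based pixel coordinates).
#' Intensities are floating point internally; each channel is linearly
#' scaled to the 16-bit range and the scaling (`offset`, `scale` with
#' `stored = (value - offset) / scale`) is recorded in the truth JSON so the
#' original values can be recovered without saturation.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_scene <- function(scene, dir, prefix = "scene") {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    dapi = file.path(dir, paste0(prefix, "_dapi.tif")),
    cadh = file.path(dir, paste0(prefix, "_cadh.tif")),
    truth = file.path(dir, paste0(prefix, "_truth.json")),
    centers = file.path(dir, paste0(prefix, "_centers.csv"))
  )
  sc_nuc <- write_tiff16(scene$nuclei_image, paths["dapi"])
  sc_cad <- write_tiff16(scene$cadherin_image, paths["cadh"])
  truth <- scene$truth
  json <- list(
    seed = scene$seed,
    field_size = truth$field_size,
    planted_count = truth$planted_count,
    centers = unname(as.matrix(truth$centers)),
    pair_interfaces = truth$pair_interfaces,
    perinuclear_spots = truth$perinuclear_spots,
    planted_areas = truth$planted_areas,
    phenotype = unclass(truth$phenotype),
    cell_regions = lapply(truth$cell_regions, unname),
    intensity_scaling = list(dapi = sc_nuc, cadh = sc_cad)
  )
  jsonlite::write_json(json, paths["truth"], auto_unbox = TRUE, digits = NA,
                       null = "null")
  centers <- as.data.frame(truth$centers)
  if (nrow(centers)) names(centers) <- c("row", "col")
  else centers <- data.frame(row = numeric(), col = numeric())
  utils::write.csv(centers, paths["centers"], row.names = FALSE)
  invisible(paths)
}

write_tiff16 <- function(image, path) {
  lo <- min(image); hi <- max(image)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((image - lo) / scale, path, bits.per.sample = 16,
                  compression = "none")
  list(offset = lo, scale = scale)
}

#' Read a scene channel written by [write_scene()]
#'
#' Restores the original intensity scale using the scaling metadata stored in
#' the truth JSON.
#'
#' @param tiff_path path to the channel TIFF.
#' @param truth_path path to the matching `_truth.json`.
#' @param channel `"dapi"` or `"cadh"`.
#' @return Numeric intensity matrix on the original scale.
#' @export
read_scene_channel <- function(tiff_path, truth_path,
                               channel = c("dapi", "cadh")) {
  channel <- match.arg(channel)
  img <- read_image(tiff_path)
  meta <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
  sc <- meta$intensity_scaling[[channel]]
  img * sc$scale + sc$offset
}

#' Read planted centers from a scene CSV
#'
#' @param path path to a `_centers.csv` written by [write_scene()].
#' @return A tibble with 0-based `row`, `col`.
#' @export
read_centers <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
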