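#' Write lifetime maps to 32-bit floating-point TIFF files
#'
#' One TIFF per channel (`lifetime_ch<k>.tif`), missing pixels stored as 0.
#' TIFF float samples live on the [0, 1] scale, so lifetimes are divided by
#' `scale` nanoseconds on disk; the sidecar records the scale along with the
#' pixel pitch and channel list.
#'
#' @param maps Named list of `lifetime_map` objects from
#'   [build_lifetime_map()].
#' @param dir Output directory (created if needed).
#' @param scale Nanoseconds mapped to full scale on disk.
#' @return Invisibly, the paths written.
#' @export
write_lifetime_maps <- function(maps, dir, scale = 100) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (m in maps) {
    stopifnot(inherits(m, "lifetime_map"))
    img <- m$lifetime
    img[is.na(img)] <- 0
    p <- file.path(dir, sprintf("lifetime_ch%d.tif", m$channel))
    tiff::writeTIFF(img / scale, p, bits.per.sample = 32L, reduce = FALSE)
    paths <- c(paths, p)
  }
  meta <- list(
    pixel_pitch_um = maps[[1]]$pixel_pitch,
    channels = vapply(maps, function(m) m$channel, integer(1)),
    missing_value = 0,
    lifetime_scale_ns = scale
  )
  mp <- file.path(dir, "lifetime_maps.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE)
  invisible(c(paths, mp))
}

#' Read a lifetime map written by [write_lifetime_maps()]
#'
#' @param path Path to the 32-bit TIFF.
#' @param pixel_pitch Pixel pitch, µm.
#' @param channel Channel id.
#' @param scale Nanoseconds at full scale, as recorded in the sidecar.
#' @return A `lifetime_map` (stored zeros become missing pixels).
#' @export
read_lifetime_map <- function(path, pixel_pitch = 20, channel = 2L,
                              scale = 100) {
  img <- tiff::readTIFF(path) * scale
  img[img <= 0] <- NA_real_
  lifetime_map(img, pixel_pitch = pixel_pitch, channel = channel)
}

#' Write a B-mode volume as a multi-page 8-bit TIFF plus JSON sidecar
#'
#' @param volume A `bmode_volume` from [reconstruct_volume()].
#' @param tif_path Output TIFF path.
#' @param json_path Output sidecar path; default replaces the extension.
#' @return Invisibly, the paths written.
#' @export
write_bmode <- function(volume, tif_path,
                        json_path = sub("\\.tiff?$", ".json", tif_path)) {
  stopifnot(inherits(volume, "bmode_volume"))
  pages <- lapply(seq_len(dim(volume$frames)[3]),
                  function(f) volume$frames[, , f] / 255)
  tiff::writeTIFF(pages, tif_path, bits.per.sample = 8L, reduce = FALSE)
  meta <- list(
    voxel_size_um = volume$voxel_size,
    dynamic_range_db = volume$dynamic_range,
    band_hz = volume$band,
    sound_speed_m_s = volume$sound_speed,
    volume_norm = volume$volume_norm
  )
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(tif_path, json_path))
}

#' Read a B-mode volume written by [write_bmode()]
#'
#' @param tif_path Path to the multi-page TIFF.
#' @param json_path Path to the JSON sidecar.
#' @return A `bmode_volume`.
#' @export
read_bmode <- function(tif_path,
                       json_path = sub("\\.tiff?$", ".json", tif_path)) {
  pages <- tiff::readTIFF(tif_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  frames <- array(0L, c(dim(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) {
    frames[, , f] <- as.integer(round(pages[[f]] * 255))
  }
  structure(
    list(frames = frames, voxel_size = meta$voxel_size_um,
         dynamic_range = meta$dynamic_range_db, band = meta$band_hz,
         sound_speed = meta$sound_speed_m_s, volume_norm = meta$volume_norm),
    class = "bmode_volume"
  )
}

#' Append homogeneity results to a longitudinal CSV
#'
#' @param results Tibble from [homogeneity_result()].
#' @param path CSV path; rows are appended when the file exists.
#' @return Invisibly, `path`.
#' @export
write_homogeneity <- function(results, path) {
  readr::write_csv(results, path, append = file.exists(path))
  invisible(path)
}
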