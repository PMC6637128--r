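#' Write an intensity volume as multi-page 32-bit float TIFF
#'
#' Minimal baseline TIFF writer (little-endian, uncompressed, one strip per
#' page, SampleFormat = IEEE float): pages are en-face z planes, rows run
#' along x. Pitch and provenance metadata are stored as a JSON string in the
#' first page's ImageDescription tag, so the file round-trips through
#' [read_volume_tiff()] without a sidecar.
#'
#' @param volume an [intensity_volume()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(volume, path) {
  stopifnot(inherits(volume, "intensity_volume"))
  v <- volume$values
  d <- dim(v)
  width <- d[3]; height <- d[2]; pages <- d[1]
  desc <- jsonlite::toJSON(list(axial_pitch_um = volume$axial_pitch_um,
                                lateral_pitch_um = volume$lateral_pitch_um,
                                provenance = volume$provenance,
                                log_scaled = volume$log_scaled,
                                n_frames = volume$n_frames),
                           auto_unbox = TRUE, digits = NA)
  desc_raw <- c(charToRaw(as.character(desc)), as.raw(0)) # nul-terminated

  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); w2(42L); w4(8L)   # header, first IFD at 8

  page_bytes <- width * height * 4
  tag <- function(id, type, count, value) c(id, type, count, value)
  offset <- 8
  for (p in seq_len(pages)) {
    has_desc <- p == 1
    n_tags <- 9L + as.integer(has_desc)
    ifd_size <- 2 + n_tags * 12 + 4
    desc_off <- offset + ifd_size
    data_off <- desc_off + if (has_desc) length(desc_raw) else 0
    next_ifd <- if (p < pages) data_off + page_bytes else 0

    w2(n_tags)
    tags <- list(
      tag(256L, 4L, 1L, width),          # ImageWidth
      tag(257L, 4L, 1L, height),         # ImageLength
      tag(258L, 3L, 1L, 32L),            # BitsPerSample
      tag(259L, 3L, 1L, 1L),             # Compression: none
      tag(262L, 3L, 1L, 1L))             # Photometric: BlackIsZero
    if (has_desc)
      tags <- c(tags, list(tag(270L, 2L, length(desc_raw), desc_off)))
    tags <- c(tags, list(
      tag(273L, 4L, 1L, data_off),       # StripOffsets
      tag(278L, 4L, 1L, height),         # RowsPerStrip
      tag(279L, 4L, 1L, page_bytes),     # StripByteCounts
      tag(339L, 3L, 1L, 3L)))            # SampleFormat: IEEE float
    for (t in tags) {
      w2(t[1]); w2(t[2]); w4(t[3])
      if (t[2] == 3L) { w2(t[4]); w2(0L) } else w4(t[4])
    }
    w4(next_ifd)
    if (has_desc) writeBin(desc_raw, con)
    writeBin(as.numeric(t(matrix(v[p, , ], d[2], d[3]))), con,
             size = 4, endian = "little")
    offset <- data_off + page_bytes
  }
  invisible(path)
}

#' Read a volume written by [write_volume_tiff()]
#'
#' @param path TIFF file path.
#' @return an [intensity_volume()].
#' @export
read_volume_tiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  r2 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  r4 <- function(off) sum(as.numeric(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  stopifnot(rawToChar(raw[1:2]) == "II", r2(2) == 42)
  ifd <- r4(4)
  pages <- list(); meta <- NULL
  width <- height <- NULL
  while (ifd != 0) {
    n_tags <- r2(ifd)
    entries <- list()
    for (t in seq_len(n_tags)) {
      base <- ifd + 2 + (t - 1) * 12
      id <- r2(base); type <- r2(base + 2); count <- r4(base + 4)
      val <- if (type == 3) r2(base + 8) else r4(base + 8)
      entries[[as.character(id)]] <- list(type = type, count = count,
                                          value = val)
    }
    width <- entries[["256"]]$value
    height <- entries[["257"]]$value
    if (!is.null(entries[["270"]]) && is.null(meta)) {
      off <- entries[["270"]]$value
      bytes <- raw[(off + 1):(off + entries[["270"]]$count)]
      meta <- jsonlite::fromJSON(rawToChar(bytes[bytes != as.raw(0)]))
    }
    doff <- entries[["273"]]$value
    nbytes <- entries[["279"]]$value
    vals <- readBin(raw[(doff + 1):(doff + nbytes)], "numeric",
                    n = nbytes / 4, size = 4, endian = "little")
    pages[[length(pages) + 1]] <- matrix(vals, nrow = height, byrow = TRUE)
    ifd <- r4(ifd + 2 + n_tags * 12)
  }
  arr <- array(0, c(length(pages), height, width))
  for (p in seq_along(pages)) arr[p, , ] <- pages[[p]]
  if (is.null(meta)) meta <- list(axial_pitch_um = 1, lateral_pitch_um = c(1, 1),
                                  provenance = "single-frame OCT",
                                  log_scaled = FALSE, n_frames = 1)
  intensity_volume(arr, meta$axial_pitch_um, meta$lateral_pitch_um,
                   provenance = meta$provenance, log_scaled = meta$log_scaled,
                   n_frames = meta$n_frames)
}

#' Export a volume as 8-bit dB-scaled TIFF values
#'
#' Display export: log-compress to dB relative to the maximum, clamp to a
#' stated dynamic-range window, and scale to 0..255. Returned (and written)
#' as a float TIFF holding the quantized 8-bit levels.
#'
#' @param volume linear-scale [intensity_volume()].
#' @param path output path, or `NULL` to only return the scaled volume.
#' @param dynamic_range_db window below the maximum (default 40).
#' @export
export_db_tiff <- function(volume, path = NULL, dynamic_range_db = 40) {
  stopifnot(inherits(volume, "intensity_volume"), !volume$log_scaled)
  v <- volume$values
  db <- 10 * log10(pmax(v, max(v) * 1e-12) / max(v))
  scaled <- round(pmin(pmax(db + dynamic_range_db, 0), dynamic_range_db) /
                    dynamic_range_db * 255)
  out <- volume
  out$values <- scaled
  out$log_scaled <- TRUE
  out$provenance <- "enhanced"
  if (!is.null(path)) write_volume_tiff(out, path)
  invisible(out)
}

#' Persist / restore a spectral frame set
#'
#' Bit-exact round trip of the raw frame container (data cube, source,
#' geometry, dispersion truth, noise level, seed) through a serialized file.
#'
#' @param frames a [simulate_frames()] result.
#' @param path file path.
#' @export
write_frameset <- function(frames, path) {
  stopifnot(inherits(frames, "spectral_frame_set"))
  saveRDS(frames, path, version = 3)
  invisible(path)
}

#' @rdname write_frameset
#' @export
read_frameset <- function(path) {
  fs <- readRDS(path)
  if (!inherits(fs, "spectral_frame_set")) stop("not a spectral frame set")
  fs
}

#' Write a contrast-versus-frames table as CSV
#'
#' @param tab result of [contrast_vs_frames()] (or its `$table`).
#' @param path output path.
#' @export
write_contrast_csv <- function(tab, path) {
  if (is.list(tab) && !is.data.frame(tab)) tab <- tab$table
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a phantom specification to a structured config list
#' @param spec a [phantom_spec()].
#' @export
phantom_to_config <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  list(extent_um = spec$extent_um,
       background_density = spec$background_density,
       background_reflectivity = spec$background_reflectivity,
       seed = spec$seed,
       regions = lapply(spec$regions, function(r) unclass(r)))
}

#' Build a phantom specification from a config list
#' @param cfg a list as produced by [phantom_to_config()] or parsed from the
#'   JSON config file.
#' @export
phantom_from_config <- function(cfg) {
  regions <- lapply(cfg$regions, function(r) {
    switch(r$type,
      layer = region_layer(r$z_min, r$z_max, r$density, r$mean_reflectivity),
      fascicle = region_fascicle(r$from, r$to, r$diameter_um, r$density,
                                 r$mean_reflectivity),
      tumor = region_tumor(r$center, r$radii, r$density, r$mean_reflectivity,
                           r$n_fingers %||% 0, r$finger_length_um %||% 60,
                           r$finger_width_um %||% 15),
      vessel = region_vessel(r$from, r$to, r$diameter_um,
                             r$attenuation_per_um),
      stop("unknown region type in config: ", r$type))
  })
  phantom_spec(cfg$extent_um, regions,
               background_density = cfg$background_density %||% 0,
               background_reflectivity = cfg$background_reflectivity %||% 0.1,
               seed = cfg$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
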