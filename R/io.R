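#' Write / read an OCT volume as multi-page TIFF
#'
#' Volumes are stored as one 32-bit float page per depth (z) plane in `[0, 1]`
#' normalized units, with the scale factor, voxel pitch and provenance in a
#' JSON sidecar (`<path>.json`). `read_volume_tiff()` restores calibrated
#' intensities.
#'
#' @param volume An [oct_volume()].
#' @param path Output TIFF path.
#' @return `write_volume_tiff()` returns `path` invisibly;
#'   `read_volume_tiff()` returns an [oct_volume()].
#' @export
write_volume_tiff <- function(volume, path) {
  stopifnot(inherits(volume, "oct_volume"))
  v <- volume$intensity
  scale <- max(v)
  if (scale <= 0) scale <- 1
  pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  sidecar <- list(kind = "oct_volume", scale = scale, pitch = volume$pitch,
                  log_scaled = volume$log_scaled,
                  grid_shape = dim(v), meta = volume$meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume_tiff
#' @export
read_volume_tiff <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar_path)) {
    abort(paste0("Volume TIFF or its JSON sidecar missing: ", path),
          class = "oct_io_error")
  }
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  gs <- c(length(pages), dim(pages[[1]]))
  v <- array(0, gs)
  for (z in seq_along(pages)) v[z, , ] <- pages[[z]]
  v <- v * side$scale
  oct_volume(v, pitch = side$pitch, log_scaled = isTRUE(side$log_scaled),
             meta = as.list(side$meta))
}

#' Write / read an integer label volume as multi-page TIFF
#'
#' Labels are scaled into `[0, 1]` by the maximum label (recorded in the JSON
#' sidecar) and restored by rounding, so round-trips are exact for label
#' counts well below 2^24.
#'
#' @param labels Integer or logical 3D array `(z, x, y)`.
#' @param path Output TIFF path.
#' @export
write_labels_tiff <- function(labels, path) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  lab <- labels
  storage.mode(lab) <- "integer"
  n <- max(lab, 1L)
  pages <- lapply(seq_len(dim(lab)[1]), function(z) lab[z, , ] / n)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(kind = "labels", n_labels = n, grid_shape = dim(lab)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_labels_tiff
#' @export
read_labels_tiff <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar_path)) {
    abort(paste0("Label TIFF or its JSON sidecar missing: ", path),
          class = "oct_io_error")
  }
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  v <- array(0, c(length(pages), dim(pages[[1]])))
  for (z in seq_along(pages)) v[z, , ] <- pages[[z]]
  lab <- round(v * side$n_labels)
  storage.mode(lab) <- "integer"
  lab
}

#' Append per-well metrics records to a tidy CSV
#'
#' @param records Tibble of metrics rows.
#' @param path CSV path.
#' @param append Append to an existing file (header written once).
#' @export
write_metrics_csv <- function(records, path, append = FALSE) {
  records <- select(records, !dplyr::where(is.list))
  if (append && file.exists(path)) {
    utils::write.table(records, path, sep = ",", row.names = FALSE,
                       col.names = FALSE, append = TRUE)
  } else {
    utils::write.csv(records, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
read_metrics_csv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Metrics CSV not found: ", path), class = "oct_io_error")
  }
  as_tibble(utils::read.csv(path))
}

#' Read a JSON or YAML run configuration
#'
#' @param path File ending in `.json`, `.yml` or `.yaml`.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Config file not found: ", path), class = "oct_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else {
    abort("Config must be .json, .yml or .yaml.", class = "oct_config_error")
  }
}

# Machine-readable provenance record: config hash + seed + version suffice to
# reproduce deterministic stages bit-for-bit.
write_provenance <- function(path, config, seed) {
  rec <- list(package = "octspheroid",
              version = as.character(utils::packageVersion("octspheroid")),
              seed = seed, config_hash = rlang::hash(config), config = config)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
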