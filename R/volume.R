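#' OCT intensity volume
#'
#' Container for a 3D OCT intensity array with voxel calibration. Axes are
#' ordered `(z, x, y)`: `z` is depth, `x` the fast lateral scan direction and
#' `y` the slow axis, so `intensity[, , y]` is one xz cross-sectional slice.
#' All quantitative analysis (segmentation thresholds, the 70%-above-mean
#' apoptotic rule) assumes linear intensity; `log_scaled` records whether the
#' array has been log-compressed for display.
#'
#' @param intensity Non-negative numeric 3D array `(z, x, y)`.
#' @param pitch Numeric length-3 vector, micrometres per voxel along
#'   `(z, x, y)`. All entries must be positive.
#' @param log_scaled Logical flag; `TRUE` if `intensity` is log-compressed.
#' @param meta Optional named list of provenance (acquisition or phantom
#'   parameters).
#'
#' @return An object of class `oct_volume`.
#' @examples
#' v <- oct_volume(array(0.1, c(8, 8, 4)), pitch = c(2, 2, 2))
#' dim(v$intensity)
#' @export
oct_volume <- function(intensity, pitch, log_scaled = FALSE, meta = list()) {
  if (!is.array(intensity) || length(dim(intensity)) != 3L) {
    abort("`intensity` must be a 3D array (z, x, y).", class = "oct_validation_error")
  }
  if (anyNA(intensity) || any(!is.finite(intensity))) {
    abort("`intensity` must be finite.", class = "oct_validation_error")
  }
  if (any(intensity < 0)) {
    abort("`intensity` must be non-negative.", class = "oct_validation_error")
  }
  pitch <- as.numeric(pitch)
  if (length(pitch) != 3L || any(!is.finite(pitch)) || any(pitch <= 0)) {
    abort("`pitch` must be three positive micrometre values (z, x, y).",
          class = "oct_validation_error")
  }
  structure(
    list(intensity = intensity, pitch = pitch,
         log_scaled = isTRUE(log_scaled), meta = meta),
    class = "oct_volume"
  )
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat("<oct_volume> ", d[1], " x ", d[2], " x ", d[3], " voxels (z, x, y)\n", sep = "")
  cat("  pitch (um):  ", paste(signif(x$pitch, 4), collapse = " x "), "\n", sep = "")
  ext <- d * x$pitch
  cat("  extent (um): ", paste(signif(ext, 4), collapse = " x "), "\n", sep = "")
  cat("  scale:       ", if (x$log_scaled) "log-compressed" else "linear", "\n", sep = "")
  invisible(x)
}

stopifnot_linear <- function(volume, what) {
  if (isTRUE(volume$log_scaled)) {
    abort(paste0(what, " requires linear intensity; this volume is log-compressed."),
          class = "oct_validation_error")
  }
}

#' Raw spectral-domain B-scan
#'
#' A single B-scan of raw interferograms: one real-valued spectrum per A-scan,
#' sampled linearly in wavenumber. Depth information lives in the oscillation
#' frequency of each spectrum and is recovered by [reconstruct_bscan()].
#'
#' @param spectra Numeric matrix, `a_scan x spectral_sample`; finite values.
#' @param pitch_lateral Micrometres between adjacent A-scans.
#' @param meta Optional named list.
#' @return An object of class `raw_bscan`.
#' @export
raw_bscan <- function(spectra, pitch_lateral = 1, meta = list()) {
  if (!is.matrix(spectra) || nrow(spectra) < 1L || ncol(spectra) < 2L) {
    abort("`spectra` must be a matrix with >= 1 A-scan and >= 2 spectral samples.",
          class = "oct_validation_error")
  }
  bad <- which(!apply(is.finite(spectra), 1L, all))
  if (length(bad)) {
    abort(paste0("Non-finite spectral values in A-scan(s) ",
                 paste(head(bad, 5L), collapse = ", "), "."),
          class = "oct_validation_error")
  }
  structure(list(spectra = spectra, a_scan_count = nrow(spectra),
                 pitch_lateral = pitch_lateral, meta = meta),
            class = "raw_bscan")
}

#' @export
print.raw_bscan <- function(x, ...) {
  cat("<raw_bscan> ", x$a_scan_count, " A-scans x ", ncol(x$spectra),
      " spectral samples\n", sep = "")
  invisible(x)
}
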