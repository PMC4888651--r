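#' Reconstruct a B-scan from raw spectra
#'
#' Standard spectral-domain OCT reconstruction: per A-scan the spectrum has
#' its mean (DC / reference term) removed, an apodization window applied, and
#' is Fourier transformed; the magnitude of the positive-frequency half gives
#' the depth profile. With `spectral_samples = M`, the output has `M / 2`
#' depth rows, and a reflector encoded at depth bin `k` (cosine of `k` cycles
#' across the spectrum) appears at output row `k`.
#'
#' The Hann window is the default apodization for measured spectra. For
#' synthetic spectra from [simulate_raw_spectra()], which are zero-phase
#' cosine combs at exact integer bins, use `window = "none"`: the rectangular
#' window is then exact by DFT orthogonality, whereas Hann's negative
#' side-coefficients cancel the interior of constant-reflectivity regions.
#'
#' @param raw A [raw_bscan()].
#' @param window Apodization: `"hann"` (default) or `"none"`.
#' @param log_scale If `TRUE`, return `log1p` of the magnitude (display only;
#'   keep `FALSE` for quantitative analysis).
#' @return Numeric matrix `depth x a_scan` of non-negative intensities.
#' @examples
#' sp <- matrix(cos(2 * pi * 12 * (0:127) / 128), nrow = 1, byrow = TRUE)
#' img <- reconstruct_bscan(raw_bscan(sp), window = "none")
#' which.max(img[, 1]) # depth bin 12
#' @export
reconstruct_bscan <- function(raw, window = c("hann", "none"), log_scale = FALSE) {
  if (!inherits(raw, "raw_bscan")) {
    abort("`raw` must be a raw_bscan object.", class = "oct_validation_error")
  }
  window <- match.arg(window)
  sp <- raw$spectra
  m <- ncol(sp)
  # DC removal per A-scan, then apodization along the spectral axis.
  sp <- sp - rowMeans(sp)
  if (window == "hann") {
    w <- 0.5 * (1 - cos(2 * pi * seq_len(m) / m))
    sp <- sweep(sp, 2L, w, `*`)
  }
  ft <- mvfft(t(sp))                 # spectral axis in rows
  half <- ft[seq(2L, m %/% 2 + 1L), , drop = FALSE] # positive frequencies, DC dropped
  img <- Mod(half)
  if (log_scale) img <- log1p(img)
  img
}

#' Stack reconstructed B-scans into a volume
#'
#' Frames are stacked along the slow (`y`) axis in the order given; the
#' acquisition geometry of the source system stacks 250 B-scans of
#' 2048 A-scans each into one volumetric image.
#'
#' @param bscans List of equally shaped `depth x a_scan` matrices.
#' @param pitch Micrometres per voxel along `(z, x, y)`.
#' @param log_scaled Whether the frames are log-compressed.
#' @param meta Provenance list.
#' @return An [oct_volume()].
#' @export
assemble_volume <- function(bscans, pitch, log_scaled = FALSE, meta = list()) {
  if (!length(bscans)) {
    abort("`bscans` must contain at least one frame.", class = "oct_validation_error")
  }
  d1 <- dim(bscans[[1]])
  for (i in seq_along(bscans)) {
    if (!identical(dim(bscans[[i]]), d1)) {
      abort(paste0("Frame ", i, " has shape ", paste(dim(bscans[[i]]), collapse = "x"),
                   "; expected ", paste(d1, collapse = "x"), "."),
            class = "oct_validation_error")
    }
  }
  vol <- array(unlist(bscans, use.names = FALSE), dim = c(d1, length(bscans)))
  oct_volume(vol, pitch = pitch, log_scaled = log_scaled, meta = meta)
}

#' Reconstruct a full volume from raw B-scans
#'
#' Convenience wrapper: reconstructs every [raw_bscan()] and assembles the
#' stack, optionally cropping the depth axis to the original extent (the FFT
#' returns `spectral_samples / 2` depth bins, which may exceed the imaged
#' depth).
#'
#' @inheritParams reconstruct_bscan
#' @param raws List of [raw_bscan()] objects.
#' @param pitch Micrometres per voxel along `(z, x, y)`.
#' @param depth Optional number of depth rows to keep.
#' @return An [oct_volume()].
#' @export
reconstruct_volume <- function(raws, pitch, window = c("hann", "none"), depth = NULL) {
  window <- match.arg(window)
  frames <- map(raws, function(r) {
    img <- reconstruct_bscan(r, window = window)
    if (!is.null(depth)) img <- img[seq_len(depth), , drop = FALSE]
    img
  })
  assemble_volume(frames, pitch = pitch,
                  meta = list(source = "reconstruct_volume", window = window))
}
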