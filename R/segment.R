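# Global Otsu over a vector of intensities, via EBImage's implementation.
# (EBImage::otsu thresholds each 2D frame separately; feeding the pooled
# nonzero intensities as a single frame yields the global threshold.)
otsu_vector <- function(v) {
  v <- v[is.finite(v)]
  if (!length(v)) return(Inf)
  r <- range(v)
  if (r[1] == r[2]) return(r[1])
  EBImage::otsu(EBImage::Image(matrix(v, nrow = 1L)), range = r, levels = 256L)
}

# Per-slice ledger rows for one labelled xz slice. Perimeter is estimated
# from boundary transition counts: a transition between z-neighbours exposes
# an edge of length pitch_x, between x-neighbours an edge of length pitch_z.
# "edge" reports the raw exposed-edge length (the Manhattan boundary);
# "crofton" multiplies by pi/4, the two-direction Cauchy-Crofton correction,
# which is asymptotically exact for smooth convex outlines.
slice_ledger <- function(lab2, pitch_z, pitch_x, estimator) {
  nlab <- max(lab2)
  if (nlab == 0L) return(NULL)
  area_px <- tabulate(lab2[lab2 > 0L], nbins = nlab)
  ez <- integer(nlab) # transitions between z-neighbours
  ex <- integer(nlab) # transitions between x-neighbours
  pad <- function(m, axis) {
    if (axis == 1L) rbind(0L, m, 0L) else cbind(0L, m, 0L)
  }
  count_dir <- function(m, axis) {
    p <- pad(m, axis)
    if (axis == 1L) { a <- p[-1L, , drop = FALSE]; b <- p[-nrow(p), , drop = FALSE] }
    else { a <- p[, -1L, drop = FALSE]; b <- p[, -ncol(p), drop = FALSE] }
    mism <- a != b
    tabulate(c(a[mism & a > 0L], b[mism & b > 0L]), nbins = nlab)
  }
  ez <- count_dir(lab2, 1L)
  ex <- count_dir(lab2, 2L)
  per <- ez * pitch_x + ex * pitch_z
  if (estimator == "crofton") per <- per * pi / 4
  list(slice_object = seq_len(nlab), area_px = area_px,
       area_um2 = area_px * pitch_z * pitch_x, perimeter_um = per)
}

#' Segment spheroid nodules in an OCT volume
#'
#' Foreground is found by a global threshold (Otsu over the nonzero voxels by
#' default) after optional 3x3x3 boxcar despeckling, cleaned by a per-slice
#' morphological opening, then labelled as 3D connected components. Each xz
#' cross-sectional slice additionally contributes a ledger of 2D objects with
#' calibrated perimeter and enclosed area, the per-slice accounting on which
#' the global surface-area-to-volume ratio is built.
#'
#' @param volume An [oct_volume()] with linear intensity.
#' @param threshold Fixed foreground threshold; `NULL` (default) uses Otsu on
#'   nonzero voxels.
#' @param smooth Apply the 3x3x3 boxcar before thresholding (recommended for
#'   speckled data; harmless on clean data).
#' @param opening_radius Radius in pixels of the per-slice opening used to
#'   remove isolated speckle; `0` disables it.
#' @param estimator Perimeter estimator: `"crofton"` (default; two-direction
#'   Cauchy-Crofton, accurate for rounded outlines) or `"edge"` (raw exposed
#'   pixel-edge length).
#' @return An object of class `nodule_labels`: list with `labels` (integer 3D
#'   array, 0 = background), `ledger` (tibble: `y_index`, `object_id` = 3D
#'   label, `slice_object`, `area_um2`, `perimeter_um`), `foreground_threshold`,
#'   `n_objects`, `total_volume_um3`, `total_surface_um2`, `pitch`,
#'   `estimator`. An empty foreground yields an empty ledger with a warning.
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(40, 56, 56),
#'                                     voxel_pitch = c(4, 4, 4),
#'                                     n_spheroids = 1, radius_range = c(50, 60)))
#' seg <- segment_nodules(ph$volume)
#' seg$n_objects
#' @export
segment_nodules <- function(volume, threshold = NULL, smooth = TRUE,
                            opening_radius = 1L,
                            estimator = c("crofton", "edge")) {
  stopifnot(inherits(volume, "oct_volume"))
  stopifnot_linear(volume, "Nodule segmentation")
  estimator <- match.arg(estimator)
  pitch <- volume$pitch
  x <- volume$intensity
  xs <- if (smooth) box3_mean(x) else x
  thr <- threshold %||% otsu_vector(xs[xs > 0])
  mask <- xs > thr
  if (any(mask) && opening_radius > 0L) {
    kern <- EBImage::makeBrush(2L * opening_radius + 1L, shape = "box")
    mask <- EBImage::opening(mask, kern) > 0
  }
  if (!any(mask)) {
    warn("No foreground voxels above threshold; returning empty segmentation.")
    return(structure(
      list(labels = array(0L, dim(x)), ledger = empty_ledger(),
           foreground_threshold = thr, n_objects = 0L,
           total_volume_um3 = 0, total_surface_um2 = 0,
           pitch = pitch, estimator = estimator),
      class = "nodule_labels"))
  }
  labels3 <- label3d(mask) # 3D-connected components (6-neighbourhood)
  ny <- dim(x)[3]
  rows <- vector("list", ny)
  for (y in seq_len(ny)) {
    sl <- mask[, , y]
    if (!any(sl)) next
    lab2 <- EBImage::bwlabel(sl)
    storage.mode(lab2) <- "integer"
    led <- slice_ledger(lab2, pitch[1], pitch[2], estimator)
    if (is.null(led)) next
    # map each 2D object to its 3D parent label via one member voxel
    first_vox <- match(led$slice_object, lab2)
    l3 <- labels3[, , y][first_vox]
    rows[[y]] <- tibble(
      y_index = y, object_id = as.integer(l3),
      slice_object = led$slice_object,
      area_um2 = led$area_um2, perimeter_um = led$perimeter_um
    )
  }
  ledger <- bind_rows(rows)
  structure(
    list(labels = labels3, ledger = ledger,
         foreground_threshold = thr,
         n_objects = as.integer(max(labels3)),
         total_volume_um3 = sum(ledger$area_um2) * pitch[3],
         total_surface_um2 = sum(ledger$perimeter_um) * pitch[3],
         pitch = pitch, estimator = estimator),
    class = "nodule_labels"
  )
}

empty_ledger <- function() {
  tibble(y_index = integer(), object_id = integer(), slice_object = integer(),
         area_um2 = numeric(), perimeter_um = numeric())
}

#' @export
print.nodule_labels <- function(x, ...) {
  cat("<nodule_labels> ", x$n_objects, " 3D object(s), ",
      nrow(x$ledger), " slice-ledger rows\n", sep = "")
  cat("  threshold: ", signif(x$foreground_threshold, 4),
      "  total volume: ", signif(x$total_volume_um3, 4), " um^3\n", sep = "")
  invisible(x)
}

#' Detect hyperscattering apoptotic bodies
#'
#' Within each segmented nodule, voxels brighter than `factor` times the
#' nodule's mean intensity (the 70%-above-mean rule at the default 1.7) form
#' the candidate mask. Candidate components are size-filtered, then touching
#' bodies are split by a distance-transform watershed seeded at distance
#' maxima. Because the threshold is relative to the nodule mean, the feature
#' mask is invariant under global intensity scaling.
#'
#' @param volume An [oct_volume()] with linear intensity.
#' @param nodules A [segment_nodules()] result for the same volume.
#' @param factor Threshold multiplier over the mean nodule intensity; must be
#'   positive. Default 1.7.
#' @param size_filter_radius_um Radii in micrometres of the equivalent
#'   spheres bounding feature size (default 4 and 40 um); converted to voxel
#'   count bounds at the volume's pitch.
#' @param mean_scope `"nodule"` (default) computes the reference mean per 3D
#'   nodule; `"global"` pools all nodule voxels.
#' @param smooth Apply the 3x3x3 boxcar before thresholding. Default `FALSE`:
#'   on clean data the sharp threshold recovers body volumes exactly. Set
#'   `TRUE` for speckled data, where per-voxel thresholding is meaningless;
#'   the averaging trades a partial-volume bias on the smallest bodies for
#'   suppression of speckle-driven false positives.
#' @param seed_min_separation_vox Minimum separation between watershed seeds,
#'   in voxels of the distance map; `NULL` (default) uses each seed's own
#'   distance value, i.e. one body radius.
#' @return An object of class `apoptotic_features`: list with `features`
#'   (tibble: `feature_id`, `n_voxels`, `volume_um3`, centroid voxel
#'   coordinates, `mean_intensity`, `nodule_id`), `label_array` (integer 3D
#'   array of feature labels), `thresholds` (per-nodule tibble), `factor`,
#'   `size_filter_vox`, `parent_nodule_volume_um3`, `pitch`.
#' @export
detect_apoptotic_bodies <- function(volume, nodules, factor = 1.7,
                                    size_filter_radius_um = c(4, 40),
                                    mean_scope = c("nodule", "global"),
                                    smooth = FALSE, seed_min_separation_vox = NULL) {
  stopifnot(inherits(volume, "oct_volume"), inherits(nodules, "nodule_labels"))
  stopifnot_linear(volume, "Apoptotic body detection")
  if (factor <= 0) abort("`factor` must be > 0.", class = "oct_validation_error")
  mean_scope <- match.arg(mean_scope)
  pitch <- volume$pitch
  voxvol <- vox_volume_um3(pitch)
  min_vox <- max(1L, round(4 / 3 * pi * size_filter_radius_um[1]^3 / voxvol))
  max_vox <- max(min_vox, round(4 / 3 * pi * size_filter_radius_um[2]^3 / voxvol))

  empty <- function() structure(
    list(features = empty_features(), label_array = array(0L, dim(volume$intensity)),
         thresholds = tibble(nodule_id = integer(), mean_intensity = numeric(),
                             threshold = numeric()),
         factor = factor, size_filter_vox = c(min_vox, max_vox),
         parent_nodule_volume_um3 = nodules$total_volume_um3, pitch = pitch),
    class = "apoptotic_features")

  if (nodules$n_objects == 0L) {
    warn("No segmented nodules; returning empty apoptotic feature set.")
    return(empty())
  }

  xs <- if (smooth) box3_mean(volume$intensity) else volume$intensity
  labels <- nodules$labels
  idx <- which(labels > 0L)
  labv <- labels[idx]
  sums <- rowsum(xs[idx], labv)
  cnts <- tabulate(labv, nbins = nodules$n_objects)
  mu <- as.numeric(sums[match(seq_len(nodules$n_objects), as.integer(rownames(sums)))]) / cnts
  if (mean_scope == "global") mu[] <- sum(xs[idx]) / length(idx)
  thr_tbl <- tibble(nodule_id = seq_len(nodules$n_objects),
                    mean_intensity = mu, threshold = factor * mu)

  cand <- array(FALSE, dim(xs))
  cand[idx] <- xs[idx] > factor * mu[labv]
  if (!any(cand)) {
    out <- empty()
    out$thresholds <- thr_tbl
    return(out)
  }

  cl <- label3d(cand)
  sizes <- tabulate(cl[cl > 0L])
  keep <- which(sizes >= min_vox & sizes <= max_vox)
  cand <- array(cl %in% keep, dim(xs)) & cand
  if (!any(cand)) {
    out <- empty()
    out$thresholds <- thr_tbl
    return(out)
  }

  w <- split_touching_bodies(cand, pitch, min_seed_sep_vox = seed_min_separation_vox)
  fsz <- tabulate(w[w > 0L])
  final <- which(fsz >= min_vox)
  if (!length(final)) {
    out <- empty()
    out$thresholds <- thr_tbl
    return(out)
  }

  gs <- dim(xs)
  feats <- map(seq_along(final), function(k) {
    l <- final[k]
    fv <- which(w == l)
    i0 <- fv - 1L
    zc <- i0 %% gs[1] + 1L
    xc <- (i0 %/% gs[1]) %% gs[2] + 1L
    yc <- i0 %/% (gs[1] * gs[2]) + 1L
    par <- labels[fv]
    par <- par[par > 0L]
    tibble(
      feature_id = k, n_voxels = length(fv),
      volume_um3 = length(fv) * voxvol,
      centroid_z = mean(zc), centroid_x = mean(xc), centroid_y = mean(yc),
      mean_intensity = mean(volume$intensity[fv]),
      nodule_id = if (length(par)) as.integer(names(sort(table(par), decreasing = TRUE))[1]) else NA_integer_
    )
  })
  relab <- array(0L, gs)
  for (k in seq_along(final)) relab[w == final[k]] <- k
  structure(
    list(features = bind_rows(feats), label_array = relab, thresholds = thr_tbl,
         factor = factor, size_filter_vox = c(min_vox, max_vox),
         parent_nodule_volume_um3 = nodules$total_volume_um3, pitch = pitch),
    class = "apoptotic_features")
}

empty_features <- function() {
  tibble(feature_id = integer(), n_voxels = integer(), volume_um3 = numeric(),
         centroid_z = numeric(), centroid_x = numeric(), centroid_y = numeric(),
         mean_intensity = numeric(), nodule_id = integer())
}

#' @export
print.apoptotic_features <- function(x, ...) {
  cat("<apoptotic_features> ", nrow(x$features), " feature(s), factor ",
      x$factor, ", size filter [", x$size_filter_vox[1], ", ",
      x$size_filter_vox[2], "] voxels\n", sep = "")
  invisible(x)
}

#' @rdname tidy_octspheroid
#' @export
tidy.nodule_labels <- function(x, ...) x$ledger

#' @rdname tidy_octspheroid
#' @export
tidy.apoptotic_features <- function(x, ...) x$features
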