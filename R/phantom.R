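#' Phantom specification
#'
#' Parameters of a synthetic OCT spheroid phantom. Defaults follow the
#' source imaging geometry and model system: nodules of 400-700 um diameter
#' (radius 200-350 um), a 2048 A-scan x 1.8 mm fast axis, 250 B-scans over
#' 600 um, and an axial pitch of half the 2.2 um axial resolution. Apoptosis
#' is rendered as small hyperscattering spheres (default 5-15 um radius)
#' placed preferentially at the nodule periphery; structural disruption is
#' rendered by [apply_fragmentation()]. Tests and examples typically override
#' `grid_shape`, `voxel_pitch` and `radius_range` with scaled-down values.
#'
#' @param grid_shape Integer length-3, voxels along `(z, x, y)`.
#' @param voxel_pitch Numeric length-3, micrometres per voxel `(z, x, y)`.
#' @param n_spheroids Number of nodules to place (may be 0).
#' @param radius_range Nodule radius range in micrometres `(min, max)`.
#' @param base_reflectivity Mean backscatter of nodule tissue (dimensionless).
#' @param background_reflectivity Backscatter of the surrounding medium.
#' @param fragmentation Fraction in `[0, 1]` of each nodule's voxels displaced
#'   into detached fragments.
#' @param apoptotic_fraction Target fraction in `[0, 1]` of nodule volume
#'   occupied by hyperscattering apoptotic bodies.
#' @param apoptotic_gain Multiplicative intensity of apoptotic bodies over the
#'   nodule base reflectivity; must exceed the detection factor (default 1.7)
#'   to be recoverable.
#' @param apoptotic_radius_range Apoptotic body radius range in micrometres.
#' @param periphery_bias Probability that a body is placed in the peripheral
#'   shell (55-92% of the nodule radius) rather than the core, reflecting the
#'   peripheral apoptosis pattern seen after chemotherapy alone.
#' @param speckle Logical; multiply intensities by fully developed speckle
#'   (unit-mean gamma noise).
#' @param speckle_looks Gamma shape parameter (number of looks); 1 gives the
#'   exponential intensity statistics of fully developed speckle.
#' @param attenuation_coeff Exponential attenuation per micrometre of depth;
#'   intensity is scaled by `exp(-2 * attenuation_coeff * depth_um)`.
#' @param seed Integer RNG seed; output is deterministic given the spec.
#'
#' @return A validated list of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(grid_shape = c(48, 64, 64), voxel_pitch = c(4, 4, 4),
#'                      n_spheroids = 1, radius_range = c(60, 80))
#' @export
phantom_spec <- function(grid_shape = c(1024L, 2048L, 250L),
                         voxel_pitch = c(1.1, 1800 / 2048, 600 / 250),
                         n_spheroids = 3,
                         radius_range = c(200, 350),
                         base_reflectivity = 1,
                         background_reflectivity = 0.05,
                         fragmentation = 0,
                         apoptotic_fraction = 0,
                         apoptotic_gain = 3,
                         apoptotic_radius_range = c(5, 15),
                         periphery_bias = 0.7,
                         speckle = FALSE,
                         speckle_looks = 1,
                         attenuation_coeff = 5e-4,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  voxel_pitch <- as.numeric(voxel_pitch)
  chk <- function(ok, msg) if (!ok) abort(msg, class = "oct_validation_error")
  chk(length(grid_shape) == 3L && all(grid_shape >= 1L), "`grid_shape` must be 3 positive integers.")
  chk(length(voxel_pitch) == 3L && all(voxel_pitch > 0), "`voxel_pitch` must be 3 positive values.")
  chk(n_spheroids >= 0, "`n_spheroids` must be >= 0.")
  chk(length(radius_range) == 2L && radius_range[1] > 0 && radius_range[1] <= radius_range[2],
      "`radius_range` must be positive and ordered (min, max).")
  extent <- grid_shape * voxel_pitch
  if (n_spheroids > 0) {
    chk(all(2 * radius_range[2] <= extent),
        "`radius_range` does not fit inside the grid: nodule diameter exceeds an axis extent.")
  }
  chk(fragmentation >= 0 && fragmentation <= 1, "`fragmentation` must be in [0, 1].")
  chk(apoptotic_fraction >= 0 && apoptotic_fraction <= 1, "`apoptotic_fraction` must be in [0, 1].")
  chk(apoptotic_gain > 0, "`apoptotic_gain` must be > 0.")
  chk(length(apoptotic_radius_range) == 2L && apoptotic_radius_range[1] > 0 &&
        apoptotic_radius_range[1] <= apoptotic_radius_range[2],
      "`apoptotic_radius_range` must be positive and ordered.")
  chk(periphery_bias >= 0 && periphery_bias <= 1, "`periphery_bias` must be in [0, 1].")
  chk(speckle_looks > 0, "`speckle_looks` must be > 0.")
  chk(attenuation_coeff >= 0, "`attenuation_coeff` must be >= 0.")
  chk(base_reflectivity > 0 && background_reflectivity >= 0,
      "Reflectivities must be positive (background may be 0).")
  structure(
    list(grid_shape = grid_shape, voxel_pitch = voxel_pitch,
         n_spheroids = as.integer(n_spheroids), radius_range = radius_range,
         base_reflectivity = base_reflectivity,
         background_reflectivity = background_reflectivity,
         fragmentation = fragmentation,
         apoptotic_fraction = apoptotic_fraction,
         apoptotic_gain = apoptotic_gain,
         apoptotic_radius_range = apoptotic_radius_range,
         periphery_bias = periphery_bias,
         speckle = isTRUE(speckle), speckle_looks = speckle_looks,
         attenuation_coeff = attenuation_coeff, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Depth attenuation profile along z (one value per z index, voxel centres).
attenuation_profile <- function(spec) {
  z_um <- (seq_len(spec$grid_shape[1]) - 0.5) * spec$voxel_pitch[1]
  exp(-2 * spec$attenuation_coeff * z_um)
}

# Render intensity from component masks; attenuation recycles along z (the
# first array dimension), speckle uses the current RNG stream.
render_intensity <- function(spec, nodule_mask, apoptotic_mask) {
  refl <- array(spec$background_reflectivity, spec$grid_shape)
  refl[nodule_mask] <- spec$base_reflectivity
  refl[apoptotic_mask] <- spec$apoptotic_gain * spec$base_reflectivity
  vol <- refl * attenuation_profile(spec)
  if (spec$speckle) {
    vol <- vol * rgamma(length(vol), shape = spec$speckle_looks,
                        rate = spec$speckle_looks)
  }
  vol
}

#' Generate a synthetic OCT spheroid phantom
#'
#' Places quasi-spherical nodules at non-overlapping random positions, adds
#' hyperscattering apoptotic bodies up to the requested volume fraction,
#' renders intensity as reflectivity x depth attenuation (x optional
#' speckle), and optionally displaces a fraction of each nodule into detached
#' fragments via [apply_fragmentation()]. Ground truth masks are returned
#' alongside the volume; `true_apoptotic_fraction` is the exact voxel-count
#' ratio and `true_sa_to_v` uses the same stacked-slice perimeter convention
#' as [global_sa_to_v()].
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` (an [oct_volume()]) and `truth`
#'   (class `phantom_truth`: `nodule_mask`, `fragment_labels`,
#'   `apoptotic_mask`, `true_apoptotic_fraction`, `true_sa_to_v`, `centers`,
#'   `radii`, `spec`).
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(40, 56, 56),
#'                                     voxel_pitch = c(4, 4, 4),
#'                                     n_spheroids = 1,
#'                                     radius_range = c(50, 60), seed = 3))
#' ph$truth$true_sa_to_v
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  gs <- spec$grid_shape
  pitch <- spec$voxel_pitch
  extent <- gs * pitch
  n <- spec$n_spheroids

  centers <- matrix(numeric(0), ncol = 3)
  radii <- numeric(0)
  if (n > 0) {
    centers <- matrix(NA_real_, nrow = n, ncol = 3)
    radii <- runif(n, spec$radius_range[1], spec$radius_range[2])
    # clearance between nodule surfaces: enough physical distance that the
    # 3x3x3 despeckle smoothing cannot bridge neighbours at any pitch
    sep_margin <- max(10, 4 * max(pitch))
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        cand <- vapply(1:3, function(ax) {
          lo <- radii[i] + pitch[ax]
          hi <- extent[ax] - radii[i] - pitch[ax]
          if (hi <= lo) (lo + hi) / 2 else runif(1, lo, hi)
        }, numeric(1))
        ok <- TRUE
        if (i > 1L) {
          d <- sqrt(colSums((t(centers[seq_len(i - 1L), , drop = FALSE]) - cand)^2))
          ok <- all(d > radii[i] + radii[seq_len(i - 1L)] + sep_margin)
        }
        if (ok) { centers[i, ] <- cand; placed <- TRUE; break }
      }
      if (!placed) {
        abort(paste0("Could not place spheroid ", i,
                     " without overlap after 200 attempts; reduce `n_spheroids` or `radius_range`."),
              class = "oct_placement_error")
      }
    }
  }

  labels <- array(0L, gs)
  for (i in seq_len(n)) {
    labels[sphere_indices(gs, pitch, centers[i, ], radii[i])] <- i
  }
  nodule_mask <- labels > 0L

  apoptotic_mask <- array(FALSE, gs)
  if (n > 0 && spec$apoptotic_fraction > 0) {
    for (i in seq_len(n)) {
      apoptotic_mask <- place_apoptotic_bodies(
        spec, labels, apoptotic_mask, nodule_id = i,
        center = centers[i, ], radius = radii[i]
      )
    }
  }

  vol <- render_intensity(spec, nodule_mask, apoptotic_mask)
  truth <- structure(
    list(nodule_mask = nodule_mask, fragment_labels = labels,
         apoptotic_mask = apoptotic_mask,
         true_apoptotic_fraction = if (any(nodule_mask)) sum(apoptotic_mask) / sum(nodule_mask) else 0,
         true_sa_to_v = if (any(nodule_mask)) mask_sa_to_v(nodule_mask, pitch) else NA_real_,
         centers = centers, radii = radii, voxel_loss = 0, spec = spec),
    class = "phantom_truth"
  )
  volume <- oct_volume(vol, pitch = pitch,
                       meta = list(source = "phantom", seed = spec$seed))
  out <- list(volume = volume, truth = truth)
  if (spec$fragmentation > 0 && n > 0) {
    out <- apply_fragmentation(out$volume, out$truth, spec$fragmentation)
  }
  out
}

# Fill one nodule with non-touching hyperscattering spheres up to the target
# voxel fraction. Placement prefers the peripheral shell; radii shrink toward
# the remaining budget so the achieved fraction lands close to the target.
place_apoptotic_bodies <- function(spec, labels, apoptotic_mask, nodule_id,
                                   center, radius) {
  gs <- spec$grid_shape
  pitch <- spec$voxel_pitch
  nod_vox <- sum(labels == nodule_id)
  target <- round(spec$apoptotic_fraction * nod_vox)
  if (target < 1L) return(apoptotic_mask)
  r_lo <- spec$apoptotic_radius_range[1]
  r_hi <- min(spec$apoptotic_radius_range[2], 0.45 * radius)
  r_hi <- max(r_hi, r_lo)
  voxvol <- vox_volume_um3(pitch)
  mean_body <- max(1, 4 / 3 * pi * mean(c(r_lo, r_hi))^3 / voxvol)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 80L * ceiling(target / mean_body) + 400L
  while (placed < target && attempts < max_attempts) {
    attempts <- attempts + 1L
    r_b <- runif(1, r_lo, r_hi)
    remaining <- target - placed
    r_need <- (3 * remaining * voxvol / (4 * pi))^(1 / 3)
    if (r_need < r_b) r_b <- max(r_lo, r_need)
    u_max <- max(radius - r_b - min(pitch), 0)
    frac <- if (runif(1) < spec$periphery_bias) runif(1, 0.55, 0.92) else runif(1, 0, 0.55)
    u <- frac * u_max
    dir <- rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    cen <- center + u * dir
    idx <- sphere_indices(gs, pitch, cen, r_b)
    if (!length(idx)) next
    if (any(labels[idx] != nodule_id)) next
    if (any(apoptotic_mask[dilate_indices(idx, gs)])) next
    if (placed + length(idx) > target + 0.5 * length(idx) && placed > 0L) next
    apoptotic_mask[idx] <- TRUE
    placed <- placed + length(idx)
  }
  if (placed < 0.9 * target) {
    warn(paste0("Nodule ", nodule_id, ": reached apoptotic fraction ",
                signif(placed / nod_vox, 3), " of requested ",
                signif(spec$apoptotic_fraction, 3), " after placement attempts."))
  }
  apoptotic_mask
}

#' Displace a fraction of each nodule into detached fragments
#'
#' Models the structural disruption and fragmentation that accompanies
#' treatment-induced loss of cell-cell adhesion: the requested voxel fraction
#' is peeled from the outside of each parent nodule and re-deposited as small
#' detached spheres in a shell around the parent, conserving total foreground
#' voxel count within 1% (placement losses are recorded in
#' `truth$voxel_loss`). Fragments never touch each other or remaining
#' nodules, so the fragment size cap bounds every new connected component.
#'
#' @param volume The phantom [oct_volume()].
#' @param truth The matching `phantom_truth`.
#' @param fragmentation Fraction in `[0, 1]` of each parent nodule's voxels
#'   to displace.
#' @param fragment_radius_range Fragment radius range in micrometres.
#' @param shell_width Base width in micrometres of the deposition shell
#'   around each parent (widened automatically when the displaced volume
#'   needs more room).
#' @param seed Optional seed; when `NULL` (default) the current RNG stream is
#'   used, which is how [generate_phantom()] keeps whole-phantom determinism.
#' @return A list `(volume, truth)` with updated intensity, masks, labels and
#'   recomputed `true_sa_to_v`.
#' @export
apply_fragmentation <- function(volume, truth, fragmentation,
                                fragment_radius_range = c(8, 20),
                                shell_width = 60, seed = NULL) {
  if (fragmentation < 0 || fragmentation > 1) {
    abort("`fragmentation` must be in [0, 1].", class = "oct_validation_error")
  }
  if (fragmentation == 0) return(list(volume = volume, truth = truth))
  run <- function() {
    apply_fragmentation_impl(volume, truth, fragmentation,
                             fragment_radius_range, shell_width)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

apply_fragmentation_impl <- function(volume, truth, fragmentation,
                                     fragment_radius_range, shell_width) {
  spec <- truth$spec
  gs <- spec$grid_shape
  pitch <- spec$voxel_pitch
  voxvol <- vox_volume_um3(pitch)
  labels <- truth$fragment_labels
  nodule_mask <- truth$nodule_mask
  apoptotic_mask <- truth$apoptotic_mask
  intensity <- volume$intensity
  att <- attenuation_profile(spec)
  n_before <- sum(nodule_mask)
  n_parents <- nrow(truth$centers)
  next_label <- max(labels)
  total_removed <- 0L
  total_placed <- 0L
  fr_lo <- fragment_radius_range[1]
  fr_hi <- fragment_radius_range[2]

  bg_fill <- function(idx) {
    v <- spec$background_reflectivity * att[((idx - 1L) %% gs[1]) + 1L]
    if (spec$speckle) v <- v * rgamma(length(idx), spec$speckle_looks, spec$speckle_looks)
    v
  }
  fg_fill <- function(idx) {
    v <- spec$base_reflectivity * att[((idx - 1L) %% gs[1]) + 1L]
    if (spec$speckle) v <- v * rgamma(length(idx), spec$speckle_looks, spec$speckle_looks)
    v
  }

  for (p in seq_len(n_parents)) {
    pvox <- which(labels == p)
    np <- length(pvox)
    if (!np) next
    n_remove <- round(fragmentation * np)
    if (n_remove < 1L) next
    # Peel from the outside in: drop the voxels farthest from the centre.
    i0 <- pvox - 1L
    zc <- (i0 %% gs[1] + 0.5) * pitch[1]
    xc <- ((i0 %/% gs[1]) %% gs[2] + 0.5) * pitch[2]
    yc <- (i0 %/% (gs[1] * gs[2]) + 0.5) * pitch[3]
    d2 <- (zc - truth$centers[p, 1])^2 + (xc - truth$centers[p, 2])^2 +
      (yc - truth$centers[p, 3])^2
    removed <- pvox[order(d2, decreasing = TRUE)[seq_len(n_remove)]]
    labels[removed] <- 0L
    nodule_mask[removed] <- FALSE
    apoptotic_mask[removed] <- FALSE
    intensity[removed] <- bg_fill(removed)
    total_removed <- total_removed + n_remove

    # Deposition shell: from just outside the shrunken core to the parent
    # radius plus a width sized so the displaced volume fits loosely.
    r_core <- (3 * (np - n_remove) * voxvol / (4 * pi))^(1 / 3)
    outer_r <- truth$radii[p] + shell_width
    need_um3 <- n_remove * voxvol
    repeat {
      shell_um3 <- 4 / 3 * pi * (outer_r^3 - r_core^3)
      if (shell_um3 >= 5 * need_um3 || outer_r > max(gs * pitch)) break
      outer_r <- outer_r * 1.25
    }
    placed <- 0L
    attempts <- 0L
    mean_frag <- max(1, 4 / 3 * pi * mean(c(fr_lo, fr_hi))^3 / voxvol)
    max_attempts <- 100L * ceiling(n_remove / mean_frag) + 400L
    while (placed < round(0.995 * n_remove) && attempts < max_attempts) {
      attempts <- attempts + 1L
      r_f <- runif(1, fr_lo, fr_hi)
      remaining <- n_remove - placed
      r_need <- (3 * remaining * voxvol / (4 * pi))^(1 / 3)
      if (r_need < r_f) r_f <- max(fr_lo * 0.5, r_need)
      u <- runif(1, max(r_core + r_f + min(pitch), 0), max(outer_r - r_f, r_core + r_f + min(pitch)))
      dir <- rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      cen <- truth$centers[p, ] + u * dir
      if (any(cen - r_f < 0) || any(cen + r_f > gs * pitch)) next
      idx <- sphere_indices(gs, pitch, cen, r_f)
      if (!length(idx)) next
      if (any(nodule_mask[dilate_indices(idx, gs)])) next
      overshoot <- placed + length(idx) - n_remove
      if (overshoot > 0.5 * length(idx) && remaining > mean_frag) next
      next_label <- next_label + 1L
      labels[idx] <- next_label
      nodule_mask[idx] <- TRUE
      intensity[idx] <- fg_fill(idx)
      placed <- placed + length(idx)
    }
    total_placed <- total_placed + placed
  }

  n_after <- sum(nodule_mask)
  loss <- (n_before - n_after) / max(n_before, 1L)
  if (abs(loss) > 0.01) {
    warn(paste0("Fragmentation changed foreground voxel count by ",
                signif(100 * loss, 3), "% (placement collisions)."))
  }
  truth$nodule_mask <- nodule_mask
  truth$fragment_labels <- labels
  truth$apoptotic_mask <- apoptotic_mask
  truth$true_apoptotic_fraction <-
    if (n_after) sum(apoptotic_mask) / n_after else 0
  truth$true_sa_to_v <- if (n_after) mask_sa_to_v(nodule_mask, pitch) else NA_real_
  truth$voxel_loss <- loss
  volume <- oct_volume(intensity, pitch = pitch, meta = volume$meta)
  list(volume = volume, truth = truth)
}

#' Simulate raw spectral interferograms from a volume
#'
#' Inverse of the FFT reconstruction: each A-scan's axial intensity profile
#' is encoded as a zero-phase cosine comb, depth index `j` mapping to `j`
#' cycles across the spectrum, on top of a constant reference (DC) level.
#' [reconstruct_bscan()] with `window = "none"` recovers the profile exactly
#' (up to conjugate symmetry); see that function for why the rectangular
#' window is the right pairing for these synthetic spectra.
#'
#' @param volume An [oct_volume()].
#' @param spectral_samples Samples per spectrum; must be at least twice the
#'   axial extent in voxels (default exactly twice).
#' @param dc_level Constant reference intensity added to every spectrum.
#' @return A list of [raw_bscan()] objects, one per y position.
#' @export
simulate_raw_spectra <- function(volume, spectral_samples = NULL, dc_level = 1) {
  stopifnot(inherits(volume, "oct_volume"))
  nz <- dim(volume$intensity)[1]
  m <- spectral_samples %||% (2L * nz)
  if (m < 2L * nz) {
    abort(paste0("`spectral_samples` (", m, ") must be >= 2 x axial extent (",
                 2L * nz, ") to avoid aliasing."),
          class = "oct_validation_error")
  }
  comb <- cos(2 * pi / m * outer(seq_len(nz), 0:(m - 1L)))
  ny <- dim(volume$intensity)[3]
  lapply(seq_len(ny), function(y) {
    sp <- t(volume$intensity[, , y]) %*% comb + dc_level
    raw_bscan(sp, pitch_lateral = volume$pitch[2],
              meta = list(y_index = y, depth_voxels = nz))
  })
}
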