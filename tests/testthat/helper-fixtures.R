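# Shared fixture builders. All phantoms here are scaled-down study
# conditions: coarser pitch and smaller grids than the instrument geometry,
# with nodule diameters kept large relative to both voxel and body sizes.

# Small phantom spec for fast structural tests (paper-sized nodules at 8 um).
small_spec <- function(...) {
  args <- utils::modifyList(
    list(grid_shape = c(64L, 96L, 96L), voxel_pitch = c(8, 8, 8),
         n_spheroids = 2L, radius_range = c(110, 150), seed = 3L),
    list(...))
  do.call(phantom_spec, args)
}

# Finer-pitched single-nodule spec for apoptotic-body work (bodies must span
# several voxels).
apoptotic_spec <- function(...) {
  args <- utils::modifyList(
    list(grid_shape = c(100L, 110L, 110L), voxel_pitch = c(2.5, 2.5, 2.5),
         n_spheroids = 1L, radius_range = c(105, 115),
         apoptotic_gain = 3, seed = 5L),
    list(...))
  do.call(phantom_spec, args)
}

# A volume holding one nodule that contains two bright bodies of radius
# `r_um` with centres `sep_um` apart (a "dumbbell" when they touch).
dumbbell_volume <- function(sep_um, r_um = 16, gain = 3, pitch = c(2, 2, 2)) {
  gs <- c(44L, 88L, 44L)
  v <- array(0.05, gs)
  ctr <- c(44, 88, 44)
  nod_r <- sep_um / 2 + r_um + 6
  v[octspheroid:::sphere_indices(gs, pitch, ctr, nod_r)] <- 1
  for (cx in c(ctr[2] - sep_um / 2, ctr[2] + sep_um / 2)) {
    v[octspheroid:::sphere_indices(gs, pitch, c(ctr[1], cx, ctr[3]), r_um)] <- gain
  }
  oct_volume(v, pitch)
}

# Digital ball mask of radius `r_vox` voxels at 1 um pitch.
ball_mask <- function(r_vox, margin = 4L) {
  n <- 2L * (r_vox + margin)
  gs <- c(n, n, n)
  m <- array(FALSE, gs)
  m[octspheroid:::sphere_indices(gs, c(1, 1, 1), rep(n / 2, 3), r_vox)] <- TRUE
  m
}

# Independent brute-force SA:V oracle: per-slice loops over pixels counting
# exposed edges and areas directly (no shared code with the implementation).
brute_sa_to_v <- function(mask, pitch, crofton = FALSE) {
  gs <- dim(mask)
  per_total <- 0
  area_total <- 0
  for (y in seq_len(gs[3])) {
    sl <- mask[, , y]
    if (!any(sl)) next
    for (z in seq_len(gs[1])) for (x in seq_len(gs[2])) {
      if (!sl[z, x]) next
      area_total <- area_total + pitch[1] * pitch[2]
      up <- if (z == 1L) FALSE else sl[z - 1L, x]
      dn <- if (z == gs[1]) FALSE else sl[z + 1L, x]
      lf <- if (x == 1L) FALSE else sl[z, x - 1L]
      rt <- if (x == gs[2]) FALSE else sl[z, x + 1L]
      per_total <- per_total + (!up) * pitch[2] + (!dn) * pitch[2] +
        (!lf) * pitch[1] + (!rt) * pitch[1]
    }
  }
  if (crofton) per_total <- per_total * pi / 4
  (per_total * pitch[3]) / (area_total * pitch[3])
}

# Independent two-sample pooled t oracle (textbook formula).
brute_ttest <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * stats::pt(-abs(t), df = na + nb - 2)
  list(t = t, p = p)
}
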