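# Internal 3D array helpers. Volumes are numeric arrays indexed (z, x, y):
# z is depth (axial), x the fast lateral scan, y the slow (B-scan) axis, so
# volume[, , y] is one xz cross-sectional slice.

# Shift a 3D array by `by` voxels along `axis`, filling vacated planes.
shift3 <- function(a, axis, by, fill = 0) {
  d <- dim(a)
  n <- d[axis]
  if (abs(by) >= n) {
    out <- array(fill, d)
    return(out)
  }
  idx <- lapply(d, seq_len)
  src <- idx
  dst <- idx
  if (by > 0) {
    src[[axis]] <- seq_len(n - by)
    dst[[axis]] <- seq_len(n - by) + by
  } else if (by < 0) {
    src[[axis]] <- seq_len(n + by) - by
    dst[[axis]] <- seq_len(n + by)
  } else {
    return(a)
  }
  out <- array(fill, d)
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Separable 3x3x3 boxcar mean with edge renormalisation (borders average
# over the in-grid neighbours only, so constant fields stay constant).
box3_mean <- function(a) {
  sm <- a
  w <- array(1, dim(a))
  for (ax in 1:3) {
    sm <- sm + shift3(sm, ax, 1L) + shift3(sm, ax, -1L)
    w <- w + shift3(w, ax, 1L) + shift3(w, ax, -1L)
  }
  sm / w
}

# Integer distance-to-background by iterative 6-neighbourhood erosion.
# Chebyshev-like city-block distance; exact enough to seed a watershed of
# small quasi-spherical bodies. Runs in O(radius) full-array passes.
erosion_distance <- function(mask) {
  d <- array(0L, dim(mask))
  cur <- mask
  k <- 0L
  while (any(cur)) {
    k <- k + 1L
    d[cur] <- k
    cur <- cur &
      shift3(cur, 1L, 1L, FALSE) & shift3(cur, 1L, -1L, FALSE) &
      shift3(cur, 2L, 1L, FALSE) & shift3(cur, 2L, -1L, FALSE) &
      shift3(cur, 3L, 1L, FALSE) & shift3(cur, 3L, -1L, FALSE)
  }
  d
}

# Linear indices of voxels whose centres fall inside a sphere of radius
# `radius_um` centred at `center_um` (micrometres), on a grid with the given
# shape (z, x, y) and per-axis pitch. Voxel centre of index i is (i - 0.5)*pitch.
sphere_indices <- function(grid_shape, pitch, center_um, radius_um) {
  rng <- vector("list", 3L)
  for (ax in 1:3) {
    lo <- max(1L, ceiling((center_um[ax] - radius_um) / pitch[ax] + 0.5))
    hi <- min(grid_shape[ax], floor((center_um[ax] + radius_um) / pitch[ax] + 0.5))
    if (lo > hi) return(integer(0))
    rng[[ax]] <- lo:hi
  }
  dz2 <- ((rng[[1]] - 0.5) * pitch[1] - center_um[1])^2
  dx2 <- ((rng[[2]] - 0.5) * pitch[2] - center_um[2])^2
  dy2 <- ((rng[[3]] - 0.5) * pitch[3] - center_um[3])^2
  r2 <- radius_um^2
  inside <- outer(outer(dz2, dx2, `+`), dy2, `+`) <= r2
  if (!any(inside)) return(integer(0))
  iz <- rep(rng[[1]], times = length(rng[[2]]) * length(rng[[3]]))
  ix <- rep(rep(rng[[2]], each = length(rng[[1]])), times = length(rng[[3]]))
  iy <- rep(rng[[3]], each = length(rng[[1]]) * length(rng[[2]]))
  lin <- iz + (ix - 1L) * grid_shape[1] + (iy - 1L) * grid_shape[1] * grid_shape[2]
  lin[as.vector(inside)]
}

# Dilate a set of linear voxel indices by one voxel (6-neighbourhood),
# clipping at the grid faces. Used for clearance checks during placement.
dilate_indices <- function(lin, grid_shape) {
  nz <- grid_shape[1]; nx <- grid_shape[2]; ny <- grid_shape[3]
  i0 <- lin - 1L
  z <- i0 %% nz
  x <- (i0 %/% nz) %% nx
  y <- i0 %/% (nz * nx)
  out <- c(
    lin,
    lin[z > 0L] - 1L, lin[z < nz - 1L] + 1L,
    lin[x > 0L] - nz, lin[x < nx - 1L] + nz,
    lin[y > 0L] - nz * nx, lin[y < ny - 1L] + nz * nx
  )
  unique(out)
}

vox_volume_um3 <- function(pitch) prod(pitch)

# True 3D connected components (6-neighbourhood) of a logical array, via the
# voxel adjacency graph. Components are numbered 1..k in order of their first
# voxel in raster (column-major) order, so labelling is deterministic.
label3d <- function(mask) {
  gs <- dim(mask)
  out <- array(0L, gs)
  idx <- which(mask)
  if (!length(idx)) return(out)
  rank <- array(0L, gs)
  rank[idx] <- seq_along(idx)
  i0 <- idx - 1L
  z <- i0 %% gs[1]
  x <- (i0 %/% gs[1]) %% gs[2]
  y <- i0 %/% (gs[1] * gs[2])
  edges <- list()
  step <- c(1L, gs[1], gs[1] * gs[2])
  coord <- list(z, x, y)
  for (ax in 1:3) {
    ok <- coord[[ax]] < gs[ax] - 1L
    nb <- idx[ok] + step[ax]
    has <- mask[nb]
    a <- rank[idx[ok][has]]
    b <- rank[nb[has]]
    edges[[ax]] <- rbind(a, b)
  }
  el <- do.call(cbind, edges)
  g <- igraph::make_graph(as.vector(el), n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership
  # renumber by first raster appearance
  first <- match(seq_len(max(memb)), memb)
  relab <- integer(max(memb))
  relab[order(first)] <- seq_len(max(memb))
  out[idx] <- relab[memb]
  out
}

# Regional maxima of a non-negative integer field over a mask: connected
# plateaus of constant value with no strictly greater 6-neighbour reachable
# through equal values. Domination (a greater neighbour) is propagated
# across equal-valued neighbours until a fixpoint.
regional_maxima <- function(d3, mask) {
  dom <- array(FALSE, dim(d3))
  for (ax in 1:3) for (s in c(1L, -1L)) {
    dom <- dom | (shift3(d3, ax, s, 0L) > d3)
  }
  dom <- dom & mask
  repeat {
    spread <- array(FALSE, dim(d3))
    for (ax in 1:3) for (s in c(1L, -1L)) {
      spread <- spread |
        (shift3(d3, ax, s, -1L) == d3 & shift3(dom, ax, s, FALSE))
    }
    spread <- spread & mask & !dom
    if (!any(spread)) break
    dom <- dom | spread
  }
  mask & !dom
}

# Deterministic distance-transform watershed for small quasi-spherical
# bodies: seeds are the 6-neighbourhood local maxima of the erosion-count
# distance (connected plateaus merged to their first raster voxel), thinned
# so that no seed lies within its own radius of a stronger seed; every voxel
# is then assigned to the nearest seed of its connected component.
split_touching_bodies <- function(mask, pitch, min_seed_sep_vox = NULL) {
  gs <- dim(mask)
  comp <- label3d(mask)
  ncomp <- max(comp)
  if (ncomp == 0L) return(comp)
  d3 <- erosion_distance(mask)
  plat <- label3d(regional_maxima(d3, mask))
  nseed <- max(plat)
  # seed position: centroid voxel of each maximal plateau (rounded), which
  # for a clean sphere is its centre; values/coords in voxel units
  sz <- sx <- sy <- sval <- scomp <- numeric(nseed)
  for (l in seq_len(nseed)) {
    pv <- which(plat == l)
    i0 <- pv - 1L
    sz[l] <- mean(i0 %% gs[1])
    sx[l] <- mean((i0 %/% gs[1]) %% gs[2])
    sy[l] <- mean(i0 %/% (gs[1] * gs[2]))
    sval[l] <- d3[pv[1]]
    scomp[l] <- comp[pv[1]]
  }
  seed_order_key <- sz + sx * gs[1] + sy * gs[1] * gs[2]
  # Greedy thinning, strongest first (raster tie-break): a seed lying within
  # a kept seed's own radius is a spurious ridge maximum of the same body
  # (the erosion distance at a body centre is its voxel radius + 1, hence
  # the +1 offset); the centre of a genuinely distinct touching body sits
  # beyond the stronger body's radius by construction.
  ord <- order(-sval, seed_order_key)
  keep <- logical(nseed)
  for (k in ord) {
    ok <- TRUE
    ki <- which(keep & scomp == scomp[k])
    if (length(ki)) {
      dd <- sqrt((sz[ki] - sz[k])^2 + (sx[ki] - sx[k])^2 + (sy[ki] - sy[k])^2)
      sep <- if (is.null(min_seed_sep_vox)) sval[ki] + 1 else min_seed_sep_vox
      ok <- all(dd > sep)
    }
    keep[k] <- ok
  }
  out <- array(0L, gs)
  lab_next <- 0L
  vox <- which(mask)
  vi0 <- vox - 1L
  vz <- (vi0 %% gs[1]) * pitch[1]
  vx <- ((vi0 %/% gs[1]) %% gs[2]) * pitch[2]
  vy <- (vi0 %/% (gs[1] * gs[2])) * pitch[3]
  szu <- sz * pitch[1]; sxu <- sx * pitch[2]; syu <- sy * pitch[3]
  vcomp <- comp[vox]
  for (cmp in seq_len(ncomp)) {
    sk <- which(keep & scomp == cmp)
    inc <- vcomp == cmp
    if (length(sk) <= 1L) {
      lab_next <- lab_next + 1L
      out[vox[inc]] <- lab_next
      next
    }
    dmat <- outer(vz[inc], szu[sk], `-`)^2 + outer(vx[inc], sxu[sk], `-`)^2 +
      outer(vy[inc], syu[sk], `-`)^2
    nearest <- max.col(-dmat, ties.method = "first")
    out[vox[inc]] <- lab_next + nearest
    lab_next <- lab_next + length(sk)
  }
  out
}
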