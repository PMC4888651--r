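test_that("an all-background volume yields an empty ledger with a warning", {
  v <- oct_volume(array(0, c(16, 16, 4)), c(1, 1, 1))
  expect_warning(seg <- segment_nodules(v), "foreground")
  expect_equal(seg$n_objects, 0L)
  expect_equal(nrow(seg$ledger), 0L)
})

test_that("a 10x10 square at 1 um pitch gives perimeter 40 and area 100 (edge rule)", {
  v <- array(0, c(16, 16, 3))
  v[4:13, 4:13, 2] <- 1
  seg <- segment_nodules(oct_volume(v, c(1, 1, 1)), threshold = 0.5,
                         smooth = FALSE, opening_radius = 0L, estimator = "edge")
  expect_equal(nrow(seg$ledger), 1L)
  expect_equal(seg$ledger$perimeter_um, 40)
  expect_equal(seg$ledger$area_um2, 100)
})

test_that("digital disk ledger matches area and perimeter bounds", {
  for (rho in c(10, 14)) {
    n <- 2 * (rho + 3)
    sl <- array(0, c(n, n, 3))
    ctr <- n / 2
    for (z in 1:n) for (x in 1:n) {
      if ((z - 0.5 - ctr)^2 + (x - 0.5 - ctr)^2 <= rho^2) sl[z, x, 2] <- 1
    }
    seg <- segment_nodules(oct_volume(sl, c(1, 1, 1)), threshold = 0.5,
                           smooth = FALSE, opening_radius = 0L)
    expect_equal(seg$ledger$area_um2, pi * rho^2, tolerance = 0.03)
    expect_equal(seg$ledger$perimeter_um, 2 * pi * rho, tolerance = 0.10)
    # edge estimator agrees with the independent brute-force edge count
    seg_e <- segment_nodules(oct_volume(sl, c(1, 1, 1)), threshold = 0.5,
                             smooth = FALSE, opening_radius = 0L, estimator = "edge")
    expect_equal(seg_e$ledger$perimeter_um * pi / 4, seg$ledger$perimeter_um)
    expect_equal(brute_sa_to_v(sl > 0.5, c(1, 1, 1)),
                 sum(seg_e$ledger$perimeter_um) / sum(seg_e$ledger$area_um2))
  }
})

test_that("a clean five-nodule phantom segments into exactly five 3D objects", {
  spec <- phantom_spec(grid_shape = c(80L, 112L, 112L), voxel_pitch = c(8, 8, 8),
                       n_spheroids = 5L, radius_range = c(120, 180), seed = 7L)
  seg <- segment_nodules(generate_phantom(spec)$volume)
  expect_equal(seg$n_objects, 5L)
  # every ledger row belongs to a live 3D object
  expect_true(all(seg$ledger$object_id %in% 1:5))
  expect_true(all(seg$ledger$area_um2 > 0))
  expect_true(all(seg$ledger$perimeter_um >= 0))
})

test_that("segmented totals agree with phantom ground truth", {
  ph <- generate_phantom(small_spec(seed = 23L))
  seg <- segment_nodules(ph$volume)
  true_vol <- sum(ph$truth$nodule_mask) * prod(ph$volume$pitch)
  expect_equal(seg$total_volume_um3, true_vol, tolerance = 0.10)
  expect_equal(global_sa_to_v(seg), ph$truth$true_sa_to_v, tolerance = 0.10)
})

test_that("a perfectly uniform nodule contains no apoptotic features", {
  v <- array(0.05, c(40, 40, 40))
  v[octspheroid:::sphere_indices(c(40, 40, 40), c(2, 2, 2), c(40, 40, 40), 30)] <- 1
  vol <- oct_volume(v, c(2, 2, 2))
  seg <- segment_nodules(vol, smooth = FALSE)
  f <- detect_apoptotic_bodies(vol, seg)
  expect_equal(nrow(f$features), 0L)
})

test_that("apoptotic threshold is relative: global scaling leaves masks unchanged", {
  vol <- dumbbell_volume(44)
  seg <- segment_nodules(vol)
  f1 <- detect_apoptotic_bodies(vol, seg)
  vol2 <- oct_volume(vol$intensity * 7.3, vol$pitch)
  seg2 <- segment_nodules(vol2)
  f2 <- detect_apoptotic_bodies(vol2, seg2)
  expect_identical(f1$label_array, f2$label_array)
  expect_equal(f2$thresholds$threshold, 7.3 * f1$thresholds$threshold)
})

test_that("six well-separated bright bodies are found as six features", {
  gs <- c(60L, 60L, 60L)
  pitch <- c(2.5, 2.5, 2.5)
  v <- array(0.05, gs)
  v[octspheroid:::sphere_indices(gs, pitch, c(75, 75, 75), 60)] <- 1
  centers <- rbind(c(45, 75, 75), c(105, 75, 75), c(75, 45, 75),
                   c(75, 105, 75), c(75, 75, 45), c(75, 75, 105))
  for (i in 1:6) v[octspheroid:::sphere_indices(gs, pitch, centers[i, ], 10)] <- 3
  vol <- oct_volume(v, pitch)
  f <- detect_apoptotic_bodies(vol, segment_nodules(vol, smooth = FALSE))
  expect_equal(nrow(f$features), 6L)
  expect_true(all(f$features$nodule_id == 1L))
  # calibrated volumes near the true 10 um sphere volume
  expect_equal(mean(f$features$volume_um3), 4 / 3 * pi * 10^3, tolerance = 0.15)
})

test_that("touching bright bodies are split into two by the watershed", {
  for (sep in c(34, 40, 52)) {
    f <- detect_apoptotic_bodies(dumbbell_volume(sep),
                                 segment_nodules(dumbbell_volume(sep)))
    expect_equal(nrow(f$features), 2L)
  }
  # exactly tangent spheres split when thresholding is unsmoothed
  vol <- dumbbell_volume(32)
  f0 <- detect_apoptotic_bodies(vol, segment_nodules(vol), smooth = FALSE)
  expect_equal(nrow(f0$features), 2L)
})

test_that("detection contracts: bad factor errors, empty nodules warn", {
  vol <- dumbbell_volume(44)
  seg <- segment_nodules(vol)
  expect_error(detect_apoptotic_bodies(vol, seg, factor = 0),
               class = "oct_validation_error")
  empty <- suppressWarnings(segment_nodules(oct_volume(array(0, c(8, 8, 8)), c(1, 1, 1))))
  expect_warning(f <- detect_apoptotic_bodies(vol, empty), "No segmented")
  expect_equal(nrow(f$features), 0L)
})

test_that("log-scaled volumes are refused for quantitative analysis", {
  v <- oct_volume(array(1, c(8, 8, 8)), c(1, 1, 1), log_scaled = TRUE)
  expect_error(segment_nodules(v), "linear", class = "oct_validation_error")
})
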