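test_that("empty phantom is pure background with empty truth", {
  ph <- generate_phantom(small_spec(n_spheroids = 0L))
  att <- octspheroid:::attenuation_profile(small_spec(n_spheroids = 0L))
  expect_false(any(ph$truth$nodule_mask))
  expect_false(any(ph$truth$apoptotic_mask))
  expect_equal(ph$truth$true_apoptotic_fraction, 0)
  # every A-scan is the attenuated background level
  expect_equal(ph$volume$intensity[, 1, 1], 0.05 * att)
})

test_that("phantom generation is deterministic for a fixed seed", {
  spec <- small_spec(fragmentation = 0.2, apoptotic_fraction = 0.05,
                     voxel_pitch = c(4, 4, 4), radius_range = c(60, 90),
                     speckle = TRUE, seed = 7L)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$intensity, b$volume$intensity)
  expect_identical(a$truth$fragment_labels, b$truth$fragment_labels)
  expect_identical(a$truth$apoptotic_mask, b$truth$apoptotic_mask)
})

test_that("achieved apoptotic fraction tracks the requested target", {
  ph <- generate_phantom(apoptotic_spec(apoptotic_fraction = 0.10))
  expect_equal(ph$truth$true_apoptotic_fraction, 0.10, tolerance = 0.01)
  # exact voxel-count identity
  expect_identical(
    ph$truth$true_apoptotic_fraction,
    sum(ph$truth$apoptotic_mask) / sum(ph$truth$nodule_mask))
  expect_true(all(ph$truth$nodule_mask[ph$truth$apoptotic_mask]))
})

test_that("impossible placement raises an error naming the spheroid", {
  spec <- phantom_spec(grid_shape = c(40L, 40L, 40L), voxel_pitch = c(4, 4, 4),
                       n_spheroids = 5L, radius_range = c(70, 75), seed = 1L)
  expect_error(generate_phantom(spec), "spheroid",
               class = "oct_placement_error")
})

test_that("spec validation rejects out-of-range parameters", {
  expect_error(small_spec(fragmentation = 1.5), class = "oct_validation_error")
  expect_error(small_spec(apoptotic_fraction = -0.1), class = "oct_validation_error")
  expect_error(small_spec(apoptotic_gain = 0), class = "oct_validation_error")
  expect_error(small_spec(radius_range = c(500, 600)), class = "oct_validation_error")
})

test_that("fragmentation 0 is the identity and conservation holds across levels", {
  ph <- generate_phantom(small_spec(seed = 11L))
  out <- apply_fragmentation(ph$volume, ph$truth, 0)
  expect_identical(out$volume$intensity, ph$volume$intensity)
  expect_identical(sort(unique(as.vector(out$truth$fragment_labels))), c(0L, 1L, 2L))
  for (f in c(0.1, 0.5)) {
    res <- apply_fragmentation(ph$volume, ph$truth, f, seed = 21L)
    expect_lt(abs(res$truth$voxel_loss), 0.01)
  }
})

test_that("surface-to-volume ground truth grows with fragmentation", {
  r01 <- generate_phantom(small_spec(fragmentation = 0.1, seed = 13L))
  r05 <- generate_phantom(small_spec(fragmentation = 0.5, seed = 13L))
  expect_gt(r05$truth$true_sa_to_v, r01$truth$true_sa_to_v)
})

test_that("full fragmentation leaves no component above the fragment cap", {
  spec <- small_spec(grid_shape = c(72L, 96L, 96L), radius_range = c(90, 110),
                     fragmentation = 1, seed = 17L)
  ph <- generate_phantom(spec)
  lab <- octspheroid:::label3d(ph$truth$nodule_mask)
  sizes <- tabulate(lab[lab > 0L])
  # max fragment radius 20 um, plus half a voxel of rasterization slack
  cap_vox <- 4 / 3 * pi * (20 + max(spec$voxel_pitch) / 2)^3 / prod(spec$voxel_pitch)
  expect_true(all(sizes <= ceiling(cap_vox)))
  expect_gt(max(lab), 5) # the nodules really did shatter
})

test_that("speckle is unit-mean multiplicative noise", {
  cl <- generate_phantom(small_spec(seed = 19L))
  sp <- generate_phantom(small_spec(seed = 19L, speckle = TRUE))
  fg <- cl$truth$nodule_mask
  ratio <- sp$volume$intensity[fg] / cl$volume$intensity[fg]
  expect_equal(mean(ratio), 1, tolerance = 0.02)
  # exponential intensity statistics: sd equals the mean for 1-look speckle
  expect_equal(sd(ratio), 1, tolerance = 0.05)
})
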