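test_that("square slice gives SA:V 0.4 under the edge convention", {
  m <- array(FALSE, c(16, 16, 3))
  m[4:13, 4:13, 2] <- TRUE
  expect_equal(mask_sa_to_v(m, c(1, 1, 1), estimator = "edge"), 0.4)
})

test_that("digital ball SA:V matches the stacked-circle analytic value", {
  r <- 20
  m <- ball_mask(r)
  got <- mask_sa_to_v(m, c(1, 1, 1)) # crofton default
  expect_equal(got, 3 * pi / (4 * r), tolerance = 0.10)
  # and agrees with the independent brute-force pixel-walk oracle
  expect_equal(got, brute_sa_to_v(m, c(1, 1, 1), crofton = TRUE), tolerance = 1e-12)
})

test_that("splitting a ball into disjoint half-size balls raises the ratio", {
  big <- ball_mask(16)
  small8 <- array(FALSE, c(48, 96, 96))
  k <- 0
  for (cz in c(24)) for (cx in c(24, 72)) for (cy in c(24, 72)) {
    k <- k + 1
    small8[octspheroid:::sphere_indices(c(48, 96, 96), c(1, 1, 1),
                                        c(cz, cx, cy), 8)] <- TRUE
  }
  # also place 4 more to make 8 total half-size balls
  for (cx in c(24, 72)) for (cy in c(24, 72)) {
    small8[octspheroid:::sphere_indices(c(48, 96, 96), c(1, 1, 1),
                                        c(40, cx - 8, cy - 8), 8)] <- TRUE
  }
  expect_gt(mask_sa_to_v(small8, c(1, 1, 1)), mask_sa_to_v(big, c(1, 1, 1)))
  # analytic: halving the radius doubles 3pi/(4r)
  expect_equal(mask_sa_to_v(small8, c(1, 1, 1)) / mask_sa_to_v(big, c(1, 1, 1)),
               2, tolerance = 0.1)
})

test_that("SA:V scales exactly inversely with voxel pitch", {
  m <- ball_mask(12)
  r1 <- mask_sa_to_v(m, c(1, 1, 1))
  r3 <- mask_sa_to_v(m, c(3, 3, 3))
  expect_equal(r3, r1 / 3, tolerance = 1e-12)
})

test_that("global ratio pools surfaces and volumes rather than averaging ratios", {
  ph <- generate_phantom(small_spec(radius_range = c(80, 150), seed = 29L))
  seg <- segment_nodules(ph$volume)
  led <- seg$ledger
  pooled <- sum(led$perimeter_um) / sum(led$area_um2)
  expect_equal(global_sa_to_v(seg), pooled, tolerance = 1e-12)
  per_object <- vapply(split(led, led$object_id),
                       function(d) sum(d$perimeter_um) / sum(d$area_um2), numeric(1))
  # with unequal nodules the mean of ratios differs from the pooled ratio
  expect_false(isTRUE(all.equal(mean(per_object), pooled, tolerance = 1e-6)))
})

test_that("disruption index and normalization contracts hold", {
  expect_equal(disruption_index(0.2, 0.2), 0)
  expect_equal(disruption_index(0.26, 0.20), 0.3)
  expect_error(disruption_index(0.2, 0), class = "oct_validation_error")
  expect_equal(normalize_to_control(0.02, 0.02), 1)
  expect_equal(normalize_to_control(0.05, 0.02), 2.5)
  expect_error(normalize_to_control(1, -1), class = "oct_validation_error")
  v <- c(0.3, 0.1, 0.7, 0.2)
  expect_identical(order(normalize_to_control(v, 0.2)), order(v))
})

test_that("empty ledgers give an undefined-metric error distinct from zero", {
  empty <- suppressWarnings(segment_nodules(oct_volume(array(0, c(8, 8, 8)), c(1, 1, 1))))
  expect_error(global_sa_to_v(empty), class = "oct_undefined_metric")
})

test_that("apoptotic density is the feature-to-spheroid volume fraction", {
  vol <- dumbbell_volume(44)
  seg <- segment_nodules(vol)
  f <- detect_apoptotic_bodies(vol, seg)
  expect_equal(apoptotic_density(f),
               sum(f$features$volume_um3) / seg$total_volume_um3)
  # empty feature set -> zero density, not an error
  v0 <- array(0.05, c(40, 40, 40))
  v0[octspheroid:::sphere_indices(c(40, 40, 40), c(2, 2, 2), c(40, 40, 40), 30)] <- 1
  vol0 <- oct_volume(v0, c(2, 2, 2))
  f0 <- detect_apoptotic_bodies(vol0, segment_nodules(vol0, smooth = FALSE))
  expect_equal(apoptotic_density(f0), 0)
})

test_that("apoptotic fraction is recovered across a parameter grid", {
  errs <- vapply(c(0.05, 0.15), function(f) {
    ph <- generate_phantom(apoptotic_spec(apoptotic_fraction = f))
    seg <- segment_nodules(ph$volume)
    fe <- detect_apoptotic_bodies(ph$volume, seg)
    abs(apoptotic_density(fe) - ph$truth$true_apoptotic_fraction)
  }, numeric(1))
  expect_lt(mean(errs), 0.02)
})

test_that("normalize_records adds control-relative columns per day", {
  rec <- tibble::tibble(
    well_id = paste0("w", 1:6),
    treatment = rep(c("NT", "PDT"), 3),
    day = rep(c(0, 1, 1), each = 2),
    sa_to_v = c(0.2, 0.3, 0.2, 0.4, 0.2, 0.5),
    apoptotic_density = c(0.02, 0.04, 0.02, 0.06, 0.02, 0.08))
  out <- normalize_records(rec, control = "NT")
  expect_equal(out$disruption_index[out$treatment == "NT"], rep(0, 3))
  expect_equal(out$normalized_sa_to_v[out$treatment == "NT"], rep(1, 3))
  expect_equal(out$disruption_index[2], 0.5)
  expect_equal(out$normalized_apoptotic_density[4], 3)
  expect_error(normalize_records(rec, control = "missing"),
               class = "oct_validation_error")
})
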