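test_that("phantom generation is bit-identical for the same spec and seed", {
  spec <- phantom_spec(scale = 0.6, seed = 9L)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$voxels, b$volume$voxels)
})

test_that("bone mask volume matches the analytic solid volume", {
  # single ellipsoid (no ala) so a closed-form volume oracle exists
  spec <- phantom_spec(
    bone_shape = list(body_center = c(0, 0, 0), body_semi = c(18, 12, 10),
                      ala_center = NULL, ala_semi = NULL,
                      cortical_thickness = 2),
    fragment_pose = NULL, with_rods = FALSE, noise_sd = 0)
  ph <- generate_phantom(spec)
  mid_hu <- (20 + (1.5 + 0.0829) / 0.0026) / 2  # soft tissue | cortical
  mask <- segment(ph$volume, mid_hu)
  analytic <- 4 / 3 * pi * prod(c(18, 12, 10))
  expect_lt(abs(mask_volume(mask) - analytic) / analytic, 0.02)
})

test_that("noiseless phantom round-trips the generating law to 1e-10", {
  ph <- noiseless_phantom()
  law <- fit_hu_to_density(sample_rods(ph$volume, ph$truth$rods))
  expect_equal(law$intercept, ph$truth$true_hu_to_density$intercept,
               tolerance = 1e-10)
  expect_equal(law$slope, ph$truth$true_hu_to_density$slope,
               tolerance = 1e-10)
})

test_that("phantom scene content: rods monotone, fragment metal, surfaces closed", {
  ph <- noiseless_phantom()
  s <- sample_rods(ph$volume, ph$truth$rods)
  expect_true(all(diff(s$mean_hu) > 0))
  fp <- ph$truth$spec$fragment_pose
  ctr <- fp$point + fp$length / 2 * fp$direction / sqrt(sum(fp$direction^2))
  idx <- round((ctr - ph$volume$origin) / ph$volume$spacing) + 1
  expect_gte(ph$volume$voxels[idx[1], idx[2], idx[3]], 2000)
  expect_true(is_watertight(ph$truth$true_surfaces$bone))
  expect_true(is_watertight(ph$truth$true_surfaces$fragment))
  for (ax in ph$truth$true_axes)
    expect_equal(sum(ax$direction^2), 1, tolerance = 1e-12)
})

test_that("invalid phantom specifications are rejected", {
  expect_error(phantom_spec(rod_densities = c(0, 0.1, 0.1, 0.15, 0.2)),
               "increasing")
  expect_error(phantom_spec(noise_sd = -1))
  expect_error(phantom_spec(voxel_spacing = 0))
})

test_that("post-drill scenes carry the pose and landmarks consistently", {
  ph <- noiseless_phantom()
  plans <- ph$truth$plans
  realized <- lapply(plans, function(pl) line3d(pl$entry, pl$direction))
  pose <- rigid_transform(rotation_about_axis(c(0, 0, 1), 10), c(5, 2, -1))
  pd <- simulate_postdrill_volume(ph$truth, realized, pose)
  expect_s3_class(pd, "ct_volume")
  expect_equal(pd$landmarks$post,
               transform_points(pose, pd$landmarks$plan), tolerance = 1e-12)
  expect_true(any(pd$voxels >= 2000))
  # realized axis missing the bone entirely is rejected
  miss <- list(S1 = line3d(c(0, 0, 300), c(1, 0, 0)))
  expect_error(simulate_postdrill_volume(ph$truth, miss, pose),
               "does not intersect")
})
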