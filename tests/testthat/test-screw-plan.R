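test_that("parametric screw geometry matches its specification", {
  spec <- screw_spec()
  s <- make_screw(spec)
  expect_true(is_watertight(s))
  bb <- apply(s$vertices, 2, range)
  expect_equal(bb[2, 3] - bb[1, 3],
               spec$length + spec$head_offset + spec$head_height,
               tolerance = 1e-9)
  expect_equal(bb[2, 1] - bb[1, 1], spec$head_diameter, tolerance = 1e-9)
  # shaft diameter measured at the tip ring
  tip <- s$vertices[, 3] < 1e-9
  expect_equal(max(sqrt(rowSums(s$vertices[tip, 1:2, drop = FALSE]^2))),
               spec$diameter / 2, tolerance = 1e-9)
})

test_that("smooth screw volume matches the cylinder-plus-head closed form", {
  spec <- screw_spec(thread = FALSE)
  s <- make_screw(spec, segments = 96)
  oracle <- pi * (spec$diameter / 2)^2 * (spec$length + spec$head_offset) +
    pi * (spec$head_diameter / 2)^2 * spec$head_height
  expect_lt(abs(mesh_volume(s) - oracle) / oracle, 0.01)
})

test_that("invalid screw dimensions are rejected", {
  expect_error(screw_spec(diameter = 0))
  expect_error(screw_spec(length = -1))
})

test_that("virtual insertion reports purchase and cortical crossings", {
  ph <- noiseless_phantom()
  tr <- ph$truth
  assy <- assembly(tr$true_surfaces$bone, tr$true_surfaces$fragment)
  for (pl in tr$plans) assy <- place_screw(assy, pl)
  expect_true(assy$plans$S1$bicortical)
  expect_equal(assy$plans$S1$cortex_crossings, 2L)
  expect_false(assy$plans$ALA$bicortical)
  expect_equal(assy$plans$ALA$cortex_crossings, 1L)
  expect_gt(assy$plans$ALA$inserted_length_mm,
            assy$plans$S1$inserted_length_mm)
  miss <- trajectory_plan("X", c(500, 0, 0), c(0, 0, 1))
  expect_error(place_screw(assy, miss), "does not intersect")
})

test_that("clearance check matches the parallel-cylinder closed form", {
  # fragment cylinder parallel to a planned screw, axis distance d:
  # surface distance = d - r_screw - r_frag
  frag <- transform_mesh(
    sacronav:::revolve_profile(c(2, 2), c(0, 30), 96),
    rigid_transform(diag(3), c(12, 0, 10)))
  plan <- trajectory_plan("S1", c(0, 0, 60), c(0, 0, -1),
                          screw_spec(length = 45, diameter = 6.5))
  cc <- check_collision(plan, frag, clearance = 1, segments = 96)
  expect_equal(cc$distance_mm, 12 - 3.25 - 2, tolerance = 0.05)
  expect_true(cc$pass)
})

test_that("a plan through the fragment collides with overlap volume", {
  frag <- transform_mesh(
    sacronav:::revolve_profile(c(2, 2), c(0, 30), 48),
    rigid_transform(diag(3), c(0, 0, 10)))
  plan <- trajectory_plan("S1", c(0, 0, 60), c(0, 0, -1))
  cc <- check_collision(plan, frag, clearance = 0.5)
  expect_equal(cc$distance_mm, 0)
  expect_true(cc$overlap)
  expect_false(cc$pass)
  # voxelization oracle: intersection of the two solids is non-empty
  screw <- transform_mesh(make_screw(plan$screw), screw_pose(plan))
  g <- as.matrix(expand.grid(seq(-4, 4, 0.5), seq(-4, 4, 0.5),
                             seq(5, 20, 0.5)))
  both <- points_in_mesh(g, screw) & points_in_mesh(g, frag)
  expect_gt(sum(both), 0)
})

test_that("touching surfaces pass at zero clearance by definition", {
  # parallel cylinders exactly touching: distance 0 counts as >= 0
  frag <- transform_mesh(
    sacronav:::revolve_profile(c(2, 2), c(0, 30), 96),
    rigid_transform(diag(3), c(5.25, 0, 10)))
  plan <- trajectory_plan("S1", c(0, 0, 60), c(0, 0, -1))
  cc <- check_collision(plan, frag, clearance = 0, segments = 96)
  expect_true(cc$pass)
})
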