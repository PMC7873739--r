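test_that("meshing a lattice-aligned cube conserves volume exactly", {
  mesh <- tetrahedralize(assembly(bone = make_box(c(0, 0, 0), c(1, 1, 1))), 0.5)
  expect_equal(sum(tet_volumes(mesh)), 1, tolerance = 1e-9)
  expect_true(all(tet_volumes(mesh) > 0))
  # midside nodes at exact edge midpoints
  el <- mesh$elements
  pairs <- rbind(c(1, 2), c(2, 3), c(1, 3), c(1, 4), c(2, 4), c(3, 4))
  for (m in 1:6) {
    mid <- (mesh$nodes[el[, pairs[m, 1]], ] + mesh$nodes[el[, pairs[m, 2]], ]) / 2
    expect_equal(mesh$nodes[el[, 4 + m], ], mid, tolerance = 1e-12)
  }
})

test_that("element count grows strictly under refinement", {
  assy <- assembly(bone = make_box(c(0, 0, 0), c(24, 12, 12)))
  n_coarse <- nrow(tetrahedralize(assy, 6)$elements)
  n_fine <- nrow(tetrahedralize(assy, 2)$elements)
  expect_gt(n_fine, n_coarse)
})

test_that("embedded screw shares interface nodes with the bone", {
  plan <- trajectory_plan("S1", c(10, 10, 20), c(0, 0, -1),
                          screw_spec(length = 16, diameter = 5,
                                     head_diameter = 8, head_height = 4,
                                     head_offset = 3))
  assy <- assembly(bone = make_box(c(0, 0, 0), c(20, 20, 20)))
  assy <- place_screw(assy, plan)
  mesh <- tetrahedralize(assy, 2)
  sn <- unique(as.vector(mesh$elements[mesh$part == "S1", ]))
  bn <- unique(as.vector(mesh$elements[mesh$part == "bone", ]))
  shared <- intersect(sn, bn)
  expect_gt(length(shared), 0)
  # the embedded interface is merged: no duplicated coordinates there
  deep <- shared[mesh$nodes[shared, 3] < 18]
  key <- apply(round(mesh$nodes[deep, , drop = FALSE], 9), 1, paste,
               collapse = ",")
  expect_false(anyDuplicated(key) > 0)
})

test_that("uniform-HU volumes give every bone element the same modulus", {
  vol <- ct_volume(array(300, c(30, 30, 30)), 1, origin = c(-1, -1, -1))
  mesh <- tetrahedralize(assembly(bone = make_box(c(0, 0, 0), c(24, 24, 24))), 3)
  model <- density_modulus_model()
  mesh <- assign_element_materials(mesh, vol, model)
  expected <- as.numeric(hu_to_modulus(model, 300))
  expect_equal(unique(mesh$E), expected, tolerance = 1e-12)
})

test_that("implant elements get the titanium constants regardless of HU", {
  plan <- trajectory_plan("S1", c(10, 10, 20), c(0, 0, -1),
                          screw_spec(length = 16, diameter = 5,
                                     head_diameter = 8, head_height = 4,
                                     head_offset = 3))
  assy <- place_screw(assembly(bone = make_box(c(0, 0, 0), c(20, 20, 20))), plan)
  vol <- ct_volume(array(150, c(36, 36, 36)), 1, origin = c(-4, -4, -4))
  mesh <- assign_element_materials(tetrahedralize(assy, 2), vol,
                                   density_modulus_model())
  expect_true(all(mesh$E[mesh$part == "S1"] == 114000))
  expect_true(all(mesh$nu[mesh$part == "S1"] == 0.3))
})

test_that("a two-phase volume maps to a bimodal modulus distribution", {
  vol <- ct_volume(array(100, c(30, 30, 30)), 1, origin = c(-1, -1, -1))
  vol$voxels[1:15, , ] <- 500
  mesh <- tetrahedralize(assembly(bone = make_box(c(0, 0, 0), c(24, 24, 24))), 3)
  model <- density_modulus_model()
  mesh <- assign_element_materials(mesh, vol, model)
  e1 <- as.numeric(hu_to_modulus(model, 100))
  e2 <- as.numeric(hu_to_modulus(model, 500))
  # away from the split plane every element sits at one of the two values
  pure <- abs(mesh$E - e1) < 1e-9 | abs(mesh$E - e2) < 1e-9
  expect_gt(mean(pure), 0.8)
  expect_true(any(abs(mesh$E - e1) < 1e-9) && any(abs(mesh$E - e2) < 1e-9))
})

test_that("meshes outside the volume bounds are rejected", {
  vol <- ct_volume(array(300, c(10, 10, 10)), 1)
  mesh <- tetrahedralize(assembly(bone = make_box(c(0, 0, 0), c(24, 24, 24))), 3)
  expect_error(assign_element_materials(mesh, vol, density_modulus_model()),
               "outside the volume")
})

test_that("node sets resolve the boundary-condition regions", {
  assy <- assembly(bone = make_box(c(0, 0, 0), c(30, 10, 12)))
  plan <- trajectory_plan("S1", c(15, 5, 12), c(0, 0, -1),
                          screw_spec(length = 9, diameter = 4,
                                     head_diameter = 6, head_height = 4,
                                     head_offset = 3))
  assy <- place_screw(assy, plan)
  mesh <- tetrahedralize(assy, 2)
  sets <- define_node_sets(mesh, list(depth = 2), 1 / 3,
                           head_spec = list(plan = plan))
  z <- mesh$nodes[, 3]
  bone_nodes <- unique(as.vector(mesh$elements[mesh$part == "bone", ]))
  zr <- range(z[bone_nodes])
  # caudal selection equals a brute-force coordinate filter on surface nodes
  expect_true(all(z[sets$fixed_caudal] <= zr[1] + diff(zr) / 3 + 1e-9))
  expect_true(all(z[sets$fixed_endplate] >= zr[2] - 2))
  # full caudal fraction selects every bone surface node
  sets_all <- define_node_sets(mesh, list(depth = 2), 1,
                               head_spec = list(plan = plan))
  expect_true(all(sets$fixed_caudal %in% sets_all$fixed_caudal))
  surf_bone <- intersect(sacronav:::boundary_nodes(mesh), bone_nodes)
  expect_setequal(sets_all$fixed_caudal, surf_bone)
  # head measurement band: middle third of the head's axial extent
  spec <- plan$screw
  s0 <- spec$length + spec$head_offset
  zh <- mesh$nodes[sets$head_measure, 3]
  band <- 12 + spec$head_offset + c(spec$head_height / 3,
                                    2 * spec$head_height / 3)
  expect_true(all(zh >= band[1] - 1e-6 & zh <= band[2] + 1e-6))
})
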