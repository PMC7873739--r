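test_that("surface of a voxel cube is watertight with spherical topology", {
  vol <- ct_volume(array(0, c(16, 16, 16)), 1)
  vol$voxels[5:12, 5:12, 5:12] <- 1000
  s <- extract_surface(segment(vol, 500))
  expect_true(is_watertight(s))
  expect_equal(max(mesh_components(s)), 1)
  expect_equal(mesh_genus(s), 0)
  expect_gt(mesh_volume(s), 0)  # oriented outward
})

test_that("sphere surface area is within 3 percent of the analytic value", {
  r <- 8
  s <- sphere_surface(r)
  expect_lt(abs(mesh_area(s) - 4 * pi * r^2) / (4 * pi * r^2), 0.03)
  expect_lt(abs(mesh_volume(s) - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3), 0.03)
})

test_that("disjoint blobs yield separately reported components", {
  vol <- ct_volume(array(0, c(30, 14, 14)), 1)
  vol$voxels[4:10, 4:10, 4:10] <- 1000
  vol$voxels[18:24, 4:10, 4:10] <- 1000
  m <- vol$voxels >= 500
  mask <- structure(list(mask = m, spacing = vol$spacing,
                         origin = vol$origin), class = "ct_mask")
  s <- extract_surface(mask)
  expect_equal(max(mesh_components(s)), 2)
})

test_that("empty masks are rejected", {
  mask <- structure(list(mask = array(FALSE, c(4, 4, 4)), spacing = rep(1, 3),
                         origin = rep(0, 3)), class = "ct_mask")
  expect_error(extract_surface(mask), "empty")
})

test_that("STL files round-trip through both encodings", {
  s <- make_box(c(0, 0, 0), c(2, 3, 4))
  for (binary in c(TRUE, FALSE)) {
    path <- tempfile(fileext = ".stl")
    write_stl(s, path, binary = binary)
    r <- read_stl(path)
    expect_equal(nrow(r$faces), nrow(s$faces))
    expect_equal(mesh_volume(r), 24, tolerance = 1e-5)
    expect_true(is_watertight(r))
    unlink(path)
  }
})

test_that("degenerate or out-of-bounds faces are rejected by the container", {
  v <- diag(3)
  expect_error(surface_mesh(v, matrix(c(1, 2, 2), 1)), "degenerate")
  expect_error(surface_mesh(v, matrix(c(1, 2, 4), 1)), "bounds")
})
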