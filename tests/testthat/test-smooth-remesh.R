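test_that("zero smoothing iterations return the identical mesh", {
  s <- sphere_surface(8)
  expect_identical(smooth_surface(s, 0, 0.7)$vertices, s$vertices)
})

test_that("default smoothing preserves enclosed volume within 2 percent", {
  s <- sphere_surface(8)
  sm <- smooth_surface(s, 6, 0.7)
  expect_lt(abs(mesh_volume(sm) - mesh_volume(s)) / mesh_volume(s), 0.02)
})

test_that("smoothing strictly reduces radial roughness of a noisy sphere", {
  s <- sphere_surface(8)
  set.seed(5)
  n <- s$vertices / sqrt(rowSums(s$vertices^2))
  noisy <- surface_mesh(s$vertices + n * rnorm(nrow(s$vertices), 0, 0.15),
                        s$faces)
  dev0 <- max(abs(sqrt(rowSums(noisy$vertices^2)) - 8))
  sm <- smooth_surface(noisy, 6, 0.7)
  dev1 <- max(abs(sqrt(rowSums(sm$vertices^2)) - 8))
  expect_lt(dev1, dev0)
})

test_that("open meshes are smoothed with a warning, boundary fixed", {
  s <- sphere_surface(8)
  open_mesh <- surface_mesh(s$vertices, s$faces[-(1:5), ])
  expect_warning(smooth_surface(open_mesh, 2, 0.5), "open")
})

test_that("remeshing reaches the target edge length and stays watertight", {
  s <- sphere_surface(8)
  rm6 <- remesh_uniform(s, 0.6)
  med <- median(edge_lengths(rm6))
  expect_gt(med, 0.45)
  expect_lt(med, 0.75)
  expect_true(is_watertight(rm6))
  vol <- 4 / 3 * pi * 8^3
  expect_lt(abs(mesh_volume(rm6) - vol) / vol, 0.03)
})

test_that("a target far above the object size still gives a valid coarse mesh", {
  s <- sphere_surface(8)
  rc <- remesh_uniform(s, 10)
  expect_true(is_watertight(rc))
  expect_lt(nrow(rc$faces), 200)
})

test_that("sharp cube edges survive remeshing within 0.05 mm", {
  bx <- make_box(c(-5, -5, -5), c(5, 5, 5))
  rc <- remesh_uniform(bx, 0.6, sharp_angle_deg = 60)
  expect_true(is_watertight(rc))
  tt <- seq(-5, 5, length.out = 81)
  edges_pts <- rbind(cbind(tt, 5, 5), cbind(tt, -5, -5),
                     cbind(5, tt, -5), cbind(-5, tt, 5),
                     cbind(5, -5, tt), cbind(-5, 5, tt))
  expect_lt(max(closest_point_on_mesh(edges_pts, rc)$distance), 0.05)
  expect_lt(abs(mesh_volume(rc) - 1000) / 1000, 0.01)
})

test_that("segment-extract-remesh preserves analytic volume end-to-end", {
  r <- 8
  vol <- sphere_volume(r)
  s <- remesh_uniform(extract_surface(segment(vol, 500)), 0.8)
  expect_lt(abs(mesh_volume(s) - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3), 0.03)
})
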