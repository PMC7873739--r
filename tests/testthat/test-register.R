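test_that("landmark registration of identical points is the identity", {
  set.seed(7)
  p <- matrix(rnorm(18), 6, 3)
  tr <- landmark_register(p, p)
  expect_equal(tr$rotation, diag(3), tolerance = 1e-12)
  expect_equal(tr$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_lt(attr(tr, "rms"), 1e-12)
})

test_that("landmark registration recovers a known rigid motion to 1e-10", {
  for (seed in c(1, 8, 77)) {
    set.seed(seed)
    p <- matrix(rnorm(24, sd = 20), 8, 3)
    R <- rotation_about_axis(rnorm(3), runif(1, 5, 170))
    t <- rnorm(3, sd = 30)
    q <- p %*% t(R) + matrix(t, 8, 3, byrow = TRUE)
    tr <- landmark_register(p, q)
    expect_lt(max(abs(tr$rotation - R)), 1e-10)
    expect_lt(max(abs(tr$translation - t)), 1e-9)
  }
})

test_that("reflective correspondences still yield a proper rotation", {
  set.seed(2)
  p <- matrix(rnorm(15, sd = 10), 5, 3)
  q <- p
  q[, 1] <- -q[, 1]  # mirror
  tr <- landmark_register(p, q)
  expect_gt(det(tr$rotation), 0)
  expect_gt(attr(tr, "rms"), 0.1)
})

test_that("collinear landmarks are rejected", {
  p <- cbind(1:5, 0, 0)
  expect_error(landmark_register(p, p + 1), "collinear|degenerate")
})

test_that("ICP refines a small known pose offset below 0.05 degrees", {
  s <- sphere_surface(8)
  # make the shape rotationally asymmetric so the pose is observable
  v <- s$vertices
  v[, 1] <- v[, 1] * (1 + 0.3 * tanh(v[, 3] / 4))
  target <- surface_mesh(v, s$faces)
  true_R <- rotation_about_axis(c(0, 1, 0.3), 2)
  moved <- transform_mesh(target, invert_transform(
    rigid_transform(true_R, c(0.5, -0.3, 0.2))))
  init <- rigid_transform(rotation_about_axis(c(0, 1, 0.3), 1), c(0, 0, 0))
  tr <- refine_register(moved, target, init)
  err <- rotation_angle_deg(t(tr$rotation) %*% true_R)
  expect_lt(err, 0.05)
  expect_true(is.finite(attr(tr, "rms")))
})

test_that("identical meshes under identity init converge immediately", {
  s <- sphere_surface(8)
  tr <- refine_register(s, s, rigid_transform())
  expect_lt(rotation_angle_deg(tr$rotation), 1e-4)
  expect_lt(attr(tr, "rms"), 1e-6)
})

test_that("non-overlapping meshes are rejected", {
  s <- sphere_surface(8)
  far <- transform_mesh(s, rigid_transform(diag(3), c(500, 0, 0)))
  expect_error(refine_register(far, s, rigid_transform()), "overlap")
})
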