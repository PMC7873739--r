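test_that("hemisphere selection recovers half the sphere area", {
  s <- sphere_surface(8)
  patch <- extract_contact_patch(s, list(direction = c(0, 0, 1),
                                         max_normal_angle_deg = 95,
                                         zlim = c(0, 10)))
  expect_lt(abs(mesh_area(patch) - 2 * pi * 8^2) / (2 * pi * 8^2), 0.03)
  expect_equal(max(mesh_components(patch)), 1)
})

test_that("selectors matching nothing are rejected", {
  s <- sphere_surface(8)
  expect_error(extract_contact_patch(
    s, list(direction = c(0, 0, 1), xlim = c(100, 110))), "no faces")
})

test_that("a flat patch with two tubes builds a genus-2 printable solid", {
  # flat square patch in the z = 0 plane, normals +z
  n <- 15
  g <- expand.grid(x = seq(-15, 15, length.out = n),
                   y = seq(-15, 15, length.out = n))
  V <- cbind(g$x, g$y, 0)
  id <- function(i, j) (j - 1) * n + i
  F <- do.call(rbind, lapply(1:(n - 1), function(j) {
    do.call(rbind, lapply(1:(n - 1), function(i)
      rbind(c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
            c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))))
  }))
  patch <- surface_mesh(V, F)
  plans <- list(
    A = trajectory_plan("A", c(-7, 0, 0), c(0, 0, -1)),
    B = trajectory_plan("B", c(7, 0, 0), c(0, 0, -1)))
  gs <- guide_spec()
  guide <- cached("flat_guide", build_guide(patch, plans, gs,
                                            resolution = 0.35))
  expect_true(is_watertight(guide))
  expect_equal(mesh_genus(guide), 2)
  # tube axes recovered from the inner channel walls within 0.1 degrees
  for (pl in plans) {
    ax <- line3d(pl$entry, pl$direction)
    d <- line_point_distance(ax, guide$vertices)
    s_ax <- (guide$vertices - matrix(pl$entry, nrow(guide$vertices), 3,
                                     byrow = TRUE)) %*% (-pl$direction)
    sel <- d < gs$tube_inner_diameter / 2 + 0.25 & s_ax > 1 &
      s_ax < gs$tube_length - 1
    fit <- fit_cylinder_axis(guide$vertices[sel, ], solid = FALSE)
    expect_lt(angle_between(fit, ax), 0.1)
  }
})

test_that("zero shell thickness is rejected", {
  expect_error(guide_spec(shell_thickness = 0), "shell_thickness")
  expect_error(guide_spec(tube_inner_diameter = 8, tube_outer_diameter = 7))
})

test_that("plans missing the patch footprint are named in the error", {
  s <- sphere_surface(8)
  patch <- extract_contact_patch(s, list(direction = c(0, 0, 1),
                                         max_normal_angle_deg = 45))
  far <- list(Q = trajectory_plan("Q", c(80, 0, 0), c(0, 0, -1)))
  expect_error(build_guide(patch, far, guide_spec()), "Q")
})

test_that("part comparison distances are signed, clipped and summarised", {
  s <- sphere_surface(8)
  same <- compare_cast_to_pattern(s, s)
  expect_lt(max(abs(same$signed_distance)), 1e-9)
  # concentric spheres: inner vs outer reads approximately -delta
  inner <- surface_mesh(s$vertices * (6.5 / 8), s$faces)
  d <- compare_cast_to_pattern(inner, s)
  expect_equal(mean(d$signed_distance), -1.5, tolerance = 0.1)
  expect_equal(min(d$clipped), -1)          # clipped at the render scale
  expect_gt(abs(d$stats$p95_abs), 1)        # stats keep the true magnitude
})
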