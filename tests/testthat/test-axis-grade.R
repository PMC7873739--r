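test_that("line-to-line angle is symmetric, orientation-free and bounded", {
  a <- line3d(c(0, 0, 0), c(1, 0, 0))
  b <- line3d(c(5, 1, 2), c(1, 1, 0))
  expect_equal(angle_between(a, a), 0)
  expect_equal(angle_between(a, b), 45, tolerance = 1e-12)
  expect_equal(angle_between(b, a), angle_between(a, b))
  expect_equal(angle_between(a, line3d(c(0, 0, 0), c(-1, 0, 0))), 0)
  set.seed(3)
  for (i in 1:20) {
    u <- line3d(c(0, 0, 0), rnorm(3))
    v <- line3d(c(0, 0, 0), rnorm(3))
    ang <- angle_between(u, v)
    expect_gte(ang, 0); expect_lte(ang, 90)
  }
})

test_that("cylinder axis fit is exact on noiseless surface points", {
  th <- seq(0, 2 * pi, length.out = 37)[-37]
  z <- seq(0, 40, by = 2)
  pts0 <- cbind(as.vector(outer(1.25 * cos(th), rep(1, length(z)))),
                as.vector(outer(1.25 * sin(th), rep(1, length(z)))),
                as.vector(outer(rep(1, length(th)), z)))
  R <- rotation_about_axis(c(1, 2, 0.5), 33)
  pts <- pts0 %*% t(R) + matrix(c(4, -2, 7), nrow(pts0), 3, byrow = TRUE)
  ax <- fit_cylinder_axis(pts, expected_diameter = 2.5, solid = FALSE)
  truth <- line3d(c(4, -2, 7), as.numeric(R %*% c(0, 0, 1)))
  expect_lt(angle_between(ax, truth), 1e-6)
  expect_equal(attr(ax, "radius"), 1.25, tolerance = 1e-9)
})

test_that("noisy cylinder points still give the axis within 0.5 degrees", {
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  z <- seq(0, 40, by = 1)
  base <- cbind(as.vector(outer(1.25 * cos(th), rep(1, length(z)))),
                as.vector(outer(1.25 * sin(th), rep(1, length(z)))),
                as.vector(outer(rep(1, length(th)), z)))
  for (seed in c(1, 5, 12, 23)) {
    set.seed(seed)
    pts <- base + matrix(rnorm(length(base), 0, 0.05), ncol = 3)
    ax <- fit_cylinder_axis(pts, solid = FALSE)
    expect_lt(angle_between(ax, line3d(c(0, 0, 0), c(0, 0, 1))), 0.5)
  }
})

test_that("isotropic point clouds are rejected as axisless", {
  set.seed(9)
  u <- matrix(rnorm(600), ncol = 3)
  sph <- 5 * u / sqrt(rowSums(u^2))
  expect_error(fit_cylinder_axis(sph), "dominant axis|isotropic")
})

test_that("Gertzbein-Robbins bands map breach distance to grades", {
  bone <- make_box(c(-20, -20, 0), c(20, 20, 40))
  screw <- screw_spec(length = 30, diameter = 6.5)
  corridor <- list(axis = line3d(c(0, 0, -10), c(0, 0, 1)), radius = 5)
  contained <- grade_trajectory(line3d(c(0.5, 0, -5), c(0, 0, 1)), screw,
                                bone, corridor)
  expect_equal(contained$grade, "A")
  expect_equal(contained$breach_mm, 0)
  # parallel offset d: breach = d + r_screw - r_corridor exactly
  b1 <- grade_trajectory(line3d(c(2.75, 0, -5), c(0, 0, 1)), screw, bone,
                         corridor)
  expect_equal(b1$breach_mm, 1, tolerance = 1e-9)
  expect_equal(b1$grade, "B")
  b3 <- grade_trajectory(line3d(c(4.95, 0, -5), c(0, 0, 1)), screw, bone,
                         corridor)
  expect_equal(b3$breach_mm, 3.2, tolerance = 1e-9)
  expect_equal(b3$grade, "C")
  b7 <- grade_trajectory(line3d(c(8.75, 0, -5), c(0, 0, 1)), screw, bone,
                         corridor)
  expect_equal(b7$breach_mm, 7, tolerance = 1e-9)
  expect_equal(b7$grade, "E")
})
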