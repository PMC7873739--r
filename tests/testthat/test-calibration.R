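test_that("rod sampling on a noiseless phantom reproduces generating HU", {
  ph <- noiseless_phantom()
  s <- sample_rods(ph$volume, ph$truth$rods)
  inv <- law_invert(ph$truth$true_hu_to_density)
  expect_equal(s$mean_hu, law_eval(inv, ph$truth$rods$densities),
               tolerance = 1e-12)
})

test_that("rod means over a constant field equal the constant", {
  vol <- ct_volume(array(100, c(40, 60, 40)), 1, origin = c(-20, -30, -20))
  rods <- rod_geometry(cbind(c(-10, 0, 10), 0, 0), radius = 5, axis = 2,
                       half_length = 20, densities = c(0, 0.1, 0.2))
  s <- sample_rods(vol, rods)
  expect_equal(s$mean_hu, rep(100, 3))
})

test_that("noisy rod means and fitted slope behave like sample statistics", {
  for (seed in c(3, 11, 29)) {
    ph <- generate_phantom(phantom_spec(noise_sd = 40, seed = seed,
                                        scale = 0.7))
    s <- sample_rods(ph$volume, ph$truth$rods)
    inv <- law_invert(ph$truth$true_hu_to_density)
    truth <- law_eval(inv, ph$truth$rods$densities)
    # 4 sigma / sqrt(n) CLT bound per rod mean
    expect_true(all(abs(s$mean_hu - truth) <= 4 * 40 / sqrt(s$n_voxels)))
    # slope perturbation is of order sigma/sqrt(n): generous empirical cap
    law <- fit_hu_to_density(s)
    expect_lt(abs(law$slope - 0.0026), 5e-4)
  }
})

test_that("calibration fit recovers an exact linear relationship", {
  s <- data.frame(mean_hu = c(0, 100, 250, 400, 800),
                  known_density = 0.001 * c(0, 100, 250, 400, 800))
  law <- fit_hu_to_density(s)
  expect_equal(law$slope, 0.001, tolerance = 1e-12)
  expect_equal(law$intercept, 0, tolerance = 1e-12)
  expect_equal(attr(law, "r_squared"), 1)
})

test_that("calibration on samples synthesized from the clinical law returns it", {
  gen <- linear_law(-0.0829, 0.0026, "HU", "g/cm^3")
  hu <- c(31.9, 51.1, 70.3, 89.6, 108.8)
  s <- data.frame(mean_hu = hu, known_density = law_eval(gen, hu))
  law <- fit_hu_to_density(s)
  expect_equal(law$intercept, -0.0829, tolerance = 1e-10)
  expect_equal(law$slope, 0.0026, tolerance = 1e-10)
})

test_that("OLS fit equals the closed-form normal equations", {
  set.seed(4)
  hu <- c(30, 50, 70, 90, 110)
  dens <- -0.08 + 0.0026 * hu + rnorm(5, 0, 0.004)
  law <- fit_hu_to_density(data.frame(mean_hu = hu, known_density = dens))
  X <- cbind(1, hu)
  beta <- solve(crossprod(X), crossprod(X, dens))
  expect_equal(law$intercept, beta[1], tolerance = 1e-12)
  expect_equal(law$slope, beta[2], tolerance = 1e-12)
})

test_that("degenerate calibrations are rejected", {
  expect_error(fit_hu_to_density(data.frame(mean_hu = 5, known_density = 1)),
               "two rods")
  expect_error(fit_hu_to_density(
    data.frame(mean_hu = c(5, 5), known_density = c(0, 0.1))), "degenerate")
})
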