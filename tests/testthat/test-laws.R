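test_that("linear laws evaluate and invert exactly", {
  law <- linear_law(0.5, 0.25, "a", "b")
  expect_identical(law_eval(law, c(0, 2, -4)), c(0.5, 1.0, -0.5))
  inv <- law_invert(law)
  x <- c(-3.2, 0, 17.5)
  expect_equal(law_eval(inv, law_eval(law, x)), x, tolerance = 1e-12)
  expect_error(law_invert(linear_law(1, 0)), "slope")
})

test_that("default material model carries the calibrated coefficients", {
  m <- density_modulus_model()
  expect_equal(m$hu_to_density$intercept, -0.0829)
  expect_equal(m$hu_to_density$slope, 0.0026)
  expect_equal(m$density_to_modulus$intercept, -34.7)
  expect_equal(m$density_to_modulus$slope, 3230)
  expect_equal(m$poisson, 0.3)
})

test_that("density-modulus mapping clamps below the floor and flags it", {
  m <- density_modulus_model()
  # below the zero crossing (~0.0107 g/cm^3) the law is negative
  e <- density_to_modulus(m, c(0, 0.0107, 0.2))
  expect_equal(as.numeric(e[1]), m$e_min)
  expect_true(attr(e, "clamped")[1])
  expect_false(attr(e, "clamped")[3])
  expect_equal(as.numeric(e[3]), -34.7 + 3230 * 0.2)  # 611.3 MPa
})

test_that("HU to modulus mapping is monotone after clamping", {
  m <- density_modulus_model()
  hu <- seq(-200, 2000, by = 7)
  e <- hu_to_modulus(m, hu)
  expect_true(all(diff(as.numeric(e)) >= 0))
})

test_that("model constructor rejects invalid floors and Poisson ratios", {
  expect_error(density_modulus_model(e_min = 0))
  expect_error(density_modulus_model(poisson = 0.5))
})
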