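#' Linear calibration / material law
#'
#' `output = intercept + slope * input`. Used both for the Hounsfield-unit to
#' apparent-density conversion obtained from the in-scan calibration phantom
#' and for the density to elastic-modulus relation.
#'
#' @param intercept Intercept in output units.
#' @param slope Slope in output units per input unit (finite).
#' @param input,output Labels for the input and output quantities.
#' @return An object of class `linear_law`.
#' @export
linear_law <- function(intercept, slope, input = "x", output = "y") {
  stopifnot(is.finite(intercept), is.finite(slope))
  structure(list(intercept = as.numeric(intercept), slope = as.numeric(slope),
                 input = input, output = output),
            class = "linear_law")
}

#' @export
print.linear_law <- function(x, ...) {
  cat(sprintf("linear_law: %s = %.6g %+.6g * %s\n",
              x$output, x$intercept, x$slope, x$input))
  invisible(x)
}

#' Evaluate a linear law
#' @param law A [linear_law()].
#' @param x Numeric input values.
#' @return `intercept + slope * x`, exactly.
#' @export
law_eval <- function(law, x) law$intercept + law$slope * x

#' Invert a linear law
#' @param law A [linear_law()] with nonzero slope.
#' @return The inverse [linear_law()] mapping output back to input.
#' @export
law_invert <- function(law) {
  if (law$slope == 0) stop("law with zero slope is not invertible")
  linear_law(-law$intercept / law$slope, 1 / law$slope,
             input = law$output, output = law$input)
}

#' Density-modulus material model
#'
#' Bundles the two linear laws of the QCT material pipeline, the clamping
#' floor for the elastic modulus, and the Poisson ratio. Defaults are the
#' clinically calibrated laws used throughout the package:
#' `rho_app = -0.0829 + 0.0026 * HU` (g/cm^3) and
#' `E = -34.7 + 3230 * rho_app` (MPa, Kopperdahl-type trabecular relation),
#' with `nu = 0.3`. The modulus law crosses zero near
#' `rho_app ~ 0.0107 g/cm^3`; values below are clamped to `e_min` to keep
#' element stiffness positive definite.
#'
#' @param hu_to_density [linear_law()] HU -> g/cm^3.
#' @param density_to_modulus [linear_law()] g/cm^3 -> MPa.
#' @param e_min Modulus floor, MPa (> 0).
#' @param poisson Poisson ratio, in (0, 0.5).
#' @return An object of class `density_modulus_model`.
#' @export
density_modulus_model <- function(
    hu_to_density = linear_law(-0.0829, 0.0026, "HU", "g/cm^3"),
    density_to_modulus = linear_law(-34.7, 3230, "g/cm^3", "MPa"),
    e_min = 0.01, poisson = 0.3) {
  stopifnot(inherits(hu_to_density, "linear_law"),
            inherits(density_to_modulus, "linear_law"),
            e_min > 0, poisson > 0, poisson < 0.5)
  structure(list(hu_to_density = hu_to_density,
                 density_to_modulus = density_to_modulus,
                 e_min = e_min, poisson = poisson),
            class = "density_modulus_model")
}

#' @export
print.density_modulus_model <- function(x, ...) {
  cat("density_modulus_model\n")
  cat("  "); print(x$hu_to_density)
  cat("  "); print(x$density_to_modulus)
  cat(sprintf("  e_min = %g MPa, poisson = %g\n", x$e_min, x$poisson))
  invisible(x)
}

#' Apparent density to elastic modulus
#'
#' Evaluates the density-modulus law and clamps the result below at the
#' model's `e_min` floor.
#'
#' @param model A [density_modulus_model()].
#' @param rho Apparent density values, g/cm^3.
#' @return Numeric modulus values in MPa, with attribute `clamped`: logical
#'   vector flagging values raised to the floor.
#' @export
density_to_modulus <- function(model, rho) {
  stopifnot(all(is.finite(rho)))
  e_raw <- law_eval(model$density_to_modulus, rho)
  clamped <- e_raw < model$e_min
  e <- pmax(e_raw, model$e_min)
  attr(e, "clamped") <- clamped
  e
}

#' Hounsfield units to elastic modulus
#'
#' Convenience composition of the two laws plus clamping.
#' @inheritParams density_to_modulus
#' @param hu HU values.
#' @export
hu_to_modulus <- function(model, hu) {
  density_to_modulus(model, law_eval(model$hu_to_density, hu))
}
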