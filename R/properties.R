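#' Thermophysical properties of whole blood
#'
#' Bundles the constants and fitted models needed by the thermal Marangoni
#' computation: thermal conductivity, density, specific heat capacity,
#' hematocrit level and (optionally) a logarithmic surface-tension fit.
#'
#' Defaults are the measured constants for sheep blood: conductivity
#' 0.52 W/(m.°C), density 1.04873 g/ml, specific heat 3617 J/(kg.°C).
#' The hematocrit default of 35% sits in the typical ovine range; it is a
#' configurable default, not a measured value.
#'
#' @param lambda Thermal conductivity, W/(m.°C).
#' @param rho Density, g/ml.
#' @param cp Specific heat capacity, J/(kg.°C).
#' @param ht Hematocrit level, percent (0-100).
#' @param sigma_fit Optional `log_fit` model of surface tension against
#'   temperature, as returned by [fit_surface_tension()].
#'
#' @return An object of class `blood_properties`.
#' @examples
#' props <- blood_properties()
#' thermal_diffusivity(props$lambda, props$rho, props$cp)
#' @export
blood_properties <- function(lambda = 0.52, rho = 1.04873, cp = 3617,
                             ht = 35, sigma_fit = NULL) {
  stopifnot(lambda > 0, rho > 0, cp > 0, ht >= 0, ht <= 100)
  if (!is.null(sigma_fit) && !inherits(sigma_fit, "log_fit")) {
    abort("`sigma_fit` must be a `log_fit` object from fit_surface_tension().")
  }
  structure(
    list(lambda = lambda, rho = rho, cp = cp, ht = ht, sigma_fit = sigma_fit),
    class = "blood_properties"
  )
}

#' @export
print.blood_properties <- function(x, ...) {
  cat("<blood_properties>\n")
  cat(sprintf("  lambda: %.4g W/(m.degC)   rho: %.5f g/ml   cp: %.4g J/(kg.degC)   Ht: %.1f%%\n",
              x$lambda, x$rho, x$cp, x$ht))
  if (is.null(x$sigma_fit)) {
    cat("  sigma(T): <absent>\n")
  } else {
    cat(sprintf("  sigma(T) = %.4g ln(T) + %.4g mN/m  (r2 = %.4f)\n",
                x$sigma_fit$a, x$sigma_fit$b, x$sigma_fit$r2))
  }
  invisible(x)
}

#' Dynamic viscosity of water
#'
#' Vogel-type empirical model
#' \deqn{\eta_w(T) = 2.414\times 10^{-5}\; 10^{247.8/(T+133)}}
#' with temperature in degrees Celsius, valid above the pole at -133 °C.
#' At 20 °C it returns about 1.005e-3 Pa.s, matching tabulated water
#' viscosity to within 0.5%.
#'
#' @param temp Temperature, °C. Vectorised.
#' @return Dynamic viscosity, Pa.s.
#' @examples
#' water_viscosity(20)
#' @export
water_viscosity <- function(temp) {
  if (any(temp <= -133)) abort("`temp` must exceed -133 degC (pole of the exponent).")
  2.414e-5 * 10^(247.8 / (temp + 133))
}

#' Relative viscosity of whole blood
#'
#' Empirical hematocrit-temperature model
#' \deqn{\eta_{r} = 2.03\exp[(0.0332 - 1.08\times10^{-4} T)\,Ht + 0.02\,T]}
#' giving blood viscosity relative to water. Note the model is used
#' verbatim: the \eqn{\exp(0.02T)} term makes the relative (not absolute)
#' viscosity rise with temperature.
#'
#' @param temp Blood temperature, °C (>= 0). Vectorised.
#' @param ht Hematocrit level, percent (0-100).
#' @return Dimensionless relative viscosity.
#' @examples
#' blood_relative_viscosity(37, ht = 35)
#' @export
blood_relative_viscosity <- function(temp, ht = 35) {
  if (any(temp < 0)) abort("`temp` must be >= 0 degC.")
  if (any(ht < 0 | ht > 100)) abort("`ht` must lie in [0, 100] percent.")
  2.03 * exp((0.0332 - 1.08e-4 * temp) * ht + 0.02 * temp)
}

#' Dynamic viscosity of whole blood
#'
#' Product of the relative-viscosity model ([blood_relative_viscosity()])
#' and the water-viscosity model ([water_viscosity()]).
#'
#' @inheritParams blood_relative_viscosity
#' @return Dynamic viscosity, Pa.s.
#' @examples
#' blood_viscosity(37, ht = 35)
#' @export
blood_viscosity <- function(temp, ht = 35) {
  blood_relative_viscosity(temp, ht) * water_viscosity(temp)
}

#' Thermal diffusivity
#'
#' \deqn{\alpha = \lambda / (\rho\, C_p)}
#'
#' Two unit conventions are exposed. `mode = "paper_numeric"` plugs the
#' density in as its g/ml numeral, which for the default blood constants
#' gives 1.3708e-4 — the value conventionally quoted for this system.
#' `mode = "si"` converts density to kg/m^3 and returns a true SI
#' diffusivity in m^2/s (a factor 1e-3 smaller).
#'
#' @param lambda Thermal conductivity, W/(m.°C).
#' @param rho Density, g/ml.
#' @param cp Specific heat capacity, J/(kg.°C).
#' @param mode `"paper_numeric"` or `"si"`.
#' @return Thermal diffusivity (m^2/s in `"si"` mode).
#' @examples
#' thermal_diffusivity(0.52, 1.04873, 3617)            # 1.3708e-04
#' thermal_diffusivity(0.52, 1.04873, 3617, mode = "si") # 1.3708e-07 m2/s
#' @export
thermal_diffusivity <- function(lambda, rho, cp, mode = c("paper_numeric", "si")) {
  mode <- match.arg(mode)
  if (any(c(lambda, rho, cp) <= 0)) abort("lambda, rho and cp must all be positive.")
  rho_eff <- if (mode == "si") rho * 1000 else rho
  lambda / (rho_eff * cp)
}

#' Logarithmic surface-tension fit
#'
#' Least-squares fit of the logarithmic trend
#' \deqn{\sigma(T) = a \ln T + b}
#' to tensiometer measurements of surface tension against temperature.
#' The logarithmic form is the trend family with the highest correlation
#' for blood over 24-90 °C; its derivative \eqn{d\sigma/dT = a/T} feeds
#' the Marangoni number.
#'
#' @param temp Temperatures, °C (> 0), length >= 3.
#' @param sigma Surface tensions, mN/m, same length.
#' @return A `log_fit` object with fields `a` (mN/m per ln °C), `b` (mN/m)
#'   and `r2`.
#' @examples
#' T6 <- c(24, 37, 50, 60, 75, 90)
#' fit_surface_tension(T6, -11.5 * log(T6) + 88)
#' @export
fit_surface_tension <- function(temp, sigma) {
  if (length(temp) < 3) abort("At least 3 (temp, sigma) points are required.")
  if (length(sigma) != length(temp)) abort("`temp` and `sigma` lengths differ.")
  if (any(temp <= 0)) abort("All temperatures must be positive (ln T).")
  fit <- lm(sigma ~ log(temp))
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((sigma - mean(sigma))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(a = unname(coef(fit)[2]), b = unname(coef(fit)[1]),
         r2 = r2, n = length(temp)),
    class = "log_fit"
  )
}

#' Construct a logarithmic surface-tension model directly
#'
#' For configurations that carry the coefficients of
#' \eqn{\sigma(T) = a \ln T + b} rather than raw measurements.
#'
#' @param a Slope coefficient, mN/m per unit ln(°C).
#' @param b Intercept, mN/m.
#' @param r2 Coefficient of determination (NA when not applicable).
#' @return A `log_fit` object.
#' @export
log_fit <- function(a, b, r2 = NA_real_) {
  if (!is.na(r2) && (r2 < 0 || r2 > 1)) abort("`r2` must lie in [0, 1].")
  structure(list(a = a, b = b, r2 = r2, n = NA_integer_), class = "log_fit")
}

#' @export
print.log_fit <- function(x, ...) {
  cat(sprintf("<log_fit> sigma(T) = %.6g ln(T) + %.6g mN/m, r2 = %.6f (n = %d)\n",
              x$a, x$b, x$r2, x$n))
  invisible(x)
}

#' @rdname fit_surface_tension
#' @param x,object A `log_fit` object.
#' @param ... Unused.
#' @export
tidy.log_fit <- function(x, ...) {
  tibble(term = c("a (slope of ln T)", "b (intercept)"),
         estimate = c(x$a, x$b))
}

#' @rdname fit_surface_tension
#' @export
glance.log_fit <- function(x, ...) {
  tibble(r.squared = x$r2, nobs = x$n)
}

#' Evaluate a surface-tension fit
#'
#' @param model A `log_fit` object.
#' @param temp Temperature(s), °C (> 0).
#' @return Surface tension, mN/m.
#' @export
predict_sigma <- function(model, temp) {
  stopifnot(inherits(model, "log_fit"))
  if (any(temp <= 0)) abort("`temp` must be positive.")
  model$a * log(temp) + model$b
}

#' Temperature derivative of surface tension
#'
#' For the logarithmic model \eqn{\sigma = a\ln T + b} the derivative is
#' \eqn{a/T}. When two temperatures are supplied (triple line and drop
#' centre) the mean of the two point derivatives is returned — the form
#' entering the Marangoni number.
#'
#' @param model A `log_fit` object.
#' @param temp Temperature, °C (> 0), or the first of two temperatures.
#' @param temp2 Optional second temperature; when present the mean of the
#'   two point derivatives is returned.
#' @return d(sigma)/dT in mN/(m.°C).
#' @examples
#' fit <- fit_surface_tension(c(24, 37, 50, 60, 75, 90),
#'                            -11.5 * log(c(24, 37, 50, 60, 75, 90)) + 88)
#' dsigma_dT(fit, 23)
#' @export
dsigma_dT <- function(model, temp, temp2 = NULL) {
  stopifnot(inherits(model, "log_fit"))
  if (any(temp <= 0) || (!is.null(temp2) && any(temp2 <= 0))) {
    abort("Temperatures must be positive.")
  }
  if (is.null(temp2)) return(model$a / temp)
  (model$a / temp + model$a / temp2) / 2
}

# Default sigma(T) curve used by the synthetic study: an invented but
# plausible logarithmic decline for blood, NOT a measured fit.
default_sigma_fit <- function() {
  temps <- c(24, 37, 50, 60, 75, 90)
  fit_surface_tension(temps, -11.5 * log(temps) + 88)
}
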