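#' Dynamic viscosity of pure water
#'
#' Empirical correlation for the dynamic viscosity of liquid water as a
#' function of temperature, expressed relative to the reference value
#' 1.002 mPa s at 20 degrees Celsius. Reproduces standard handbook values
#' to better than 0.1 percent over the liquid range (for example
#' 0.890 mPa s at 25 C and 0.797 mPa s at 30 C).
#'
#' @param temperature Absolute temperature in kelvin. Must lie strictly
#'   inside the liquid range of water at ambient pressure,
#'   (273.15, 373.15) K.
#' @return Dynamic viscosity in pascal seconds (vectorised over
#'   `temperature`).
#' @examples
#' water_viscosity(303.15) # ~ 0.797e-3 Pa s
#' @export
water_viscosity <- function(temperature) {
  if (!is.numeric(temperature) || any(!is.finite(temperature))) {
    abort("`temperature` must be a finite numeric vector (kelvin).")
  }
  if (any(temperature <= 273.15 | temperature >= 373.15)) {
    abort(paste0(
      "`temperature` must lie in the open interval (273.15, 373.15) K ",
      "(liquid water at ambient pressure); got ",
      paste(signif(temperature[temperature <= 273.15 | temperature >= 373.15], 6),
            collapse = ", "), "."
    ))
  }
  tc <- temperature - 273.15
  # log10(eta/eta20) form with eta20 = 1.002 mPa s
  a <- 20 - tc
  num <- a * (1.2378 - 1.303e-3 * a + 3.06e-6 * a^2 + 2.55e-8 * a^3)
  1.002e-3 * 10^(num / (tc + 96))
}

#' Experimental conditions for hydrodynamic and relaxation calculations
#'
#' Bundles the sample temperature, solvent viscosity and spectrometer field
#' shared by every Stokes-Einstein(-Debye) conversion and relaxation
#' computation. When `viscosity` is not supplied it is computed for pure
#' water at `temperature` via [water_viscosity()]; buffer or D2O corrections
#' are the caller's responsibility via an explicit override.
#'
#' @param temperature Absolute temperature in kelvin (default 303.15 K,
#'   i.e. 30 C).
#' @param viscosity Dynamic viscosity in Pa s, or `NULL` to use pure water
#'   at `temperature`.
#' @param field_mhz Proton Larmor frequency in MHz (optional; required only
#'   by the relaxation functions). Must lie in [400, 1000] when given.
#' @return An object of class `dd_conditions`: a list with elements
#'   `temperature`, `viscosity` and `field_mhz`.
#' @examples
#' conditions() # 303.15 K, pure-water viscosity
#' conditions(298.15, field_mhz = 600)
#' @export
conditions <- function(temperature = 303.15, viscosity = NULL, field_mhz = NULL) {
  if (!is.numeric(temperature) || length(temperature) != 1 || temperature <= 0) {
    abort("`temperature` must be a single positive number (kelvin).")
  }
  if (is.null(viscosity)) {
    viscosity <- water_viscosity(temperature)
  } else if (!is.numeric(viscosity) || length(viscosity) != 1 || viscosity <= 0) {
    abort("`viscosity` must be a single positive number (Pa s).")
  }
  if (!is.null(field_mhz)) {
    if (!is.numeric(field_mhz) || length(field_mhz) != 1 ||
        field_mhz < 400 || field_mhz > 1000) {
      abort("`field_mhz` must be a single number in [400, 1000] (proton MHz).")
    }
  }
  structure(
    list(temperature = temperature, viscosity = viscosity, field_mhz = field_mhz),
    class = "dd_conditions"
  )
}

#' @export
print.dd_conditions <- function(x, ...) {
  cat("<dd_conditions>\n")
  cat(sprintf("  temperature: %.2f K\n", x$temperature))
  cat(sprintf("  viscosity:   %.4g Pa s\n", x$viscosity))
  cat(sprintf("  field:       %s\n",
              if (is.null(x$field_mhz)) "unset" else sprintf("%g MHz (1H)", x$field_mhz)))
  invisible(x)
}

as_conditions <- function(cond) {
  if (inherits(cond, "dd_conditions")) return(cond)
  if (is.list(cond)) return(do.call(conditions, cond))
  abort("`cond` must be a `dd_conditions` object (see `conditions()`).")
}
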