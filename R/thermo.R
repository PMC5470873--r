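#' Thermodynamic constants
#'
#' Bundles the absolute temperature with the gas and Faraday constants used
#' throughout the permeation model. The thermal voltage RT/F sets the voltage
#' scale of every exponential in the model (about 25.4 mV at 295 K).
#'
#' @param temperature_K Absolute temperature in kelvin. Defaults to 295 K
#'   (room temperature).
#' @return An object of class `thermo`: a list with `temperature_K`,
#'   `gas_constant` (J mol^-1 K^-1), `faraday` (C mol^-1).
#' @examples
#' th <- thermo()
#' thermal_voltage_mV(th)
#' @export
thermo <- function(temperature_K = 295) {
  if (!is.numeric(temperature_K) || length(temperature_K) != 1 ||
      !is.finite(temperature_K) || temperature_K <= 0) {
    rlang::abort("`temperature_K` must be a single positive finite number.",
                 class = "ivperm_invalid_argument")
  }
  structure(
    list(temperature_K = temperature_K,
         gas_constant = 8.31446261815324,
         faraday = 96485.33212),
    class = "thermo"
  )
}

#' @rdname thermo
#' @param x A `thermo` object.
#' @return `thermal_voltage_mV()`: the thermal voltage RT/F in millivolt.
#' @export
thermal_voltage_mV <- function(x) {
  stopifnot(inherits(x, "thermo"))
  1000 * x$gas_constant * x$temperature_K / x$faraday
}

#' @export
print.thermo <- function(x, ...) {
  cat(sprintf("<thermo> T = %g K, RT/F = %.3f mV\n",
              x$temperature_K, thermal_voltage_mV(x)))
  invisible(x)
}

#' Permeant-ion specification
#'
#' Valence and the intracellular/extracellular concentrations of the permeant
#' ion. The default is chloride (z = -1) at symmetrical 150 mM, the condition
#' of the rectification experiments.
#'
#' @param valence Integer charge number z (nonzero); -1 for Cl-.
#' @param conc_in,conc_out Intracellular and extracellular concentration in
#'   mM. Both must be non-negative and not both zero.
#' @return An object of class `ion_spec`.
#' @examples
#' ion_spec()                          # symmetric 150 mM Cl-
#' ion_spec(conc_in = 15)              # 10-fold gradient
#' @export
ion_spec <- function(valence = -1, conc_in = 150, conc_out = 150) {
  if (!is.numeric(valence) || length(valence) != 1 || valence == 0 ||
      valence != round(valence)) {
    rlang::abort("`valence` must be a nonzero integer charge number.",
                 class = "ivperm_invalid_argument")
  }
  if (!is.numeric(conc_in) || !is.numeric(conc_out) ||
      length(conc_in) != 1 || length(conc_out) != 1 ||
      conc_in < 0 || conc_out < 0 || (conc_in == 0 && conc_out == 0)) {
    rlang::abort("Concentrations must be non-negative and not both zero.",
                 class = "ivperm_invalid_argument")
  }
  structure(list(valence = as.integer(valence),
                 conc_in = conc_in, conc_out = conc_out),
            class = "ion_spec")
}

#' @export
print.ion_spec <- function(x, ...) {
  cat(sprintf("<ion_spec> z = %+d, [in] = %g mM, [out] = %g mM\n",
              x$valence, x$conc_in, x$conc_out))
  invisible(x)
}

#' Nernst equilibrium potential
#'
#' The voltage at which the net current through a perfectly selective pore is
#' zero: E = (RT/zF) ln(c_out/c_in). For the barrier model this is the exact
#' zero-crossing of the current for every choice of barrier parameters.
#'
#' @param ion An [ion_spec()]; both concentrations must be strictly positive.
#' @param thermo A [thermo()] object.
#' @return The equilibrium potential in mV.
#' @examples
#' nernst_potential(ion_spec(conc_in = 15, conc_out = 150))  # about -58.5 mV
#' @export
nernst_potential <- function(ion, thermo = ivperm::thermo()) {
  stopifnot(inherits(ion, "ion_spec"), inherits(thermo, "thermo"))
  if (ion$conc_in <= 0 || ion$conc_out <= 0) {
    rlang::abort(
      "Nernst potential is undefined when a concentration is zero.",
      class = "ivperm_undefined_potential")
  }
  thermal_voltage_mV(thermo) / ion$valence * log(ion$conc_out / ion$conc_in)
}
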