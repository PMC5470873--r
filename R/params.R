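#' Barrier-model parameters
#'
#' Free parameters of the n-barrier Eyring permeation model. `sigma_beta` and
#' `sigma_h` are the rate constants for crossing the innermost and the
#' internal (middle) barriers *relative to the outermost barrier*; values
#' below 1 mean a higher barrier than the outermost one. `amplitude` is the
#' proportionality factor A multiplying zF in the current equation; it sets
#' the absolute current scale and cancels on normalized curves.
#'
#' @param sigma_beta Relative rate over the innermost barrier (> 0).
#' @param sigma_h Relative rate over the middle barrier(s) (> 0).
#' @param amplitude Proportionality factor A (> 0), current units per mM
#'   after multiplication by zF.
#' @param n_barriers Integer number of barriers (>= 2); fixed at 3 for the
#'   standard analysis.
#' @return An object of class `barrier_params`.
#' @examples
#' barrier_params()                      # linear (all barriers equal)
#' barrier_params(sigma_beta = 0.1)      # raised innermost barrier
#' @export
barrier_params <- function(sigma_beta = 1, sigma_h = 1, amplitude = 1,
                           n_barriers = 3) {
  chk <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
      rlang::abort(sprintf("`%s` must be a single positive finite number.", nm),
                   class = "ivperm_invalid_argument")
    }
  }
  chk(sigma_beta, "sigma_beta"); chk(sigma_h, "sigma_h")
  chk(amplitude, "amplitude")
  if (!is.numeric(n_barriers) || length(n_barriers) != 1 ||
      n_barriers != round(n_barriers) || n_barriers < 2) {
    rlang::abort("`n_barriers` must be an integer >= 2.",
                 class = "ivperm_invalid_argument")
  }
  structure(list(sigma_beta = sigma_beta, sigma_h = sigma_h,
                 amplitude = amplitude, n_barriers = as.integer(n_barriers)),
            class = "barrier_params")
}

#' @export
print.barrier_params <- function(x, ...) {
  cat(sprintf(
    "<barrier_params> n = %d, sigma_beta = %g, sigma_h = %g, A = %g\n",
    x$n_barriers, x$sigma_beta, x$sigma_h, x$amplitude))
  invisible(x)
}

#' Descriptive activation-energy profile
#'
#' Converts the relative rate constants into activation-energy offsets of the
#' innermost and middle barriers relative to the outermost one,
#' dEa = -RT ln(sigma), reported in kJ/mol. A sigma below 1 therefore maps to
#' a positive energy offset (higher barrier).
#'
#' @param params A [barrier_params()] object.
#' @param thermo A [thermo()] object.
#' @return A one-row tibble of class `energy_profile` with columns
#'   `delta_ea_in_minus_out_kJmol`, `delta_ea_mid_minus_out_kJmol`,
#'   `n_barriers`.
#' @examples
#' energy_profile(barrier_params(sigma_beta = 0.1))  # +5.65 kJ/mol at 295 K
#' @export
energy_profile <- function(params, thermo = ivperm::thermo()) {
  stopifnot(inherits(params, "barrier_params"), inherits(thermo, "thermo"))
  rt <- thermo$gas_constant * thermo$temperature_K / 1000  # kJ/mol
  out <- tibble::tibble(
    delta_ea_in_minus_out_kJmol = -rt * log(params$sigma_beta),
    delta_ea_mid_minus_out_kJmol = -rt * log(params$sigma_h),
    n_barriers = params$n_barriers
  )
  class(out) <- c("energy_profile", class(out))
  out
}

#' Invert an energy profile back to relative rates
#'
#' The inverse of [energy_profile()]: sigma = exp(-dEa/RT).
#'
#' @param profile An `energy_profile` (one row).
#' @param thermo A [thermo()] object.
#' @param amplitude Amplitude to attach to the reconstructed parameters.
#' @return A [barrier_params()] object.
#' @export
params_from_energy_profile <- function(profile, thermo = ivperm::thermo(),
                                       amplitude = 1) {
  stopifnot(inherits(profile, "energy_profile"), nrow(profile) == 1)
  rt <- thermo$gas_constant * thermo$temperature_K / 1000
  barrier_params(
    sigma_beta = exp(-profile$delta_ea_in_minus_out_kJmol / rt),
    sigma_h = exp(-profile$delta_ea_mid_minus_out_kJmol / rt),
    amplitude = amplitude,
    n_barriers = profile$n_barriers
  )
}
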