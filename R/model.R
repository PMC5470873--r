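#' Closed-form current of the n-barrier Eyring permeation model
#'
#' Net single-species current through a chain of `n` Eyring barriers equally
#' spaced in electrical distance, with the innermost barrier scaled by
#' `sigma_beta` and the internal one(s) by `sigma_h` relative to the
#' outermost. With u = zFV/RT the current is
#'
#'   I = zFA e^(u/2n) (c_in - c_out e^(-u)) /
#'       \[ e^(-u(n-1)/n) + (1/sigma_h) (1 - e^(-u(n-2)/n))/(e^(u/n) - 1)
#'         + 1/sigma_beta \]
#'
#' The quotient in the denominator has a removable singularity at V = 0 and
#' is evaluated by its analytic limit (n - 2) when |u/n| < 1e-8, so the
#' current is continuous through 0 mV. The zero crossing is the Nernst
#' potential of the permeant ion for every parameter choice.
#'
#' Voltage convention: V = V_in - V_out; positive current is outward movement
#' of positive charge, so with z = -1 chloride influx at depolarized
#' potentials is a positive current.
#'
#' @param v_mV Membrane voltage(s) in mV (finite, vectorized).
#' @param ion An [ion_spec()].
#' @param params A [barrier_params()].
#' @param thermo A [thermo()].
#' @return Numeric vector of currents in the units set by `amplitude`.
#' @examples
#' barrier_current(c(-100, 100), ion_spec(), barrier_params(sigma_beta = 0.1))
#' @export
barrier_current <- function(v_mV, ion, params, thermo = ivperm::thermo()) {
  stopifnot(inherits(ion, "ion_spec"), inherits(params, "barrier_params"),
            inherits(thermo, "thermo"))
  if (!is.numeric(v_mV) || length(v_mV) == 0 || any(!is.finite(v_mV))) {
    rlang::abort("`v_mV` must be finite numeric voltage(s).",
                 class = "ivperm_invalid_argument")
  }
  z <- ion$valence
  n <- params$n_barriers
  rt <- thermo$gas_constant * thermo$temperature_K
  u <- z * thermo$faraday * (v_mV / 1000) / rt
  # removable singularity at u = 0: the quotient tends to (n - 2); expm1
  # keeps the direct branch accurate arbitrarily close to the limit
  q <- ifelse(abs(u / n) < 1e-12,
              n - 2,
              -expm1(-u * (n - 2) / n) / expm1(u / n))
  denom <- exp(-u * (n - 1) / n) + q / params$sigma_h + 1 / params$sigma_beta
  z * thermo$faraday * params$amplitude * exp(u / (2 * n)) *
    (ion$conc_in - ion$conc_out * exp(-u)) / denom
}

#' Model I-V curve on a voltage grid
#'
#' Evaluates [barrier_current()] on a set of voltages and optionally
#' normalizes to the current at +120 mV (evaluating the model there for the
#' divisor if +120 mV is not on the grid).
#'
#' @inheritParams barrier_current
#' @param voltages_mV Strictly increasing voltages in mV.
#' @param normalize Normalize to the response at +120 mV?
#' @return An [iv_curve()] tibble.
#' @examples
#' barrier_iv(seq(-100, 120, 20), ion_spec(), barrier_params(), normalize = TRUE)
#' @export
barrier_iv <- function(voltages_mV, ion, params, thermo = ivperm::thermo(),
                       normalize = FALSE) {
  if (length(voltages_mV) == 0 ||
      is.unsorted(voltages_mV, strictly = TRUE)) {
    rlang::abort("`voltages_mV` must be nonempty and strictly increasing.",
                 class = "ivperm_invalid_argument")
  }
  i <- barrier_current(voltages_mV, ion, params, thermo)
  if (!normalize) return(iv_curve(voltages_mV, i, normalization = "raw"))
  i120 <- barrier_current(120, ion, params, thermo)
  if (abs(i120) < .Machine$double.eps * 100) {
    rlang::abort("Model current at +120 mV is zero; cannot normalize.",
                 class = "ivperm_degenerate_normalization")
  }
  iv_curve(voltages_mV, i / i120,
           normalization = "normalized_to_plus120mV")
}

#' Rectification index
#'
#' The ratio |I(+100 mV)| / |I(-100 mV)|. Values above 1 indicate outward
#' rectification, below 1 inward rectification. The method for
#' `barrier_params` evaluates the model exactly at +/-100 mV; the data-frame
#' method reads the currents off an I-V table, interpolating linearly if
#' +/-100 mV are only bracketed.
#'
#' @param x A [barrier_params()] object or an I-V table (e.g. [iv_curve()])
#'   with columns `voltage_mV` and `current`.
#' @param ... Passed to methods.
#' @return Dimensionless ratio.
#' @examples
#' rectification_index(barrier_params(sigma_beta = 0.1), ion_spec())
#' @export
rectification_index <- function(x, ...) UseMethod("rectification_index")

#' @rdname rectification_index
#' @inheritParams barrier_current
#' @export
rectification_index.barrier_params <- function(x, ion = ion_spec(),
                                               thermo = ivperm::thermo(),
                                               ...) {
  i <- barrier_current(c(-100, 100), ion, x, thermo)
  if (i[1] == 0) {
    rlang::abort("Current at -100 mV is zero; rectification index undefined.",
                 class = "ivperm_undefined_index")
  }
  abs(i[2]) / abs(i[1])
}

#' @rdname rectification_index
#' @export
rectification_index.data.frame <- function(x, ...) {
  stopifnot(all(c("voltage_mV", "current") %in% names(x)))
  ineg <- interp_current(x, -100)
  ipos <- interp_current(x, 100)
  if (ineg == 0) {
    rlang::abort("Current at -100 mV is zero; rectification index undefined.",
                 class = "ivperm_undefined_index")
  }
  abs(ipos) / abs(ineg)
}
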