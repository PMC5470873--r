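#' Hopping-chain description of the permeation path
#'
#' An explicit sequential-barrier transport model used as an independent
#' check of the closed-form current and to explore perturbations the
#' two-sigma parameterization cannot express (e.g. raising only the
#' outermost barrier). Barrier j (counted from the intracellular side) has a
#' rate multiplier `gamma[j]` relative to the outermost barrier; barrier
#' peaks sit at fractional electrical distance (2j-1)/(2n), wells at j/n,
#' equally spaced, with equal well depths. The mapping
#' `gamma = c(sigma_beta, sigma_h, ..., sigma_h, 1)` reproduces
#' [barrier_params()] exactly.
#'
#' @param gamma Positive rate multipliers, one per barrier (length >= 2).
#' @param base_rate Overall rate scale (arbitrary units); cancels on
#'   normalized curves.
#' @return An object of class `hopping_chain`.
#' @examples
#' hopping_chain(c(0.1, 1, 1))    # raised innermost barrier
#' hopping_chain(c(1, 1, 0.1))    # raised outermost barrier
#' @export
hopping_chain <- function(gamma, base_rate = 1) {
  if (!is.numeric(gamma) || length(gamma) < 2 || any(!is.finite(gamma)) ||
      any(gamma <= 0)) {
    rlang::abort("`gamma` must be >= 2 positive finite rate multipliers.",
                 class = "ivperm_invalid_argument")
  }
  if (!is.numeric(base_rate) || length(base_rate) != 1 || base_rate <= 0) {
    rlang::abort("`base_rate` must be a single positive number.",
                 class = "ivperm_invalid_argument")
  }
  structure(list(gamma = as.numeric(gamma),
                 n_barriers = length(gamma),
                 base_rate = base_rate),
            class = "hopping_chain")
}

#' @rdname hopping_chain
#' @param params A [barrier_params()] object to convert.
#' @export
chain_from_params <- function(params, base_rate = 1) {
  stopifnot(inherits(params, "barrier_params"))
  n <- params$n_barriers
  hopping_chain(c(params$sigma_beta,
                  rep(params$sigma_h, n - 2),
                  1),
                base_rate = base_rate)
}

#' Steady-state flux through a hopping chain
#'
#' Solves the linear steady-state master equation for the n-1 internal well
#' occupancies with Eyring rates k+_j = base_rate * gamma_j * exp(u/2n) and
#' k-_j = base_rate * gamma_j * exp(-u/2n), u = zFV/RT (each hop spans
#' electrical distance 1/n with the peak midway), boundary wells clamped to
#' the reservoir concentrations. Returns the net flux, positive for outward
#' ion movement; at steady state the flux across every barrier is identical.
#'
#' @param chain A [hopping_chain()].
#' @param ion An [ion_spec()].
#' @param v_mV Single membrane voltage in mV.
#' @param thermo A [thermo()].
#' @param per_barrier If `TRUE`, return the vector of per-barrier fluxes
#'   (useful for conservation checks) instead of the scalar net flux.
#' @return Net flux in `base_rate * mM` units (scalar), or a length-n vector
#'   when `per_barrier = TRUE`.
#' @examples
#' ch <- hopping_chain(c(1, 1, 1))
#' steady_state_flux(ch, ion_spec(), 100)
#' @export
steady_state_flux <- function(chain, ion, v_mV, thermo = ivperm::thermo(),
                              per_barrier = FALSE) {
  stopifnot(inherits(chain, "hopping_chain"), inherits(ion, "ion_spec"),
            is.numeric(v_mV), length(v_mV) == 1, is.finite(v_mV))
  n <- chain$n_barriers
  rt <- thermo$gas_constant * thermo$temperature_K
  u <- ion$valence * thermo$faraday * (v_mV / 1000) / rt
  a <- exp(u / (2 * n))
  kp <- chain$base_rate * chain$gamma * a     # outward hops
  km <- chain$base_rate * chain$gamma / a     # inward hops
  ci <- ion$conc_in; co <- ion$conc_out
  # occupancies of wells 1..n-1 (well 0 = inside, well n = outside reservoir)
  p <- if (n == 2) {
    (kp[1] * ci + km[2] * co) / (km[1] + kp[2])
  } else {
    m <- matrix(0, n - 1, n - 1)
    b <- numeric(n - 1)
    for (j in seq_len(n - 1)) {
      m[j, j] <- -(km[j] + kp[j + 1])
      if (j > 1) m[j, j - 1] <- kp[j]
      if (j < n - 1) m[j, j + 1] <- km[j + 1]
    }
    b[1] <- -kp[1] * ci
    b[n - 1] <- b[n - 1] - km[n] * co
    solve(m, b)
  }
  occ <- c(ci, p, co)
  flux <- kp * occ[seq_len(n)] - km * occ[seq_len(n) + 1]
  if (per_barrier) flux else flux[1]
}

#' I-V curve from a hopping chain
#'
#' Current = zF * flux per voltage, optionally normalized to +120 mV.
#'
#' @inheritParams steady_state_flux
#' @param voltages_mV Strictly increasing voltages in mV.
#' @param normalize Normalize to the response at +120 mV?
#' @return An [iv_curve()] tibble.
#' @examples
#' chain_iv(hopping_chain(c(1, 1, 0.1)), ion_spec(), seq(-100, 120, 20))
#' @export
chain_iv <- function(chain, ion, voltages_mV, thermo = ivperm::thermo(),
                     normalize = FALSE) {
  if (length(voltages_mV) == 0 ||
      is.unsorted(voltages_mV, strictly = TRUE)) {
    rlang::abort("`voltages_mV` must be nonempty and strictly increasing.",
                 class = "ivperm_invalid_argument")
  }
  flux <- vapply(voltages_mV, function(v)
    steady_state_flux(chain, ion, v, thermo), numeric(1))
  i <- ion$valence * thermo$faraday * flux
  if (!normalize) return(iv_curve(voltages_mV, i, normalization = "raw"))
  i120 <- ion$valence * thermo$faraday *
    steady_state_flux(chain, ion, 120, thermo)
  if (abs(i120) < .Machine$double.eps * 100) {
    rlang::abort("Chain current at +120 mV is zero; cannot normalize.",
                 class = "ivperm_degenerate_normalization")
  }
  iv_curve(voltages_mV, i / i120,
           normalization = "normalized_to_plus120mV")
}
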