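#' Construct an I-V curve table
#'
#' The central exchange object of the pipeline: a tibble of (voltage, current)
#' points, optionally with a per-point standard error and patch count, tagged
#' with its normalization state. Currents are in pA for raw curves and
#' dimensionless for curves normalized to the response at +120 mV.
#'
#' @param voltage_mV Strictly increasing voltages in mV.
#' @param current Currents (pA, or dimensionless when normalized).
#' @param sem Optional standard error of the mean per point.
#' @param n_patches Optional number of patches averaged per point.
#' @param normalization `"raw"` or `"normalized_to_plus120mV"`.
#' @return A tibble of class `iv_curve`.
#' @export
iv_curve <- function(voltage_mV, current, sem = NULL, n_patches = NULL,
                     normalization = c("raw", "normalized_to_plus120mV")) {
  normalization <- match.arg(normalization)
  if (length(voltage_mV) == 0 || length(current) != length(voltage_mV)) {
    rlang::abort("`voltage_mV` and `current` must be nonempty, equal length.",
                 class = "ivperm_invalid_argument")
  }
  if (is.unsorted(voltage_mV, strictly = TRUE)) {
    rlang::abort("`voltage_mV` must be strictly increasing (no duplicates).",
                 class = "ivperm_invalid_argument")
  }
  out <- tibble::tibble(voltage_mV = as.numeric(voltage_mV),
                        current = as.numeric(current))
  if (!is.null(sem)) out$sem <- as.numeric(sem)
  if (!is.null(n_patches)) out$n_patches <- as.integer(n_patches)
  if (normalization == "normalized_to_plus120mV") {
    i120 <- which(out$voltage_mV == 120)
    if (length(i120) == 1 && abs(out$current[i120] - 1) > 1e-6) {
      rlang::abort("Normalized curve must have current 1 at +120 mV.",
                   class = "ivperm_invalid_argument")
    }
  }
  attr(out, "normalization") <- normalization
  class(out) <- c("iv_curve", class(out))
  out
}

#' @rdname iv_curve
#' @param x An object.
#' @export
is_normalized <- function(x) {
  identical(attr(x, "normalization"), "normalized_to_plus120mV")
}

# Interpolate the current of an I-V table at a voltage (linear between the
# bracketing grid points; exact when the voltage is on the grid).
interp_current <- function(curve, at_mV) {
  v <- curve$voltage_mV; i <- curve$current
  hit <- which(v == at_mV)
  if (length(hit) == 1) return(i[hit])
  if (at_mV < min(v) || at_mV > max(v)) {
    rlang::abort(sprintf("Voltage %g mV outside the measured range.", at_mV),
                 class = "ivperm_out_of_range")
  }
  stats::approx(v, i, xout = at_mV)$y
}

# Zero crossing of an I-V table by linear interpolation between the
# bracketing voltage pair; errors when there is no crossing or more than one.
zero_crossing <- function(voltage_mV, current) {
  s <- sign(current)
  exact <- which(current == 0)
  cross <- which(s[-1] * s[-length(s)] < 0)
  n_cross <- length(exact) + length(cross)
  if (n_cross == 0) {
    rlang::abort("I-V relation does not cross zero within the voltage range.",
                 class = "ivperm_out_of_range")
  }
  if (n_cross > 1) {
    rlang::abort("Multiple zero crossings; reversal potential is ambiguous.",
                 class = "ivperm_ambiguous_reversal")
  }
  if (length(exact) == 1) return(voltage_mV[exact])
  j <- cross[1]
  voltage_mV[j] - current[j] * (voltage_mV[j + 1] - voltage_mV[j]) /
    (current[j + 1] - current[j])
}
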