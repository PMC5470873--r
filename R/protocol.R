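#' Voltage step protocol
#'
#' The instantaneous-current protocol: from a holding potential, each sweep
#' jumps to a fixed +80 mV pre-pulse (the rundown reference) and then to one
#' test voltage. Test voltages must include +120 mV (normalization) and
#' +/-100 mV (rectification index). `filter_cutoff_kHz` is recorded as
#' acquisition metadata only; traces are not re-filtered.
#'
#' @param test_voltages_mV Test steps in mV, strictly increasing; default
#'   -100 to +120 in 20 mV increments.
#' @param prepulse_voltage_mV Pre-pulse voltage (default +80 mV).
#' @param prepulse_duration_ms,test_duration_ms Segment durations in ms.
#' @param holding_voltage_mV Holding potential between sweeps (metadata).
#' @param sample_rate_kHz Digitization rate (default 20 kHz).
#' @param filter_cutoff_kHz Analogue filter cutoff (default 5 kHz, metadata).
#' @param dead_time_ms Settling time after each voltage step during which
#'   samples are unusable (capacitive transient stand-in, default 0.5 ms).
#' @return An object of class `step_protocol`.
#' @export
step_protocol <- function(test_voltages_mV = seq(-100, 120, by = 20),
                          prepulse_voltage_mV = 80,
                          prepulse_duration_ms = 10,
                          test_duration_ms = 20,
                          holding_voltage_mV = 0,
                          sample_rate_kHz = 20,
                          filter_cutoff_kHz = 5,
                          dead_time_ms = 0.5) {
  if (is.unsorted(test_voltages_mV, strictly = TRUE)) {
    rlang::abort("`test_voltages_mV` must be strictly increasing.",
                 class = "ivperm_invalid_argument")
  }
  if (!all(c(-100, 100, 120) %in% test_voltages_mV)) {
    rlang::abort(
      "Test voltages must include +120 and +/-100 mV (normalization and RI).",
      class = "ivperm_invalid_argument")
  }
  if (sample_rate_kHz <= 2 * filter_cutoff_kHz) {
    rlang::abort("`sample_rate_kHz` must exceed twice `filter_cutoff_kHz`.",
                 class = "ivperm_invalid_argument")
  }
  stopifnot(prepulse_duration_ms > 0, test_duration_ms > 0, dead_time_ms >= 0)
  structure(list(test_voltages_mV = as.numeric(test_voltages_mV),
                 prepulse_voltage_mV = prepulse_voltage_mV,
                 prepulse_duration_ms = prepulse_duration_ms,
                 test_duration_ms = test_duration_ms,
                 holding_voltage_mV = holding_voltage_mV,
                 sample_rate_kHz = sample_rate_kHz,
                 filter_cutoff_kHz = filter_cutoff_kHz,
                 dead_time_ms = dead_time_ms),
            class = "step_protocol")
}

#' @export
print.step_protocol <- function(x, ...) {
  cat(sprintf(
    "<step_protocol> %d sweeps: %+g mV pre-pulse (%g ms) then test %g..%g mV (%g ms), %g kHz\n",
    length(x$test_voltages_mV), x$prepulse_voltage_mV, x$prepulse_duration_ms,
    min(x$test_voltages_mV), max(x$test_voltages_mV), x$test_duration_ms,
    x$sample_rate_kHz))
  invisible(x)
}

#' Recording noise and artefact model
#'
#' Parameters of the deviations of a synthetic recording from the ideal
#' model current: additive Gaussian sample noise, a linear (ohmic) leak
#' background, multiplicative per-sweep rundown with availability
#' a_s = exp(-s / rundown_tau) for sweep index s (s = 0 for the first sweep),
#' and, at the dataset level, lognormal patch-to-patch amplitude variability
#' and a uniform voltage offset.
#'
#' @param gaussian_sd_pA Sample noise standard deviation (pA).
#' @param leak_conductance_pA_per_mV Ohmic leak slope (pA/mV).
#' @param leak_offset_pA Constant leak offset (pA).
#' @param rundown_tau_sweeps Rundown time constant in sweeps; `Inf` disables
#'   rundown.
#' @param patch_amplitude_cv Lognormal coefficient of variation of the
#'   per-patch amplitude.
#' @param offset_range_mV Half-width of the uniform per-patch voltage offset
#'   distribution (mV); the default +/-3 mV makes the <2 mV QC rule reject
#'   about a third of patches.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(gaussian_sd_pA = 10,
                        leak_conductance_pA_per_mV = 0.05,
                        leak_offset_pA = 0,
                        rundown_tau_sweeps = 20,
                        patch_amplitude_cv = 0.3,
                        offset_range_mV = 3) {
  vals <- c(gaussian_sd_pA, leak_conductance_pA_per_mV,
            rundown_tau_sweeps, patch_amplitude_cv, offset_range_mV)
  if (any(!is.numeric(vals)) || any(is.na(vals)) || any(vals < 0)) {
    rlang::abort("Noise scale parameters must be non-negative.",
                 class = "ivperm_invalid_argument")
  }
  structure(list(gaussian_sd_pA = gaussian_sd_pA,
                 leak_conductance_pA_per_mV = leak_conductance_pA_per_mV,
                 leak_offset_pA = leak_offset_pA,
                 rundown_tau_sweeps = rundown_tau_sweeps,
                 patch_amplitude_cv = patch_amplitude_cv,
                 offset_range_mV = offset_range_mV),
            class = "noise_model")
}

#' @rdname noise_model
#' @return `noise_free()`: a `noise_model` with all artefacts switched off.
#' @export
noise_free <- function() {
  noise_model(gaussian_sd_pA = 0, leak_conductance_pA_per_mV = 0,
              leak_offset_pA = 0, rundown_tau_sweeps = Inf,
              patch_amplitude_cv = 0, offset_range_mV = 0)
}
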