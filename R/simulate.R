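#' Calibrate the model amplitude to a target current
#'
#' Returns a copy of `params` with `amplitude` scaled so that the model
#' current at `at_mV` equals `target_pA`. Used by the synthetic-data
#' generator to put recordings on a realistic absolute scale (hundreds of pA
#' at +120 mV for a healthy macroscopic patch).
#'
#' @param params A [barrier_params()].
#' @param ion An [ion_spec()].
#' @param thermo A [thermo()].
#' @param target_pA Desired current at `at_mV` (default 500 pA).
#' @param at_mV Calibration voltage (default +120 mV).
#' @return A [barrier_params()] with adjusted amplitude.
#' @export
calibrate_amplitude <- function(params, ion = ion_spec(),
                                thermo = ivperm::thermo(),
                                target_pA = 500, at_mV = 120) {
  i <- barrier_current(at_mV, ion, params, thermo)
  if (i == 0) {
    rlang::abort("Model current at the calibration voltage is zero.",
                 class = "ivperm_invalid_argument")
  }
  barrier_params(sigma_beta = params$sigma_beta, sigma_h = params$sigma_h,
                 amplitude = params$amplitude * target_pA / i,
                 n_barriers = params$n_barriers)
}

new_patch_recording <- function(sweeps, protocol, ion, calcium_mM, patch_id,
                                voltage_offset_mV, true_params = NULL,
                                amplitude_scale = 1) {
  structure(list(sweeps = sweeps, protocol = protocol, ion = ion,
                 calcium_mM = calcium_mM, patch_id = patch_id,
                 voltage_offset_mV = voltage_offset_mV,
                 true_params = true_params,
                 amplitude_scale = amplitude_scale),
            class = "patch_recording")
}

#' @export
print.patch_recording <- function(x, ...) {
  cat(sprintf(
    "<patch_recording> %s: %d sweeps x %d samples, Ca2+ = %g mM, offset = %+.2f mV\n",
    x$patch_id, length(unique(x$sweeps$sweep_index)),
    sum(x$sweeps$sweep_index == x$sweeps$sweep_index[1]),
    x$calcium_mM, x$voltage_offset_mV))
  invisible(x)
}

# One sweep trace: pre-pulse segment then test segment, sampled at the
# protocol rate. The channel obeys the barrier model instantaneously (no
# gating relaxation); rundown scales pre-pulse and test identically.
sweep_trace <- function(protocol, sweep_index, test_v, channel_fun,
                        leak_fun, sd_pA) {
  dt <- 1 / protocol$sample_rate_kHz
  n_pp <- round(protocol$prepulse_duration_ms * protocol$sample_rate_kHz)
  n_test <- round(protocol$test_duration_ms * protocol$sample_rate_kHz)
  t <- (seq_len(n_pp + n_test) - 1) * dt
  v <- c(rep(protocol$prepulse_voltage_mV, n_pp), rep(test_v, n_test))
  i <- channel_fun(v, sweep_index) + leak_fun(v)
  if (sd_pA > 0) i <- i + stats::rnorm(length(i), sd = sd_pA)
  tibble::tibble(sweep_index = sweep_index, time_ms = t,
                 voltage_mV = v, current_pA = i)
}

#' Simulate an inside-out patch recording
#'
#' Generates one synthetic recording: one sweep per test voltage, in
#' protocol order. Sweep s (0-based) carries channel current
#' a_s * I_model(v - offset) with availability a_s = exp(-s / rundown_tau)
#' applied identically at the pre-pulse and the test step, plus an ohmic
#' leak g * (v - offset) + leak_offset, plus Gaussian sample noise. A
#' voltage offset shifts the apparent I-V relation along the voltage axis by
#' +offset. Ground-truth parameters are stored in the recording.
#'
#' @param params A [barrier_params()] ground truth.
#' @param protocol A [step_protocol()].
#' @param ion An [ion_spec()].
#' @param noise A [noise_model()].
#' @param thermo A [thermo()].
#' @param patch_id Identifier string.
#' @param voltage_offset_mV Voltage offset of this patch (mV).
#' @param amplitude_scale Per-patch multiplicative amplitude factor.
#' @param calcium_mM Intracellular Ca2+ (1 mM = saturating activation).
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   recordings.
#' @return A `patch_recording`: sweep data in `$sweeps` (tibble with
#'   `sweep_index`, `time_ms`, `voltage_mV`, `current_pA`) plus condition
#'   metadata and ground truth.
#' @examples
#' rec <- simulate_patch(barrier_params(), seed = 1)
#' rec$sweeps
#' @export
simulate_patch <- function(params, protocol = step_protocol(),
                           ion = ion_spec(), noise = noise_model(),
                           thermo = ivperm::thermo(),
                           patch_id = "patch-1", voltage_offset_mV = 0,
                           amplitude_scale = 1, calcium_mM = 1,
                           seed = NULL) {
  stopifnot(inherits(params, "barrier_params"),
            inherits(protocol, "step_protocol"),
            inherits(noise, "noise_model"))
  channel_fun <- function(v, s) {
    avail <- exp(-s / noise$rundown_tau_sweeps)
    avail * amplitude_scale *
      barrier_current(v - voltage_offset_mV, ion, params, thermo)
  }
  leak_fun <- function(v) {
    noise$leak_conductance_pA_per_mV * (v - voltage_offset_mV) +
      noise$leak_offset_pA
  }
  gen <- function() {
    purrr::map2_dfr(seq_along(protocol$test_voltages_mV) - 1L,
                    protocol$test_voltages_mV,
                    function(s, tv) sweep_trace(protocol, s, tv, channel_fun,
                                                leak_fun,
                                                noise$gaussian_sd_pA))
  }
  sweeps <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  new_patch_recording(sweeps, protocol, ion, calcium_mM, patch_id,
                      voltage_offset_mV, true_params = params,
                      amplitude_scale = amplitude_scale)
}

#' Simulate a Ca2+-free background recording
#'
#' The paired background recording of a patch: same protocol, leak and
#' offset, but no intracellular Ca2+, so the channel is shut and the traces
#' contain leak and noise only (no rundown).
#'
#' @inheritParams simulate_patch
#' @return A `patch_recording` with `calcium_mM = 0` and no ground truth.
#' @export
simulate_background <- function(protocol = step_protocol(),
                                noise = noise_model(),
                                thermo = ivperm::thermo(),
                                patch_id = "patch-1",
                                voltage_offset_mV = 0, seed = NULL) {
  leak_fun <- function(v) {
    noise$leak_conductance_pA_per_mV * (v - voltage_offset_mV) +
      noise$leak_offset_pA
  }
  gen <- function() {
    purrr::map2_dfr(seq_along(protocol$test_voltages_mV) - 1L,
                    protocol$test_voltages_mV,
                    function(s, tv) sweep_trace(protocol, s, tv,
                                                function(v, s) 0, leak_fun,
                                                noise$gaussian_sd_pA))
  }
  sweeps <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  new_patch_recording(sweeps, protocol, ion_spec(), 0, patch_id,
                      voltage_offset_mV)
}

#' Simulate a multi-patch, multi-construct dataset
#'
#' Emulates the study design: for each construct, `n_patches` independent
#' patches with lognormal amplitude variability (coefficient of variation
#' `patch_amplitude_cv`), uniform voltage offsets in
#' `+/- offset_range_mV`, multiplicative rundown, leak, and noise; each test
#' recording is paired with a Ca2+-free background recording sharing the
#' patch's leak and offset. When the ionic conditions are asymmetric, a
#' symmetric-solution control recording (for offset QC) is generated per
#' patch as well. All per-patch seeds derive deterministically from `seed`.
#'
#' @param constructs Named list of [barrier_params()] ground truths, e.g.
#'   `list(WT = barrier_params(), K588A = barrier_params(sigma_beta = 0.1))`.
#' @param n_patches Patches per construct (default 12, within the study's
#'   8-15 range).
#' @inheritParams simulate_patch
#' @param seed Master integer seed.
#' @return A `patch_dataset`: list with `$recordings`, `$backgrounds`,
#'   `$controls` (symmetric-condition recordings, `NULL` entries when the
#'   main condition is already symmetric) - each a list keyed by
#'   `construct.patch` - and `$info`, a tibble of per-patch draws.
#' @export
simulate_dataset <- function(constructs, n_patches = 12,
                             protocol = step_protocol(), ion = ion_spec(),
                             noise = noise_model(),
                             thermo = ivperm::thermo(), seed = 1) {
  stopifnot(is.list(constructs), length(constructs) >= 1,
            !is.null(names(constructs)), n_patches >= 1)
  symmetric <- ion$conc_in == ion$conc_out
  sym_ion <- ion_spec(ion$valence, ion$conc_out, ion$conc_out)
  draws <- withr::with_seed(seed, {
    k <- length(constructs) * n_patches
    sdlog <- sqrt(log(1 + noise$patch_amplitude_cv^2))
    tibble::tibble(
      construct = rep(names(constructs), each = n_patches),
      patch = rep(seq_len(n_patches), times = length(constructs)),
      amplitude_scale = if (sdlog > 0)
        stats::rlnorm(k, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      else rep(1, k),
      offset_mV = if (noise$offset_range_mV > 0)
        stats::runif(k, -noise$offset_range_mV, noise$offset_range_mV)
      else rep(0, k),
      seed = sample.int(.Machine$integer.max - 3L, k)
    )
  })
  draws$patch_id <- sprintf("%s.%02d", draws$construct, draws$patch)
  recs <- vector("list", nrow(draws)); bgs <- recs; ctrls <- recs
  for (r in seq_len(nrow(draws))) {
    d <- draws[r, ]
    recs[[r]] <- simulate_patch(constructs[[d$construct]], protocol, ion,
                                noise, thermo, patch_id = d$patch_id,
                                voltage_offset_mV = d$offset_mV,
                                amplitude_scale = d$amplitude_scale,
                                seed = d$seed)
    bgs[[r]] <- simulate_background(protocol, noise, thermo,
                                    patch_id = d$patch_id,
                                    voltage_offset_mV = d$offset_mV,
                                    seed = d$seed + 1L)
    if (!symmetric) {
      ctrls[[r]] <- simulate_patch(constructs[[d$construct]], protocol,
                                   sym_ion, noise, thermo,
                                   patch_id = d$patch_id,
                                   voltage_offset_mV = d$offset_mV,
                                   amplitude_scale = d$amplitude_scale,
                                   seed = d$seed + 2L)
    }
  }
  names(recs) <- draws$patch_id; names(bgs) <- draws$patch_id
  names(ctrls) <- draws$patch_id
  structure(list(recordings = recs, backgrounds = bgs,
                 controls = if (symmetric) NULL else ctrls,
                 info = draws, ion = ion, protocol = protocol,
                 noise = noise, thermo = thermo, seed = seed),
            class = "patch_dataset")
}

#' @export
print.patch_dataset <- function(x, ...) {
  cat(sprintf("<patch_dataset> %d recording(s): %s\n",
              length(x$recordings),
              paste(unique(x$info$construct), collapse = ", ")))
  invisible(x)
}
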