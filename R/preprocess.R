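new_instantaneous_iv <- function(tbl, patch_id,
                                 background_subtracted = FALSE,
                                 rundown_corrected = FALSE) {
  attr(tbl, "patch_id") <- patch_id
  attr(tbl, "background_subtracted") <- background_subtracted
  attr(tbl, "rundown_corrected") <- rundown_corrected
  class(tbl) <- unique(c("instantaneous_iv", class(tbl)))
  tbl
}

#' Extract instantaneous currents from a recording
#'
#' Measures the instantaneous current after each voltage jump of every sweep
#' as the mean of the samples falling in `[window[1], window[2])` ms after
#' the jump (pre-pulse and test step separately). The window must start at
#' or after the protocol's dead time and end within both segments.
#'
#' @param recording A `patch_recording`.
#' @param window_ms Length-2 numeric, averaging window after each jump in
#'   ms (default 0.5 to 2.0).
#' @return A tibble of class `instantaneous_iv` with one row per sweep:
#'   `sweep_index`, `voltage_mV` (test voltage), `i_prepulse_pA`,
#'   `i_test_pA`; correction-state flags are carried as attributes.
#' @export
extract_instantaneous <- function(recording, window_ms = c(0.5, 2)) {
  stopifnot(inherits(recording, "patch_recording"))
  p <- recording$protocol
  if (length(window_ms) != 2 || window_ms[1] >= window_ms[2] ||
      window_ms[1] < p$dead_time_ms ||
      window_ms[2] > min(p$prepulse_duration_ms, p$test_duration_ms)) {
    rlang::abort(paste0(
      "Averaging window must lie after the dead time (",
      p$dead_time_ms, " ms) and within both step segments."),
      class = "ivperm_invalid_window")
  }
  pp <- p$prepulse_duration_ms
  out <- recording$sweeps |>
    dplyr::group_by(.data$sweep_index) |>
    dplyr::summarise(
      voltage_mV = .data$voltage_mV[.data$time_ms >= pp][1],
      i_prepulse_pA = mean(.data$current_pA[.data$time_ms >= window_ms[1] &
                                              .data$time_ms < window_ms[2]]),
      i_test_pA = mean(.data$current_pA[.data$time_ms >= pp + window_ms[1] &
                                          .data$time_ms < pp + window_ms[2]]),
      .groups = "drop") |>
    dplyr::arrange(.data$sweep_index)
  new_instantaneous_iv(out, recording$patch_id)
}

#' Subtract a background recording
#'
#' Pointwise subtraction of the Ca2+-free background measurement at matched
#' test voltages (and at the pre-pulse), removing the leak contribution.
#' Must precede rundown correction.
#'
#' @param iv,background `instantaneous_iv` tables from the same patch with
#'   identical test voltages.
#' @return `iv` with background removed and the `background_subtracted`
#'   flag set.
#' @export
subtract_background <- function(iv, background) {
  stopifnot(inherits(iv, "instantaneous_iv"),
            inherits(background, "instantaneous_iv"))
  if (!identical(attr(iv, "patch_id"), attr(background, "patch_id"))) {
    rlang::abort("Background is from a different patch.",
                 class = "ivperm_pairing_error")
  }
  if (!isTRUE(all.equal(iv$voltage_mV, background$voltage_mV))) {
    rlang::abort("Background test voltages do not match the recording.",
                 class = "ivperm_pairing_error")
  }
  if (isTRUE(attr(iv, "background_subtracted"))) {
    rlang::abort("Background already subtracted.",
                 class = "ivperm_state_error")
  }
  out <- iv
  out$i_prepulse_pA <- iv$i_prepulse_pA - background$i_prepulse_pA
  out$i_test_pA <- iv$i_test_pA - background$i_test_pA
  new_instantaneous_iv(out, attr(iv, "patch_id"),
                       background_subtracted = TRUE)
}

#' Correct for channel rundown using the pre-pulse reference
#'
#' Divides each sweep's test current by the fraction of pre-pulse (+80 mV)
#' current remaining relative to the first sweep. Because rundown scales the
#' pre-pulse and the test response of a sweep by the same availability
#' factor, this restores every sweep to the first sweep's availability;
#' skipping it lets rundown masquerade as rectification. Requires background
#' subtraction first.
#'
#' @param iv An `instantaneous_iv` with background subtracted.
#' @param min_fraction Reference floor: the reference pre-pulse current must
#'   exceed this fraction of the largest absolute pre-pulse current
#'   (default 0.01).
#' @return `iv` with rundown-corrected currents and the flag set.
#' @export
correct_rundown <- function(iv, min_fraction = 0.01) {
  stopifnot(inherits(iv, "instantaneous_iv"))
  if (!isTRUE(attr(iv, "background_subtracted"))) {
    rlang::abort("Subtract the background before rundown correction.",
                 class = "ivperm_state_error")
  }
  if (isTRUE(attr(iv, "rundown_corrected"))) {
    rlang::abort("Rundown already corrected.", class = "ivperm_state_error")
  }
  ref <- iv$i_prepulse_pA[which.min(iv$sweep_index)]
  if (abs(ref) < min_fraction * max(abs(iv$i_prepulse_pA))) {
    rlang::abort("Reference pre-pulse current too small to correct rundown.",
                 class = "ivperm_uncorrectable_rundown")
  }
  remaining <- iv$i_prepulse_pA / ref
  out <- iv
  out$i_test_pA <- iv$i_test_pA / remaining
  out$i_prepulse_pA <- iv$i_prepulse_pA / remaining
  new_instantaneous_iv(out, attr(iv, "patch_id"),
                       background_subtracted = TRUE,
                       rundown_corrected = TRUE)
}

#' Normalize to the response at +120 mV
#'
#' Divides all test currents by the current at +120 mV, producing the
#' dimensionless I/I(120 mV) curve used for fitting and averaging. Requires
#' prior rundown correction.
#'
#' @param iv A rundown-corrected `instantaneous_iv` containing +120 mV.
#' @param min_fraction Floor for the +120 mV divisor as a fraction of the
#'   largest absolute test current (default 0.01).
#' @return An [iv_curve()] tibble in normalized units.
#' @export
normalize_iv <- function(iv, min_fraction = 0.01) {
  stopifnot(inherits(iv, "instantaneous_iv"))
  if (!isTRUE(attr(iv, "rundown_corrected"))) {
    rlang::abort("Correct rundown before normalizing.",
                 class = "ivperm_state_error")
  }
  tbl <- dplyr::arrange(iv, .data$voltage_mV)
  i120 <- tbl$i_test_pA[tbl$voltage_mV == 120]
  if (length(i120) != 1) {
    rlang::abort("+120 mV must be present exactly once.",
                 class = "ivperm_invalid_argument")
  }
  if (abs(i120) < min_fraction * max(abs(tbl$i_test_pA))) {
    rlang::abort("Current at +120 mV too small to normalize.",
                 class = "ivperm_degenerate_normalization")
  }
  iv_curve(tbl$voltage_mV, tbl$i_test_pA / i120,
           normalization = "normalized_to_plus120mV")
}

#' Voltage-offset quality control
#'
#' Estimates the residual voltage offset of a patch from a recording made in
#' symmetrical solutions: the offset is the zero crossing of the
#' instantaneous I-V relation (linear interpolation between the bracketing
#' voltages). Patches with an absolute offset of 2 mV or more are rejected.
#'
#' @param recording A `patch_recording` made in symmetrical solutions.
#' @param background Optional paired background recording, subtracted before
#'   the zero crossing is located (recommended whenever a leak offset may be
#'   present).
#' @param window_ms Averaging window, as in [extract_instantaneous()].
#' @param threshold_mV Acceptance threshold (default 2 mV, strict).
#' @return One-row tibble of class `qc_report`: `patch_id`,
#'   `voltage_offset_mV`, `offset_pass`, `n_sweeps_used`,
#'   `exclusion_reasons` (comma-separated, empty when accepted).
#' @export
qc_patch <- function(recording, background = NULL, window_ms = c(0.5, 2),
                     threshold_mV = 2) {
  iv <- extract_instantaneous(recording, window_ms)
  if (!is.null(background)) {
    iv <- subtract_background(iv, extract_instantaneous(background,
                                                        window_ms))
    iv <- correct_rundown(iv)
  }
  tbl <- dplyr::arrange(iv, .data$voltage_mV)
  offset <- tryCatch(zero_crossing(tbl$voltage_mV, tbl$i_test_pA),
                     error = function(e) NA_real_)
  reasons <- character()
  if (is.na(offset)) {
    reasons <- c(reasons, "offset_indeterminate")
  } else if (abs(offset) >= threshold_mV) {
    reasons <- c(reasons, sprintf("offset_%.2f_mV_exceeds_threshold", offset))
  }
  out <- tibble::tibble(
    patch_id = recording$patch_id,
    voltage_offset_mV = offset,
    offset_pass = !is.na(offset) && abs(offset) < threshold_mV,
    n_sweeps_used = nrow(tbl),
    exclusion_reasons = paste(reasons, collapse = ","))
  class(out) <- c("qc_report", class(out))
  out
}

#' Average normalized I-V curves across patches
#'
#' Pointwise mean and standard error of the mean (sd/sqrt(n)) over replicate
#' normalized curves sharing the same voltage grid.
#'
#' @param curves List of normalized [iv_curve()] tibbles on one grid.
#' @return An [iv_curve()] with `sem` and `n_patches` columns.
#' @export
aggregate_patches <- function(curves) {
  stopifnot(is.list(curves), length(curves) >= 1)
  if (!all(vapply(curves, is_normalized, logical(1)))) {
    rlang::abort("All curves must be normalized before averaging.",
                 class = "ivperm_state_error")
  }
  grid <- curves[[1]]$voltage_mV
  ok <- vapply(curves, function(cv) isTRUE(all.equal(cv$voltage_mV, grid)),
               logical(1))
  if (!all(ok)) {
    rlang::abort("Curves are not on a common voltage grid.",
                 class = "ivperm_alignment_error")
  }
  m <- vapply(curves, function(cv) cv$current, numeric(length(grid)))
  m <- matrix(m, nrow = length(grid))
  n <- length(curves)
  iv_curve(grid, rowMeans(m),
           sem = if (n > 1) apply(m, 1, stats::sd) / sqrt(n) else rep(0, length(grid)),
           n_patches = rep(n, length(grid)),
           normalization = "normalized_to_plus120mV")
}

#' Full per-patch preprocessing
#'
#' Convenience wrapper running extraction, background subtraction, rundown
#' correction and normalization in the prescribed order.
#'
#' @inheritParams qc_patch
#' @param recording,background Paired test and Ca2+-free recordings.
#' @return A normalized [iv_curve()].
#' @export
preprocess_patch <- function(recording, background, window_ms = c(0.5, 2)) {
  extract_instantaneous(recording, window_ms) |>
    subtract_background(extract_instantaneous(background, window_ms)) |>
    correct_rundown() |>
    normalize_iv()
}

#' Preprocess a whole synthetic dataset
#'
#' Runs offset QC on every patch (using the symmetric-condition control when
#' the main condition is asymmetric), preprocesses the accepted patches, and
#' averages them per construct.
#'
#' @param dataset A `patch_dataset` from [simulate_dataset()].
#' @param window_ms Averaging window, as in [extract_instantaneous()].
#' @return A list: `$qc` (tibble, one row per patch), `$patch_curves` (named
#'   list of accepted per-patch curves), `$aggregated` (named list of mean
#'   [iv_curve()]s per construct), `$table` (tidy tibble with `construct`,
#'   `voltage_mV`, `mean_norm_current`, `sem`, `n_patches`).
#' @export
preprocess_dataset <- function(dataset, window_ms = c(0.5, 2)) {
  stopifnot(inherits(dataset, "patch_dataset"))
  ids <- dataset$info$patch_id
  qc <- purrr::map_dfr(ids, function(id) {
    rec <- if (is.null(dataset$controls)) dataset$recordings[[id]]
           else dataset$controls[[id]]
    qc_patch(rec, dataset$backgrounds[[id]], window_ms)
  })
  qc$construct <- dataset$info$construct
  accepted <- ids[qc$offset_pass]
  curves <- purrr::map(accepted, function(id) {
    preprocess_patch(dataset$recordings[[id]], dataset$backgrounds[[id]],
                     window_ms)
  })
  names(curves) <- accepted
  by_construct <- split(accepted,
                        dataset$info$construct[match(accepted, ids)])
  aggregated <- purrr::map(by_construct,
                           function(ids2) aggregate_patches(curves[ids2]))
  table <- purrr::imap_dfr(aggregated, function(cv, nm) {
    tibble::tibble(construct = nm, voltage_mV = cv$voltage_mV,
                   mean_norm_current = cv$current, sem = cv$sem,
                   n_patches = cv$n_patches)
  })
  list(qc = qc, patch_curves = curves, aggregated = aggregated,
       table = table)
}
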