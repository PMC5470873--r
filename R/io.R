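#' Write recordings to CSV with a JSON sidecar
#'
#' Sweep samples go to a single CSV (columns `patch_id`, `sweep_index`,
#' `time_ms`, `voltage_mV`, `current_pA`); protocol, ionic conditions,
#' offsets and - for synthetic data - the ground-truth parameters go to a
#' JSON sidecar next to it.
#'
#' @param recordings A `patch_recording` or list of them.
#' @param path Path of the CSV file; the sidecar is written to the same
#'   path with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_sweeps <- function(recordings, path) {
  if (inherits(recordings, "patch_recording")) recordings <- list(recordings)
  stopifnot(all(vapply(recordings, inherits, logical(1), "patch_recording")))
  tbl <- purrr::map_dfr(recordings, function(r) {
    dplyr::mutate(r$sweeps, patch_id = r$patch_id, .before = 1)
  })
  readr::write_csv(tbl, path)
  meta <- purrr::map(recordings, function(r) {
    list(patch_id = r$patch_id,
         calcium_mM = r$calcium_mM,
         voltage_offset_mV = r$voltage_offset_mV,
         amplitude_scale = r$amplitude_scale,
         ion = unclass(r$ion),
         protocol = unclass(r$protocol),
         true_params = if (!is.null(r$true_params))
           unclass(r$true_params) else NULL)
  })
  names(meta) <- vapply(recordings, function(r) r$patch_id, character(1))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

#' Read recordings from CSV + JSON sidecar
#'
#' Inverse of [write_sweeps()]. The CSV schema is validated; malformed or
#' missing values are reported with their file line numbers. A warning is
#' issued for patches whose sweeps lack a +120 mV test step, since
#' normalization will fail downstream.
#'
#' @param path Path of the sweep CSV; the sidecar is read from the matching
#'   `.json` path.
#' @return A named list of `patch_recording` objects.
#' @export
read_sweeps <- function(path) {
  if (!file.exists(path) || !file.exists(sidecar_path(path))) {
    rlang::abort("Sweep CSV or its JSON sidecar not found.",
                 class = "ivperm_parse_error")
  }
  required <- c("patch_id", "sweep_index", "time_ms", "voltage_mV",
                "current_pA")
  tbl <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) rlang::abort(conditionMessage(e),
                                     class = "ivperm_parse_error"))
  if (!all(required %in% names(tbl))) {
    rlang::abort(paste("Missing columns:",
                       paste(setdiff(required, names(tbl)), collapse = ", ")),
                 class = "ivperm_parse_error")
  }
  bad <- which(!stats::complete.cases(tbl[required]) |
                 !is.finite(tbl$current_pA))
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "Malformed rows at line(s) %s of %s (counting the header as line 1).",
      paste(utils::head(bad + 1, 5), collapse = ", "), basename(path)),
      class = "ivperm_parse_error")
  }
  meta <- jsonlite::read_json(sidecar_path(path))
  recs <- purrr::map(meta, function(m) {
    sw <- dplyr::filter(tbl, .data$patch_id == m$patch_id) |>
      dplyr::select(-"patch_id")
    if (nrow(sw) == 0) {
      rlang::abort(sprintf("No sweep rows for patch '%s'.", m$patch_id),
                   class = "ivperm_parse_error")
    }
    pr <- m$protocol
    protocol <- step_protocol(
      test_voltages_mV = unlist(pr$test_voltages_mV),
      prepulse_voltage_mV = pr$prepulse_voltage_mV,
      prepulse_duration_ms = pr$prepulse_duration_ms,
      test_duration_ms = pr$test_duration_ms,
      holding_voltage_mV = pr$holding_voltage_mV,
      sample_rate_kHz = pr$sample_rate_kHz,
      filter_cutoff_kHz = pr$filter_cutoff_kHz,
      dead_time_ms = pr$dead_time_ms)
    if (!120 %in% unique(sw$voltage_mV)) {
      rlang::warn(sprintf(
        "Patch '%s' has no +120 mV sweep; normalization will fail.",
        m$patch_id))
    }
    tp <- NULL
    if (is.list(m$true_params) && !is.null(m$true_params$sigma_beta)) {
      tp <- barrier_params(m$true_params$sigma_beta, m$true_params$sigma_h,
                           m$true_params$amplitude,
                           m$true_params$n_barriers)
    }
    new_patch_recording(
      tibble::as_tibble(sw), protocol,
      ion_spec(m$ion$valence, m$ion$conc_in, m$ion$conc_out),
      m$calcium_mM, m$patch_id, m$voltage_offset_mV, true_params = tp,
      amplitude_scale = m$amplitude_scale %||% 1)
  })
  names(recs) <- vapply(meta, function(m) m$patch_id, character(1))
  recs
}
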