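#' Reversal potential from an I-V curve
#'
#' Zero crossing of the measured I-V relation by linear interpolation
#' between the bracketing voltage pair, minus the patch's voltage offset
#' when a QC report is supplied (the offset is measured in symmetrical
#' solutions and subtracted from reversal potentials obtained under
#' asymmetric conditions).
#'
#' @param curve An I-V table (`voltage_mV`, `current`) crossing zero exactly
#'   once within its range.
#' @param qc Optional `qc_report` for the same patch (its
#'   `voltage_offset_mV` is subtracted), or a plain number: the averaged
#'   offset, for constructs without usable per-patch symmetric data.
#'   Supplying a correction for a curve whose offset was already removed is
#'   an error.
#' @return One-row tibble: `erev_raw_mV` (interpolated crossing),
#'   `offset_mV` (0 when no report given), `erev_mV` (corrected value).
#' @examples
#' curve <- barrier_iv(seq(-100, 120, 20), ion_spec(conc_in = 15),
#'                     barrier_params())
#' estimate_reversal(curve)   # about -58.5 mV
#' @export
estimate_reversal <- function(curve, qc = NULL) {
  stopifnot(all(c("voltage_mV", "current") %in% names(curve)))
  if (!is.null(qc) && isTRUE(attr(curve, "offset_corrected"))) {
    rlang::abort("Offset was already subtracted from this curve.",
                 class = "ivperm_state_error")
  }
  raw <- zero_crossing(curve$voltage_mV, curve$current)
  offset <- 0
  if (!is.null(qc)) {
    if (inherits(qc, "qc_report")) {
      if (is.na(qc$voltage_offset_mV)) {
        rlang::abort("QC report carries no measurable offset.",
                     class = "ivperm_invalid_argument")
      }
      offset <- qc$voltage_offset_mV
    } else if (is.numeric(qc) && length(qc) == 1 && is.finite(qc)) {
      offset <- qc
    } else {
      rlang::abort("`qc` must be a qc_report or a single numeric offset.",
                   class = "ivperm_invalid_argument")
    }
  }
  tibble::tibble(erev_raw_mV = raw, offset_mV = offset,
                 erev_mV = raw - offset)
}

#' Nernst-comparison selectivity table
#'
#' For each intracellular Cl- concentration, compares the offset-corrected
#' reversal potential with the Nernst potential of Cl-. Small deviations
#' across a concentration series indicate that the channel remains strongly
#' anion selective under all tested conditions.
#'
#' @param curves Named list of I-V tables, one per intracellular condition;
#'   names are the intracellular Cl- concentrations in mM (>= 2 required).
#' @param cl_out_mM Extracellular Cl- concentration (default 150 mM).
#' @param qc_reports Optional named list of `qc_report`s or numeric offsets
#'   parallel to `curves` (per-condition offset subtraction); or a single
#'   report/offset applied to all conditions (the averaged-offset fallback
#'   used when per-patch symmetric data are unavailable).
#' @param thermo A [thermo()].
#' @param construct Construct label carried into the output.
#' @return A tibble of class `selectivity_result`, one row per condition:
#'   `construct`, `cl_in_mM`, `erev_raw_mV`, `erev_mV`, `nernst_mV`,
#'   `deviation_mV`; the maximum absolute deviation is available via
#'   `max(abs(.$deviation_mV))`.
#' @export
selectivity_table <- function(curves, cl_out_mM = 150, qc_reports = NULL,
                              thermo = ivperm::thermo(), construct = "WT") {
  if (length(curves) < 2 || is.null(names(curves))) {
    rlang::abort(">= 2 named intracellular concentrations required.",
                 class = "ivperm_invalid_argument")
  }
  single_qc <- inherits(qc_reports, "qc_report") ||
    (is.numeric(qc_reports) && length(qc_reports) == 1)
  out <- purrr::imap_dfr(curves, function(cv, nm) {
    qc <- if (single_qc) qc_reports else qc_reports[[nm]]
    est <- estimate_reversal(cv, qc)
    cl_in <- as.numeric(nm)
    nernst <- nernst_potential(ion_spec(-1, cl_in, cl_out_mM), thermo)
    tibble::tibble(construct = construct, cl_in_mM = cl_in,
                   erev_raw_mV = est$erev_raw_mV, erev_mV = est$erev_mV,
                   nernst_mV = nernst,
                   deviation_mV = est$erev_mV - nernst)
  }) |> dplyr::arrange(dplyr::desc(.data$cl_in_mM))
  class(out) <- c("selectivity_result", class(out))
  out
}

#' Nernst-slope regression
#'
#' Regresses corrected reversal potentials on ln([Cl-]out/[Cl-]in). For a
#' perfectly Cl--selective pore the slope is RT/zF per e-fold, about
#' -25.4 mV at 295 K for z = -1.
#'
#' @param table A `selectivity_result` with >= 3 conditions.
#' @return One-row tibble: `slope_mV_per_efold`, `intercept_mV`,
#'   `r_squared`.
#' @export
nernst_slope <- function(table) {
  stopifnot(inherits(table, "selectivity_result"))
  if (nrow(table) < 3) {
    rlang::abort(">= 3 conditions required for the slope regression.",
                 class = "ivperm_invalid_argument")
  }
  # x = ln(c_out/c_in) up to an additive constant (which only moves the
  # intercept, never the slope)
  x <- log(max(table$cl_in_mM) / table$cl_in_mM)
  fit <- stats::lm(erev_mV ~ x, data = cbind(table, x = x))
  s <- summary(fit)
  tibble::tibble(slope_mV_per_efold = unname(stats::coef(fit)[2]),
                 intercept_mV = unname(stats::coef(fit)[1]),
                 r_squared = s$r.squared)
}
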