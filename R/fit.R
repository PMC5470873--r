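#' Fit the barrier model to a normalized I-V curve
#'
#' Weighted least-squares fit of the n-barrier model to an I/I(120 mV)
#' curve. The amplitude cancels by evaluating the model normalized to its
#' own +120 mV response, leaving two free parameters (sigma_beta, sigma_h)
#' searched in log space within bounds, from a 3x3 multistart grid of
#' log-spaced starting values; the best converged start wins. Weights are
#' 1/sem^2 where a positive standard error is available, uniform otherwise
#' (points with sem = 0 get zero weight when other points carry one).
#' Confidence intervals come from the local quadratic approximation at the
#' optimum and are descriptive only - the barrier model itself is a
#' phenomenological description, not a physical pore map.
#'
#' @param curve A normalized [iv_curve()] with at least 5 voltages spanning
#'   both signs.
#' @param ion An [ion_spec()] describing the recording solutions.
#' @param thermo A [thermo()].
#' @param n_barriers Fixed structural barrier count (default 3).
#' @param bounds Length-2 bounds on both sigmas (default `c(1e-3, 1e3)`).
#' @return An object of class `barrier_fit`; see [tidy.barrier_fit()] and
#'   [glance.barrier_fit()] for tabular summaries.
#' @examples
#' curve <- barrier_iv(seq(-100, 120, 20), ion_spec(),
#'                     barrier_params(sigma_beta = 0.1), normalize = TRUE)
#' fit <- fit_barrier_model(curve, ion_spec())
#' tidy(fit)
#' @export
fit_barrier_model <- function(curve, ion = ion_spec(),
                              thermo = ivperm::thermo(), n_barriers = 3,
                              bounds = c(1e-3, 1e3)) {
  if (!is_normalized(curve)) {
    rlang::abort("`curve` must be normalized to +120 mV before fitting.",
                 class = "ivperm_precondition_error")
  }
  v <- curve$voltage_mV
  if (length(v) < 5 || min(v) >= 0 || max(v) <= 0) {
    rlang::abort("Need >= 5 voltages spanning negative and positive values.",
                 class = "ivperm_precondition_error")
  }
  y <- curve$current
  w <- rep(1, length(v))
  if ("sem" %in% names(curve) && any(curve$sem > 0)) {
    w <- ifelse(curve$sem > 0, 1 / curve$sem^2, 0)
  }
  model_norm <- function(logsig) {
    p <- barrier_params(exp(logsig[1]), exp(logsig[2]),
                        n_barriers = n_barriers)
    barrier_current(v, ion, p, thermo) /
      barrier_current(120, ion, p, thermo)
  }
  obj <- function(logsig) sum(w * (y - model_norm(logsig))^2)
  starts <- unname(as.matrix(expand.grid(log(c(0.1, 1, 10)),
                                         log(c(0.1, 1, 10)))))
  lo <- log(bounds[1]); hi <- log(bounds[2])
  fits <- apply(starts, 1, function(s) {
    tryCatch(stats::optim(s, obj, method = "L-BFGS-B", lower = lo,
                          upper = hi,
                          control = list(factr = 1e4, maxit = 500)),
             error = function(e) NULL)
  })
  fits <- Filter(function(f) !is.null(f) && is.finite(f$value), fits)
  if (length(fits) == 0) {
    rlang::abort("Barrier-model fit failed from every starting point.",
                 class = "ivperm_fit_failure")
  }
  vals <- vapply(fits, function(f) f$value, numeric(1))
  best <- fits[[which.min(vals)]]
  est <- unname(best$par)
  # a start placed at the optimum can abort its line search with an
  # "abnormal termination" code while returning the exact minimizer; judge
  # convergence against the best cleanly-converged start instead
  conv_vals <- vals[vapply(fits, function(f) f$convergence == 0, logical(1))]
  converged <- best$convergence == 0 ||
    (length(conv_vals) > 0 && best$value <= min(conv_vals) + 1e-10)
  params_hat <- barrier_params(exp(est[1]), exp(est[2]),
                               n_barriers = n_barriers)
  # descriptive covariance of (ln sigma_beta, ln sigma_h) from local
  # curvature: cov = 2 s^2 H^-1 with H the hessian of the weighted SSE
  ndf <- max(1, sum(w > 0) - 2)
  s2 <- best$value / ndf
  se <- rep(NA_real_, 2)
  hess <- tryCatch(stats::optimHess(est, obj), error = function(e) NULL)
  if (!is.null(hess)) {
    cv <- tryCatch(2 * s2 * solve(hess), error = function(e) NULL)
    if (!is.null(cv) && all(diag(cv) >= 0)) se <- sqrt(diag(cv))
  }
  sym_ion <- ion_spec(ion$valence,
                      conc_in = ion$conc_out, conc_out = ion$conc_out)
  structure(list(
    params_hat = params_hat,
    energy_profile = energy_profile(params_hat, thermo),
    rectification_index = rectification_index(params_hat, sym_ion, thermo),
    residual_norm = sqrt(best$value),
    log_sigma = stats::setNames(est, c("log_sigma_beta", "log_sigma_h")),
    log_sigma_se = stats::setNames(se, c("log_sigma_beta", "log_sigma_h")),
    converged = converged,
    n_barriers_fixed = n_barriers,
    n_points = length(v),
    curve = curve, ion = ion, thermo = thermo,
    fitted = model_norm(est)), class = "barrier_fit")
}

#' @export
print.barrier_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<barrier_fit> n = %d barriers: sigma_beta = %.4g, ",
           "sigma_h = %.4g, RI = %.3f, residual norm = %.3g%s\n"),
    x$n_barriers_fixed, x$params_hat$sigma_beta, x$params_hat$sigma_h,
    x$rectification_index, x$residual_norm,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Tidy a barrier-model fit
#'
#' @param x A `barrier_fit`.
#' @param conf_level Level of the descriptive (local-curvature) confidence
#'   intervals on the log-sigma scale.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate` (sigma
#'   scale), `delta_ea_kJmol` (energy offset vs the outermost barrier),
#'   `conf_low`, `conf_high` (sigma scale).
#' @export
tidy.barrier_fit <- function(x, conf_level = 0.95, ...) {
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- x$log_sigma; se <- x$log_sigma_se
  ep <- x$energy_profile
  tibble::tibble(
    term = c("sigma_beta", "sigma_h"),
    estimate = exp(est),
    delta_ea_kJmol = c(ep$delta_ea_in_minus_out_kJmol,
                       ep$delta_ea_mid_minus_out_kJmol),
    conf_low = exp(est - zq * se),
    conf_high = exp(est + zq * se))
}

#' Glance at a barrier-model fit
#'
#' @param x A `barrier_fit`.
#' @param ... Unused.
#' @return One-row tibble with fit-level summaries: `rectification_index`,
#'   `residual_norm`, `n_points`, `n_barriers`, `converged`.
#' @export
glance.barrier_fit <- function(x, ...) {
  tibble::tibble(rectification_index = x$rectification_index,
                 residual_norm = x$residual_norm,
                 n_points = x$n_points,
                 n_barriers = x$n_barriers_fixed,
                 converged = x$converged)
}

#' Refit at alternative barrier counts
#'
#' Sensitivity check: refits the same curve with the barrier count fixed at
#' each value of `n_set`.
#'
#' @inheritParams fit_barrier_model
#' @param n_set Barrier counts to try (default 3, 4, 5).
#' @return Tibble with one row per `n_barriers`: the fitted sigmas, RI and
#'   residual norm.
#' @export
fit_sensitivity <- function(curve, ion = ion_spec(),
                            thermo = ivperm::thermo(), n_set = c(3, 4, 5),
                            bounds = c(1e-3, 1e3)) {
  purrr::map_dfr(n_set, function(n) {
    f <- fit_barrier_model(curve, ion, thermo, n_barriers = n,
                           bounds = bounds)
    tibble::tibble(n_barriers = n, sigma_beta = f$params_hat$sigma_beta,
                   sigma_h = f$params_hat$sigma_h,
                   rectification_index = f$rectification_index,
                   residual_norm = f$residual_norm)
  })
}

#' Slope conductance around a voltage
#'
#' Local linear fit of a raw I-V relation within a window around
#' `at_mV` (the study reads it at -100 mV); the slope is the conductance.
#'
#' @param curve A raw-current I-V table (`voltage_mV`, `current` in pA).
#' @param at_mV Voltage at which to evaluate (default -100).
#' @param window_mV Half-width of the fitting window (default 20 mV).
#' @return Conductance in pA/mV (= nS).
#' @export
slope_conductance <- function(curve, at_mV = -100, window_mV = 20) {
  stopifnot(all(c("voltage_mV", "current") %in% names(curve)))
  sel <- abs(curve$voltage_mV - at_mV) <= window_mV
  if (sum(sel) < 2) {
    rlang::abort("Need at least 2 points within the window.",
                 class = "ivperm_insufficient_points")
  }
  unname(stats::coef(stats::lm(current ~ voltage_mV,
                               data = curve[sel, ]))[2])
}

#' Concentration-conductance relationship
#'
#' Slope conductance at `at_mV` for each intracellular Cl- concentration,
#' with an optional saturating-hyperbola summary
#' G = G_max c / (c + K_half). The barrier model itself is linear in
#' concentration, so on model-generated data the relationship is a straight
#' line and the hyperbola's K_half is unbounded; the hyperbola is reported
#' as a descriptive summary only.
#'
#' @param curves Named list of raw [iv_curve()]s; names are the
#'   intracellular Cl- concentrations in mM.
#' @param at_mV Evaluation voltage (default -100).
#' @param window_mV Window half-width for [slope_conductance()].
#' @param fit_hyperbola Attempt the saturating fit (needs >= 2 distinct
#'   concentrations; silently skipped if the fit fails to converge).
#' @return A list: `$table` (tibble `conc_mM`, `conductance_pA_per_mV`) and
#'   `$hyperbola` (one-row tibble `g_max`, `k_half_mM`, or `NULL`).
#' @export
concentration_conductance <- function(curves, at_mV = -100, window_mV = 20,
                                      fit_hyperbola = TRUE) {
  if (length(curves) == 0 || is.null(names(curves))) {
    rlang::abort("`curves` must be a nonempty named list.",
                 class = "ivperm_invalid_argument")
  }
  tbl <- purrr::imap_dfr(curves, function(cv, nm) {
    tibble::tibble(conc_mM = as.numeric(nm),
                   conductance_pA_per_mV = slope_conductance(cv, at_mV,
                                                             window_mV))
  }) |> dplyr::arrange(.data$conc_mM)
  hyp <- NULL
  if (fit_hyperbola && length(unique(tbl$conc_mM)) >= 2) {
    hyp <- tryCatch({
      fit <- stats::nls(
        conductance_pA_per_mV ~ gmax * conc_mM / (conc_mM + khalf),
        data = tbl,
        start = list(gmax = max(tbl$conductance_pA_per_mV) * 2,
                     khalf = stats::median(tbl$conc_mM)),
        control = stats::nls.control(warnOnly = TRUE))
      cf <- stats::coef(fit)
      tibble::tibble(g_max = unname(cf["gmax"]),
                     k_half_mM = unname(cf["khalf"]))
    }, error = function(e) NULL)
  }
  list(table = tbl, hyperbola = hyp)
}
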