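# Ion stoichiometry per formula unit for the salts used in the recording
# solutions. Unknown components are kept in the map but contribute no Cl-,
# Na+ or Ca2+.
salt_stoichiometry <- function() {
  tibble::tribble(
    ~salt,        ~cl, ~na, ~ca, ~egta,
    "NaCl",         1,   1,   0,     0,
    "KCl",          1,   0,   0,     0,
    "CaCl2",        2,   0,   1,     0,
    "MgCl2",        2,   0,   0,     0,
    "HCl",          1,   0,   0,     0,
    "NMDG-Cl",      1,   0,   0,     0,
    "Ca(OH)2",      0,   0,   1,     0,
    "CaSO4",        0,   0,   1,     0,
    "NaOH",         0,   1,   0,     0,
    "Na2SO4",       0,   2,   0,     0,
    "EGTA",         0,   0,   0,     1,
    "HEPES",        0,   0,   0,     0,
    "(NMDG)2SO4",   0,   0,   0,     0)
}

#' Recording-solution composition
#'
#' A named map of salt concentrations (mM) with derived total Cl-, Na+ and
#' nominal free Ca2+. Free Ca2+ is bookkept as max(0, total Ca - EGTA) - the
#' convention under which the standard NaCl buffer (150 NaCl, 5.99 Ca(OH)2,
#' 5 EGTA, 10 HEPES) carries its working concentration of ~1 mM Ca2+ - not
#' a multi-equilibrium speciation calculation.
#'
#' @param ... Salt concentrations in mM, e.g. `NaCl = 150, EGTA = 5`.
#'   Component names are matched against a built-in stoichiometry table;
#'   unknown names are retained but contribute no derived ions.
#' @param pH Solution pH (default 7.4).
#' @return An object of class `solution_spec`.
#' @examples
#' nacl_buffer()
#' cl_mM(nacl_buffer())
#' @export
solution_spec <- function(..., pH = 7.4) {
  comp <- c(...)
  if (length(comp) == 0 || is.null(names(comp)) || any(names(comp) == "")) {
    rlang::abort("Provide named salt concentrations in mM.",
                 class = "ivperm_invalid_argument")
  }
  if (any(!is.finite(comp)) || any(comp < 0)) {
    rlang::abort("Concentrations must be finite and non-negative.",
                 class = "ivperm_invalid_argument")
  }
  structure(list(components = comp, pH = pH), class = "solution_spec")
}

#' @export
print.solution_spec <- function(x, ...) {
  cat("<solution_spec> pH", x$pH, "\n")
  for (nm in names(x$components)) {
    cat(sprintf("  %-12s %g mM\n", nm, x$components[[nm]]))
  }
  cat(sprintf("  [Cl-] = %g mM, [Na+] = %g mM, free Ca2+ ~ %g mM\n",
              cl_mM(x), na_mM(x), free_ca_mM(x)))
  invisible(x)
}

ion_total <- function(sol, column) {
  st <- salt_stoichiometry()
  idx <- match(names(sol$components), st$salt)
  mult <- ifelse(is.na(idx), 0, st[[column]][idx])
  sum(mult * sol$components)
}

#' @rdname solution_spec
#' @param sol A `solution_spec`.
#' @return `cl_mM()`, `na_mM()`: total chloride / sodium in mM;
#'   `free_ca_mM()`: nominal free Ca2+ in mM.
#' @export
cl_mM <- function(sol) ion_total(sol, "cl")

#' @rdname solution_spec
#' @export
na_mM <- function(sol) ion_total(sol, "na")

#' @rdname solution_spec
#' @export
free_ca_mM <- function(sol) {
  max(0, ion_total(sol, "ca") - ion_total(sol, "egta"))
}

#' Standard recording solutions
#'
#' The buffers of the functional experiments: `nacl_buffer()` (150 mM NaCl,
#' 5.99 mM Ca(OH)2, 5 mM EGTA, 10 mM HEPES, pH 7.4), the Cl--free
#' `nmdg_so4_solution()` (100 mM (NMDG)2SO4 with the same Ca/EGTA/HEPES)
#' used to dilute intracellular NaCl at constant Ca2+, and `kcl_buffer()`
#' for high-ionic-strength recordings.
#'
#' @return A [solution_spec()].
#' @export
nacl_buffer <- function() {
  solution_spec(NaCl = 150, `Ca(OH)2` = 5.99, EGTA = 5, HEPES = 10)
}

#' @rdname nacl_buffer
#' @export
nmdg_so4_solution <- function() {
  solution_spec(`(NMDG)2SO4` = 100, `Ca(OH)2` = 5.99, EGTA = 5, HEPES = 10)
}

#' @rdname nacl_buffer
#' @export
kcl_buffer <- function() {
  solution_spec(KCl = 150, `Ca(OH)2` = 5.99, EGTA = 5, HEPES = 10)
}

#' Mix two solutions
#'
#' Componentwise affine mixture `ratio * a + (1 - ratio) * b`, the operation
#' used to set intermediate intracellular NaCl concentrations by mixing the
#' NaCl buffer with the (NMDG)2SO4 solution.
#'
#' @param a,b [solution_spec()] objects with compatible pH.
#' @param ratio Volume fraction of `a` in `[0, 1]`.
#' @return A [solution_spec()].
#' @examples
#' cl_mM(mix_solutions(nacl_buffer(), nmdg_so4_solution(), 0.1))  # 15 mM
#' @export
mix_solutions <- function(a, b, ratio) {
  stopifnot(inherits(a, "solution_spec"), inherits(b, "solution_spec"))
  if (!is.numeric(ratio) || length(ratio) != 1 || ratio < 0 || ratio > 1) {
    rlang::abort("`ratio` must be a single number in [0, 1].",
                 class = "ivperm_invalid_argument")
  }
  if (abs(a$pH - b$pH) > 0.05) {
    rlang::abort("Solutions have incompatible pH.",
                 class = "ivperm_invalid_argument")
  }
  nm <- union(names(a$components), names(b$components))
  ca <- stats::setNames(rep(0, length(nm)), nm)
  cb <- ca
  ca[names(a$components)] <- a$components
  cb[names(b$components)] <- b$components
  mixed <- ratio * ca + (1 - ratio) * cb
  if (any(mixed > 0)) mixed <- mixed[mixed > 0]
  do.call(solution_spec, c(as.list(mixed), list(pH = a$pH)))
}
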