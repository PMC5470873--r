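#' Plot an I-V curve
#'
#' Points with s.e.m. error bars where available, with guide lines through
#' zero; normalized curves are labeled I/I(+120 mV).
#'
#' @param object An [iv_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.iv_curve <- function(object, ...) {
  ylab <- if (is_normalized(object)) "I / I(+120 mV)" else "current (pA)"
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$voltage_mV, y = .data$current)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey40") +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::labs(x = "voltage (mV)", y = ylab) +
    ggplot2::theme_classic()
  if ("sem" %in% names(object)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$current - .data$sem,
                   ymax = .data$current + .data$sem), width = 3)
  }
  p
}

#' Plot a barrier-model fit
#'
#' Data points (with s.e.m. where available) and the fitted model curve
#' evaluated on a fine voltage grid, annotated with the fitted parameters.
#'
#' @param object A `barrier_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.barrier_fit <- function(object, ...) {
  vgrid <- seq(min(object$curve$voltage_mV), max(object$curve$voltage_mV),
               length.out = 200)
  mc <- barrier_current(vgrid, object$ion, object$params_hat,
                        object$thermo) /
    barrier_current(120, object$ion, object$params_hat, object$thermo)
  lab <- sprintf("sigma_beta = %.3g\nsigma_h = %.3g\nRI = %.2f",
                 object$params_hat$sigma_beta, object$params_hat$sigma_h,
                 object$rectification_index)
  autoplot.iv_curve(object$curve) +
    ggplot2::geom_line(data = tibble::tibble(voltage_mV = vgrid,
                                             current = mc),
                       colour = "firebrick", linewidth = 0.6) +
    ggplot2::annotate("text", x = min(vgrid), y = max(mc), label = lab,
                      hjust = 0, vjust = 1, size = 3)
}

#' Plot a descriptive energy profile
#'
#' Schematic barrier diagram: equal wells at zero energy and barrier peaks
#' at their activation-energy offsets relative to the outermost barrier
#' (which is drawn at zero by convention - only offsets are defined).
#'
#' @param object An `energy_profile` (one row).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.energy_profile <- function(object, ...) {
  stopifnot(nrow(object) == 1)
  n <- object$n_barriers
  heights <- c(object$delta_ea_in_minus_out_kJmol,
               rep(object$delta_ea_mid_minus_out_kJmol, n - 2), 0)
  peaks <- (2 * seq_len(n) - 1) / (2 * n)
  # smooth cosine bumps between wells so the profile reads as a landscape
  xx <- seq(0, 1, length.out = 400)
  yy <- numeric(length(xx))
  for (j in seq_len(n)) {
    span <- xx >= (j - 1) / n & xx <= j / n
    phase <- (xx[span] - (j - 1) / n) * n * pi
    yy[span] <- heights[j] * (1 - cos(2 * phase)) / 2
  }
  ggplot2::ggplot(tibble::tibble(x = xx, y = yy),
                  ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::geom_point(data = tibble::tibble(x = peaks, y = heights),
                        size = 1.8) +
    ggplot2::labs(x = "electrical distance (intracellular -> extracellular)",
                  y = expression(Delta * E[a] ~ "(kJ/mol, vs outermost)")) +
    ggplot2::theme_classic()
}

#' Compare construct I-V relations
#'
#' Overlay of per-construct mean normalized I-V relations from a tidy
#' preprocessing table.
#'
#' @param table Tidy tibble with `construct`, `voltage_mV`,
#'   `mean_norm_current`, `sem` (as produced by [preprocess_dataset()]).
#' @return A ggplot object.
#' @export
plot_construct_iv <- function(table) {
  ggplot2::ggplot(table,
                  ggplot2::aes(.data$voltage_mV, .data$mean_norm_current,
                               colour = .data$construct)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_norm_current - .data$sem,
                   ymax = .data$mean_norm_current + .data$sem),
      size = 0.2) +
    ggplot2::labs(x = "voltage (mV)", y = "I / I(+120 mV)",
                  colour = NULL) +
    ggplot2::theme_classic()
}
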