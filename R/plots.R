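#' Plot methods for navclamp result types
#'
#' `autoplot()` methods returning ggplot objects: current-voltage relations,
#' conduction-voltage and availability curves with optional Boltzmann
#' overlays, recovery time courses, concentration-effect curves with
#' optional Hill overlays, and raw sweep bundles.
#'
#' @param object The result object to plot.
#' @param fit Optional fit object overlaid as a smooth curve
#'   ([fit_boltzmann()] for voltage curves, [fit_hill()] for
#'   concentration-effect curves, [fit_single_exponential()] for recovery).
#' @param ... Unused.
#' @return A ggplot object.
#' @name navclamp-autoplot
NULL

#' @rdname navclamp-autoplot
#' @export
autoplot.nav_iv <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$v_mV, .data$density_pA_pF)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Test potential (mV)",
                  y = "Peak current density (pA/pF)")
}

boltzmann_overlay <- function(fit, vrange) {
  v <- seq(vrange[1], vrange[2], length.out = 200)
  sgn <- if (fit$direction == "increasing") -1 else 1
  tibble::tibble(v_mV = v,
                 value = fit$amplitude / (1 + exp(sgn * (v - fit$vhalf) /
                                                    fit$k)))
}

#' @rdname navclamp-autoplot
#' @export
autoplot.nav_gv <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$v_mV, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Test potential (mV)", y = "G/Gmax")
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_line(data = boltzmann_overlay(fit,
                                                         range(object$v_mV)),
                                colour = "firebrick")
  }
  p
}

#' @rdname navclamp-autoplot
#' @export
autoplot.nav_availability <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$v_mV, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Conditioning potential (mV)", y = "I/Imax")
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_line(data = boltzmann_overlay(fit,
                                                         range(object$v_mV)),
                                colour = "firebrick")
  }
  p
}

#' @rdname navclamp-autoplot
#' @export
autoplot.nav_recovery <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$t_ms, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Recovery interval at -130 mV (ms)", y = "I/Imax")
  if (!is.null(fit)) {
    tt <- seq(min(object$t_ms), max(object$t_ms), length.out = 200)
    ov <- tibble::tibble(t_ms = tt,
                         value = fit$offset + fit$amplitude * exp(-tt /
                                                                    fit$tau))
    p <- p + ggplot2::geom_line(data = ov, colour = "firebrick")
  }
  p
}

#' @rdname navclamp-autoplot
#' @export
autoplot.nav_concentration_effect <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$conc_uM, .data$value)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$accepted)) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::labs(x = "Concentration (uM)", y = "I/Imax")
  if (!is.null(fit)) {
    cc <- exp(seq(log(min(object$conc_uM)), log(max(object$conc_uM)),
                  length.out = 200))
    ov <- tibble::tibble(
      conc_uM = cc,
      value = fit$min + (fit$max - fit$min) /
        (1 + (cc / fit$ic50)^fit$hill_slope))
    p <- p + ggplot2::geom_line(data = ov, colour = "firebrick")
  }
  p
}

#' @rdname navclamp-autoplot
#' @param sweeps Integer indices of the sweeps to draw (default all).
#' @param corrected Draw leak-corrected currents (default) or raw traces.
#' @export
autoplot.sweep_bundle <- function(object, sweeps = NULL, corrected = TRUE,
                                  ...) {
  sweeps <- sweeps %||% seq_along(object$sweeps)
  df <- purrr::map_dfr(sweeps, function(i) {
    tr <- object$sweeps[[i]]$trace
    tibble::tibble(sweep = i, time_ms = tr$time_ms,
                   i_pA = if (corrected) corrected_current(object, i)
                          else tr$i_pA)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$i_pA,
                                   group = .data$sweep)) +
    ggplot2::geom_line(linewidth = 0.3, alpha = 0.8) +
    ggplot2::labs(x = "Time (ms)", y = "Current (pA)",
                  title = sprintf("%s / %s (%s)", object$preset_name,
                                  object$protocol$kind, object$mode))
}
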