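#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Boltzmann fit
#'
#' @param x A `boltzmann_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.boltzmann_fit <- function(x, ...) {
  tibble::tibble(term = c("vhalf", "k", "amplitude"),
                 estimate = c(x$vhalf, x$k, x$amplitude))
}

#' @rdname tidy.boltzmann_fit
#' @export
glance.boltzmann_fit <- function(x, ...) {
  tibble::tibble(vhalf = x$vhalf, k = x$k, amplitude = x$amplitude,
                 direction = x$direction, rmse = x$rmse, n = x$n)
}

#' Tidy a single-exponential fit
#'
#' @param x An `exp_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter.
#' @export
tidy.exp_fit <- function(x, ...) {
  tibble::tibble(term = c("tau", "amplitude", "offset"),
                 estimate = c(x$tau, x$amplitude, x$offset))
}

#' @rdname tidy.exp_fit
#' @export
glance.exp_fit <- function(x, ...) {
  tibble::tibble(tau = x$tau, amplitude = x$amplitude, offset = x$offset,
                 rmse = x$rmse, n = x$n)
}

#' Tidy a Hill fit
#'
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter.
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble::tibble(term = c("ic50", "hill_slope", "min", "max"),
                 estimate = c(x$ic50, x$hill_slope, x$min, x$max))
}

#' @rdname tidy.hill_fit
#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(ic50 = x$ic50, hill_slope = x$hill_slope, min = x$min,
                 max = x$max, rmse = x$rmse, n = x$n)
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return `tidy()` returns the pairwise Welch tests; `glance()` the omnibus
#'   ANOVA row.
#' @export
tidy.group_comparison <- function(x, ...) x$pairwise

#' @rdname tidy.group_comparison
#' @export
glance.group_comparison <- function(x, ...) x$anova
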