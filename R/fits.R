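#' Fit a Boltzmann function to a voltage-indexed curve
#'
#' Nonlinear least-squares fit of
#' `y = A / (1 + exp(-(V - V1/2) / k))` (increasing direction) or
#' `y = A / (1 + exp((V - V1/2) / k))` (decreasing), with the slope factor
#' `k` reported as a positive magnitude. The amplitude `A` is fixed at 1 by
#' default, matching the normalized conduction-voltage and availability
#' analysis; `amplitude = "free"` fits `A` as well, which removes the bias
#' introduced when the normalization reference (the most extreme observed
#' point) is itself not at full amplitude.
#'
#' The start values are deterministic: `V1/2` from the half-maximum crossing
#' by linear interpolation and `k = 7` mV.
#'
#' @param data A data frame with columns `v_mV` and `value` (e.g. a
#'   [normalize_gv()] or [build_availability_curve()] result).
#' @param direction `"increasing"` (activation) or `"decreasing"`
#'   (availability).
#' @param amplitude `"fixed"` (A = 1) or `"free"`.
#' @return An object of class `boltzmann_fit` with elements `vhalf`, `k`,
#'   `amplitude`, `direction`, `rmse`, `n` and `data`.
#' @export
fit_boltzmann <- function(data, direction = c("increasing", "decreasing"),
                          amplitude = c("fixed", "free")) {
  direction <- match.arg(direction)
  amplitude <- match.arg(amplitude)
  v <- data$v_mV
  y <- data$value
  if (length(v) < 4) stop("need at least 4 points", call. = FALSE)
  if (diff(range(y)) < 0.05 * max(abs(y), 1e-12)) {
    stop("degenerate input: no transition to fit (constant values)",
         call. = FALSE)
  }
  sgn <- if (direction == "increasing") -1 else 1
  a0 <- max(abs(y))
  yh <- y / a0
  ord <- order(v)
  vh0 <- tryCatch(stats::approx(yh[ord], v[ord], xout = 0.5, ties = mean)$y,
                  error = function(e) NA_real_)
  if (is.na(vh0)) vh0 <- stats::median(v)
  df <- data.frame(v = v, y = y)
  fit <- tryCatch({
    if (amplitude == "fixed") {
      minpack.lm::nlsLM(y ~ 1 / (1 + exp(sgn * (v - vh) / k)), data = df,
                        start = list(vh = vh0, k = 7),
                        lower = c(-Inf, 1e-3), upper = c(Inf, 200),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      minpack.lm::nlsLM(y ~ A / (1 + exp(sgn * (v - vh) / k)), data = df,
                        start = list(A = a0, vh = vh0, k = 7),
                        lower = c(1e-6, -Inf, 1e-3), upper = c(10, Inf, 200),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    }
  }, error = function(e) {
    stop("Boltzmann fit did not converge: ", conditionMessage(e),
         call. = FALSE)
  })
  cf <- stats::coef(fit)
  structure(list(
    vhalf = unname(cf[["vh"]]), k = unname(cf[["k"]]),
    amplitude = if (amplitude == "fixed") 1 else unname(cf[["A"]]),
    direction = direction,
    rmse = sqrt(mean(stats::resid(fit)^2)),
    n = length(v), data = tibble::as_tibble(data[, c("v_mV", "value")])
  ), class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<boltzmann_fit %s> V1/2 = %.2f mV, k = %.2f mV (rmse %.2g, n %d)\n",
              x$direction, x$vhalf, x$k, x$rmse, x$n))
  invisible(x)
}

#' Fit a single-exponential time course
#'
#' Least-squares fit of `y = offset + amplitude * exp(-t / tau)` with
#' `tau > 0`, used both for the inactivation decay of individual sweeps and
#' for the recovery-from-inactivation curve (where the amplitude is
#' negative). Start values are deterministic (offset from the final sample,
#' tau from the 1/e crossing of the initial excursion).
#'
#' @param data A data frame with columns `t_ms` and `value`, at least 4 rows.
#' @return An object of class `exp_fit` with `tau` (ms), `amplitude`,
#'   `offset`, `rmse`, `n` and `data`.
#' @export
fit_single_exponential <- function(data) {
  t <- data$t_ms
  y <- data$value
  if (length(t) < 4) stop("need at least 4 samples", call. = FALSE)
  off0 <- y[which.max(t)]
  amp0 <- y[which.min(t)] - off0
  if (abs(amp0) < 1e-12) stop("degenerate input: no decay to fit",
                              call. = FALSE)
  frac <- (y - off0) / amp0
  ord <- order(t)
  tau0 <- tryCatch(stats::approx(frac[ord], t[ord], xout = exp(-1),
                                 ties = mean)$y,
                   error = function(e) NA_real_)
  if (is.na(tau0) || tau0 <= 0) tau0 <- diff(range(t)) / 5
  df <- data.frame(t = t, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ off + amp * exp(-t / tau), data = df,
                      start = list(off = off0, amp = amp0, tau = tau0),
                      lower = c(-Inf, -Inf, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) {
      stop("exponential fit did not converge: ", conditionMessage(e),
           call. = FALSE)
    })
  cf <- stats::coef(fit)
  structure(list(
    tau = unname(cf[["tau"]]), amplitude = unname(cf[["amp"]]),
    offset = unname(cf[["off"]]),
    rmse = sqrt(mean(stats::resid(fit)^2)),
    n = length(t), data = tibble::as_tibble(data[, c("t_ms", "value")])
  ), class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> tau = %.3f ms, amplitude = %.3g, offset = %.3g (n %d)\n",
              x$tau, x$amplitude, x$offset, x$n))
  invisible(x)
}

#' Fit a Hill concentration-effect function
#'
#' Bounded nonlinear least squares of
#' `y = min + (max - min) / (1 + (x / IC50)^hill)` with
#' `0 <= min <= max <= 1` and `hill > 0` for a curve decreasing in
#' concentration (remaining fraction of current). Start values are
#' deterministic: `max` at 1, `min` at the smallest observed value, `IC50`
#' from the half-effect crossing interpolated on log concentration.
#'
#' @param data A data frame with columns `conc_uM` and `value` (remaining
#'   current I/Imax), at least 4 concentrations. Rows with an `accepted`
#'   column set to `FALSE` are dropped first.
#' @return An object of class `hill_fit` with `ic50` (uM), `hill_slope`,
#'   `min`, `max`, `rmse`, `n` and `data`.
#' @export
fit_hill <- function(data) {
  if ("accepted" %in% names(data)) data <- data[data$accepted, , drop = FALSE]
  x <- data$conc_uM
  y <- data$value
  if (length(x) < 4) stop("need at least 4 concentrations", call. = FALSE)
  if (any(x <= 0)) stop("concentrations must be positive", call. = FALSE)
  half <- (max(y) + min(y)) / 2
  ord <- order(x)
  ic0 <- tryCatch(exp(stats::approx(y[ord], log(x[ord]), xout = half,
                                    ties = mean)$y),
                  error = function(e) NA_real_)
  if (is.na(ic0)) ic0 <- exp(mean(log(x)))
  df <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ ymin + (ymax - ymin) / (1 + (x / ic50)^hill),
                      data = df,
                      start = list(ymin = min(y), ymax = 1, ic50 = ic0,
                                   hill = 1),
                      lower = c(0, 0, 1e-9, 0.05),
                      upper = c(1, 1, 1e9, 20),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) {
      stop("Hill fit did not converge: ", conditionMessage(e), call. = FALSE)
    })
  cf <- stats::coef(fit)
  if (cf[["ymin"]] > cf[["ymax"]]) {
    warning("Hill fit returned min > max; inspect the data", call. = FALSE)
  }
  structure(list(
    ic50 = unname(cf[["ic50"]]), hill_slope = unname(cf[["hill"]]),
    min = unname(cf[["ymin"]]), max = unname(cf[["ymax"]]),
    rmse = sqrt(mean(stats::resid(fit)^2)),
    n = length(x), data = tibble::as_tibble(data[, c("conc_uM", "value")])
  ), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "<hill_fit> IC50 = %.3g uM, hill = %.2f, range [%.2f, %.2f] (n %d)\n",
    x$ic50, x$hill_slope, x$min, x$max, x$n))
  invisible(x)
}
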