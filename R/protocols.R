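#' Construct one of the voltage-clamp pulse protocols
#'
#' Builds the four protocols used to characterize the sodium current, plus
#' the depolarized-prepulse wash-in variant:
#'
#' * `ACTIVATION`: 21 sweeps. From -90 mV holding, an 80-ms conditioning
#'   prepulse to -130 mV, then a 40-ms test step spanning +80 to -130 mV in
#'   uniform 10.5-mV decrements, then back to -90 mV. Intersweep 8 s, P/-6
#'   leak subtraction on.
#' * `INACTIVATION`: 17 sweeps. A 100-ms prepulse to -130 mV, a 500-ms
#'   conditioning step from -135 to -55 mV in +5-mV increments, then a 50-ms
#'   test step to 0 mV. Intersweep 8 s.
#' * `RECOVERY`: a 500-ms inactivating step to -10 mV, a recovery gap at
#'   -130 mV of 0.5-50 ms, then a brief -10-mV test step. Intersweep 8 s.
#' * `WASHIN`: 100 sweeps at 1 Hz; 80 ms at the conditioning prepulse
#'   (default -130 mV, overridable to probe inactivated-state block), then a
#'   40-ms step to -10 mV.
#'
#' Every sweep starts with a short segment at the holding potential used as
#' the baseline for P/-6 subtraction.
#'
#' @param kind One of `"ACTIVATION"`, `"INACTIVATION"`, `"RECOVERY"`,
#'   `"WASHIN"`.
#' @param extended_grid Logical (`ACTIVATION` only): append -20 and -30 mV
#'   test sweeps for current-density readouts at those voltages.
#' @param prepulse_mV Conditioning prepulse override (`WASHIN` only); must lie
#'   in \[-130, -55\] mV.
#' @param n_sweeps Number of sweeps (`WASHIN` only, default 100).
#' @param gaps_ms Recovery gap grid (`RECOVERY` only), default
#'   `c(0.5, 1, 2, 3, 5, 7.5, 10, 15, 20, 30, 40, 50)`.
#' @param sampling_khz Sampling rate, 10 or 20 kHz, or `NULL` to take the
#'   cell model's default at run time.
#' @return An object of class `pulse_protocol`: list with `name`, `kind`,
#'   `holding_mV`, `intersweep_s`, `leak_subtraction`, `sampling_khz`,
#'   `sweep_values` (the per-sweep test voltage, conditioning voltage or gap
#'   duration) and `sweeps`, a list of per-sweep segment tables
#'   (`role`, `dur_ms`, `v_mV`).
#' @export
build_protocol <- function(kind = c("ACTIVATION", "INACTIVATION", "RECOVERY",
                                    "WASHIN"),
                           extended_grid = FALSE, prepulse_mV = -130,
                           n_sweeps = 100,
                           gaps_ms = c(0.5, 1, 2, 3, 5, 7.5, 10, 15, 20,
                                       30, 40, 50),
                           sampling_khz = NULL) {
  kind <- match.arg(kind)
  if (!is.null(sampling_khz) && !sampling_khz %in% c(10, 20)) {
    stop("sampling_khz must be 10 or 20", call. = FALSE)
  }
  holding <- -90
  hold_seg <- function() tibble::tibble(role = "hold", dur_ms = 5,
                                        v_mV = holding)
  seg <- function(role, dur, v) tibble::tibble(role = role, dur_ms = dur,
                                               v_mV = v)
  if (kind == "WASHIN") {
    if (prepulse_mV < -130 || prepulse_mV > -55) {
      stop("prepulse_mV must lie in [-130, -55] mV", call. = FALSE)
    }
  } else if (prepulse_mV != -130) {
    stop("prepulse_mV can only be overridden for the WASHIN protocol",
         call. = FALSE)
  }
  sweeps <- switch(kind,
    ACTIVATION = {
      v_test <- seq(80, -130, by = -10.5)
      if (extended_grid) v_test <- c(v_test, -20, -30)
      lapply(v_test, function(v) {
        dplyr::bind_rows(hold_seg(), seg("prepulse", 80, -130),
                         seg("test", 40, v), seg("tail", 20, holding))
      })
    },
    INACTIVATION = {
      v_cond <- seq(-135, -55, by = 5)
      lapply(v_cond, function(v) {
        dplyr::bind_rows(hold_seg(), seg("prepulse", 100, -130),
                         seg("cond", 500, v), seg("test", 50, 0),
                         seg("tail", 20, holding))
      })
    },
    RECOVERY = {
      lapply(gaps_ms, function(gap) {
        dplyr::bind_rows(hold_seg(), seg("depol", 500, -10),
                         seg("gap", gap, -130), seg("test", 20, -10),
                         seg("tail", 20, holding))
      })
    },
    WASHIN = {
      sw <- dplyr::bind_rows(hold_seg(), seg("prepulse", 80, prepulse_mV),
                             seg("test", 40, -10))
      rep(list(sw), n_sweeps)
    }
  )
  sweep_values <- switch(kind,
    ACTIVATION = vapply(sweeps, function(s) s$v_mV[s$role == "test"],
                        numeric(1)),
    INACTIVATION = seq(-135, -55, by = 5),
    RECOVERY = gaps_ms,
    WASHIN = seq_len(n_sweeps)
  )
  intersweep <- if (kind == "WASHIN") {
    1 - sum(sweeps[[1]]$dur_ms) / 1000
  } else 8
  structure(list(
    name = tolower(kind), kind = kind, holding_mV = holding,
    intersweep_s = intersweep,
    leak_subtraction = TRUE,
    sampling_khz = sampling_khz,
    prepulse_mV = prepulse_mV,
    sweep_values = sweep_values,
    sweeps = sweeps
  ), class = "pulse_protocol")
}

#' @export
print.pulse_protocol <- function(x, ...) {
  cat(sprintf("<pulse_protocol %s> %d sweeps, holding %g mV, intersweep %g s\n",
              x$kind, length(x$sweeps), x$holding_mV, x$intersweep_s))
  cat(sprintf("  P/-6 subtraction: %s\n",
              if (x$leak_subtraction) "on" else "off"))
  invisible(x)
}

protocol_total_ms <- function(protocol) {
  sum(vapply(protocol$sweeps, function(s) sum(s$dur_ms), numeric(1)))
}
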