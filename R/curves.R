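#' Detect the peak inward current in a trace window
#'
#' Returns the most negative sample (inward convention) within a window,
#' after discarding an initial blanking interval that masks residual
#' capacitive edge transients.
#'
#' @param trace A data frame with columns `time_ms` and `i_pA`.
#' @param window Integer vector `c(first, last)` sample indices of the
#'   segment to search.
#' @param blanking_ms Time discarded at the start of the window (ms).
#' @return One-row tibble with `peak_pA`, `t_peak_ms` and `idx`.
#' @export
detect_peak <- function(trace, window = c(1L, nrow(trace)), blanking_ms = 0) {
  if (window[2] < window[1] || window[1] < 1 || window[2] > nrow(trace)) {
    stop("invalid peak window", call. = FALSE)
  }
  idx <- seq.int(window[1], window[2])
  t0 <- trace$time_ms[idx[1]]
  keep <- idx[trace$time_ms[idx] - t0 >= blanking_ms]
  if (length(keep) < 1) stop("blanking removed the whole window", call. = FALSE)
  k <- keep[which.min(trace$i_pA[keep])]
  tibble::tibble(peak_pA = trace$i_pA[k], t_peak_ms = trace$time_ms[k],
                 idx = k)
}

default_blanking <- function(bundle) if (bundle$mode == "KINETIC") 0.3 else 0

# leak-corrected peak of sweep i inside the segment with the given role
sweep_peak <- function(bundle, i, role = "test", blanking_ms = NULL) {
  blanking_ms <- blanking_ms %||% default_blanking(bundle)
  win <- segment_window(bundle, i, role)
  ic <- corrected_current(bundle, i)
  tr <- tibble::tibble(time_ms = bundle$sweeps[[i]]$trace$time_ms, i_pA = ic)
  detect_peak(tr, win, blanking_ms)
}

#' Build the current-voltage relation from an activation bundle
#'
#' Leak-corrected peak current of every test sweep, normalized to the cell
#' capacitance, as a function of the test potential.
#'
#' @param bundle A [run_protocol()] bundle from the `ACTIVATION` protocol.
#' @param blanking_ms Peak-detection edge blanking; defaults to 0.3 ms for
#'   kinetic-mode bundles and 0 for idealized ones.
#' @return A tibble of class `nav_iv` with columns `v_mV`, `peak_pA` and
#'   `density_pA_pF`, sorted by voltage, with attributes `cm` and `e_rev`.
#' @export
build_iv <- function(bundle, blanking_ms = NULL) {
  if (bundle$protocol$kind != "ACTIVATION") {
    stop("build_iv needs an ACTIVATION-protocol bundle", call. = FALSE)
  }
  pk <- vapply(seq_along(bundle$sweeps), function(i) {
    sweep_peak(bundle, i, "test", blanking_ms)$peak_pA
  }, numeric(1))
  out <- tibble::tibble(
    v_mV = vapply(bundle$sweeps, function(s) s$value, numeric(1)),
    peak_pA = pk,
    density_pA_pF = pk / bundle$cm
  )
  out <- out[order(out$v_mV), ]
  attr(out, "cm") <- bundle$cm
  attr(out, "e_rev") <- bundle$e_rev
  class(out) <- c("nav_iv", class(out))
  out
}

#' Estimate the maximal conductance from the linear limb of an IV curve
#'
#' Least-squares slope over the +50 to +80 mV range where the conductance is
#' saturated. The literal mode regresses `I = Gmax * V` through the origin;
#' the driving-force mode regresses `I = Gmax * (V - e_rev)`, which is
#' self-consistent with a non-zero sodium reversal potential.
#'
#' @param iv A [build_iv()] curve.
#' @param fit_range Voltage range (mV) used, default `c(50, 80)`.
#' @param mode `"literal"` or `"driving_force"`.
#' @param e_rev Reversal potential (mV) for the driving-force mode; defaults
#'   to the curve's recorded value, else the Nernst potential of the
#'   recording solutions.
#' @return Conductance density in nS/pF (operating on `density_pA_pF`).
#' @export
estimate_gmax <- function(iv, fit_range = c(50, 80),
                          mode = c("literal", "driving_force"),
                          e_rev = NULL) {
  mode <- match.arg(mode)
  e_rev <- e_rev %||% attr(iv, "e_rev") %||% nernst_potential(150, 5)
  sel <- iv$v_mV >= min(fit_range) & iv$v_mV <= max(fit_range)
  if (sum(sel) < 2) stop("need at least 2 IV points in the fit range",
                         call. = FALSE)
  x <- if (mode == "literal") iv$v_mV[sel] else iv$v_mV[sel] - e_rev
  y <- iv$density_pA_pF[sel]
  if (all(abs(y) < 1e-12)) {
    warning("all currents in the fit range are zero; Gmax is degenerate",
            call. = FALSE)
    return(0)
  }
  sum(x * y) / sum(x * x)
}

#' Normalize an IV curve to a conduction-voltage (GV) relation
#'
#' The literal mode divides each point by `gmax * V` (excluding |V| < 5 mV,
#' where the expression is singular); the driving-force mode divides by
#' `gmax * (V - e_rev)` and reproduces the steady-state activation curve
#' exactly on idealized data.
#'
#' @inheritParams estimate_gmax
#' @param gmax Conductance density (nS/pF), > 0.
#' @return A tibble of class `nav_gv` with columns `v_mV` and `value`.
#' @export
normalize_gv <- function(iv, gmax, mode = c("literal", "driving_force"),
                         e_rev = NULL) {
  mode <- match.arg(mode)
  if (gmax <= 0) stop("gmax must be > 0", call. = FALSE)
  e_rev <- e_rev %||% attr(iv, "e_rev") %||% nernst_potential(150, 5)
  if (mode == "literal") {
    keep <- abs(iv$v_mV) >= 5
    out <- tibble::tibble(v_mV = iv$v_mV[keep],
                          value = iv$density_pA_pF[keep] /
                            (gmax * iv$v_mV[keep]))
  } else {
    out <- tibble::tibble(v_mV = iv$v_mV,
                          value = iv$density_pA_pF /
                            (gmax * (iv$v_mV - e_rev)))
  }
  class(out) <- c("nav_gv", class(out))
  out
}

#' Steady-state availability curve from an inactivation bundle
#'
#' Normalizes the leak-corrected peak currents of the 0-mV test pulses to the
#' largest peak across sweeps and indexes them by the conditioning potential.
#'
#' @param bundle A [run_protocol()] bundle from the `INACTIVATION` protocol.
#' @param blanking_ms See [build_iv()].
#' @return A tibble of class `nav_availability` with columns `v_mV` and
#'   `value`; attribute `reference_pA` holds the normalization peak.
#' @export
build_availability_curve <- function(bundle, blanking_ms = NULL) {
  if (bundle$protocol$kind != "INACTIVATION") {
    stop("build_availability_curve needs an INACTIVATION-protocol bundle",
         call. = FALSE)
  }
  pk <- vapply(seq_along(bundle$sweeps), function(i) {
    sweep_peak(bundle, i, "test", blanking_ms)$peak_pA
  }, numeric(1))
  ref <- min(pk)  # largest inward peak
  out <- tibble::tibble(
    v_mV = vapply(bundle$sweeps, function(s) s$value, numeric(1)),
    value = pk / ref
  )
  out <- out[order(out$v_mV), ]
  attr(out, "reference_pA") <- ref
  class(out) <- c("nav_availability", class(out))
  out
}

#' Recovery-from-inactivation curve from a recovery bundle
#'
#' Fraction of current recovered (test-pulse peak over the maximum test-pulse
#' peak) as a function of the -130 mV gap duration.
#'
#' @param bundle A [run_protocol()] bundle from the `RECOVERY` protocol.
#' @param blanking_ms See [build_iv()].
#' @return A tibble of class `nav_recovery` with columns `t_ms` (gap) and
#'   `value` (I/Imax).
#' @export
build_recovery_curve <- function(bundle, blanking_ms = NULL) {
  if (bundle$protocol$kind != "RECOVERY") {
    stop("build_recovery_curve needs a RECOVERY-protocol bundle",
         call. = FALSE)
  }
  pk <- vapply(seq_along(bundle$sweeps), function(i) {
    sweep_peak(bundle, i, "test", blanking_ms)$peak_pA
  }, numeric(1))
  ref <- min(pk)
  out <- tibble::tibble(
    t_ms = vapply(bundle$sweeps, function(s) s$value, numeric(1)),
    value = pk / ref
  )
  out <- out[order(out$t_ms), ]
  attr(out, "reference_pA") <- ref
  class(out) <- c("nav_recovery", class(out))
  out
}

washin_steady_peak <- function(bundle, blanking_ms = NULL, last_n = 5) {
  n <- length(bundle$sweeps)
  idx <- seq.int(max(1L, n - last_n + 1L), n)
  pk <- vapply(idx, function(i) {
    sweep_peak(bundle, i, "test", blanking_ms)$peak_pA
  }, numeric(1))
  drift <- if (length(pk) > 1) {
    stats::coef(stats::lm(pk ~ seq_along(pk)))[[2]] * (length(pk) - 1)
  } else 0
  list(steady_pA = mean(pk), drift_pA = drift)
}

#' Concentration-effect curve from wash-in bundles
#'
#' For every concentration, the steady-state current is the mean
#' leak-corrected test-pulse peak of the last five sweeps, accepted only if
#' the linear drift across those sweeps is below 1% of the control steady
#' state; the reported value is steady/control (remaining fraction I/Imax).
#'
#' @param control A drug-free `WASHIN` bundle.
#' @param bundles List of `WASHIN` bundles, one per concentration, ascending
#'   (drugs are washed in from the lowest to the highest concentration).
#' @param last_n Number of terminal sweeps averaged (default 5).
#' @param drift_tol Maximal admissible drift, as a fraction of the control
#'   steady state (default 0.01).
#' @return A tibble of class `nav_concentration_effect` with columns
#'   `conc_uM`, `value`, `block` (= 1 - value) and `accepted`; attributes
#'   `drug` and `control_pA`.
#' @export
build_concentration_effect <- function(control, bundles, last_n = 5,
                                       drift_tol = 0.01) {
  if (control$protocol$kind != "WASHIN" || !is.null(control$drug)) {
    stop("control must be a drug-free WASHIN bundle", call. = FALSE)
  }
  concs <- vapply(bundles, function(b) b$conc_uM %||% NA_real_, numeric(1))
  if (any(is.na(concs))) stop("all bundles must carry a drug concentration",
                              call. = FALSE)
  if (any(diff(concs) <= 0)) {
    stop("concentrations must be strictly ascending", call. = FALSE)
  }
  ctrl <- washin_steady_peak(control, last_n = last_n)
  vals <- accepted <- numeric(length(bundles))
  for (i in seq_along(bundles)) {
    s <- washin_steady_peak(bundles[[i]], last_n = last_n)
    accepted[i] <- abs(s$drift_pA) < drift_tol * abs(ctrl$steady_pA)
    vals[i] <- s$steady_pA / ctrl$steady_pA
  }
  out <- tibble::tibble(conc_uM = concs, value = vals, block = 1 - vals,
                        accepted = as.logical(accepted))
  attr(out, "drug") <- bundles[[1]]$drug
  attr(out, "control_pA") <- ctrl$steady_pA
  class(out) <- c("nav_concentration_effect", class(out))
  out
}

#' Simulate a full concentration-effect experiment
#'
#' Convenience pipeline: runs a drug-free control wash-in and one wash-in per
#' concentration against the same cell model, then assembles the
#' concentration-effect curve with [build_concentration_effect()].
#'
#' @param preset A [make_preset()] model.
#' @param drug A [drug_spec()].
#' @param concentrations Concentration series (uM); defaults to the drug's
#'   tested series.
#' @param mode,seed Passed to [run_protocol()].
#' @param prepulse_mV Wash-in conditioning prepulse (default -130 mV; use
#'   -90/-100 mV to probe inactivated-state block).
#' @param n_sweeps Sweeps per wash-in (default 100).
#' @return A `nav_concentration_effect` tibble.
#' @export
simulate_concentration_effect <- function(preset, drug,
                                          concentrations = NULL,
                                          mode = "IDEALIZED", seed = NULL,
                                          prepulse_mV = -130,
                                          n_sweeps = 100) {
  concentrations <- concentrations %||% drug$concentrations
  proto <- build_protocol("WASHIN", prepulse_mV = prepulse_mV,
                          n_sweeps = n_sweeps)
  control <- run_protocol(preset, proto, mode = mode, seed = seed)
  bundles <- lapply(seq_along(concentrations), function(i) {
    run_protocol(preset, proto, drug = drug, conc = concentrations[i],
                 mode = mode,
                 seed = if (is.null(seed)) NULL else seed + i)
  })
  build_concentration_effect(control, bundles)
}

#' Series-resistance voltage-error exclusion screen
#'
#' The voltage error is the largest leak-corrected peak current in the
#' bundle times the residual series resistance; recordings whose error
#' exceeds the threshold (5 mV for the COS-7 expression models, 8 mV for
#' stem cell-derived cardiomyocytes) are excluded from analysis.
#'
#' @param bundle A [run_protocol()] bundle.
#' @param threshold_mV Exclusion threshold; defaults by cell model.
#' @param rs_residual Residual series resistance (MOhm); defaults to the
#'   bundle's metadata.
#' @return One-row tibble with `peak_pA`, `error_mV`, `threshold_mV`, `keep`.
#' @export
voltage_error_screen <- function(bundle, threshold_mV = NULL,
                                 rs_residual = NULL) {
  rs <- rs_residual %||% bundle$rs_residual
  if (is.null(rs)) stop("no residual series resistance available",
                        call. = FALSE)
  threshold_mV <- threshold_mV %||%
    if (identical(bundle$preset_name, "HSC_CM")) 8 else 5
  pk <- min(vapply(seq_along(bundle$sweeps), function(i) {
    sweep_peak(bundle, i, "test")$peak_pA
  }, numeric(1)))
  err <- abs(pk) * rs / 1000  # pA * MOhm -> uV -> mV
  tibble::tibble(peak_pA = pk, error_mV = err, threshold_mV = threshold_mV,
                 keep = err <= threshold_mV)
}
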