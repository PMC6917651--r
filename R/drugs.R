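#' Drug specification for state-dependent sodium-channel block
#'
#' Describes one sodium-channel blocker under the modulated/guarded-receptor
#' scheme: the drug binds only while the channel occupies its accessible state
#' (open for class Ia/Ic, inactivated for class Ib), with first-order kinetics
#' `dB/dt = kon * conc * phi * (1 - B) - koff * B` where `phi` is the
#' accessible-state occupancy.
#'
#' @param name Drug name (lower case).
#' @param drug_class `"Ia"`, `"Ib"` or `"Ic"` (Vaughan-Williams subclass).
#' @param scheme `"OPEN_STATE"` or `"INACTIVATED_STATE"`. Class Ia/Ic must be
#'   open-state, class Ib inactivated-state.
#' @param kon Binding rate constant, 1/(uM ms).
#' @param koff Unbinding rate constant, 1/ms (state independent).
#' @param beta1_affinity_factor Multiplies the apparent Kd when the beta1
#'   subunit is present (`NAV15_B1` and `HSC_CM` presets); >= 1, used for
#'   class Ib drugs only.
#' @param max_block Maximal fraction of current suppressed by a fully bound
#'   channel population, in (0, 1].
#' @param concentrations Tested concentration series (uM), strictly increasing.
#' @return An object of class `drug_spec`.
#' @export
drug_spec <- function(name, drug_class, scheme, kon, koff,
                      beta1_affinity_factor = 1, max_block = 1,
                      concentrations = numeric()) {
  drug_class <- match.arg(drug_class, c("Ia", "Ib", "Ic"))
  scheme <- match.arg(scheme, c("OPEN_STATE", "INACTIVATED_STATE"))
  if (drug_class %in% c("Ia", "Ic") && scheme != "OPEN_STATE") {
    stop("class Ia/Ic drugs must use the OPEN_STATE scheme", call. = FALSE)
  }
  if (drug_class == "Ib" && scheme != "INACTIVATED_STATE") {
    stop("class Ib drugs must use the INACTIVATED_STATE scheme", call. = FALSE)
  }
  if (kon <= 0 || koff <= 0) stop("kon and koff must be > 0", call. = FALSE)
  if (beta1_affinity_factor < 1) {
    stop("beta1_affinity_factor must be >= 1", call. = FALSE)
  }
  if (max_block <= 0 || max_block > 1) {
    stop("max_block must be in (0, 1]", call. = FALSE)
  }
  if (length(concentrations) &&
      any(diff(concentrations) <= 0)) {
    stop("concentrations must be strictly increasing", call. = FALSE)
  }
  structure(list(name = name, drug_class = drug_class, scheme = scheme,
                 kon = kon, koff = koff,
                 beta1_affinity_factor = beta1_affinity_factor,
                 max_block = max_block, concentrations = concentrations),
            class = "drug_spec")
}

#' @export
print.drug_spec <- function(x, ...) {
  cat(sprintf("<drug_spec %s> class %s (%s)\n", x$name, x$drug_class, x$scheme))
  cat(sprintf("  kon %.4g /(uM ms), koff %.4g /ms, Kd %.3g uM\n",
              x$kon, x$koff, x$koff / x$kon))
  cat(sprintf("  max_block %.2f, beta1 factor %.1f, concentrations: %s uM\n",
              x$max_block, x$beta1_affinity_factor,
              paste(x$concentrations, collapse = ", ")))
  invisible(x)
}

drug_cache <- new.env(parent = emptyenv())

#' Load the packaged drug library
#'
#' Reads the five-drug library (quinidine, ajmaline, lidocaine, phenytoin,
#' flecainide) with class assignments, binding schemes, calibrated kinetic
#' constants and the tested concentration series.
#'
#' @param path Optional path to an alternative drugs JSON document with the
#'   same schema (user-overridable library).
#' @return Named list of [drug_spec()] objects.
#' @export
load_drug_library <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(drug_cache$lib)) return(drug_cache$lib)
    path <- system.file("extdata", "drugs.json", package = "navclamp",
                        mustWork = TRUE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lib <- lapply(names(raw), function(nm) {
    d <- raw[[nm]]
    drug_spec(name = nm, drug_class = d$class, scheme = d$scheme,
              kon = d$kon, koff = d$koff,
              beta1_affinity_factor = d$beta1_affinity_factor,
              max_block = d$max_block,
              concentrations = as.numeric(d$concentrations))
  })
  names(lib) <- names(raw)
  drug_cache$lib <- lib
  lib
}

# kon scaled by the beta1 affinity factor when the preset carries beta1
effective_kon <- function(drug, preset_name) {
  if (drug$scheme == "INACTIVATED_STATE" &&
      preset_name %in% c("NAV15_B1", "HSC_CM")) {
    drug$kon / drug$beta1_affinity_factor
  } else {
    drug$kon
  }
}

#' Equilibrium bound fraction under the guarded-receptor scheme
#'
#' `kon * conc * phi / (kon * conc * phi + koff)`: the steady-state occupancy
#' when the channel spends a constant fraction `phi` of time in the
#' drug-accessible state. Zero when the channel is never accessible.
#'
#' @param kon Binding rate, 1/(uM ms).
#' @param koff Unbinding rate, 1/ms.
#' @param conc Drug concentration (uM), >= 0.
#' @param accessibility Accessible-state occupancy `phi`, in \[0, 1\].
#' @return Equilibrium bound fraction in \[0, 1).
#' @export
equilibrium_block <- function(kon, koff, conc, accessibility = 1) {
  if (any(conc < 0)) stop("concentration must be >= 0", call. = FALSE)
  if (any(accessibility < 0 | accessibility > 1)) {
    stop("accessibility must be in [0, 1]", call. = FALSE)
  }
  x <- kon * conc * accessibility
  ifelse(x == 0, 0, x / (x + koff))
}

#' Advance the bound fraction over a constant-accessibility interval
#'
#' Exact exponential relaxation toward [equilibrium_block()] at the current
#' accessibility: with rate `r = kon * conc * phi + koff`, `B` relaxes as
#' `B_eq + (B - B_eq) * exp(-r * dt)`. Exact for piecewise-constant
#' accessibility, so two half-steps compose to one full step.
#'
#' @param bound Current bound fraction, in \[0, 1\].
#' @param accessibility Accessible-state occupancy during the interval.
#' @param conc Drug concentration (uM).
#' @param dt Interval (ms), > 0.
#' @param spec A [drug_spec()] (only `kon` and `koff` are used).
#' @return Updated bound fraction.
#' @export
block_step <- function(bound, accessibility, conc, dt, spec) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  rate <- spec$kon * conc * accessibility + spec$koff
  beq <- equilibrium_block(spec$kon, spec$koff, conc, accessibility)
  b <- beq + (bound - beq) * exp(-rate * dt)
  min(max(b, 0), 1)
}

#' Closed-form block accumulation over a pulse train
#'
#' Per cycle, the channel is accessible (`phi = accessibility`) for `duty`
#' ms and inaccessible (`phi = 0`, pure `koff` unbinding) for the remaining
#' `cycle - duty` ms. Both half-cycles are affine in the bound fraction, so
#' the per-cycle map is affine and the trajectory and its fixed point are
#' available in closed form.
#'
#' @param spec A [drug_spec()].
#' @param conc Drug concentration (uM).
#' @param duty Accessible time per cycle (ms), `0 <= duty <= cycle`.
#' @param cycle Cycle length (ms).
#' @param n_pulses Number of cycles, >= 1.
#' @param accessibility Occupancy of the accessible state during the duty
#'   window (default 1).
#' @return A tibble with columns `pulse` and `block` (bound fraction at the
#'   end of each accessible window), with attribute `steady_state` holding the
#'   analytic fixed point of the per-cycle map.
#' @export
pulse_train_block <- function(spec, conc, duty, cycle, n_pulses,
                              accessibility = 1) {
  if (duty < 0 || duty > cycle) stop("need 0 <= duty <= cycle", call. = FALSE)
  if (n_pulses < 1) stop("n_pulses must be >= 1", call. = FALSE)
  rate_on <- spec$kon * conc * accessibility + spec$koff
  beq <- equilibrium_block(spec$kon, spec$koff, conc, accessibility)
  e_on <- exp(-rate_on * duty)
  e_off <- exp(-spec$koff * (cycle - duty))
  # B measured at end of duty: B' = e_on*e_off*B + beq*(1 - e_on)
  alpha <- e_on * e_off
  beta <- beq * (1 - e_on)
  b <- numeric(n_pulses)
  cur <- 0
  for (i in seq_len(n_pulses)) {
    cur <- beq + (cur - beq) * e_on  # accessible window
    b[i] <- cur
    cur <- cur * e_off               # inaccessible remainder
  }
  ss <- if (alpha < 1) beta / (1 - alpha) else beq
  out <- tibble::tibble(pulse = seq_len(n_pulses), block = b)
  attr(out, "steady_state") <- ss
  out
}

#' Apparent dissociation constant of an inactivated-state blocker
#'
#' The inactivated-state Kd divided by the fraction of time the channel is
#' inactivated, scaled by the beta1 affinity factor; the apparent affinity
#' rises (Kd falls) as inactivation is promoted, e.g. by depolarizing the
#' conditioning prepulse.
#'
#' @param kd_i Intrinsic inactivated-state Kd (uM).
#' @param inactivated_fraction Occupancy of the inactivated state, in (0, 1\].
#' @param beta1_factor Affinity factor >= 1 (default 1).
#' @return Apparent Kd in uM; `Inf` when the inactivated fraction is 0 (no
#'   accessible state).
#' @export
apparent_kd_inactivated <- function(kd_i, inactivated_fraction,
                                    beta1_factor = 1) {
  if (any(inactivated_fraction < 0 | inactivated_fraction > 1)) {
    stop("inactivated_fraction must be in [0, 1]", call. = FALSE)
  }
  ifelse(inactivated_fraction == 0, Inf,
         beta1_factor * kd_i / inactivated_fraction)
}

# -- wash-in cycle machinery ------------------------------------------------

# Periodic gate/accessibility summary of the 1-Hz wash-in cycle:
# prepulse (80 ms) -> test step (40 ms) -> rest at holding (remainder).
# The availability gate follows exact exponential relaxation in each phase;
# its periodic fixed point and time averages are closed form. The activation
# gate is treated as instantaneous (tau_a << all phase durations).
washin_phases <- function(preset, prepulse_mV = -130, step_mV = -10,
                          holding_mV = -90, prepulse_ms = 80, step_ms = 40,
                          cycle_ms = 1000) {
  g <- preset$gating
  v <- c(prepulse = prepulse_mV, step = step_mV, holding = holding_mV)
  dur <- c(prepulse_ms, step_ms, cycle_ms - prepulse_ms - step_ms)
  if (dur[3] < 0) stop("cycle shorter than prepulse + step", call. = FALSE)
  hinf <- steady_state_availability(v, g)
  tau <- tau_h(v, g)
  ee <- exp(-dur / tau)
  # periodic fixed point of h at the start of the prepulse
  # h -> hinf_i + (h - hinf_i) e_i applied for i = 1..3
  a1 <- prod(ee)
  b1 <- 0
  for (i in 1:3) b1 <- hinf[i] + (b1 - hinf[i]) * ee[i]
  h0 <- if (a1 < 1) b1 / (1 - a1) else hinf[1]
  h_start <- numeric(3); h_end <- numeric(3); hbar <- numeric(3)
  h <- h0
  for (i in 1:3) {
    h_start[i] <- h
    h_end[i] <- hinf[i] + (h - hinf[i]) * ee[i]
    hbar[i] <- hinf[i] + (h - hinf[i]) * (tau[i] / dur[i]) * (1 - ee[i])
    h <- h_end[i]
  }
  ainf <- steady_state_activation(v, g)
  tibble::tibble(
    phase = c("prepulse", "step", "rest"),
    v_mV = unname(v), dur_ms = dur,
    h_start = h_start, h_end = h_end, h_mean = hbar,
    phi_open = unname(ainf) * hbar,
    phi_inactivated = 1 - hbar
  )
}

# Steady-state and per-sweep measured block (fraction of peak current
# suppressed, i.e. max_block * bound fraction at the start of the test step)
# under the 1-Hz wash-in protocol. Closed form; shared by the idealized
# simulator and kon calibration.
washin_block_trajectory <- function(preset, drug, conc, n_sweeps = 100,
                                    prepulse_mV = -130, step_mV = -10,
                                    holding_mV = -90, prepulse_ms = 80,
                                    step_ms = 40, cycle_ms = 1000) {
  ph <- washin_phases(preset, prepulse_mV, step_mV, holding_mV,
                      prepulse_ms, step_ms, cycle_ms)
  kon <- effective_kon(drug, preset$name)
  phi <- if (drug$scheme == "OPEN_STATE") ph$phi_open else ph$phi_inactivated
  rate <- kon * conc * phi + drug$koff
  beq <- ifelse(kon * conc * phi == 0, 0,
                kon * conc * phi / (kon * conc * phi + drug$koff))
  ee <- exp(-rate * ph$dur_ms)
  # measurement point: end of the prepulse (start of the test step), where
  # the peak current is read. cycle order from that point: step, rest, prepulse
  ord <- c(2, 3, 1)
  b <- numeric(n_sweeps)
  # drug application starts at the first prepulse
  cur <- beq[1] + (0 - beq[1]) * ee[1]
  for (i in seq_len(n_sweeps)) {
    b[i] <- cur
    for (j in ord) cur <- beq[j] + (cur - beq[j]) * ee[j]
  }
  alpha <- prod(ee)
  bfix <- 0
  for (j in ord) bfix <- beq[j] + (bfix - beq[j]) * ee[j]
  ss <- if (alpha < 1) bfix / (1 - alpha) else max(beq)
  out <- tibble::tibble(sweep = seq_len(n_sweeps), bound = b,
                        block = drug$max_block * b)
  attr(out, "steady_state_bound") <- ss
  attr(out, "steady_state_block") <- drug$max_block * ss
  out
}

#' Calibrate the binding rate constant against a target block level
#'
#' Root-finds `kon` (with `koff` fixed by the drug's class) so that the
#' steady-state fraction of peak-current inhibition under the 1-Hz wash-in
#' protocol equals `target_block`. Deterministic; the simulated wash-in at
#' the returned `kon` reproduces the target to better than 0.1% absolute.
#'
#' @param spec A [drug_spec()] template (its `kon` is ignored).
#' @param target_block Target steady-state inhibition fraction, must satisfy
#'   `0 < target_block < max_block`.
#' @param conc Calibration concentration (uM).
#' @param model A [make_preset()] object defining the gating background.
#' @param prepulse_mV Conditioning prepulse of the wash-in protocol.
#' @param cycle_ms,prepulse_ms,step_ms Wash-in cycle timing (ms).
#' @return Calibrated `kon` in 1/(uM ms).
#' @export
calibrate_kd <- function(spec, target_block, conc, model,
                         prepulse_mV = -130, cycle_ms = 1000,
                         prepulse_ms = 80, step_ms = 40) {
  if (target_block <= 0 || target_block >= spec$max_block) {
    stop(sprintf(
      "target block %.3f is infeasible: must lie in (0, max_block = %.2f)",
      target_block, spec$max_block), call. = FALSE)
  }
  fun <- function(log10_kon) {
    s <- spec
    s$kon <- 10^log10_kon
    attr(washin_block_trajectory(model, s, conc, n_sweeps = 1,
                                 prepulse_mV = prepulse_mV,
                                 prepulse_ms = prepulse_ms, step_ms = step_ms,
                                 cycle_ms = cycle_ms),
         "steady_state_block") - target_block
  }
  lo <- -9; hi <- 4
  if (fun(hi) < 0) {
    stop("target block unreachable even at the kon upper bracket",
         call. = FALSE)
  }
  root <- stats::uniroot(fun, c(lo, hi), tol = 1e-12)$root
  10^root
}

#' Serialize a drug library to JSON
#'
#' @param path Output file path.
#' @param library Named list of [drug_spec()] objects; defaults to the
#'   packaged library.
#' @return `path`, invisibly.
#' @export
write_drug_library <- function(path, library = NULL) {
  if (is.null(library)) library <- load_drug_library()
  out <- lapply(library, function(d) {
    list(class = d$drug_class, scheme = d$scheme, kon = d$kon, koff = d$koff,
         beta1_affinity_factor = d$beta1_affinity_factor,
         max_block = d$max_block, concentrations = d$concentrations)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
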