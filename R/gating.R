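#' Nernst equilibrium potential
#'
#' Computes the Nernst potential for a monovalent cation from the external and
#' internal concentrations. Used to fix the sodium reversal potential of the
#' simulated current from the recording solutions (150 mM Na+ external, 5 mM
#' internal) at room temperature.
#'
#' @param c_out External concentration (mM), must be positive.
#' @param c_in Internal concentration (mM), must be positive.
#' @param temperature Absolute temperature in kelvin. Default 294.15 K (21 degC).
#' @return Equilibrium potential in mV.
#' @examples
#' nernst_potential(150, 5) # ~ +86.2 mV
#' @export
nernst_potential <- function(c_out, c_in, temperature = 294.15) {
  if (any(c_out <= 0) || any(c_in <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  R <- 8.314462618   # J / (mol K)
  FARADAY <- 96485.33212  # C / mol
  1000 * (R * temperature / FARADAY) * log(c_out / c_in)
}

#' Gating parameter set
#'
#' Bundles the Boltzmann parameters of steady-state activation and
#' availability, the voltage-dependent inactivation time constant
#' interpolation, and the maximal conductance density of one cell model.
#'
#' @param vhalf_act,k_act Activation midpoint (mV) and slope factor (mV, > 0).
#' @param vhalf_inact,k_inact Availability midpoint (mV) and slope factor
#'   (mV, > 0; magnitude, the curve is decreasing).
#' @param tau_act_max Activation time constant (ms), voltage independent.
#' @param tau_inact_dep Inactivation decay time constant at depolarized
#'   voltages (ms).
#' @param tau_rec Recovery-from-inactivation time constant at -130 mV (ms).
#' @param tau_h_vmid,tau_h_vslope Midpoint (mV) and slope (mV) of the logistic
#'   interpolation of `tau_h()` between `tau_rec` and `tau_inact_dep`.
#' @param gmax_density Maximal conductance density (nS/pF).
#' @param e_rev Reversal potential (mV).
#' @return An object of class `gating_params` (a validated list).
#' @export
gating_params <- function(vhalf_act, k_act, vhalf_inact, k_inact,
                          tau_act_max = 0.3, tau_inact_dep = 1.5,
                          tau_rec = 5.9, tau_h_vmid = -70, tau_h_vslope = 10,
                          gmax_density = 1, e_rev = nernst_potential(150, 5)) {
  p <- list(
    vhalf_act = vhalf_act, k_act = k_act,
    vhalf_inact = vhalf_inact, k_inact = k_inact,
    tau_act_max = tau_act_max, tau_inact_dep = tau_inact_dep,
    tau_rec = tau_rec, tau_h_vmid = tau_h_vmid, tau_h_vslope = tau_h_vslope,
    gmax_density = gmax_density, e_rev = e_rev
  )
  ok <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
               logical(1))
  if (!all(ok)) stop("all gating parameters must be finite scalars", call. = FALSE)
  if (k_act <= 0 || k_inact <= 0) stop("slope factors must be > 0", call. = FALSE)
  if (tau_act_max <= 0 || tau_inact_dep <= 0 || tau_rec <= 0) {
    stop("time constants must be > 0", call. = FALSE)
  }
  structure(p, class = "gating_params")
}

#' Steady-state activation
#'
#' Boltzmann voltage dependence of channel opening,
#' `1 / (1 + exp(-(v - vhalf_act) / k_act))`; strictly increasing in `v`.
#'
#' @param v Membrane potential (mV), vectorized.
#' @param p A [gating_params()] object (or a model preset's `$gating`).
#' @return Open probability of the activation gate, in (0, 1).
#' @export
steady_state_activation <- function(v, p) {
  p <- as_gating(p)
  1 / (1 + exp(-(v - p$vhalf_act) / p$k_act))
}

#' Steady-state availability
#'
#' Fraction of channels not inactivated after a long conditioning step,
#' `1 / (1 + exp((v - vhalf_inact) / k_inact))`; strictly decreasing in `v`.
#'
#' @inheritParams steady_state_activation
#' @return Available fraction, in (0, 1).
#' @export
steady_state_availability <- function(v, p) {
  p <- as_gating(p)
  1 / (1 + exp((v - p$vhalf_inact) / p$k_inact))
}

#' Voltage-dependent inactivation time constant
#'
#' Logistic interpolation between the recovery time constant measured at
#' -130 mV (hyperpolarized limit) and the fast inactivation decay time
#' constant at depolarized voltages.
#'
#' @inheritParams steady_state_activation
#' @return Time constant of the availability gate (ms).
#' @export
tau_h <- function(v, p) {
  p <- as_gating(p)
  w <- 1 / (1 + exp((v - p$tau_h_vmid) / p$tau_h_vslope))
  p$tau_inact_dep + (p$tau_rec - p$tau_inact_dep) * w
}

#' Advance the two gates over a constant-voltage interval
#'
#' Exact exponential relaxation of the activation gate `a` and availability
#' gate `h` toward their steady states at voltage `v`. Exact for piecewise
#' constant voltage: two steps of `dt` compose to one step of `2 dt`.
#'
#' @param state Numeric vector `c(a, h)`, both in \[0, 1\].
#' @param v Membrane potential (mV) held during the interval.
#' @param dt Interval duration (ms), > 0.
#' @param p A [gating_params()] object.
#' @return Updated `c(a, h)`.
#' @export
gate_step <- function(state, v, dt, p) {
  p <- as_gating(p)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  a_inf <- steady_state_activation(v, p)
  h_inf <- steady_state_availability(v, p)
  a <- a_inf + (state[[1]] - a_inf) * exp(-dt / p$tau_act_max)
  h <- h_inf + (state[[2]] - h_inf) * exp(-dt / tau_h(v, p))
  c(a = min(max(a, 0), 1), h = min(max(h, 0), 1))
}

as_gating <- function(p) {
  if (inherits(p, "nav_preset")) return(p$gating)
  if (inherits(p, "gating_params")) return(p)
  stop("expected a gating_params object or model preset", call. = FALSE)
}

#' Cell-level recording parameters
#'
#' Passive and instrumentation properties of one simulated cell: membrane
#' capacitance, residual (uncompensated) series resistance, ohmic leak,
#' capacitive-transient time constant and additive current noise.
#'
#' @param cm Membrane capacitance (pF), > 0.
#' @param rs_residual Residual series resistance (MOhm), >= 0.
#' @param g_leak Leak conductance (nS).
#' @param e_leak Leak reversal potential (mV).
#' @param noise_sd Additive Gaussian current noise s.d. (pA), >= 0.
#' @param cap_transient_tau Capacitive transient time constant (ms).
#' @return An object of class `cell_params`.
#' @export
cell_params <- function(cm = 20, rs_residual = 1, g_leak = 1, e_leak = -20,
                        noise_sd = 10, cap_transient_tau = 0.1) {
  if (cm <= 0) stop("cm must be > 0", call. = FALSE)
  if (rs_residual < 0) stop("rs_residual must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (cap_transient_tau < 0) {
    stop("cap_transient_tau must be >= 0 (0 disables the transient)",
         call. = FALSE)
  }
  structure(list(cm = cm, rs_residual = rs_residual, g_leak = g_leak,
                 e_leak = e_leak, noise_sd = noise_sd,
                 cap_transient_tau = cap_transient_tau),
            class = "cell_params")
}

#' Names of the packaged cell-model presets
#'
#' @return Character vector: `"NAV15"` (Nav1.5 alone in COS-7),
#'   `"NAV15_B1"` (Nav1.5 + beta1) and `"HSC_CM"` (human stem cell-derived
#'   cardiomyocyte).
#' @export
preset_names <- function() c("NAV15", "NAV15_B1", "HSC_CM")

preset_cache <- new.env(parent = emptyenv())

load_preset_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(preset_cache$table)) return(preset_cache$table)
    path <- system.file("extdata", "presets.json", package = "navclamp",
                        mustWork = TRUE)
  }
  tab <- jsonlite::read_json(path, simplifyVector = TRUE)
  preset_cache$table <- tab
  tab
}

#' Build a cell-model preset
#'
#' Returns the gating and cell parameters of one of the three packaged cell
#' models. Gating midpoints, slope factors and recovery time constants are the
#' central values measured for each model; the maximal conductance density is
#' calibrated so that the idealized activation-protocol peak current density
#' at the model's reference voltage equals the measured density (the closed
#' form `gmax * a_inf(Vref) * h_inf(Vcond) * (Vref - e_rev)` with the -130 mV
#' conditioning availability included).
#'
#' @param name One of [preset_names()].
#' @param contaminant Logical; for `"HSC_CM"` only, adds a small transient
#'   outward K+ conductance (I_to) activating above -10 mV. Off by default.
#' @param config_path Optional path to an alternative presets JSON document.
#' @return An object of class `nav_preset`: list with `name`, `gating`
#'   ([gating_params()]), `cell` ([cell_params()]), `sampling_khz`, and
#'   `contaminant` (list with `on`, `g_density`, `e_k`, `vhalf`, `k`,
#'   `tau_inact`).
#' @examples
#' p <- make_preset("NAV15")
#' p$gating$vhalf_act
#' @export
make_preset <- function(name, contaminant = FALSE, config_path = NULL) {
  tab <- load_preset_table(config_path)
  if (!name %in% names(tab)) {
    stop(sprintf("unknown preset '%s'; valid names: %s", name,
                 paste(names(tab), collapse = ", ")), call. = FALSE)
  }
  cfg <- tab[[name]]
  e_rev <- nernst_potential(cfg$solutions$na_out_mM, cfg$solutions$na_in_mM,
                            cfg$solutions$temperature_K)
  g <- gating_params(
    vhalf_act = cfg$gating$vhalf_act, k_act = cfg$gating$k_act,
    vhalf_inact = cfg$gating$vhalf_inact, k_inact = cfg$gating$k_inact,
    tau_act_max = cfg$gating$tau_act_max,
    tau_inact_dep = cfg$gating$tau_inact_dep,
    tau_rec = cfg$gating$tau_rec,
    tau_h_vmid = cfg$gating$tau_h_vmid, tau_h_vslope = cfg$gating$tau_h_vslope,
    gmax_density = 1, e_rev = e_rev
  )
  # calibrate gmax: idealized density at the reference voltage after the
  # -130 mV conditioning prepulse must equal the printed density
  ref <- cfg$density_ref
  drive <- steady_state_activation(ref$v_mV, g) *
    steady_state_availability(cfg$conditioning_mV, g) * (ref$v_mV - e_rev)
  g$gmax_density <- ref$density_pA_pF / drive
  cl <- cell_params(cm = cfg$cell$cm, rs_residual = cfg$cell$rs_residual,
                    g_leak = cfg$cell$g_leak, e_leak = cfg$cell$e_leak,
                    noise_sd = cfg$cell$noise_sd,
                    cap_transient_tau = cfg$cell$cap_transient_tau)
  cont <- cfg$contaminant
  if (is.null(cont)) cont <- list(g_density = 0, e_k = -85, vhalf = 10,
                                  k = 10, tau_inact = 20)
  if (contaminant && cont$g_density == 0) {
    stop(sprintf("preset '%s' has no contaminating conductance defined", name),
         call. = FALSE)
  }
  cont$on <- isTRUE(contaminant)
  structure(list(name = name, gating = g, cell = cl,
                 sampling_khz = cfg$sampling_khz, contaminant = cont),
            class = "nav_preset")
}

#' @export
print.nav_preset <- function(x, ...) {
  g <- x$gating
  cat(sprintf("<nav_preset %s>\n", x$name))
  cat(sprintf("  activation:   V1/2 %+.1f mV, k %.1f mV\n", g$vhalf_act, g$k_act))
  cat(sprintf("  availability: V1/2 %+.1f mV, k %.1f mV\n",
              g$vhalf_inact, g$k_inact))
  cat(sprintf("  tau_rec %.2f ms, gmax %.3f nS/pF, Erev %+.1f mV\n",
              g$tau_rec, g$gmax_density, g$e_rev))
  cat(sprintf("  cell: %.0f pF, Rs %.1f MOhm, leak %.1f nS, noise %.0f pA\n",
              x$cell$cm, x$cell$rs_residual, x$cell$g_leak, x$cell$noise_sd))
  invisible(x)
}

#' Serialize presets to a JSON document
#'
#' Writes the packaged preset configuration (or a modified copy) to `path` in
#' the same schema that [make_preset()] reads, allowing user-overridable
#' preset libraries.
#'
#' @param path Output file path.
#' @param table A preset table as returned by the internal reader; defaults to
#'   the packaged table.
#' @return `path`, invisibly.
#' @export
write_presets <- function(path, table = NULL) {
  if (is.null(table)) table <- load_preset_table()
  jsonlite::write_json(table, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
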