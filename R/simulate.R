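#' Run a pulse protocol against a cell model
#'
#' Simulates the whole-cell current elicited by a [build_protocol()] program
#' in one of two modes:
#'
#' * `IDEALIZED`: noise- and artifact-free traces. Activation is treated as
#'   instantaneous (the gate sits at its steady state within each segment)
#'   while availability relaxes exponentially, so the first sample of every
#'   test segment carries exactly the closed-form peak
#'   `cm * gmax * a_inf(V) * h_start * (V - e_rev) * (1 - max_block * B)`.
#' * `KINETIC`: both gates relax with their finite time constants
#'   (exact exponential updates at the sampling step), and ohmic leak,
#'   capacitive edge transients, additive Gaussian noise and (optionally) a
#'   contaminating transient outward current are added. When the protocol has
#'   P/-6 subtraction enabled, six inverted one-sixth-amplitude subsweeps are
#'   recorded alongside each sweep.
#'
#' State-dependent drug block is included when a drug and concentration are
#' given: in kinetic mode the bound fraction is integrated per sample against
#' the instantaneous accessible-state occupancy; in idealized mode the
#' closed-form 1-Hz wash-in recursion supplies the per-sweep bound fraction
#' (for non-wash-in protocols, the resting equilibrium at the holding
#' potential).
#'
#' @param preset A [make_preset()] cell model.
#' @param protocol A [build_protocol()] object.
#' @param drug Optional [drug_spec()].
#' @param conc Drug concentration (uM), required with `drug`, > 0.
#' @param mode `"IDEALIZED"` or `"KINETIC"`.
#' @param seed Integer seed; required in kinetic mode when the preset has
#'   nonzero current noise. The same preset, drug, protocol, mode and seed
#'   yield an identical bundle.
#' @return An object of class `sweep_bundle`: metadata (preset name, cm,
#'   residual series resistance, sampling rate, mode, drug, concentration,
#'   seed) plus one record per sweep with the sweep's `value` (test voltage,
#'   conditioning voltage or gap), a `trace` tibble (`time_ms`, `v_mV`,
#'   `i_pA`) and, when recorded, a `subs` matrix of the six P/-6 subsweep
#'   currents.
#' @export
run_protocol <- function(preset, protocol, drug = NULL, conc = NULL,
                         mode = c("IDEALIZED", "KINETIC"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(preset, "nav_preset"), inherits(protocol, "pulse_protocol"))
  if (!is.null(drug)) {
    if (is.null(conc) || conc <= 0) {
      stop("a positive drug concentration is required with a drug",
           call. = FALSE)
    }
  }
  khz <- protocol$sampling_khz %||% preset$sampling_khz
  g <- preset$gating
  cell <- preset$cell
  kinetic <- mode == "KINETIC"
  if (kinetic && cell$noise_sd > 0 && is.null(seed)) {
    stop("a seed is required in kinetic mode when noise_sd > 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  # per-sweep bound fraction for idealized mode
  b_sweep <- rep(0, length(protocol$sweeps))
  if (!is.null(drug) && !kinetic) {
    if (protocol$kind == "WASHIN") {
      traj <- washin_block_trajectory(
        preset, drug, conc, n_sweeps = length(protocol$sweeps),
        prepulse_mV = protocol$prepulse_mV,
        cycle_ms = 1000 * (protocol$intersweep_s) +
          sum(protocol$sweeps[[1]]$dur_ms))
      b_sweep <- traj$bound
    } else {
      phi <- resting_phi(preset, drug, protocol$holding_mV)
      b_sweep[] <- equilibrium_block(effective_kon(drug, preset$name),
                                     drug$koff, conc, phi)
    }
  }

  kon_eff <- if (!is.null(drug)) effective_kon(drug, preset$name) else 0
  b_carry <- 0  # kinetic-mode bound fraction carried across sweeps
  sweeps <- vector("list", length(protocol$sweeps))
  for (i in seq_along(protocol$sweeps)) {
    segs <- protocol$sweeps[[i]]
    if (kinetic) {
      sim <- simulate_sweep_kinetic(segs, preset, khz, drug, conc, b_carry,
                                    kon_eff)
      b_carry <- sim$b_end
      main <- sim$trace
      subs <- NULL
      if (protocol$leak_subtraction) {
        subs <- matrix(0, nrow = nrow(main), ncol = 6)
        sub_segs <- segs
        sub_segs$v_mV <- protocol$holding_mV -
          (segs$v_mV - protocol$holding_mV) / 6
        for (k in 1:6) {
          subs[, k] <- simulate_sweep_kinetic(sub_segs, preset, khz, drug,
                                              conc, b_carry, kon_eff)$trace$i_pA
        }
      }
      if (!is.null(drug)) {
        b_carry <- intersweep_block_update(preset, drug, conc, b_carry,
                                           kon_eff,
                                           protocol$holding_mV,
                                           protocol$intersweep_s * 1000)
      }
    } else {
      main <- simulate_sweep_idealized(segs, preset, khz, drug, b_sweep[i])
      subs <- NULL
    }
    sweeps[[i]] <- list(value = protocol$sweep_values[i], trace = main,
                        subs = subs)
  }
  structure(list(
    protocol = protocol,
    preset_name = preset$name,
    cm = cell$cm,
    rs_residual = cell$rs_residual,
    sampling_khz = khz,
    mode = mode,
    drug = if (is.null(drug)) NULL else drug$name,
    conc_uM = conc,
    max_block = if (is.null(drug)) NULL else drug$max_block,
    seed = seed,
    e_rev = g$e_rev,
    sweeps = sweeps
  ), class = "sweep_bundle")
}

#' @export
print.sweep_bundle <- function(x, ...) {
  cat(sprintf("<sweep_bundle %s/%s> %d sweeps @ %g kHz, mode %s%s\n",
              x$preset_name, x$protocol$kind, length(x$sweeps),
              x$sampling_khz, x$mode,
              if (is.null(x$drug)) "" else
                sprintf(", %s %g uM", x$drug, x$conc_uM)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resting_phi <- function(preset, drug, holding_mV) {
  g <- preset$gating
  hh <- steady_state_availability(holding_mV, g)
  if (drug$scheme == "OPEN_STATE") {
    steady_state_activation(holding_mV, g) * hh
  } else {
    1 - hh
  }
}

segment_times <- function(dur_ms, khz) {
  n <- max(1L, as.integer(round(dur_ms * khz)))
  (seq_len(n) - 1) / khz
}

simulate_sweep_idealized <- function(segs, preset, khz, drug, bound) {
  g <- preset$gating
  cm <- preset$cell$cm
  scale <- if (is.null(drug)) 1 else 1 - drug$max_block * bound
  h <- steady_state_availability(segs$v_mV[1], g)  # sweep starts at holding
  t_off <- 0
  pieces <- vector("list", nrow(segs))
  for (s in seq_len(nrow(segs))) {
    v <- segs$v_mV[s]
    tt <- segment_times(segs$dur_ms[s], khz)
    hinf <- steady_state_availability(v, g)
    th <- tau_h(v, g)
    hv <- hinf + (h - hinf) * exp(-tt / th)
    a <- steady_state_activation(v, g)
    i_na <- cm * g$gmax_density * a * hv * (v - g$e_rev) * scale
    pieces[[s]] <- tibble::tibble(time_ms = t_off + tt, v_mV = v, i_pA = i_na)
    h <- hinf + (h - hinf) * exp(-segs$dur_ms[s] / th)
    t_off <- t_off + segs$dur_ms[s]
  }
  dplyr::bind_rows(pieces)
}

simulate_sweep_kinetic <- function(segs, preset, khz, drug, conc, b0,
                                   kon_eff) {
  g <- preset$gating
  cell <- preset$cell
  cm <- cell$cm
  dt <- 1 / khz
  v0 <- segs$v_mV[1]
  a <- steady_state_activation(v0, g)
  h <- steady_state_availability(v0, g)
  b <- b0
  v_prev <- v0
  t_off <- 0
  pieces <- vector("list", nrow(segs))
  for (s in seq_len(nrow(segs))) {
    v <- segs$v_mV[s]
    tt <- segment_times(segs$dur_ms[s], khz)
    n <- length(tt)
    a_inf <- steady_state_activation(v, g)
    h_inf <- steady_state_availability(v, g)
    th <- tau_h(v, g)
    av <- a_inf + (a - a_inf) * exp(-tt / g$tau_act_max)
    hv <- h_inf + (h - h_inf) * exp(-tt / th)
    if (!is.null(drug)) {
      bv <- numeric(n)
      phi <- if (drug$scheme == "OPEN_STATE") av * hv else 1 - hv
      cur <- b
      for (j in seq_len(n)) {
        rate <- kon_eff * conc * phi[j] + drug$koff
        beq <- kon_eff * conc * phi[j] / rate
        cur <- beq + (cur - beq) * exp(-rate * dt)
        bv[j] <- cur
      }
      b <- cur
      scale <- 1 - drug$max_block * bv
    } else {
      scale <- 1
    }
    i_na <- cm * g$gmax_density * av * hv * (v - g$e_rev) * scale
    i_leak <- cell$g_leak * (v - cell$e_leak)
    dv <- v - v_prev
    i_cap <- if (dv != 0 && cell$cap_transient_tau > 0) {
      (cm * dv / cell$cap_transient_tau) * exp(-tt / cell$cap_transient_tau)
    } else 0
    i_to <- 0
    cont <- preset$contaminant
    if (isTRUE(cont$on) && cont$g_density > 0) {
      w <- 1 / (1 + exp(-(v - cont$vhalf) / cont$k))
      i_to <- cm * cont$g_density * w * (v - cont$e_k) *
        exp(-tt / cont$tau_inact)
    }
    noise <- if (cell$noise_sd > 0) {
      stats::rnorm(n, 0, cell$noise_sd)
    } else 0
    pieces[[s]] <- tibble::tibble(time_ms = t_off + tt, v_mV = v,
                                  i_pA = i_na + i_leak + i_cap + i_to + noise)
    # advance state to the segment end (exact)
    a <- a_inf + (a - a_inf) * exp(-segs$dur_ms[s] / g$tau_act_max)
    h <- h_inf + (h - h_inf) * exp(-segs$dur_ms[s] / th)
    v_prev <- v
    t_off <- t_off + segs$dur_ms[s]
  }
  list(trace = dplyr::bind_rows(pieces), b_end = b)
}

# block relaxation across the unrecorded intersweep interval: gates are taken
# as relaxed at the holding potential (interval >> tau_h) and the bound
# fraction follows the binding law at the time-averaged resting accessibility
intersweep_block_update <- function(preset, drug, conc, b, kon_eff,
                                    holding_mV, dur_ms) {
  if (dur_ms <= 0) return(b)
  phi <- resting_phi(preset, drug, holding_mV)
  rate <- kon_eff * conc * phi + drug$koff
  beq <- kon_eff * conc * phi / rate
  beq + (b - beq) * exp(-rate * dur_ms)
}

#' P/-6 leak and capacitance subtraction
#'
#' Removes every current component linear in voltage from a main sweep using
#' six subsweeps recorded with the command excursion inverted and scaled by
#' one sixth. Each trace is first referenced to its own holding-level
#' baseline; the corrected trace is
#' `(main - baseline) + 6 * (mean subsweep - baseline)`, which cancels ohmic
#' leak and linear capacitive transients exactly.
#'
#' @param i_main Numeric vector, the main sweep current (pA).
#' @param i_subs Numeric matrix with six columns, the subsweep currents.
#' @param baseline_idx Integer indices of the pre-step holding samples used
#'   as baseline.
#' @return Corrected current vector (pA).
#' @export
p6_subtract <- function(i_main, i_subs, baseline_idx) {
  if (is.null(dim(i_subs)) || ncol(i_subs) != 6) {
    stop("i_subs must be a matrix with 6 subsweep columns", call. = FALSE)
  }
  if (nrow(i_subs) != length(i_main)) {
    stop("subsweep length does not match the main sweep", call. = FALSE)
  }
  if (length(baseline_idx) < 1) stop("empty baseline window", call. = FALSE)
  sub_mean <- rowMeans(i_subs)
  (i_main - mean(i_main[baseline_idx])) +
    6 * (sub_mean - mean(sub_mean[baseline_idx]))
}

# leak-corrected current of sweep i: P/-6 when subsweeps were recorded,
# otherwise the trace is returned as recorded (idealized bundles contain the
# channel current only, with nothing linear to remove)
corrected_current <- function(bundle, i) {
  sw <- bundle$sweeps[[i]]
  if (is.null(sw$subs)) return(sw$trace$i_pA)
  segs <- bundle$protocol$sweeps[[i]]
  n_hold <- as.integer(round(segs$dur_ms[1] * bundle$sampling_khz))
  p6_subtract(sw$trace$i_pA, sw$subs, seq_len(max(1L, n_hold)))
}

# sample index range of the first segment with the given role in sweep i
segment_window <- function(bundle, i, role) {
  segs <- bundle$protocol$sweeps[[i]]
  khz <- bundle$sampling_khz
  ns <- vapply(segs$dur_ms, function(d) max(1L, as.integer(round(d * khz))),
               integer(1))
  ends <- cumsum(ns)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  k <- which(segs$role == role)[1]
  if (is.na(k)) stop(sprintf("no '%s' segment in sweep %d", role, i),
                     call. = FALSE)
  c(starts[k], ends[k])
}
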