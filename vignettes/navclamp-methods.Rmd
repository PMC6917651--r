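---
title: "navclamp: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{navclamp: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navclamp)
```

## The current model

The simulated whole-cell sodium current is a Hodgkin–Huxley-style two-gate
model,

$$ I_\mathrm{Na}(t) = C_m \, g_\mathrm{max} \, a(t) \, h(t) \,
   (V - E_\mathrm{rev}) \, \bigl(1 - b_\mathrm{max} B(t)\bigr), $$

with a single activation gate $a$ and a single availability gate $h$, each
relaxing exponentially toward a Boltzmann steady state:

$$ a_\infty(V) = \frac{1}{1 + e^{-(V - V_{1/2,a})/k_a}}, \qquad
   h_\infty(V) = \frac{1}{1 + e^{+(V - V_{1/2,h})/k_h}}. $$

A deliberate simplification: the observed conductance–voltage relation of a
single $a$ gate *is* $a_\infty$, so midpoints and slope factors measured
from whole-cell recordings can be carried into the model verbatim, and the
analysis pipeline applied to simulated data must return exactly the numbers
the preset was built from. A cubed activation gate ($a^3h$) would be closer
to microscopic channel physics but would break that round-trip property,
which is the main purpose of the simulator. Persistent/late sodium current,
temperature dependence and multi-state (Markov) inactivation are out of
scope.

Because voltage-clamp commands are piecewise constant, both gates (and the
drug-bound fraction) are advanced with *exact* exponential updates per
segment or sample — there is no ODE solver error anywhere in the simulator,
and composing two half-steps equals one full step to machine precision. The
test suite relies on this: an independent `deSolve` integration is used as
the oracle for the drug-binding recursion, never as the implementation.

### Time constants

* $\tau_a$ is fixed at 0.3 ms. Activation kinetics are not a quantity this
  package needs to reproduce; 0.3 ms is a realistic room-temperature value
  and fast enough that kinetic-mode conductance midpoints stay within about
  2 mV of the idealized ones.
* $\tau_h(V)$ interpolates logistically (midpoint −70 mV, slope 10 mV)
  between the measured recovery time constant at −130 mV (5.90 / 5.06 /
  5.05 ms for the three presets) and a fast depolarized inactivation decay
  of 1.5 ms. Only the hyperpolarized end is constrained by a measured
  number; the depolarized level and the interpolation shape are free
  choices of plausible magnitude. Note the hyperpolarized limit is reached
  asymptotically: $\tau_h(-130)$ evaluates to 5.889 ms for the `NAV15`
  preset, 0.2% below its `tau_rec` anchor, and the recovery pipeline
  recovers exactly this value.

### Reversal potential and conductance calibration

$E_\mathrm{rev}$ is the Nernst potential of the recording solutions
(150 mM Na⁺ external, 5 mM internal, 294.15 K), +86.2 mV; it is computed,
not fitted. `gmax_density` (nS/pF) is calibrated per preset so that the
idealized activation-protocol peak density at the preset's reference
voltage equals its reference value, *including* the availability reached by
the −130 mV conditioning prepulse ($h_\infty(-130) \approx 0.985$ for
`NAV15`). Omitting that factor would misstate the simulated density by
about 1.5%.

## Cell models

```{r presets}
for (nm in preset_names()) print(make_preset(nm))
```

Gating midpoints, slope factors and recovery time constants are the central
values of the three characterized models; they live in
`inst/extdata/presets.json` and can be overridden by pointing
`make_preset(config_path = )` at an edited copy. The cell-level parameters
(capacitance 20 pF for the COS-7 models, 15 pF for the cardiomyocyte;
residual series resistance 1 MΩ; leak 1 nS at −20 mV; noise 10 pA;
capacitive-transient τ 0.1 ms) are not measured quantities — they are
chosen so that the recording artifacts the analysis pipeline must cope with
(leak, edge transients, series-resistance voltage errors of a few mV at
nA-scale peaks) are realistically sized. The `HSC_CM` preset can optionally
include a small transient outward K⁺ conductance activating above about
−10 mV; it is off by default and exists to demonstrate why the drug
response is read at a −10 mV test step, where its contribution is minimal.

## Idealized versus kinetic mode

`run_protocol()` has two modes with one contract:

* **IDEALIZED** emits noise- and artifact-free traces in which activation is
  instantaneous, so the first sample of each test segment equals the closed
  form $C_m g_\mathrm{max} a_\infty(V) h_\mathrm{start} (V-E_\mathrm{rev})$.
  This mode is the reference for all round-trip checks.
* **KINETIC** integrates both gates at the sampling step and adds leak,
  capacitive transients, noise and (with a drug) per-sample binding. With a
  finite $\tau_a$ the peak of $a(t)h(t)$ is attenuated relative to
  $a_\infty h_\mathrm{start}$ by the analytic factor
  $(1-u)\,((\alpha+\beta)/\alpha)^{-\alpha/\beta}$ with
  $\alpha=\tau_a$, $\beta=\tau_h(V)$, $u=\alpha/(\alpha+\beta)$ — about
  40% at strongly depolarized voltages. This is real electrophysiology
  (measured peaks always under-report $g_\mathrm{max} a_\infty h$), and the
  tests verify the kinetic peaks against this closed form rather than
  against the idealized one; normalized curve *shapes* (V½ within 2 mV,
  recovery τ within 10%) are preserved.

The series-resistance voltage error is diagnosed as
$|I_\mathrm{peak}| R_s$ and drives the exclusion screen, but is not fed
back into the gating drive; this keeps the integration exact and
vectorized. Capacitive edge transients are charge-conserving single
exponentials (amplitude $C_m \Delta V / \tau_c$, so the integrated charge
is $C_m \Delta V$).

### P/-6 subtraction

When leak subtraction is on, each sweep is accompanied by six subsweeps
whose command excursion from the −90 mV holding level is scaled by −1/6,
simulated with the full physics (the channel contributes negligibly at
those small excursions, exactly as in a real recording). The correction
references each trace to its own holding-level baseline and computes
`(main − baseline) + 6 (mean sub − baseline)`, which cancels every current
component linear in voltage identically; with noise off the residual on a
purely linear cell is at floating-point level, and the suite asserts
≤ 1e-9 of full scale.

## Drug block

Block follows the modulated/guarded-receptor scheme: a drug binds only
while the channel occupies its accessible state — open for the class Ia/Ic
compounds, inactivated for class Ib — with state-independent unbinding:

$$ \frac{dB}{dt} = k_\mathrm{on} c \,\varphi(t)\,(1-B) - k_\mathrm{off} B,
   \qquad \varphi = a h \ \text{(open)} \ \text{or} \ 1-h \ \text{(inactivated)}. $$

Design choices:

* **koff per class**: 5×10⁻³ /ms (Ib), 10⁻⁴ /ms (Ia), 10⁻⁵ /ms (Ic) —
  recovery-from-block time constants of 0.2 s, 10 s and 100 s. The 10-fold
  ladder encodes the classical fast/intermediate/slow unbinding that
  defines the classes; the absolute scale is set so that block measured at
  the peak of a 1-Hz pulse train can actually accumulate for open-state
  drugs (with unbinding much faster than the interpulse interval, any
  open-state block acquired during a 40-ms step would vanish before the
  next sweep and no concentration could reproduce the reference block
  levels).
* **kon is calibrated**, not assumed: `calibrate_kd()` root-finds kon so
  that the steady-state inhibition under the wash-in protocol matches a
  packaged anchor (one concentration/percent-block pair per drug from the
  reference table, Nav1.5 column). The shipped `drugs.json` carries the
  calibrated values, and a test regenerates them from scratch.
* **β1 affinity factor**: for the class Ib drugs the apparent Kd is
  multiplied by 2.9 (lidocaine) or 2.0 (phenytoin) when the preset carries
  β1 (`NAV15_B1`, `HSC_CM`), implementing the subunit's direct effect on
  affinity; with the factor at 1, open-state concentration–effect curves
  for `NAV15` and `NAV15_B1` differ only through the h∞ shift, and the
  suite asserts exact equality when the gating background is held fixed.
* **Sub-maximal block** is a per-drug scalar `max_block` multiplying the
  conductance loss of bound channels (0.9 lidocaine, 0.75 phenytoin,
  1 otherwise), not a resistant sub-population.
* **Wash-in is instantaneous** (bath steps); the endpoints are steady
  states, so exchange kinetics are irrelevant.

In idealized mode the 1-Hz wash-in cycle is reduced to three phases
(conditioning prepulse, test step, rest at holding), each with the
time-averaged accessibility of the exactly-relaxing $h$ gate, and the
per-cycle affine recursion is iterated in closed form; the measurement
point is the start of the test step, where the peak is read. Kinetic mode
integrates $B$ per sample instead and agrees with the phase-averaged
closed form to within ~10% (binding during the rising phase of
inactivation is the difference). Binding at the holding potential is
retained for inactivated-state drugs — that resting accessibility
($1-h_\infty(-90) \approx 0.67$ for `NAV15`) is precisely what makes class
Ib block prepulse-dependent, and the suite checks that a −90 mV prepulse
always blocks more than −130 mV, at every concentration and preset.

A consequence worth knowing: the steady-state block of this scheme is not
an exact Hill function of concentration (the prepulse re-equilibration rate
itself depends on concentration), so the fitted Hill IC50 of a simulated
curve is a few tens of percent away from the scheme's half-effect
concentration. The reference data behave the same way (fitted slopes well
below 1), so this is treated as a property of the mechanism, not a defect
of the fit.

## Analysis choices

* **GV normalization** defaults to the literal `I/(Gmax·V)` with a ±5 mV
  singularity guard, because that matches the conventional workflow; a
  driving-force mode `I/(Gmax·(V−E_rev))` is provided and used for all
  round-trip checks, since the literal form is internally inconsistent near
  0 mV when the reversal potential is +86 mV. `estimate_gmax()` fits the
  +50…+80 mV limb in either convention.
* **Availability fits** use a decreasing Boltzmann with a *free* top
  amplitude. The curve is normalized to the largest observed peak (the
  −135 mV sweep), but full availability is not reached even there
  ($h_\infty(-135)\approx 0.992$ for `NAV15`); with a fixed unit amplitude
  this residual inactivation biases V½ by up to 0.2 mV, which the free
  amplitude removes exactly. `fit_boltzmann()` keeps the fixed-amplitude
  form as its default for users fitting conventional normalized data.
* **Peak detection** is the most negative sample (inward convention) in the
  test segment, after 0.3 ms of edge blanking in kinetic mode (capacitive
  transients) and none in idealized mode.
* **Wash-in steady state** is the mean test-pulse peak of the last five
  sweeps, accepted only if the linear drift across them is below 1% of the
  control steady state.
* **Fit determinism**: all nonlinear fits use bounded Levenberg–Marquardt
  (`minpack.lm`) with fixed start heuristics — Boltzmann V½ from the
  interpolated half-maximum crossing with k = 7 mV; exponential τ from the
  1/e crossing; Hill max at 1, min at the smallest observed value, IC50
  from the half-effect crossing on log concentration, with bounds
  0 ≤ min ≤ max ≤ 1. Degenerate inputs (no transition, no decay) raise
  errors rather than returning arbitrary parameters.
* **Exclusion rule**: voltage error `|peak|·Rs` against 5 mV (COS-7
  presets) or 8 mV (`HSC_CM`); passing at 5 implies passing at 8.
* **Group statistics** are reconstructed from summary data: between-group
  sums of squares from means and ns, within-group from `SEM·√n`; pairwise
  Welch t-tests are reported uncorrected by default (a `p_adjust` option
  exists), with significance flagged at p < 0.01.

## What the generator does and does not emulate

The synthetic bundles emulate the protocol structure, gating behavior,
state-dependent pharmacology, leak/capacitance artifacts and additive noise
of whole-cell recordings. They do **not** emulate cell-to-cell parameter
scatter (every simulated cell of a preset is identical), rundown or seal
drift, imperfect space clamp, liquid-junction offsets, solution-exchange
kinetics, or contributions of non-Nav1.5 channel subunits beyond the
optional outward contaminant. Passing round trips therefore demonstrate
that the pipeline is unbiased on data generated by its own model class —
they do not certify behavior under every pathology of real recordings,
though the artifact terms exercise the failure modes the exclusion rules
were designed for.

## Problem sizes and runtime

The default suite simulates full-resolution bundles (10–20 kHz sampling:
about 2,900 samples per activation sweep, 21–23 sweeps per bundle, plus six
subsweeps each in kinetic mode) and wash-ins of 40–100 one-second sweeps;
idealized concentration–effect experiments run all six lidocaine
concentrations plus control. These sizes keep the whole test suite under a
minute on a single core while matching the real protocols sweep for sweep.

## Known limitations

* The recovery pipeline returns $\tau_h(-130)$, which is 0.2% below the
  preset's nominal recovery constant (asymptotic interpolation, above).
* Kinetic-mode absolute peak densities are attenuated relative to the
  printed densities (finite-τ_a physics); calibration is defined against
  the idealized closed form.
* The drug model has one binding site, no trapping, no pH/charged-fraction
  partitioning, and its kon/koff are effective constants — only their
  calibrated steady-state consequences are meaningful, not their absolute
  magnitudes.
* Between-model differences in maximal inhibition (e.g. lidocaine's lower
  ceiling when β1 is present) are represented only through the shared
  `max_block` scalar and the affinity factor, not reproduced per model.
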