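# navclamp

Simulation and analysis of whole-cell voltage-clamp recordings of the
cardiac sodium current (I_Na), aimed at ion-channel safety pharmacology:
people who characterize Nav1.5 gating and screen sodium-channel blockers in
heterologous expression systems or stem cell-derived cardiomyocytes, and who
want a fully synthetic, seeded test bed for the analysis pipeline they apply
to real patch-clamp data.

The package has two halves that meet at a common on-disk "sweep bundle"
format:

* a **recording simulator** — a Hodgkin–Huxley-style two-gate Nav model
  (activation gate `a`, availability gate `h`, current
  `I = Cm · gmax · a · h · (V − E_rev)`), three packaged cell models
  (`NAV15`: Nav1.5 alone in COS-7; `NAV15_B1`: Nav1.5 + β1;
  `HSC_CM`: stem cell-derived cardiomyocyte), state-dependent drug block
  under the modulated/guarded-receptor scheme
  (`dB/dt = kon·c·φ·(1−B) − koff·B`, with `φ` the open- or
  inactivated-state occupancy), and realistic recording artifacts (ohmic
  leak, capacitive edge transients, series-resistance voltage error,
  Gaussian current noise);
* an **analysis pipeline** — P/-6 leak subtraction, peak detection,
  current–voltage and conductance–voltage construction, Boltzmann fits
  `y = 1/(1+exp(−(V−V½)/k))`, single-exponential recovery/decay fits, Hill
  concentration–effect fits `y = min + (max−min)/(1+(x/IC50)^h)`,
  series-resistance exclusion screening (5 mV COS-7 / 8 mV hSC-CM), and
  one-way ANOVA with pairwise Welch tests reconstructed from summary
  statistics.

Four voltage protocols are built in: steady-state activation (21 sweeps,
+80 → −130 mV), steady-state inactivation (17 conditioning steps,
−135 → −55 mV), recovery from inactivation (0.5–50 ms gaps at −130 mV) and a
1-Hz drug wash-in (100 sweeps, with an overridable conditioning prepulse to
probe inactivated-state block). A packaged reference table holds the percent
block per drug, concentration and cell model for five blockers (quinidine,
ajmaline, lidocaine, phenytoin, flecainide), and the drug library's binding
constants are calibrated against it.

## Worked example

```r
library(navclamp)

preset <- make_preset("NAV15")
preset
#> <nav_preset NAV15>
#>   activation:   V1/2 -33.5 mV, k 6.9 mV
#>   availability: V1/2 -95.8 mV, k 8.2 mV
#>   tau_rec 5.90 ms, gmax 1.298 nS/pF, Erev +86.2 mV
#>   cell: 20 pF, Rs 1.0 MOhm, leak 1.0 nS, noise 10 pA

# activation: IV -> Gmax -> GV -> Boltzmann
bundle <- run_protocol(preset, build_protocol("ACTIVATION"), mode = "IDEALIZED")
iv   <- build_iv(bundle)
gmax <- estimate_gmax(iv, mode = "driving_force")
fit_boltzmann(normalize_gv(iv, gmax, mode = "driving_force"), "increasing")
#> <boltzmann_fit increasing> V1/2 = -33.50 mV, k = 6.90 mV (rmse 7.4e-07, n 21)

# steady-state inactivation
inact <- run_protocol(preset, build_protocol("INACTIVATION"), mode = "IDEALIZED")
fit_boltzmann(build_availability_curve(inact), "decreasing", amplitude = "free")
#> <boltzmann_fit decreasing> V1/2 = -95.80 mV, k = 8.20 mV (rmse 4.1e-17, n 17)

# recovery from inactivation
rec <- run_protocol(preset, build_protocol("RECOVERY"), mode = "IDEALIZED")
fit_single_exponential(build_recovery_curve(rec))
#> <exp_fit> tau = 5.889 ms, amplitude = -1, offset = 1 (n 12)

# drug wash-in: simulated lidocaine concentration-effect curve + Hill fit
lib <- load_drug_library()
ce <- simulate_concentration_effect(preset, lib$lidocaine)
fit_hill(ce)
#> <hill_fit> IC50 = 14.7 uM, hill = 0.60, range [0.09, 1.00] (n 6)

# Hill fit of the packaged reference means (lidocaine, Nav1.5 column)
fit_hill(table1_concentration_effect("lidocaine", "NAV15"))
#> <hill_fit> IC50 = 22.5 uM, hill = 0.73, range [0.04, 1.00] (n 6)
```

The simulated round trips recover the cell model's own parameters
(activation V½ −33.5 mV, inactivation V½ −95.8 mV, recovery τ ≈ 5.89 ms —
the gating model evaluated at −130 mV), which is the core correctness check:
whatever the simulator puts in, the analysis pipeline must read back out.
The lidocaine IC50 of 22.5 µM from the reference means sits inside the
published uncertainty of that quantity; the simulated wash-in gives a
lower apparent IC50 because the fitted Hill curve summarizes a
protocol-dependent, non-Hill block mechanism.

Group statistics work from summary data (mean, SEM, n per model):

```r
glance(compare_groups(tibble::tibble(
  group = c("NAV15", "NAV15_B1", "HSC_CM"),
  mean = c(56, 37, 26), sem = c(2, 2, 2), n = c(7, 10, 11))))
#> # A tibble: 1 × 5
#>       f   df1   df2             p significant
#>   <dbl> <dbl> <dbl>         <dbl> <lgl>
#> 1  49.8     2    25 0.00000000192 TRUE
```

## Layout

* `R/` — gating model and presets, drug library and block kinetics,
  protocol builder and simulator, analysis pipeline, fits, statistics,
  bundle I/O, CLI.
* `inst/extdata/` — `presets.json`, `drugs.json`, reference block table
  (`table1.csv`, `table1_ns.csv`).
* `vignettes/navclamp-methods.Rmd` — the model, its assumptions, parameter
  choices and limitations.
* `tests/testthat/` — unit, property and end-to-end suites.
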