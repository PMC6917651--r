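test_that("detect_peak finds the most negative sample and honors blanking", {
  tr <- tibble::tibble(time_ms = seq(0, 10, by = 0.05),
                       i_pA = -1000 * exp(-(seq(0, 10, by = 0.05) - 2)^2))
  tr$i_pA[tr$time_ms == 2] <- -1234
  pk <- detect_peak(tr)
  expect_equal(pk$peak_pA, -1234)
  expect_equal(pk$t_peak_ms, 2)
  # a capacitive spike at the window edge is excluded by blanking
  tr2 <- tr
  tr2$i_pA[1] <- -50000
  expect_equal(detect_peak(tr2, blanking_ms = 0.3)$peak_pA, -1234)
  expect_equal(detect_peak(tr2, blanking_ms = 0)$peak_pA, -50000)
  expect_error(detect_peak(tr, window = c(5, 4)), "window")
})

test_that("build_iv reproduces the reference current densities", {
  b <- idealized_bundle("NAV15", "ACTIVATION", extended_grid = TRUE)
  iv <- build_iv(b)
  expect_equal(iv$density_pA_pF[iv$v_mV == -20], -119, tolerance = 1e-5)
  b1 <- idealized_bundle("NAV15_B1", "ACTIVATION", extended_grid = TRUE)
  iv1 <- build_iv(b1)
  expect_equal(iv1$density_pA_pF[iv1$v_mV == -20], -198, tolerance = 1e-5)
  # zero-conductance model gives an all-zero curve
  p0 <- preset_clean()
  p0$gating$gmax_density <- 0
  iv0 <- build_iv(run_protocol(p0, build_protocol("ACTIVATION"),
                               mode = "IDEALIZED"))
  expect_true(all(iv0$density_pA_pF == 0))
  expect_error(build_iv(idealized_bundle("NAV15", "RECOVERY")), "ACTIVATION")
})

test_that("estimate_gmax fits the linear limb in both modes", {
  iv <- tibble::tibble(v_mV = seq(50, 80, by = 10),
                       density_pA_pF = 2 * seq(50, 80, by = 10))
  class(iv) <- c("nav_iv", class(iv))
  expect_equal(estimate_gmax(iv, mode = "literal"), 2)
  iv0 <- iv; iv0$density_pA_pF <- 0
  expect_warning(g0 <- estimate_gmax(iv0), "degenerate")
  expect_equal(g0, 0)
  expect_error(estimate_gmax(iv, fit_range = c(200, 300)), "fit range")
  # driving-force mode recovers the model conductance on idealized data
  b <- idealized_bundle("NAV15", "ACTIVATION")
  g <- make_preset("NAV15")$gating
  h0 <- steady_state_availability(-130, g)
  gm <- estimate_gmax(build_iv(b), mode = "driving_force")
  expect_equal(gm, g$gmax_density * h0, tolerance = 0.01)
})

test_that("normalize_gv guards the singularity and inverts exactly", {
  iv <- tibble::tibble(v_mV = c(-10, -4, 0, 4, 10, 60),
                       density_pA_pF = c(-10, -4, 0, 4, 10, 60))
  class(iv) <- c("nav_iv", class(iv))
  gv <- normalize_gv(iv, gmax = 1, mode = "literal")
  expect_false(any(abs(gv$v_mV) < 5))
  expect_true(all(gv$value == 1))
  expect_error(normalize_gv(iv, gmax = 0), "gmax")
  # driving-force GV reproduces steady-state activation exactly
  b <- idealized_bundle("NAV15", "ACTIVATION")
  ivb <- build_iv(b)
  g <- make_preset("NAV15")$gating
  h0 <- steady_state_availability(-130, g)
  gv2 <- normalize_gv(ivb, g$gmax_density * h0, mode = "driving_force")
  expect_equal(gv2$value, steady_state_activation(gv2$v_mV, g),
               tolerance = 1e-5)
})

test_that("fit_boltzmann recovers exact synthetic parameters to 1e-6", {
  v <- seq(80, -130, by = -10.5)
  y <- 1 / (1 + exp(-(v + 40.2) / 7.4))
  f <- fit_boltzmann(tibble::tibble(v_mV = v, value = y), "increasing")
  expect_equal(f$vhalf, -40.2, tolerance = 1e-6)
  expect_equal(f$k, 7.4, tolerance = 1e-6)
  vd <- seq(-135, -55, by = 5)
  yd <- 0.97 / (1 + exp((vd + 95.8) / 8.2))
  fd <- fit_boltzmann(tibble::tibble(v_mV = vd, value = yd), "decreasing",
                      amplitude = "free")
  expect_equal(fd$vhalf, -95.8, tolerance = 1e-6)
  expect_equal(fd$k, 8.2, tolerance = 1e-6)
  expect_equal(fd$amplitude, 0.97, tolerance = 1e-6)
  expect_error(fit_boltzmann(tibble::tibble(v_mV = vd, value = rep(0.5, 17)),
                             "decreasing"), "degenerate")
})

test_that("the availability pipeline recovers each preset's inactivation", {
  want <- list(NAV15 = c(-95.8, 8.2), NAV15_B1 = c(-89.8, 6.8),
               HSC_CM = c(-80.0, 9.2))
  for (nm in preset_names()) {
    f <- availability_vhalf(idealized_bundle(nm, "INACTIVATION"))
    expect_equal(f$vhalf, want[[nm]][1], tolerance = 1e-3)
    expect_equal(f$k, want[[nm]][2], tolerance = 1e-3)
  }
})

test_that("the activation pipeline recovers each preset's GV parameters", {
  want <- list(NAV15 = c(-33.5, 6.9), NAV15_B1 = c(-36.1, 7.3),
               HSC_CM = c(-40.2, 7.4))
  for (nm in preset_names()) {
    f <- activation_vhalf(idealized_bundle(nm, "ACTIVATION"))
    expect_equal(f$vhalf, want[[nm]][1], tolerance = 1e-3)
    expect_equal(f$k, want[[nm]][2], tolerance = 1e-3)
  }
})

test_that("GV and availability curves are normalized and bracket 0.5", {
  for (nm in preset_names()) {
    av <- build_availability_curve(idealized_bundle(nm, "INACTIVATION"))
    expect_true(all(av$value >= 0 & av$value <= 1.05))
    expect_true(min(av$value) < 0.5 && max(av$value) > 0.5)
    iv <- build_iv(idealized_bundle(nm, "ACTIVATION"))
    gm <- estimate_gmax(iv, mode = "driving_force")
    gv <- normalize_gv(iv, gm, mode = "driving_force")
    expect_true(all(gv$value >= 0 & gv$value <= 1.05))
    expect_true(min(gv$value) < 0.5 && max(gv$value) > 0.5)
  }
})

test_that("single-exponential fits recover tau exactly and under noise", {
  t <- seq(0.5, 50, length.out = 30)
  f <- fit_single_exponential(tibble::tibble(t_ms = t,
                                             value = 1 - exp(-t / 5.9)))
  expect_equal(f$tau, 5.9, tolerance = 1e-6)
  expect_equal(f$offset, 1, tolerance = 1e-6)
  f2 <- fit_single_exponential(tibble::tibble(t_ms = t,
                                              value = 3 * exp(-t / 1.5) + 2))
  expect_equal(f2$tau, 1.5, tolerance = 1e-6)
  # 2% additive noise, 200 samples: tau recovered within 5%
  set.seed(42)
  tn <- seq(0, 30, length.out = 200)
  yn <- exp(-tn / 5.9) + rnorm(200, 0, 0.02)
  fn <- fit_single_exponential(tibble::tibble(t_ms = tn, value = yn))
  expect_equal(fn$tau, 5.9, tolerance = 0.05)
  expect_error(fit_single_exponential(
    tibble::tibble(t_ms = t, value = rep(1, 30))), "degenerate")
})

test_that("the recovery pipeline recovers each preset's tau_rec", {
  for (nm in preset_names()) {
    rc <- build_recovery_curve(idealized_bundle(nm, "RECOVERY"))
    f <- fit_single_exponential(rc)
    g <- make_preset(nm)$gating
    expect_equal(f$tau, tau_h(-130, g), tolerance = 1e-6)
    expect_equal(f$tau, g$tau_rec, tolerance = 0.05 / g$tau_rec)
  }
})

test_that("availability at -135 is full and crosses 0.5 at the midpoint", {
  av <- build_availability_curve(idealized_bundle("NAV15", "INACTIVATION"))
  expect_equal(av$value[av$v_mV == -135], 1)
  mid <- approx(av$value, av$v_mV, xout = 0.5 * max(av$value))$y
  expect_equal(mid, -95.8, tolerance = 0.2)
})

test_that("concentration-effect assembly normalizes against control", {
  p <- make_preset("NAV15")
  lib <- load_drug_library()
  ce <- cached("ce_lidocaine",
               simulate_concentration_effect(p, lib$lidocaine, n_sweeps = 60))
  expect_equal(ce$conc_uM, lib$lidocaine$concentrations)
  expect_true(all(ce$accepted))
  expect_true(all(diff(ce$value) < 0))  # monotone inhibition
  expect_equal(ce$block[ce$conc_uM == 30], 0.56, tolerance = 0.005)
  # a no-effect compound (vehicle-like) leaves the current untouched
  vehicle <- drug_spec("vehicle", "Ia", "OPEN_STATE", kon = 1e-12,
                       koff = 1e-4, concentrations = c(1, 2, 3, 4))
  cev <- simulate_concentration_effect(p, vehicle, n_sweeps = 20)
  expect_equal(cev$value, rep(1, 4), tolerance = 1e-6)
})

test_that("trivial block arithmetic holds: -2000 control, -700 steady", {
  # remaining fraction I/Imax = 0.35, i.e. 65% block
  expect_equal((-700) / (-2000), 0.35)
  expect_equal(1 - (-700) / (-2000), 0.65)
})

test_that("fit_hill recovers exact synthetic parameters to 1e-6", {
  x <- c(1, 3, 10, 30, 100, 300, 1000)
  y <- 0.2 + (1 - 0.2) / (1 + (x / 50)^1)
  f <- fit_hill(tibble::tibble(conc_uM = x, value = y))
  expect_equal(f$ic50, 50, tolerance = 1e-6)
  expect_equal(f$hill_slope, 1, tolerance = 1e-6)
  expect_equal(f$min, 0.2, tolerance = 1e-6)
  expect_equal(f$max, 1, tolerance = 1e-6)
  expect_error(fit_hill(tibble::tibble(conc_uM = c(1, 10, 100),
                                       value = c(1, 0.5, 0.1))), "4")
})

test_that("fitted IC50 of a simulated curve brackets half-maximal block", {
  lib <- load_drug_library()
  p <- make_preset("NAV15")
  ce <- cached("ce_lidocaine",
               simulate_concentration_effect(p, lib$lidocaine, n_sweeps = 60))
  f <- fit_hill(ce)
  half <- lib$lidocaine$max_block / 2
  below <- max(ce$conc_uM[ce$block < half])
  above <- min(ce$conc_uM[ce$block > half])
  expect_gte(f$ic50, below)
  expect_lte(f$ic50, above)
})

test_that("the series-resistance screen applies the published thresholds", {
  # 10 nA at 1 MOhm -> 10 mV -> excluded at 5 mV
  tr <- tibble::tibble(time_ms = 0:10, i_pA = c(0, rep(-10000, 10)))
  mk <- function(peak_pA, preset_name) {
    pr <- build_protocol("WASHIN", n_sweeps = 1)
    structure(list(protocol = pr, preset_name = preset_name, cm = 20,
                   rs_residual = 1, sampling_khz = 20, mode = "IDEALIZED",
                   drug = NULL, conc_uM = NULL, seed = NULL, e_rev = 86,
                   sweeps = list(list(value = 1, trace = tibble::tibble(
                     time_ms = seq(0, 124.95, by = 0.05),
                     v_mV = -90,
                     i_pA = peak_pA * exp(-(seq(0, 124.95, by = 0.05) - 90)^2)),
                     subs = NULL))),
              class = "sweep_bundle")
  }
  b10 <- mk(-10000, "NAV15")
  expect_false(voltage_error_screen(b10)$keep)
  b4 <- mk(-4000, "NAV15")
  expect_true(voltage_error_screen(b4)$keep)
  b6 <- mk(-6000, "HSC_CM")
  expect_true(voltage_error_screen(b6)$keep)   # 6 mV < 8 mV hSC-CM rule
  expect_false(voltage_error_screen(b6, threshold_mV = 5)$keep)
  # conservation: anything passing at 5 passes at 8
  for (b in list(b10, b4, b6)) {
    if (voltage_error_screen(b, threshold_mV = 5)$keep) {
      expect_true(voltage_error_screen(b, threshold_mV = 8)$keep)
    }
  }
})

test_that("summary ANOVA and pairwise Welch tests behave correctly", {
  same <- tibble::tibble(group = c("a", "b", "c"), mean = c(30, 30, 30),
                         sem = c(2, 2, 2), n = c(7, 10, 11))
  cmp <- compare_groups(same)
  expect_equal(cmp$anova$f, 0)
  expect_gt(cmp$anova$p, 0.99)
  expect_false(any(cmp$pairwise$significant))
  # two-group omnibus F equals the pooled-variance t squared
  two <- tibble::tibble(group = c("a", "b"), mean = c(56, 37),
                        sem = c(2, 2), n = c(7, 10))
  cmp2 <- compare_groups(two)
  sd1 <- 2 * sqrt(7); sd2 <- 2 * sqrt(10)
  sp2 <- ((7 - 1) * sd1^2 + (10 - 1) * sd2^2) / (7 + 10 - 2)
  t_pooled <- (56 - 37) / sqrt(sp2 * (1 / 7 + 1 / 10))
  expect_equal(cmp2$anova$f, t_pooled^2, tolerance = 1e-10)
  expect_error(compare_groups(same[1, ]), "2 groups")
  bad <- same; bad$n[1] <- 1
  expect_error(compare_groups(bad), "n >= 2")
})

test_that("the lidocaine 30 uM group row is significant in all pairs", {
  summ <- tibble::tibble(group = c("NAV15", "NAV15_B1", "HSC_CM"),
                         mean = c(56, 37, 26), sem = c(2, 2, 2),
                         n = c(7, 10, 11))
  cmp <- compare_groups(summ)
  expect_true(all(cmp$pairwise$p < 0.001))
  expect_true(all(cmp$pairwise$significant))
  expect_true(cmp$anova$significant)
})
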