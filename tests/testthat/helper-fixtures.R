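# shared fixtures: quiet presets (no noise/artifacts) and cached bundles

preset_clean <- function(name = "NAV15") {
  p <- make_preset(name)
  p$cell$noise_sd <- 0
  p$cell$g_leak <- 0
  p$cell$rs_residual <- 0
  p
}

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

idealized_bundle <- function(preset_name, kind, ...) {
  key <- paste("ideal", preset_name, kind, ...)
  cached(key, run_protocol(make_preset(preset_name),
                           build_protocol(kind, ...), mode = "IDEALIZED"))
}

activation_vhalf <- function(bundle) {
  iv <- build_iv(bundle)
  gmax <- estimate_gmax(iv, mode = "driving_force")
  fit_boltzmann(normalize_gv(iv, gmax, mode = "driving_force"), "increasing")
}

availability_vhalf <- function(bundle) {
  fit_boltzmann(build_availability_curve(bundle), "decreasing",
                amplitude = "free")
}
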