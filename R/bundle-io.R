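#' Write a sweep bundle to disk
#'
#' One directory per bundle: `meta.json` carries all metadata and the full
#' protocol serialization; each sweep is a `sweep_NNN.csv` with columns
#' `time_ms`, `v_mV`, `i_pA`, and P/-6 subsweeps (when recorded) are
#' `sweep_NNN_subM.csv` in the same schema. The round trip through
#' [read_bundle()] is lossless up to float formatting.
#'
#' @param bundle A [run_protocol()] bundle.
#' @param path Directory to create (must not already contain a bundle).
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  proto <- bundle$protocol
  meta <- list(
    schema_version = 1L,
    preset_name = bundle$preset_name,
    cm = bundle$cm, rs_residual = bundle$rs_residual,
    sampling_khz = bundle$sampling_khz, mode = bundle$mode,
    drug = bundle$drug, conc_uM = bundle$conc_uM,
    max_block = bundle$max_block, seed = bundle$seed, e_rev = bundle$e_rev,
    n_sweeps = length(bundle$sweeps),
    protocol = list(
      name = proto$name, kind = proto$kind, holding_mV = proto$holding_mV,
      intersweep_s = proto$intersweep_s,
      leak_subtraction = proto$leak_subtraction,
      sampling_khz = proto$sampling_khz, prepulse_mV = proto$prepulse_mV,
      sweep_values = proto$sweep_values,
      sweeps = lapply(proto$sweeps, function(s) as.list(s))
    )
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  for (i in seq_along(bundle$sweeps)) {
    sw <- bundle$sweeps[[i]]
    utils::write.csv(sw$trace, file.path(path, sprintf("sweep_%03d.csv", i)),
                     row.names = FALSE)
    if (!is.null(sw$subs)) {
      for (k in seq_len(ncol(sw$subs))) {
        utils::write.csv(
          tibble::tibble(time_ms = sw$trace$time_ms, v_mV = sw$trace$v_mV,
                         i_pA = sw$subs[, k]),
          file.path(path, sprintf("sweep_%03d_sub%d.csv", i, k)),
          row.names = FALSE)
      }
    }
  }
  invisible(path)
}

#' Read a sweep bundle from disk
#'
#' @param path A directory written by [write_bundle()].
#' @return A `sweep_bundle` object.
#' @export
read_bundle <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop("no meta.json in ", path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  if (!identical(as.integer(meta$schema_version), 1L)) {
    stop("unsupported bundle schema version", call. = FALSE)
  }
  files <- sort(list.files(path, pattern = "^sweep_\\d+\\.csv$"))
  if (length(files) != meta$n_sweeps) {
    stop(sprintf(
      "bundle inconsistent: meta.json declares %d sweeps but %d are present",
      meta$n_sweeps, length(files)), call. = FALSE)
  }
  pm <- meta$protocol
  sweeps_segs <- lapply(pm$sweeps, function(s) {
    tibble::tibble(role = s$role, dur_ms = s$dur_ms, v_mV = s$v_mV)
  })
  proto <- structure(list(
    name = pm$name, kind = pm$kind, holding_mV = pm$holding_mV,
    intersweep_s = pm$intersweep_s, leak_subtraction = pm$leak_subtraction,
    sampling_khz = pm$sampling_khz, prepulse_mV = pm$prepulse_mV,
    sweep_values = as.numeric(pm$sweep_values), sweeps = sweeps_segs
  ), class = "pulse_protocol")
  sweeps <- lapply(seq_len(meta$n_sweeps), function(i) {
    tr <- tibble::as_tibble(utils::read.csv(
      file.path(path, sprintf("sweep_%03d.csv", i))))
    subf <- sort(list.files(path,
                            pattern = sprintf("^sweep_%03d_sub\\d+\\.csv$", i)))
    subs <- NULL
    if (length(subf)) {
      subs <- vapply(subf, function(f) {
        utils::read.csv(file.path(path, f))$i_pA
      }, numeric(nrow(tr)))
      dimnames(subs) <- NULL
    }
    list(value = proto$sweep_values[i], trace = tr, subs = subs)
  })
  structure(list(
    protocol = proto, preset_name = meta$preset_name, cm = meta$cm,
    rs_residual = meta$rs_residual, sampling_khz = meta$sampling_khz,
    mode = meta$mode, drug = meta$drug, conc_uM = meta$conc_uM,
    max_block = meta$max_block, seed = meta$seed, e_rev = meta$e_rev,
    sweeps = sweeps
  ), class = "sweep_bundle")
}

#' Axon ABF import (stub)
#'
#' Placeholder interface for importing Axon Binary Format recordings;
#' binary acquisition formats are outside this package's scope.
#'
#' @param path Path to an `.abf` file.
#' @export
read_abf <- function(path) {
  stop("ABF import is a stub interface: convert recordings to the CSV ",
       "bundle layout (see write_bundle) instead", call. = FALSE)
}
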