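#' Load the packaged drug-inhibition reference table
#'
#' Mean percent block (+/- SEM) per drug, concentration and cell model, with
#' the pairwise p-values for the between-model comparisons as printed
#' ("not significant (p)" entries are carried verbatim in all three pairwise
#' columns of their row). The depolarized-prepulse phenytoin sub-table is
#' flagged by `prepulse = "depolarized"`; its original spelling of the drug
#' name was a typo and is normalized to "phenytoin" in the keys.
#'
#' @return A tibble of class `table1_fixture` with columns `drug_class`,
#'   `drug`, `prepulse`, `conc_uM`, `block_*` and `sem_*` per model
#'   (`nav15`, `nav15_b1`, `hsc_cm`), and the pairwise p-value columns.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1.csv", package = "navclamp",
                      mustWork = TRUE)
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                           check.names = TRUE))
  class(out) <- c("table1_fixture", class(out))
  out
}

#' Per-model cell counts for the reference drug responses
#'
#' @return A tibble with columns `drug`, `prepulse` and the number of cells
#'   per model (`n_nav15`, `n_nav15_b1`, `n_hsc_cm`).
#' @export
load_table1_ns <- function() {
  path <- system.file("extdata", "table1_ns.csv", package = "navclamp",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Look up a reference percent-block entry
#'
#' @param drug Drug name (lower case).
#' @param conc_uM Concentration in uM.
#' @param model `"NAV15"`, `"NAV15_B1"` or `"HSC_CM"`.
#' @param prepulse `"standard"` (-130 mV conditioning) or `"depolarized"`.
#' @return A list with `block` and `sem` (percent).
#' @export
table1_block <- function(drug, conc_uM,
                         model = c("NAV15", "NAV15_B1", "HSC_CM"),
                         prepulse = "standard") {
  model <- match.arg(model)
  tab <- load_table1()
  row <- tab[tab$drug == drug & tab$conc_uM == conc_uM &
               tab$prepulse == prepulse, ]
  if (nrow(row) != 1) {
    stop(sprintf("no reference entry for %s at %g uM (%s prepulse)",
                 drug, conc_uM, prepulse), call. = FALSE)
  }
  col <- switch(model, NAV15 = "nav15", NAV15_B1 = "nav15_b1",
                HSC_CM = "hsc_cm")
  list(block = row[[paste0("block_", col)]],
       sem = row[[paste0("sem_", col)]])
}

#' Remaining-fraction concentration series from the reference table
#'
#' Converts a drug's percent-block column into a concentration-effect tibble
#' (remaining fraction I/Imax) ready for [fit_hill()].
#'
#' @inheritParams table1_block
#' @return A tibble with `conc_uM`, `value` (1 - block/100) and `sem`
#'   (fractional).
#' @export
table1_concentration_effect <- function(drug,
                                        model = c("NAV15", "NAV15_B1",
                                                  "HSC_CM"),
                                        prepulse = "standard") {
  model <- match.arg(model)
  tab <- load_table1()
  rows <- tab[tab$drug == drug & tab$prepulse == prepulse, ]
  if (nrow(rows) == 0) {
    stop(sprintf("no reference rows for %s (%s prepulse)", drug, prepulse),
         call. = FALSE)
  }
  col <- switch(model, NAV15 = "nav15", NAV15_B1 = "nav15_b1",
                HSC_CM = "hsc_cm")
  tibble::tibble(conc_uM = rows$conc_uM,
                 value = 1 - rows[[paste0("block_", col)]] / 100,
                 sem = rows[[paste0("sem_", col)]] / 100)
}
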