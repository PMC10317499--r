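#' Model constants shipped with the package
#'
#' Returns the versioned constants table used throughout the analysis:
#' thermal energy RT (kcal/mol at 23 degrees C), the unliganded gating
#' equilibrium constant L0 under the two reference conditions
#' (7.4e-7 at -100 mV; 5.2e-7 for depolarized recordings with the
#' compensating eS450W background), the e-fold/60 mV voltage rule, the
#' background-mutation fold table, the ACh reference dissociation
#' constants, dwell-time analysis defaults (dead time 0.025 ms, tcrit
#' 20 ms, log-likelihood stopping increment 10) and the five reference
#' efficiency class means/sds used for planted-population validation.
#'
#' @return a named list (parsed from the package's `constants.json`).
#' @examples
#' crceta_constants()$RT_kcal_mol
#' @export
crceta_constants <- function() {
  path <- system.file("extdata", "constants.json", package = "crceta",
                      mustWork = TRUE)
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Published agonist and binding-site-mutation CRC tables
#'
#' Measured CRC descriptors (EC50, POmax with sems) and the derived
#' equilibrium constants (KdC, KdO, coupling constant c, efficiency eta)
#' for five agonists on wild-type binding sites (`agonist_table`) and for
#' five agonists on three binding-site mutants (`mutation_table`).
#' Concentration columns are in the units given by the column names
#' (`_uM`, `_nM`); `background` lists the L0-modifying background
#' mutations carried by each construct, separated by `+`.
#'
#' Derived columns in these tables were obtained by the original analysis
#' from per-curve estimates and are not always exactly reproducible from
#' the tabulated mean EC50/POmax (see the methods vignette); the
#' `reproduce_published_checks()` report recomputes only the internally
#' consistent entries.
#'
#' @return a data.frame.
#' @export
agonist_table <- function() {
  read.csv(system.file("extdata", "agonist_table.csv", package = "crceta",
                       mustWork = TRUE), stringsAsFactors = FALSE)
}

#' @rdname agonist_table
#' @export
mutation_table <- function() {
  read.csv(system.file("extdata", "mutation_table.csv", package = "crceta",
                       mustWork = TRUE), stringsAsFactors = FALSE)
}
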