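#' @importFrom rlang .data abort warn
#' @importFrom dplyr %>%
NULL

.PHENOTYPES <- c("mu_max", "lag", "cdw", "biomass_yield", "ethanol_yield")

.PHENOTYPE_UNITS <- c(
  mu_max = "1/h", lag = "h", cdw = "g/L",
  biomass_yield = "g/g", ethanol_yield = "g/g"
)

.GROUPS <- c("acids", "pentoses", "hexoses", "aldehydes", "NaCl", "ethanol")

.PHENO_KEY <- c("strain", "condition", "group", "replicate", "phenotype")

.PHENO_COLS <- c(
  "strain", "condition", "group", "replicate",
  "phenotype", "value", "units", "qc_flags"
)

#' Names of the five measured phenotypes
#'
#' The pipeline tracks five performance phenotypes per well: maximum specific
#' growth rate (`mu_max`, 1/h), lag phase (`lag`, h), final cell dry weight
#' (`cdw`, g/L), biomass yield on consumed sugars (`biomass_yield`, g/g) and
#' ethanol yield on consumed sugars (`ethanol_yield`, g/g).
#'
#' @return Character vector of length five.
#' @export
#' @examples
#' phenotype_names()
phenotype_names <- function() .PHENOTYPES

#' Measurement units of each phenotype
#'
#' @return Named character vector mapping phenotype name to unit.
#' @export
phenotype_units <- function() .PHENOTYPE_UNITS

#' Perturbation group labels
#'
#' Conditions are grouped by the physiological response they elicit:
#' weak organic acids, pentose sugars, hexose sugars, furanic/phenolic
#' aldehydes, osmotic stress (NaCl) and ethanol.
#'
#' @return Character vector of the six group labels.
#' @export
perturbation_groups <- function() .GROUPS

# internal: check a phenotype table has the expected columns
assert_phenotype_table <- function(table, need_flags = FALSE) {
  need <- c("strain", "condition", "group", "replicate", "phenotype", "value")
  if (need_flags) need <- c(need, "qc_flags")
  missing <- setdiff(need, names(table))
  if (length(missing) > 0) {
    abort(paste0(
      "phenotype table is missing column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  bad <- setdiff(unique(table$phenotype), .PHENOTYPES)
  if (length(bad) > 0) {
    abort(paste0("unknown phenotype label(s): ", paste(bad, collapse = ", ")))
  }
  invisible(table)
}

# internal: append a flag to a comma-separated qc_flags string
add_flag <- function(flags, flag, where) {
  flags[is.na(flags)] <- ""
  out <- flags
  has <- where & !grepl(paste0("(^|,)", flag, "(,|$)"), flags)
  out[has & nzchar(flags)] <- paste0(flags[has & nzchar(flags)], ",", flag)
  out[has & !nzchar(flags)] <- flag
  out
}

# internal: deterministic child seed, kept well below 2^31
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(k)
}

# internal: empty phenotype table with canonical columns
empty_phenotype_table <- function() {
  tibble::tibble(
    strain = character(), condition = character(), group = character(),
    replicate = integer(), phenotype = character(), value = double(),
    units = character(), qc_flags = character()
  )
}
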