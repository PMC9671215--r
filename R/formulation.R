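#' Reagent descriptor
#'
#' A formulation component with molar mass (g/mol), optional stock
#' concentration (mg/mL) and a functional role.
#'
#' @param name Reagent name.
#' @param molar_mass Molar mass in g/mol (> 0).
#' @param stock_concentration Stock concentration in mg/mL, or `NA`.
#' @param role One of `"payload"`, `"cationic_lipid"`, `"helper"`,
#'   `"stabilizer"`, `"adhesion"`, `"targeting"`.
#' @return Object of class `reagent`.
#' @export
reagent <- function(name, molar_mass, stock_concentration = NA_real_,
                    role = c("payload", "cationic_lipid", "helper",
                             "stabilizer", "adhesion", "targeting")) {
  role <- match.arg(role)
  .check_positive_scalar(molar_mass, "molar_mass")
  if (!is.na(stock_concentration))
    .check_positive_scalar(stock_concentration, "stock_concentration")
  structure(list(name = name, molar_mass = molar_mass,
                 stock_concentration = stock_concentration, role = role),
            class = "reagent")
}

#' Recipe line
#'
#' One addition in a synthesis recipe: a reagent plus either a mass in ug or
#' a volume in uL of its stock solution (which then requires the reagent to
#' carry a stock concentration).
#'
#' @param reagent A [reagent()].
#' @param mass_ug Mass in micrograms (exclusive with `volume_uL`).
#' @param volume_uL Stock volume in microlitres.
#' @return Object of class `recipe_line`.
#' @export
recipe_line <- function(reagent, mass_ug = NULL, volume_uL = NULL) {
  stopifnot(inherits(reagent, "reagent"))
  if (is.null(mass_ug) == is.null(volume_uL))
    .stopf("give exactly one of 'mass_ug' or 'volume_uL'")
  if (!is.null(mass_ug) && (mass_ug < 0 || !is.finite(mass_ug)))
    .stopf("'mass_ug' must be >= 0")
  if (!is.null(volume_uL)) {
    if (volume_uL < 0 || !is.finite(volume_uL))
      .stopf("'volume_uL' must be >= 0")
    if (is.na(reagent$stock_concentration))
      .stopf("volume line for '%s' requires a stock_concentration",
             reagent$name)
  }
  structure(list(reagent = reagent, mass_ug = mass_ug, volume_uL = volume_uL),
            class = "recipe_line")
}

#' Moles delivered by one recipe line
#'
#' Converts the line amount to nanomoles: volume lines go through the stock
#' concentration (uL x mg/mL = ug), then mass/molar-mass. 520 ug of POPC
#' (760.1 g/mol) gives 684 nmol.
#'
#' @param line A [recipe_line()].
#' @return Amount in nmol.
#' @export
moles_from_line <- function(line) {
  stopifnot(inherits(line, "recipe_line"))
  mass_ug <- if (!is.null(line$mass_ug)) line$mass_ug
             else line$volume_uL * line$reagent$stock_concentration
  # ug / (g/mol) = umol*1e-3 -> nmol = 1e3 * ug/MW
  1e3 * mass_ug / line$reagent$molar_mass
}

#' Mole percentages of a recipe
#'
#' Per-line molar percentages of the total, plus nearest-integer report
#' values (raw values retain full precision and sum to 100).
#'
#' @param recipe List of [recipe_line()] objects.
#' @return Data frame with columns `name`, `nmol`, `mole_percent`,
#'   `mole_percent_report`.
#' @export
mole_percentages <- function(recipe) {
  if (length(recipe) < 1L) .stopf("recipe must contain at least one line")
  nmol <- vapply(recipe, moles_from_line, numeric(1))
  total <- sum(nmol)
  if (total <= 0) .stopf("total moles must be > 0")
  pct <- 100 * nmol / total
  data.frame(
    name = vapply(recipe, function(l) l$reagent$name, character(1)),
    nmol = nmol,
    mole_percent = pct,
    mole_percent_report = round(pct),
    stringsAsFactors = FALSE
  )
}

#' Counterion stoichiometric excess
#'
#' Ratio of available counterion moles to the stoichiometric requirement
#' (`stoich` counterions per payload monomer). Values > 1 indicate excess
#' counterion, < 1 a shortfall. Scale-invariant in the overall batch size.
#'
#' @param payload_monomer_umol Payload monomer amount in umol (> 0).
#' @param counterion_umol Counterion amount in umol.
#' @param stoich Counterions required per monomer (default 2).
#' @return Dimensionless excess ratio.
#' @export
counterion_excess <- function(payload_monomer_umol, counterion_umol,
                              stoich = 2) {
  .check_positive_scalar(payload_monomer_umol, "payload_monomer_umol")
  counterion_umol / (stoich * payload_monomer_umol)
}

#' Payload dose concentration
#'
#' @param payload_nmol Payload amount in nmol.
#' @param final_volume_uL Final suspension volume in uL (> 0).
#' @return Dose concentration in nmol/uL (full precision).
#' @export
dose_concentration <- function(payload_nmol, final_volume_uL) {
  .check_positive_scalar(final_volume_uL, "final_volume_uL")
  payload_nmol / final_volume_uL
}

#' Full formulation report
#'
#' Aggregates the recipe into a report: per-line moles and mole percentages,
#' counterion excess relative to the payload, dose concentration, and
#' warnings when the counterion is sub-stoichiometric or the composition
#' deviates from a declared target formula.
#'
#' @param recipe List of [recipe_line()] objects (the shell-lipid mixture).
#' @param payload_monomer_umol Payload monomer amount in umol (optional).
#' @param counterion_umol Counterion amount in umol (optional).
#' @param stoich Counterions per payload monomer (default 2).
#' @param payload_nmol,final_volume_uL Dose inputs (optional).
#' @param target_mole_percent Named numeric vector of target mole % per
#'   reagent name (optional).
#' @param target_tol Allowed deviation from the target in percentage points.
#' @return Object of class `formulation_report`: the mole table plus
#'   `counterion_excess`, `dose_concentration` and `warnings`.
#' @export
recipe_report <- function(recipe, payload_monomer_umol = NULL,
                          counterion_umol = NULL, stoich = 2,
                          payload_nmol = NULL, final_volume_uL = NULL,
                          target_mole_percent = NULL, target_tol = 1) {
  tab <- mole_percentages(recipe)
  warnings <- character(0)
  excess <- NA_real_
  if (!is.null(payload_monomer_umol) && !is.null(counterion_umol)) {
    excess <- counterion_excess(payload_monomer_umol, counterion_umol, stoich)
    if (excess < 1)
      warnings <- c(warnings, sprintf(
        "counterion shortfall: excess ratio %.2f < 1", excess))
  }
  dose <- NA_real_
  if (!is.null(payload_nmol) && !is.null(final_volume_uL))
    dose <- dose_concentration(payload_nmol, final_volume_uL)
  if (!is.null(target_mole_percent)) {
    for (nm in names(target_mole_percent)) {
      i <- match(nm, tab$name)
      if (is.na(i)) {
        warnings <- c(warnings, sprintf("target component '%s' absent", nm))
      } else if (abs(tab$mole_percent[i] - target_mole_percent[[nm]]) >
                   target_tol) {
        warnings <- c(warnings, sprintf(
          "'%s' at %.1f mol%% deviates from target %.1f", nm,
          tab$mole_percent[i], target_mole_percent[[nm]]))
      }
    }
  }
  structure(list(table = tab, counterion_excess = excess,
                 dose_concentration = dose, warnings = warnings),
            class = "formulation_report")
}

#' @export
print.formulation_report <- function(x, ...) {
  cat("Formulation report\n")
  print(x$table, row.names = FALSE)
  if (!is.na(x$counterion_excess))
    cat(sprintf("Counterion excess: %.3f\n", x$counterion_excess))
  if (!is.na(x$dose_concentration))
    cat(sprintf("Dose concentration: %.3f nmol/uL\n", x$dose_concentration))
  if (length(x$warnings)) cat("Warnings:\n", paste(" -", x$warnings,
                                                   collapse = "\n"), "\n")
  invisible(x)
}
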