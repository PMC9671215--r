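#' Solvent medium descriptor
#'
#' A dielectric/viscous medium in which electrostatic and hydrodynamic
#' calculations are performed. Relative permittivity is dimensionless
#' (water ~ 80, methanol ~ 30, chloroform ~ 5), temperature is in kelvin and
#' viscosity (optional; needed by the DLS and electrokinetics routines) is in
#' Pa s.
#'
#' @param relative_permittivity Relative dielectric permittivity (> 0).
#' @param temperature Absolute temperature in K (default 298.15 K).
#' @param viscosity Dynamic viscosity in Pa s, or `NA` if not needed.
#' @return An object of class `solvent_medium`.
#' @examples
#' water <- solvent_medium(80)
#' bjerrum_length(water)
#' @export
solvent_medium <- function(relative_permittivity, temperature = 298.15,
                           viscosity = NA_real_) {
  .check_positive_scalar(relative_permittivity, "relative_permittivity")
  .check_positive_scalar(temperature, "temperature")
  if (!is.na(viscosity)) .check_positive_scalar(viscosity, "viscosity")
  structure(
    list(relative_permittivity = relative_permittivity,
         temperature = temperature,
         viscosity = viscosity),
    class = "solvent_medium"
  )
}

#' @export
print.solvent_medium <- function(x, ...) {
  cat(sprintf("Solvent medium: eps_rel = %g, T = %g K, eta = %s Pa.s\n",
              x$relative_permittivity, x$temperature,
              ifelse(is.na(x$viscosity), "NA", format(x$viscosity))))
  invisible(x)
}

.as_medium <- function(medium) {
  if (inherits(medium, "solvent_medium")) return(medium)
  .stopf("expected a 'solvent_medium' object; see solvent_medium()")
}

#' Bjerrum length of a dielectric medium
#'
#' Distance at which the Coulomb energy of two elementary charges equals the
#' thermal energy: lambda_B = e^2 / (4 pi epsilon0 eps_rel kB T). In water at
#' 298.15 K this evaluates to 0.70 nm; lowering the permittivity (e.g. toward
#' a chloroform-rich Bligh-Dyer phase) grows the "Bjerrum cage" inversely.
#'
#' @param medium A [solvent_medium()].
#' @return Bjerrum length in nm.
#' @examples
#' bjerrum_length(solvent_medium(80))  # ~0.70 nm
#' bjerrum_length(solvent_medium(5))   # ~11.2 nm
#' @export
bjerrum_length <- function(medium) {
  medium <- .as_medium(medium)
  k <- .const
  lb_m <- k$e^2 /
    (4 * pi * k$epsilon0 * medium$relative_permittivity *
       k$kB * medium$temperature)
  lb_m * 1e9
}

#' Manning coupling parameter
#'
#' Dimensionless ratio Gamma = lambda_B / l0 of the Bjerrum length to the
#' axial spacing between charges on a linear polyelectrolyte. Gamma > 1 is the
#' Manning condensation regime. For a single-stranded oligonucleotide in water
#' (l0 = 0.34 nm per base) Gamma ~ 2.1.
#'
#' @param bjerrum_length_nm Bjerrum length in nm (> 0).
#' @param charge_spacing_l0 Axial inter-charge spacing in nm (> 0).
#' @return Gamma, dimensionless.
#' @export
coupling_parameter <- function(bjerrum_length_nm, charge_spacing_l0) {
  .check_positive_scalar(bjerrum_length_nm, "bjerrum_length_nm")
  .check_positive_scalar(charge_spacing_l0, "charge_spacing_l0")
  bjerrum_length_nm / charge_spacing_l0
}

#' Manning condensed counterion fraction
#'
#' Fraction of the polyelectrolyte charge neutralized by condensed
#' counterions: theta = max(0, 1 - 1/Gamma). Zero at or below the Manning
#' threshold Gamma = 1, approaching 1 as the coupling diverges.
#'
#' @param coupling Coupling parameter Gamma (>= 0); vectorized.
#' @return theta in \[0, 1).
#' @examples
#' manning_condensed_fraction(2.06)  # ~0.51
#' @export
manning_condensed_fraction <- function(coupling) {
  if (!is.numeric(coupling) || any(!is.finite(coupling)) || any(coupling < 0))
    .stopf("'coupling' must be non-negative and finite")
  ifelse(coupling <= 1, 0, 1 - 1 / coupling)
}

#' Permittivity of a ternary solvent mixture
#'
#' Effective relative permittivity of a water/methanol/chloroform mixture.
#' The default rule is a volume-fraction-weighted linear mean of the component
#' permittivities (80/30/5), which reproduces the pure-component endpoints and
#' stays within the component extremes; alternative mixing rules can be
#' supplied through `model`.
#'
#' @param comp A [ternary_composition()]; converted to volume basis if needed.
#' @param permittivities Named numeric vector with entries `water`,
#'   `methanol`, `chloroform`.
#' @param densities A [density_set()] used only when `comp` is on a weight
#'   basis and must be converted.
#' @param model Mixing rule: `"linear"` (volume-weighted arithmetic mean) or a
#'   function `f(volume_fractions, permittivities)` returning a scalar.
#' @return Relative permittivity (dimensionless).
#' @examples
#' mixture_permittivity(ternary_composition(100, 0, 0))  # 80
#' mixture_permittivity(ternary_composition(50, 0, 50))  # 42.5
#' @export
mixture_permittivity <- function(comp,
                                 permittivities = c(water = 80, methanol = 30,
                                                    chloroform = 5),
                                 densities = density_set(),
                                 model = "linear") {
  comp <- .as_ternary(comp)
  need <- c("water", "methanol", "chloroform")
  if (!all(need %in% names(permittivities)))
    .stopf("permittivities must name all of: %s", paste(need, collapse = ", "))
  if (comp$basis != "volume") comp <- convert_basis(comp, densities, "volume")
  phi <- c(comp$water, comp$methanol, comp$chloroform) / 100
  eps <- unname(permittivities[need])
  if (is.function(model)) return(model(phi, eps))
  if (identical(model, "linear")) return(sum(phi * eps))
  .stopf("unknown permittivity model '%s'", model)
}

#' Full condensation assessment for a polyelectrolyte in a medium
#'
#' Combines the Bjerrum length, Manning coupling and condensed fraction into
#' one record, with a qualitative regime label (see [classify_regime()]).
#'
#' @param medium A [solvent_medium()].
#' @param charge_spacing_l0 Axial charge spacing in nm (default 0.34, the
#'   nucleotide rise).
#' @param rod_length Length of the polyion rod in nm, used for the
#'   strong-condensation criterion (default 5.44 = 16 x 0.34).
#' @return An object of class `condensation_assessment` with fields
#'   `bjerrum_length` (nm), `coupling`, `condensed_fraction`, `regime_label`.
#' @export
condensation_assessment <- function(medium, charge_spacing_l0 = 0.34,
                                    rod_length = 16 * 0.34) {
  lb <- bjerrum_length(medium)
  g <- coupling_parameter(lb, charge_spacing_l0)
  out <- structure(
    list(bjerrum_length = lb,
         coupling = g,
         condensed_fraction = manning_condensed_fraction(g),
         regime_label = NA_character_),
    class = "condensation_assessment"
  )
  out$regime_label <- classify_regime(out, rod_length)
  out
}

#' @export
print.condensation_assessment <- function(x, ...) {
  cat(sprintf(
    "Condensation: lambda_B = %.3f nm, Gamma = %.2f, theta = %.2f [%s]\n",
    x$bjerrum_length, x$coupling, x$condensed_fraction, x$regime_label))
  invisible(x)
}

#' Classify the counterion-condensation regime
#'
#' Three-way label driven by the Manning threshold and the size of the
#' Bjerrum cage relative to the polyion rod: `sub_critical` when Gamma <= 1;
#' `strongly_condensing` when the Bjerrum length spans the whole rod
#' (lambda_B >= rod length, the low-permittivity organic-phase situation);
#' `weakly_condensing` otherwise (e.g. water).
#'
#' @param assessment A `condensation_assessment` (or a list with fields
#'   `coupling` and `bjerrum_length`).
#' @param rod_length Rod length in nm.
#' @param gamma_threshold Manning threshold on Gamma (default 1).
#' @return One of `"sub_critical"`, `"weakly_condensing"`,
#'   `"strongly_condensing"`.
#' @export
classify_regime <- function(assessment, rod_length, gamma_threshold = 1) {
  .check_positive_scalar(rod_length, "rod_length")
  g <- assessment$coupling
  lb <- assessment$bjerrum_length
  if (g <= gamma_threshold) return("sub_critical")
  if (lb >= rod_length) return("strongly_condensing")
  "weakly_condensing"
}
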