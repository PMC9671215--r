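#' Coarse-grained polyanion rod
#'
#' A single-stranded oligonucleotide coarse-grained as a rigid charged
#' cylinder: `n_units` bases of axial rise `unit_rise_l0` (nm), diameter
#' `diameter_D0` (nm) and `charge_per_unit` elementary charges per base
#' (default -1 for a phosphate backbone).
#'
#' @param n_units Number of charged units (bases), >= 1.
#' @param unit_rise_l0 Rise per unit in nm (default 0.34).
#' @param diameter_D0 Rod diameter in nm (default 1.0).
#' @param charge_per_unit Charge per unit in elementary charges (default -1).
#' @return Object of class `polyanion_rod`.
#' @export
polyanion_rod <- function(n_units = 16, unit_rise_l0 = 0.34,
                          diameter_D0 = 1.0, charge_per_unit = -1) {
  if (!is.numeric(n_units) || n_units < 1) .stopf("'n_units' must be >= 1")
  .check_positive_scalar(unit_rise_l0, "unit_rise_l0")
  .check_positive_scalar(diameter_D0, "diameter_D0")
  structure(list(n_units = n_units, unit_rise_l0 = unit_rise_l0,
                 diameter_D0 = diameter_D0, charge_per_unit = charge_per_unit),
            class = "polyanion_rod")
}

#' Cationic amphiphile descriptor
#'
#' Molecular coarse-graining of the condensing cationic lipid (e.g.
#' DC-cholesterol): specific volume `v0` (nm^3), headgroup area `a0` (nm^2),
#' head-to-tail length (nm), headgroup charge (e), and bookkeeping fields
#' (pKa, molar mass).
#'
#' @param specific_volume_v0 Molecular volume in nm^3.
#' @param headgroup_area_a0 Headgroup cross-section in nm^2.
#' @param length Head-to-tail length in nm.
#' @param headgroup_charge Headgroup charge in elementary charges (default +1).
#' @param pKa Headgroup pKa (informational).
#' @param molar_mass Molar mass in g/mol (informational).
#' @return Object of class `amphiphile`.
#' @export
amphiphile <- function(specific_volume_v0 = 0.9, headgroup_area_a0 = 0.5,
                       length = 2.0, headgroup_charge = 1,
                       pKa = 9.3, molar_mass = 537.3) {
  .check_positive_scalar(specific_volume_v0, "specific_volume_v0")
  .check_positive_scalar(headgroup_area_a0, "headgroup_area_a0")
  .check_positive_scalar(length, "length")
  structure(list(specific_volume_v0 = specific_volume_v0,
                 headgroup_area_a0 = headgroup_area_a0,
                 length = length, headgroup_charge = headgroup_charge,
                 pKa = pKa, molar_mass = molar_mass),
            class = "amphiphile")
}

#' Rod geometry and surface charge density
#'
#' Closed-form geometry of the coarse-grained rod: contour length n*l0, the
#' specific (per-unit) lateral area pi*D0*l0, the per-unit lateral ring area
#' pi*l0^2, and the surface charge density charge/(pi*D0*l0) in e/nm^2. For
#' the 16-base default this gives a 5.44 nm rod with sigma ~ -0.94 e/nm^2.
#'
#' @param rod A [polyanion_rod()].
#' @return List with `length` (nm), `specific_area` (nm^2 per unit),
#'   `lateral_area` (nm^2), `surface_charge_density` (e/nm^2).
#' @export
rod_geometry <- function(rod) {
  stopifnot(inherits(rod, "polyanion_rod"))
  a_unit <- pi * rod$diameter_D0 * rod$unit_rise_l0
  list(
    length = rod$n_units * rod$unit_rise_l0,
    specific_area = a_unit,
    lateral_area = pi * rod$unit_rise_l0^2,
    surface_charge_density = rod$charge_per_unit / a_unit
  )
}

#' Surfactant packing aspect ratio and shape class
#'
#' Dimensionless packing ratio v0/(a0 * length). Values in (1/2, 1] predict a
#' cylinder-like molecule and hence a bilayer former; <= 1/2 predicts strongly
#' curved (micellar) aggregates; > 1 inverted phases. The boundary at exactly
#' 1/2 is classified micellar (half-open intervals).
#'
#' @param amph An [amphiphile()].
#' @return List with `aspect_ratio` and `shape_class` (one of
#'   `"micellar"`, `"bilayer_former"`, `"inverted"`).
#' @export
packing_aspect <- function(amph) {
  stopifnot(inherits(amph, "amphiphile"))
  ratio <- amph$specific_volume_v0 / (amph$headgroup_area_a0 * amph$length)
  shape <- if (ratio <= 0.5) "micellar"
           else if (ratio <= 1) "bilayer_former"
           else "inverted"
  list(aspect_ratio = ratio, shape_class = shape)
}

#' Predicted lamellar repeat spacing
#'
#' Additive layer model for the catanionic lamellar phase: a dense payload
#' monolayer of thickness `payload_layer` is intercalated between amphiphile
#' bilayers of thickness 2 x `amphiphile_length`, so the repeat spacing is
#' D = D_payload + 2*D1. With the default-like inputs (1 nm payload layer,
#' 2 nm lipid) this predicts D = 5 nm.
#'
#' @param payload_layer Payload (nucleic-acid) layer thickness in nm, >= 0.
#' @param amphiphile_length Amphiphile head-to-tail length in nm, >= 0.
#' @return List with `payload_layer_DGR`, `bilayer_Dbil`, `repeat_spacing_D`
#'   (all nm); the repeat spacing is exactly the sum of the other two.
#' @export
lamellar_spacing <- function(payload_layer, amphiphile_length) {
  if (payload_layer < 0 || amphiphile_length < 0)
    .stopf("layer thicknesses must be >= 0")
  dbil <- 2 * amphiphile_length
  list(payload_layer_DGR = payload_layer,
       bilayer_Dbil = dbil,
       repeat_spacing_D = payload_layer + dbil)
}

#' Catanionic stoichiometry bookkeeping
#'
#' Two independent estimates of the counterion:payload-unit ratio for a
#' charged rod wrapped by an amphiphile bilayer: (i) area matching, the
#' number of headgroups needed to tile the per-unit rod area,
#' specific_area / a0 (the bilayer then splits them evenly across
#' `leaflets` leaflets, reported as `per_leaflet`); and (ii) charge balance,
#' |unit charge| / |headgroup charge|. The two need not agree (with the
#' defaults they give ~2.1 and 1); both are returned, along with the adopted
#' ratio used downstream (default 2, the bilayer-organized formula) and the
#' residual surface charge it leaves.
#'
#' @param rod A [polyanion_rod()].
#' @param amph An [amphiphile()].
#' @param leaflets Number of amphiphile leaflets sharing the headgroups
#'   (default 2, a bilayer).
#' @param adopted_ratio Counterions per payload unit used for downstream
#'   formulation math (default 2).
#' @param tolerance Agreement tolerance between the two ratios.
#' @return List with `area_matching_ratio`, `per_leaflet`,
#'   `charge_balance_ratio`, `adopted_ratio`, `neutrality_residual` (e/nm^2)
#'   and logical `consistent`.
#' @export
catanionic_stoichiometry <- function(rod, amph, leaflets = 2,
                                     adopted_ratio = 2, tolerance = 0.25) {
  stopifnot(inherits(rod, "polyanion_rod"), inherits(amph, "amphiphile"))
  geo <- rod_geometry(rod)
  area_ratio <- geo$specific_area / amph$headgroup_area_a0
  if (amph$headgroup_charge == 0) {
    charge_ratio <- NA_real_
    warning("zero headgroup charge: charge-balance ratio undefined",
            call. = FALSE)
  } else {
    charge_ratio <- abs(rod$charge_per_unit) / abs(amph$headgroup_charge)
  }
  residual <- (geo$surface_charge_density * geo$specific_area +
                 adopted_ratio * amph$headgroup_charge) / geo$specific_area
  consistent <- !is.na(charge_ratio) &&
    abs(area_ratio - charge_ratio) < tolerance
  list(area_matching_ratio = area_ratio,
       per_leaflet = area_ratio / leaflets,
       charge_balance_ratio = charge_ratio,
       adopted_ratio = adopted_ratio,
       neutrality_residual = residual,
       consistent = consistent)
}
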