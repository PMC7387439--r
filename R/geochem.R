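#' Pore-water oxygen inventory of a sediment plug
#'
#' Moles of dissolved O2 carried into an incubation vial by the sediment
#' plug's interstitial water: concentration times pore-water volume.
#'
#' @param porewater_O2 Dissolved O2 concentration in the interstitial
#'   water, in micromolar.
#' @param sediment_volume Plug volume in cubic centimetres.
#' @param porosity Pore-water volume fraction, in (0, 1).
#' @return O2 inventory in nanomoles.
#' @export
#' @examples
#' oxygen_inventory(1.5, 15, 0.73)  # ~16.4 nmol
oxygen_inventory <- function(porewater_O2, sediment_volume, porosity = 0.73) {
  if (porewater_O2 < 0) abort("`porewater_O2` must be non-negative")
  if (sediment_volume <= 0) abort("`sediment_volume` must be positive")
  if (porosity <= 0 || porosity >= 1) abort("`porosity` must lie in (0, 1)")
  # µmol/L * (cm3 of pore water / 1000) L = µmol/1000 = nmol * ...:
  # µM * cm3 * porosity gives nmol directly (1 cm3 = 1e-3 L; 1 µmol = 1e3 nmol)
  porewater_O2 * sediment_volume * porosity
}

#' Headspace-porewater oxygen partitioning at equilibrium
#'
#' Distributes a fixed O2 inventory between a gas headspace and the
#' aqueous phase using a dimensionless Henry solubility
#' `H = C_aq / C_gas` (aqueous over gas concentration). Mass is conserved
#' exactly: `V_gas * C_gas + V_aq * C_aq = inventory`.
#'
#' @param inventory O2 inventory in nanomoles.
#' @param headspace_volume Gas headspace volume in millilitres.
#' @param water_volume Aqueous (pore-water) volume in millilitres.
#' @param henry_solubility Dimensionless aqueous/gas concentration ratio
#'   (about 0.032 for O2 near 25 degrees C).
#' @return A one-row tibble: `gas_nmol_per_mL`, `aqueous_nM`, `gas_nmol`,
#'   `aqueous_nmol`.
#' @export
#' @examples
#' oxygen_equilibrium(16.4, headspace_volume = 35, water_volume = 11)
oxygen_equilibrium <- function(inventory, headspace_volume, water_volume,
                               henry_solubility = 0.032) {
  if (inventory < 0) abort("`inventory` must be non-negative")
  if (headspace_volume < 0 || water_volume <= 0) {
    abort("volumes must be positive (headspace may be zero)")
  }
  if (henry_solubility <= 0) abort("`henry_solubility` must be positive")
  denom <- headspace_volume + henry_solubility * water_volume
  if (denom == 0) abort("zero total effective volume")
  c_gas <- inventory / denom                 # nmol per mL of gas
  c_aq <- henry_solubility * c_gas           # nmol per mL of water
  tibble::tibble(
    gas_nmol_per_mL = c_gas,
    aqueous_nM = c_aq * 1000,                # nmol/mL = µM = 1000 nM
    gas_nmol = c_gas * headspace_volume,
    aqueous_nmol = c_aq * water_volume
  )
}

#' Microbial biomass supportable by sedimentary organic carbon
#'
#' Converts a total-organic-carbon content into the number of cells it
#' could build: `TOC (g C / g) * dry bulk density (g / cm3) * 1e15 fg/g /
#' carbon per cell (fg C)`.
#'
#' @param toc_weight_fraction Organic carbon content as a weight fraction
#'   of dry sediment (e.g. 1e-4 for 0.01 weight percent).
#' @param dry_bulk_density Dry bulk density in grams per cubic
#'   centimetre.
#' @param carbon_per_cell Cellular carbon quota in femtograms (default
#'   10 fg, the conventional subseafloor value).
#' @return Supportable biomass in cells per cubic centimetre.
#' @export
#' @examples
#' toc_supportable_biomass(1e-4)  # > 1e10 cells per cm3
toc_supportable_biomass <- function(toc_weight_fraction,
                                    dry_bulk_density = 1.3,
                                    carbon_per_cell = 10) {
  if (toc_weight_fraction < 0 || toc_weight_fraction >= 1) {
    abort("`toc_weight_fraction` must lie in [0, 1)")
  }
  if (dry_bulk_density <= 0 || carbon_per_cell <= 0) {
    abort("density and carbon quota must be positive")
  }
  toc_weight_fraction * dry_bulk_density * 1e15 / carbon_per_cell
}
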