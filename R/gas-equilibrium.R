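#' Reference Henry solubilities used for gas-liquid partitioning
#'
#' Henry solubility at 25 degC (`hcp_mol_l_atm`, mol L^-1 atm^-1) and the
#' van 't Hoff temperature coefficient (`vant_hoff_k`, K) for the two gases
#' handled by the package, taken from the Sander (2015, Atmos. Chem. Phys.)
#' compilation of Henry's-law constants for water as solvent. Freshwater
#' values; no salinity or pressure correction is applied.
#'
#' @return A tibble with columns `species`, `hcp_mol_l_atm`, `vant_hoff_k`.
#' @examples
#' henry_reference()
#' @export
henry_reference <- function() {
  tibble(
    species = c("N2O", "N2"),
    hcp_mol_l_atm = c(2.5e-2, 6.4e-4),
    vant_hoff_k = c(2700, 1300)
  )
}

GAS_CONSTANT_L_ATM <- 0.08205736 # L atm mol^-1 K^-1
T_REF_K <- 298.15

#' Dimensionless Henry constant (liquid/gas concentration ratio)
#'
#' Computes H_cc = C_liquid / C_gas at equilibrium for N2O or N2 at a given
#' temperature, from the reference solubility at 25 degC with van 't Hoff
#' temperature correction and the ideal-gas conversion H_cc = Hcp * R * T.
#' H_cc decreases with temperature (gases are less soluble when warm).
#'
#' @param species `"N2O"` or `"N2"` (isotopologue labels such as `"30N2"`
#'   are accepted and mapped to their parent gas; isotopic differences in
#'   solubility are neglected).
#' @param temperature_c Temperature in degC, in (0, 60).
#'
#' @return Dimensionless H_cc (vectorised over `species` and
#'   `temperature_c`).
#' @examples
#' henry_cc("N2O", 25) # ~0.61
#' henry_cc("N2O", 30) # ~0.54
#' @export
henry_cc <- function(species, temperature_c) {
  if (any(!is.finite(temperature_c)) || any(temperature_c <= 0) ||
    any(temperature_c >= 60)) {
    abort("`temperature_c` must be in (0, 60) degC.",
      class = "n2opair_domain_error"
    )
  }
  gas <- parent_gas(species)
  ref <- henry_reference()
  idx <- match(gas, ref$species)
  t_k <- temperature_c + 273.15
  hcp <- ref$hcp_mol_l_atm[idx] *
    exp(ref$vant_hoff_k[idx] * (1 / t_k - 1 / T_REF_K))
  hcp * GAS_CONSTANT_L_ATM * t_k
}

parent_gas <- function(species) {
  gas <- dplyr::case_when(
    species %in% c("N2O", SPECIES_N2O) ~ "N2O",
    species %in% c("N2", SPECIES_N2) ~ "N2",
    TRUE ~ NA_character_
  )
  if (anyNA(gas)) {
    abort(
      paste0(
        "Unsupported species: ",
        paste(unique(species[is.na(gas)]), collapse = ", "),
        ". Supported: N2, N2O and their isotopologues."
      ),
      class = "n2opair_species_error"
    )
  }
  gas
}

#' Equilibrium phase split of a gas in a sealed vial
#'
#' Fraction of the total amount of a gas residing in the headspace and in
#' the liquid at Henry equilibrium: headspace fraction
#' V_gas / (V_gas + H_cc V_liquid). The two fractions sum to one.
#'
#' @inheritParams henry_cc
#' @param v_gas_ml,v_liquid_ml Headspace and liquid volumes, mL.
#'
#' @return A tibble with columns `species`, `headspace` and `dissolved`.
#' @examples
#' partition_fractions("N2O", 30, v_gas_ml = 15, v_liquid_ml = 15)
#' @export
partition_fractions <- function(species, temperature_c, v_gas_ml, v_liquid_ml) {
  if (any(v_gas_ml <= 0) || any(v_liquid_ml <= 0)) {
    abort("Volumes must be positive.", class = "n2opair_domain_error")
  }
  hcc <- henry_cc(species, temperature_c)
  fh <- v_gas_ml / (v_gas_ml + hcc * v_liquid_ml)
  tibble(species = species, headspace = fh, dissolved = 1 - fh)
}

#' Dissolved N2O from a headspace-equilibration measurement
#'
#' Recovers the original dissolved N2O concentration of a liquid sample
#' from the gas-phase concentration measured after equilibrating a small
#' liquid aliquot with an N2-filled headspace in a sealed vial. All N2O in
#' the aliquot redistributes between phases, so by mass balance
#'
#'   C_original = C_gas (V_gas + H_cc V_liquid) / V_liquid.
#'
#' Defaults describe the routine assay: 1 mL of sample in a 13-mL vial
#' under 12 mL of pure N2, equilibrated at 30 degC.
#'
#' @param data A data frame with a column of measured headspace
#'   concentrations (any concentration unit; the output is in the same
#'   unit).
#' @param headspace_col Name of the headspace-concentration column
#'   (default `"headspace_conc"`).
#' @param v_liquid_ml,v_gas_ml Aliquot and headspace volumes, mL.
#' @param temperature_c Equilibration temperature, degC.
#' @param species Gas species, default `"N2O"`.
#'
#' @return The input as a tibble with an added `dissolved_conc` column.
#' @seealso [dissolved_n2o()] for the scalar version.
#' @examples
#' dissolved_from_headspace(
#'   tibble::tibble(sample_id = "d776", headspace_conc = 0.051)
#' )
#' @export
dissolved_from_headspace <- function(data,
                                     headspace_col = "headspace_conc",
                                     v_liquid_ml = 1,
                                     v_gas_ml = 12,
                                     temperature_c = 30,
                                     species = "N2O") {
  if (!headspace_col %in% names(data)) {
    abort(paste0("Column `", headspace_col, "` not found in `data`."),
      class = "n2opair_parse_error"
    )
  }
  out <- as_tibble(data)
  out$dissolved_conc <- dissolved_n2o(
    out[[headspace_col]],
    v_liquid_ml = v_liquid_ml, v_gas_ml = v_gas_ml,
    temperature_c = temperature_c, species = species
  )
  out
}

#' @rdname dissolved_from_headspace
#' @param c_gas Measured gas-phase concentration(s).
#' @param hcc Optional dimensionless Henry constant override (bypasses the
#'   `species`/`temperature_c` lookup; `hcc = 0` gives the insoluble-gas
#'   limit in which all mass is driven to the headspace).
#' @export
dissolved_n2o <- function(c_gas,
                          v_liquid_ml = 1,
                          v_gas_ml = 12,
                          temperature_c = 30,
                          species = "N2O",
                          hcc = NULL) {
  if (v_liquid_ml <= 0 || v_gas_ml <= 0) {
    abort("Volumes must be positive.", class = "n2opair_domain_error")
  }
  hcc <- hcc %||% henry_cc(species, temperature_c)
  c_gas * (v_gas_ml + hcc * v_liquid_ml) / v_liquid_ml
}

#' Convert between nitrogen concentration units
#'
#' Exact factor conversions between `"mg_n_l"` (mg N per litre, counting
#' N atoms) and `"umol_l"` (micromolar of the molecule) for two-nitrogen
#' gases (N2O, N2): 1 umol L^-1 = 0.028 mg N L^-1.
#'
#' @param value Numeric vector of concentrations.
#' @param from,to Units, each one of `"mg_n_l"`, `"umol_l"`.
#' @param n_atoms Number of N atoms per molecule (default 2).
#'
#' @return Converted numeric vector.
#' @examples
#' convert_concentration(3.96, "mg_n_l", "umol_l") # ~141 uM
#' convert_concentration(9.50, "umol_l", "mg_n_l") # 0.266 mg N/L
#' @export
convert_concentration <- function(value, from, to, n_atoms = 2) {
  units <- c("mg_n_l", "umol_l")
  if (!from %in% units || !to %in% units) {
    abort("Supported units: \"mg_n_l\", \"umol_l\".",
      class = "n2opair_unit_error"
    )
  }
  if (from == to) {
    return(value)
  }
  mg_n_per_umol <- n_atoms * MG_N_PER_MMOL_N / 1000
  if (from == "umol_l") value * mg_n_per_umol else value / mg_n_per_umol
}
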