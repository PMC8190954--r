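#' Assemble the lattice energy from its components
#'
#' The lattice energy relative to isolated molecules in their gas-phase
#' minimum conformation is the intermolecular term plus the intramolecular
#' conformational strain of the molecule in the crystal:
#' `E_latt = U_inter + (E_mol_in_cryst - E_mol_min)`. The strain must be
#' non-negative: a crystal conformer below the claimed gas-phase global
#' minimum means the minimum search failed.
#'
#' @param u_inter intermolecular lattice term, kJ/mol (typically negative).
#' @param e_mol_in_cryst molecular energy in the crystal conformation, kJ/mol.
#' @param e_mol_min gas-phase global-minimum molecular energy, kJ/mol.
#' @return A one-row tibble with columns `u_inter`, `e_mol_in_cryst`,
#'   `e_mol_min`, `strain` and `e_latt` (all kJ/mol).
#' @examples
#' lattice_energy(-100, -50, -52.5)  # 2.5 kJ/mol strain
#' @export
lattice_energy <- function(u_inter, e_mol_in_cryst, e_mol_min) {
  check_finite(u_inter, "u_inter")
  check_finite(e_mol_in_cryst, "e_mol_in_cryst")
  check_finite(e_mol_min, "e_mol_min")
  strain <- e_mol_in_cryst - e_mol_min
  if (any(strain < -0.01)) {
    abort_validation(
      "crystal conformer below claimed global minimum (strain %.4g kJ/mol)",
      min(strain))
  }
  strain <- pmax(strain, 0)
  tibble::tibble(u_inter = u_inter, e_mol_in_cryst = e_mol_in_cryst,
                 e_mol_min = e_mol_min, strain = strain,
                 e_latt = u_inter + strain)
}

#' Sublimation enthalpy in the 2RT approximation
#'
#' When the six intermolecular modes per molecule are classical harmonic
#' oscillators decoupled from the intramolecular vibrations, the
#' sublimation enthalpy reduces to `-E_latt - 2RT`.
#'
#' @param e_latt lattice energy, kJ/mol (negative for a bound crystal).
#' @param temperature temperature, K.
#' @return Sublimation enthalpy, kJ/mol.
#' @examples
#' dh_sub_2rt(-125.89)  # 120.93 kJ/mol at 298.15 K
#' @export
dh_sub_2rt <- function(e_latt, temperature = 298.15) {
  check_finite(e_latt, "e_latt")
  if (any(e_latt >= 0)) abort_domain("`e_latt` must be negative for a bound crystal")
  -e_latt - 2 * .rt_kj(temperature)
}

#' Sublimation enthalpy from the full harmonic route
#'
#' Beyond the 2RT approximation, the sublimation enthalpy is assembled
#' from the lattice energy and the harmonic thermal corrections on both
#' sides of the cycle:
#' `dH_sub = -E_latt + H_corr(gas) - [E_zpe(solid) + U_thermal(solid)]`.
#' The gas correction carries the ideal-gas pV term (+RT); the solid
#' carries none. When the intramolecular modes are identical in both
#' phases their contributions cancel and only the (six per molecule)
#' intermolecular phonons differentiate this from the 2RT result.
#'
#' @param e_latt lattice energy, kJ/mol.
#' @param gas gas-phase `thermal_corrections` (from [gas_thermo()]).
#' @param solid crystal `thermal_corrections` (from [gamma_point_thermo()]
#'   or [dos_thermo()]).
#' @return Sublimation enthalpy, kJ/mol.
#' @export
dh_sub_full <- function(e_latt, gas, solid) {
  check_finite(e_latt, "e_latt")
  if (abs(gas$temperature - solid$temperature) > 1e-9) {
    abort_validation("gas (%.6g K) and solid (%.6g K) corrections are at different temperatures",
                     gas$temperature, solid$temperature)
  }
  -e_latt + gas$h_corr - (solid$e_zpe + solid$u_thermal)
}

#' Sublimation free energy from enthalpy and the two entropies
#'
#' Combines a sublimation enthalpy with the gas and solid entropies to
#' obtain the sublimation free energy at the 1 atm gas standard state:
#' `TdS_sub = T (S_gas - S_solid)` and `dG_sub = dH_sub - TdS_sub`. The
#' diagnostic `dh_plus_e_latt = dH_sub + E_latt` is reported alongside;
#' its deviation from `-2RT` measures the failure of the 2RT
#' approximation.
#'
#' @param dh_sub sublimation enthalpy, kJ/mol.
#' @param gas,solid `thermal_corrections` with entropies (gas side at the
#'   1 atm standard state).
#' @param e_latt optional lattice energy for the diagnostic column.
#' @param molar_volume optional crystal molar volume, L/mol; when given,
#'   `dg_sub_star` (Ben-Naim convention) is also reported via
#'   [convert_std_to_star()].
#' @return A one-row tibble of class `sublimation_result` with columns
#'   `dh_sub`, `tds_sub`, `dg_sub_std`, `dg_sub_star` (NA unless
#'   `molar_volume` given), `dh_plus_e_latt`, `temperature`.
#' @examples
#' g <- gas_thermo(118.09, rotor = "nonlinear", rotational_constants = c(0.1, 0.07, 0.05))
#' s <- gamma_point_thermo(mode_spectrum(rep(50, 6), character = "intermolecular"))
#' dg_sub(dh_sub_full(-125.89, g, s), g, s, e_latt = -125.89)
#' @export
dg_sub <- function(dh_sub, gas, solid, e_latt = NA_real_, molar_volume = NULL) {
  t <- gas$temperature
  tds <- t * (gas$s - solid$s) / 1000
  dg_std <- dh_sub - tds
  dg_star <- if (is.null(molar_volume)) NA_real_ else
    convert_std_to_star(dg_std, molar_volume, t)
  out <- tibble::tibble(
    dh_sub = dh_sub, tds_sub = tds, dg_sub_std = dg_std,
    dg_sub_star = dg_star, dh_plus_e_latt = dh_sub + e_latt,
    temperature = t)
  class(out) <- c("sublimation_result", class(out))
  out
}

#' Standard-state conversion for sublimation free energies
#'
#' Converts a sublimation free energy from the 1 atm gas standard state to
#' the Ben-Naim convention (transfer at fixed center of mass, i.e. equal
#' number density), which depends on the crystal molar volume:
#' `dG* = dG_std - RT ln(p0 Vm / RT)`. At `Vm = RT/p0` (~24.46 L/mol at
#' 298.15 K) the two conventions coincide.
#'
#' @param dg_std free energy at the 1 atm standard state, kJ/mol.
#' @param molar_volume crystal molar volume, L/mol (> 0).
#' @param temperature temperature, K.
#' @return Free energy in the Ben-Naim convention, kJ/mol.
#' @examples
#' convert_std_to_star(51.54, 0.077)  # 65.82 kJ/mol
#' @export
convert_std_to_star <- function(dg_std, molar_volume, temperature = 298.15) {
  check_positive(molar_volume, "molar_volume")
  rt <- .const$R * temperature
  dg_std - .rt_kj(temperature) * log(.const$p0 * molar_volume * 1e-3 / rt)
}

#' @rdname convert_std_to_star
#' @param dg_star free energy in the Ben-Naim convention, kJ/mol.
#' @export
convert_star_to_std <- function(dg_star, molar_volume, temperature = 298.15) {
  check_positive(molar_volume, "molar_volume")
  rt <- .const$R * temperature
  dg_star + .rt_kj(temperature) * log(.const$p0 * molar_volume * 1e-3 / rt)
}
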