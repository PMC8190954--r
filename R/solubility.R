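#' Intrinsic solubility from the two legs of the cycle
#'
#' Combines a sublimation free energy at the 1 atm gas standard state
#' with a hydration free energy in the Ben-Naim convention into the
#' intrinsic aqueous solubility, without needing the crystal molar
#' volume:
#' `S0 = (p0/RT) exp(-(dG_sub_std + dG_hyd_star)/RT)` in mol/L.
#' The prefactor `p0/RT` is ~0.0409 mol/L at 298.15 K
#' (log10 ~ -1.3886). Activity coefficients are assumed unity.
#'
#' @param dg_sub_std sublimation free energy, 1 atm standard state, kJ/mol.
#' @param dg_hyd_star hydration free energy, Ben-Naim convention, kJ/mol.
#' @param temperature temperature, K.
#' @return log10 of the intrinsic solubility in mol/L; vectorized.
#' @examples
#' log_s0(51.54, -49.33)  # ~ -1.78
#' @export
log_s0 <- function(dg_sub_std, dg_hyd_star, temperature = 298.15) {
  check_positive(temperature, "temperature")
  rt <- .const$R * temperature
  log10(.const$p0 / (rt * 1000)) -
    (dg_sub_std + dg_hyd_star) * 1000 / (rt * log(10))
}

#' Intrinsic solubility via the molar-volume route
#'
#' Equivalent formulation using Ben-Naim free energies for both legs and
#' the crystal molar volume: `S0 = (1/Vm) exp(-(dG_sub_star +
#' dG_hyd_star)/RT)`. Identical to [log_s0()] whenever `dg_sub_star` was
#' obtained from the standard-state value by [convert_std_to_star()] with
#' the same molar volume.
#'
#' @param dg_sub_star sublimation free energy, Ben-Naim convention, kJ/mol.
#' @param dg_hyd_star hydration free energy, Ben-Naim convention, kJ/mol.
#' @param molar_volume crystal molar volume, L/mol.
#' @param temperature temperature, K.
#' @return log10 of the intrinsic solubility in mol/L.
#' @export
log_s0_vm <- function(dg_sub_star, dg_hyd_star, molar_volume,
                      temperature = 298.15) {
  check_positive(molar_volume, "molar_volume")
  rt <- .const$R * temperature
  -log10(molar_volume) - (dg_sub_star + dg_hyd_star) * 1000 / (rt * log(10))
}

#' Back-calculate a pseudo-experimental hydration free energy
#'
#' When an experimental solubility and sublimation enthalpy exist but no
#' measured hydration free energy, the cycle can be inverted: form the
#' pseudo-experimental `dG_sub = dH_sub_expt - TdS_sub_calc` (computed
#' entropy, measured enthalpy) and solve the solubility expression for
#' `dG_hyd*`.
#'
#' @param log_s0_expt experimental log10 solubility, mol/L.
#' @param dh_sub_expt experimental sublimation enthalpy, kJ/mol.
#' @param tds_sub_calc computed T*dS_sub, kJ/mol.
#' @param temperature temperature, K.
#' @return Pseudo-experimental hydration free energy, kJ/mol.
#' @examples
#' pseudo_experimental_dg_hyd(-9.33, 148.2, 64.46)  # ~ -38.4
#' @export
pseudo_experimental_dg_hyd <- function(log_s0_expt, dh_sub_expt, tds_sub_calc,
                                       temperature = 298.15) {
  check_finite(log_s0_expt, "log_s0_expt")
  rt <- .const$R * temperature
  dg_sub <- dh_sub_expt - tds_sub_calc
  -dg_sub - rt * log(10) / 1000 * (log_s0_expt - log10(.const$p0 / (rt * 1000)))
}

#' Fold error in solubility implied by a free-energy error
#'
#' A free-energy error `delta_g` propagates into a multiplicative
#' solubility error of `10^(|delta_g| / (RT ln 10))`.
#'
#' @param delta_g free-energy difference, kJ/mol.
#' @param temperature temperature, K.
#' @return Dimensionless fold factor (>= 1); vectorized.
#' @examples
#' fold_error(2.16)  # ~2.4-fold
#' @export
fold_error <- function(delta_g, temperature = 298.15) {
  check_finite(delta_g, "delta_g")
  10^(abs(delta_g) * 1000 / (.const$R * temperature * log(10)))
}

#' Assemble a solubility result from its legs
#'
#' @param dg_sub_std sublimation free energy (1 atm standard), kJ/mol.
#' @param dg_hyd_star hydration free energy (Ben-Naim), kJ/mol; vectorized
#'   over hydration models.
#' @param temperature temperature, K.
#' @param compound optional compound label.
#' @param sublimation_model,hydration_model optional method labels.
#' @param log_s0_expt optional experimental reference; when present the
#'   signed error `log_s0_expt - log_s0_calc` is reported (positive error
#'   = solubility underestimated).
#' @return A tibble of class `solubility_result` with one row per
#'   hydration model: `compound`, `sublimation_model`, `hydration_model`,
#'   `dg_sub_std`, `dg_hyd_star`, `dg_sol_star`, `log_s0_calc`,
#'   `log_s0_expt`, `error`, `temperature`.
#' @examples
#' solubility_result(51.54, c(-49.33, -57.47), compound = "succinic acid",
#'                   hydration_model = c("SMD", "FEP"), log_s0_expt = -0.22)
#' @export
solubility_result <- function(dg_sub_std, dg_hyd_star, temperature = 298.15,
                              compound = NA_character_,
                              sublimation_model = NA_character_,
                              hydration_model = NA_character_,
                              log_s0_expt = NA_real_) {
  ls0 <- log_s0(dg_sub_std, dg_hyd_star, temperature)
  out <- tibble::tibble(
    compound = compound,
    sublimation_model = sublimation_model,
    hydration_model = hydration_model,
    dg_sub_std = dg_sub_std,
    dg_hyd_star = dg_hyd_star,
    dg_sol_star = dg_sub_std + dg_hyd_star,
    log_s0_calc = ls0,
    log_s0_expt = log_s0_expt,
    error = log_s0_expt - ls0,
    temperature = temperature)
  class(out) <- c("solubility_result", class(out))
  out
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Report-layer rounding of a solubility table
#'
#' Full precision is kept internally; only the report rounds, half-up, to
#' 2 decimals.
#'
#' @param result a `solubility_result` tibble.
#' @param digits decimal places.
#' @return The tibble with numeric solubility columns rounded.
#' @export
format_solubility <- function(result, digits = 2) {
  dplyr::mutate(result, dplyr::across(
    dplyr::any_of(c("log_s0_calc", "log_s0_expt", "error")),
    ~ round_half_up(.x, digits)))
}
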