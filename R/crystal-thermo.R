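#' Build and validate a phonon density of states
#'
#' A phonon DOS tabulates modes per cm^-1 per molecule on an ascending
#' frequency grid. Its trapezoidal integral must equal the declared total
#' mode count within 0.5%, which guards against mis-normalized inputs.
#'
#' @param frequency ascending grid of frequencies, cm^-1 (non-negative).
#' @param density modes per cm^-1 per molecule, >= 0.
#' @param modes_total expected integral of `density` (modes per molecule).
#' @return A tibble with columns `frequency`, `density`, classed
#'   `phonon_dos`, with attribute `modes_total`.
#' @seealso [dos_thermo()], [read_dos_csv()]
#' @export
phonon_dos <- function(frequency, density, modes_total) {
  frequency <- parse_numeric(frequency)
  density <- parse_numeric(density)
  if (length(frequency) != length(density) || length(frequency) < 2) {
    abort_validation("DOS grid and density must have equal length >= 2")
  }
  if (any(diff(frequency) <= 0)) abort_validation("DOS grid must be strictly ascending")
  if (any(density < 0) || any(!is.finite(density))) {
    abort_validation("DOS density must be finite and >= 0")
  }
  integral <- trapz(frequency, density)
  if (modes_total > 0 && abs(integral - modes_total) > 0.005 * modes_total) {
    abort_validation(
      "DOS integral %.6g differs from declared modes_total %.6g by more than 0.5%%",
      integral, modes_total)
  }
  if (modes_total == 0 && integral > 1e-12) {
    abort_validation("modes_total = 0 but DOS integrates to %.3g", integral)
  }
  out <- tibble::tibble(frequency = frequency, density = density)
  attr(out, "modes_total") <- modes_total
  class(out) <- c("phonon_dos", class(out))
  out
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Crystal thermal corrections by phonon-DOS integration
#'
#' Integrates the per-mode harmonic quantities of [mode_thermo()] against
#' the density of states by trapezoidal quadrature on the supplied grid
#' (no re-gridding). Results are per molecule of the crystal; no pV term.
#' Grid points below 0.01 cm^-1 are dropped (acoustic guard).
#'
#' @param dos a [phonon_dos()].
#' @param temperature temperature, K.
#' @return A one-row `thermal_corrections` tibble.
#' @examples
#' # Debye-like quadratic DOS with 6 modes up to 100 cm^-1
#' g <- phonon_dos(seq(0, 100, 0.1), 3 * 6 * seq(0, 100, 0.1)^2 / 100^3, 6)
#' dos_thermo(g, 298.15)
#' @export
dos_thermo <- function(dos, temperature = 298.15) {
  keep <- dos$frequency >= 0.01
  f <- dos$frequency[keep]
  g <- dos$density[keep]
  if (length(f) < 2 || all(g == 0)) {
    return(new_thermal_corrections(0, 0, 0, temperature))
  }
  per <- mode_thermo(f, temperature)
  new_thermal_corrections(
    e_zpe = trapz(f, g * per$zpe),
    u_thermal = trapz(f, g * per$u_thermal),
    s = trapz(f, g * per$s),
    temperature = temperature)
}

#' Crystal thermal corrections from Gamma-point modes
#'
#' Sums all non-acoustic modes of a crystal Gamma-point spectrum
#' (phonon dispersion across the Brillouin zone is ignored) and divides by
#' the number of molecules in the cell, reporting per-molecule
#' corrections.
#'
#' @param spectrum a crystal [mode_spectrum()] whose
#'   `molecules_per_cell` attribute is Z.
#' @param temperature temperature, K.
#' @param characters mode characters to include (default all non-acoustic).
#' @return A one-row `thermal_corrections` tibble (per molecule).
#' @export
gamma_point_thermo <- function(spectrum, temperature = 298.15,
                               characters = c("intermolecular", "intramolecular")) {
  z <- attr(spectrum, "molecules_per_cell")
  if (is.null(z)) z <- 1L
  if (z < 1) abort_config("`molecules_per_cell` must be >= 1")
  res <- spectrum_thermo(spectrum, temperature, characters = characters)
  new_thermal_corrections(
    e_zpe = res$e_zpe / z,
    u_thermal = res$u_thermal / z,
    s = res$s / z,
    temperature = temperature)
}

#' Read a phonon DOS from CSV
#'
#' Expects columns `frequency_cm1`, `density` with a one-line header.
#'
#' @param path file path.
#' @param modes_total declared integral; if `NULL` the trapezoidal
#'   integral of the table is used (validation then trivially passes).
#' @return A `phonon_dos` tibble.
#' @export
read_dos_csv <- function(path, modes_total = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("frequency_cm1", "density")
  if (!all(need %in% names(df))) {
    abort_config("DOS CSV %s must have columns %s", path, paste(need, collapse = ", "))
  }
  f <- parse_numeric(df$frequency_cm1)
  g <- parse_numeric(df$density)
  if (is.null(modes_total)) modes_total <- trapz(f, g)
  phonon_dos(f, g, modes_total)
}
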