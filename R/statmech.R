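#' Per-mode quantum harmonic-oscillator thermochemistry
#'
#' Evaluates the textbook quantum harmonic-oscillator contributions of a
#' vibrational mode of frequency nu (cm^-1) at temperature T. With
#' x = h*c*nu/(kB*T):
#' \itemize{
#'   \item zero-point energy: zpe = (1/2) h c NA nu
#'   \item thermal internal energy above ZPE: u = RT x / (e^x - 1)
#'   \item entropy: s = R \[x/(e^x - 1) - ln(1 - e^-x)\]
#'   \item Helmholtz correction: a = zpe + u - T s
#' }
#' In the classical (low-frequency) limit u -> RT and in the stiff-mode
#' limit u, s -> 0.
#'
#' @param frequency mode frequency in cm^-1, strictly positive; vectorized.
#' @param temperature temperature in K, strictly positive scalar.
#' @return A tibble with one row per frequency and columns `frequency`
#'   (cm^-1), `zpe`, `u_thermal`, `a` (kJ/mol) and `s` (J/(mol K)).
#' @examples
#' mode_thermo(100, 298.15)
#' @export
mode_thermo <- function(frequency, temperature = 298.15) {
  check_positive(frequency, "frequency")
  check_positive(temperature, "temperature")
  stopifnot(length(temperature) == 1L)

  x <- .const$hcNA * frequency / (.const$R * temperature)
  zpe <- 0.5 * .const$hcNA * frequency / 1000
  u <- .const$R * temperature * x / expm1(x) / 1000
  s <- .const$R * (x / expm1(x) - log1p(-exp(-x)))
  tibble::tibble(frequency = frequency, zpe = zpe, u_thermal = u,
                 s = s, a = zpe + u - temperature * s / 1000)
}

# assemble a thermal-corrections row; condensed phase carries no pV term
new_thermal_corrections <- function(e_zpe, u_thermal, s, temperature,
                                    h_corr = e_zpe + u_thermal,
                                    a_corr = e_zpe + u_thermal - temperature * s / 1000,
                                    phase = "condensed") {
  out <- tibble::tibble(
    e_zpe = e_zpe, u_thermal = u_thermal, h_corr = h_corr,
    s = s, a_corr = a_corr, temperature = temperature, phase = phase)
  class(out) <- c("thermal_corrections", class(out))
  out
}

#' Thermal corrections from a discrete mode spectrum
#'
#' Weighted sum of [mode_thermo()] over the spectrum entries whose
#' character is within `characters`. Acoustic entries are always excluded.
#' For a condensed phase no pV term applies, so the enthalpy correction is
#' `e_zpe + u_thermal`.
#'
#' @param spectrum a [mode_spectrum()] tibble (or data frame with columns
#'   `frequency`, `weight`, `character`).
#' @param temperature temperature in K.
#' @param characters mode characters to include; default both
#'   intermolecular and intramolecular.
#' @return A one-row `thermal_corrections` tibble with columns `e_zpe`,
#'   `u_thermal`, `h_corr`, `a_corr` (kJ/mol), `s` (J/(mol K)),
#'   `temperature` (K) and `phase`.
#' @details An empty selection (no mode matches `characters`) yields
#'   all-zero corrections with a warning rather than an error, so that
#'   e.g. an atom with no vibrations is handled gracefully.
#' @examples
#' sp <- mode_spectrum(rep(50, 6), character = "intermolecular")
#' spectrum_thermo(sp, 298.15, characters = "intermolecular")
#' @export
spectrum_thermo <- function(spectrum, temperature = 298.15,
                            characters = c("intermolecular", "intramolecular")) {
  if (length(characters) == 0) abort_config("`characters` must be non-empty")
  characters <- setdiff(characters, "acoustic")
  sel <- spectrum$character %in% characters & spectrum$character != "acoustic"
  if (!any(sel)) {
    warning("no modes selected; returning zero thermal corrections", call. = FALSE)
    return(new_thermal_corrections(0, 0, 0, temperature))
  }
  per <- mode_thermo(spectrum$frequency[sel], temperature)
  w <- spectrum$weight[sel]
  new_thermal_corrections(
    e_zpe = sum(w * per$zpe),
    u_thermal = sum(w * per$u_thermal),
    s = sum(w * per$s),
    temperature = temperature)
}

#' Ideal-gas thermal corrections (rigid rotor / harmonic oscillator)
#'
#' Standard RRHO gas-phase thermal analysis: translational contributions
#' from the Sackur-Tetrode equation at pressure `pressure`, rotational
#' contributions from the classical rigid rotor with symmetry number
#' `symmetry_number`, and vibrational contributions from the harmonic
#' modes in `spectrum`. The enthalpy correction carries the ideal-gas pV
#' term (+RT); the Helmholtz correction is `h_corr - RT - T*s`.
#'
#' @param mass molecular mass in amu.
#' @param rotor one of `"nonlinear"`, `"linear"`, `"atom"`.
#' @param rotational_constants rotational constants in cm^-1: three values
#'   for a nonlinear top, one for a linear rotor, ignored for an atom.
#' @param spectrum optional [mode_spectrum()] of the molecule's vibrations
#'   (all non-acoustic modes are used); `NULL` means no vibrations.
#' @param temperature temperature, K.
#' @param pressure pressure defining the translational standard state, Pa
#'   (default 1 atm).
#' @param symmetry_number rotational symmetry number (default 1; the
#'   external rotational symmetry is often unknown for drug-like
#'   molecules, and 1 is the conservative choice).
#' @return A one-row `thermal_corrections` tibble (phase `"gas"`).
#' @examples
#' # argon: translation only
#' gas_thermo(39.948, rotor = "atom")
#' @export
gas_thermo <- function(mass, rotor = c("nonlinear", "linear", "atom"),
                       rotational_constants = NULL, spectrum = NULL,
                       temperature = 298.15, pressure = 101325,
                       symmetry_number = 1) {
  rotor <- match.arg(rotor)
  check_positive(mass, "mass")
  check_positive(temperature, "temperature")
  check_positive(pressure, "pressure")
  kB <- .const$kB; h <- .const$h; R <- .const$R
  rt_kj <- .rt_kj(temperature)

  # translation: Sackur-Tetrode at the requested pressure
  m_kg <- mass * 1e-3 / .const$na
  lambda3 <- (h^2 / (2 * pi * m_kg * kB * temperature))^1.5
  s_trans <- R * (log(kB * temperature / (pressure * lambda3)) + 2.5)
  u_trans <- 1.5 * rt_kj

  # rotation: classical rigid rotor
  if (rotor == "atom") {
    s_rot <- 0; u_rot <- 0
  } else {
    if (is.null(rotational_constants) || any(rotational_constants <= 0)) {
      abort_config("rotor `%s` requires positive rotational constants (cm^-1)", rotor)
    }
    theta <- .const$hcNA * rotational_constants / .const$R  # K per constant
    if (rotor == "linear") {
      q_rot <- temperature / (symmetry_number * theta[1])
      s_rot <- R * (log(q_rot) + 1)
      u_rot <- rt_kj
    } else {
      if (length(theta) != 3) {
        abort_config("nonlinear rotor requires three rotational constants")
      }
      q_rot <- sqrt(pi) / symmetry_number * temperature^1.5 / sqrt(prod(theta))
      s_rot <- R * (log(q_rot) + 1.5)
      u_rot <- 1.5 * rt_kj
    }
  }

  # vibration
  if (is.null(spectrum) || nrow(spectrum) == 0) {
    vib <- new_thermal_corrections(0, 0, 0, temperature)
  } else {
    vib <- suppressWarnings(
      spectrum_thermo(spectrum, temperature,
                      characters = c("intermolecular", "intramolecular")))
  }

  s_total <- s_trans + s_rot + vib$s
  h_corr <- vib$e_zpe + vib$u_thermal + u_trans + u_rot + rt_kj
  new_thermal_corrections(
    e_zpe = vib$e_zpe,
    u_thermal = vib$u_thermal + u_trans + u_rot,
    s = s_total,
    temperature = temperature,
    h_corr = h_corr,
    a_corr = h_corr - rt_kj - temperature * s_total / 1000,
    phase = "gas")
}
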