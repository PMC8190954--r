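#' Physical constants used throughout the package
#'
#' CODATA 2018 values. Energies are handled internally in kJ/mol and
#' entropies in J/(mol K); unit conversion happens only at I/O boundaries.
#' The gas-phase standard state is 1 atm (101325 Pa exactly), and the
#' default temperature is 298.15 K.
#'
#' @return A named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, J/K.}
#'   \item{h}{Planck constant, J s.}
#'   \item{c}{speed of light, cm/s (so that frequencies in cm^-1 give
#'     energies directly via h*c*nu).}
#'   \item{NA}{Avogadro number, 1/mol.}
#'   \item{R}{molar gas constant, J/(mol K), equal to kB*NA.}
#'   \item{hcNA}{h*c*NA, J/mol per cm^-1 (~11.9627).}
#'   \item{p0}{standard pressure, Pa (1 atm).}
#'   \item{T_default}{default temperature, K.}
#' }
#' @examples
#' thermo_constants()$R
#' @export
thermo_constants <- function() {
  kB <- 1.380649e-23
  h  <- 6.62607015e-34
  cc <- 2.99792458e10
  na <- 6.02214076e23
  list(
    kB = kB, h = h, c = cc, `NA` = na,
    R = kB * na,
    hcNA = h * cc * na,
    p0 = 101325,
    T_default = 298.15
  )
}

# internal shorthand; evaluated once at build time
.const <- local({
  kB <- 1.380649e-23
  h  <- 6.62607015e-34
  cc <- 2.99792458e10
  na <- 6.02214076e23
  list(kB = kB, h = h, c = cc, na = na, R = kB * na, hcNA = h * cc * na,
       p0 = 101325, T_default = 298.15)
})

# RT in kJ/mol at temperature T
.rt_kj <- function(temperature) .const$R * temperature / 1000
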