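#' Build and validate a harmonic mode spectrum
#'
#' A mode spectrum is a tidy table of discrete harmonic frequencies with
#' multiplicities and a character label distinguishing intermolecular
#' (lattice/phonon) modes from intramolecular vibrations. Acoustic modes
#' (the three zero-frequency translations of a crystal) are never carried
#' as finite-frequency entries: frequencies below 0.01 cm^-1 are relabelled
#' acoustic and excluded from thermodynamic sums, with a warning.
#'
#' @param frequency numeric, mode frequencies in cm^-1 (strictly positive;
#'   imaginary modes, encoded as negative numbers, are rejected).
#' @param weight numeric multiplicity of each mode (>= 0). Defaults to 1.
#' @param character one of `"intermolecular"`, `"intramolecular"`,
#'   `"acoustic"` per mode. Defaults to `"intramolecular"`.
#' @param molecules_per_cell positive integer Z, the number of molecules in
#'   the crystallographic cell the spectrum describes (1 for a gas-phase
#'   molecule).
#' @param n_atoms optional atom count per molecule; when supplied for a
#'   crystal spectrum the total non-acoustic weight is checked against
#'   3*N*Z - 3 and a warning (not an error) is raised on mismatch, since
#'   supercell conventions vary.
#' @return A tibble with columns `frequency`, `weight`, `character` and
#'   attributes `molecules_per_cell`, classed `mode_spectrum`.
#' @examples
#' mode_spectrum(c(50, 60, 1500), character = c(
#'   "intermolecular", "intermolecular", "intramolecular"
#' ))
#' @seealso [spectrum_thermo()], [gamma_point_thermo()], [read_spectrum_csv()]
#' @export
mode_spectrum <- function(frequency, weight = 1,
                          character = "intramolecular",
                          molecules_per_cell = 1L,
                          n_atoms = NULL) {
  frequency <- parse_numeric(frequency)
  weight <- rep_len(parse_numeric(weight), length(frequency))
  character <- rep_len(as.character(character), length(frequency))

  if (any(!is.finite(frequency)) || any(frequency <= 0)) {
    bad <- frequency[!is.finite(frequency) | frequency <= 0][1]
    abort_validation(
      "mode frequencies must be strictly positive (imaginary modes not allowed); got %s cm^-1",
      format(bad))
  }
  if (any(!is.finite(weight)) || any(weight < 0)) {
    abort_validation("mode weights must be finite and >= 0")
  }
  ok <- c("intermolecular", "intramolecular", "acoustic")
  if (!all(character %in% ok)) {
    abort_validation("mode character must be one of %s", paste(ok, collapse = ", "))
  }
  if (length(molecules_per_cell) != 1L || !is.finite(molecules_per_cell) ||
      molecules_per_cell < 1) {
    abort_config("`molecules_per_cell` must be a positive integer")
  }

  # numerical zero-mode guard: near-zero frequencies are acoustic
  low <- frequency < 0.01
  if (any(low & character != "acoustic")) {
    warning(sprintf(
      "%d mode(s) below 0.01 cm^-1 treated as acoustic and excluded from thermodynamic sums",
      sum(low & character != "acoustic")), call. = FALSE)
    character[low] <- "acoustic"
  }

  spec <- tibble::tibble(frequency = frequency, weight = weight,
                         character = character)
  attr(spec, "molecules_per_cell") <- as.integer(molecules_per_cell)
  class(spec) <- c("mode_spectrum", class(spec))

  if (!is.null(n_atoms)) {
    expected <- 3 * n_atoms * molecules_per_cell - 3
    total <- sum(spec$weight[spec$character != "acoustic"])
    if (abs(total - expected) > 1e-6) {
      warning(sprintf(
        "non-acoustic mode weight %.6g differs from expected 3*N*Z - 3 = %g",
        total, expected), call. = FALSE)
    }
  }
  spec
}

#' @export
print.mode_spectrum <- function(x, ...) {
  z <- attr(x, "molecules_per_cell")
  cat(sprintf("<mode_spectrum: %d entries, total weight %.6g, Z = %d>\n",
              nrow(x), sum(x$weight), z))
  NextMethod()
}

#' Read a mode spectrum from CSV
#'
#' Expects columns `frequency_cm1`, `weight`, `character` with a one-line
#' header. Unicode minus signs in pasted tables are normalized before
#' parsing.
#'
#' @param path file path.
#' @param molecules_per_cell,n_atoms passed to [mode_spectrum()].
#' @return A `mode_spectrum` tibble.
#' @export
read_spectrum_csv <- function(path, molecules_per_cell = 1L, n_atoms = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("frequency_cm1", "weight", "character")
  if (!all(need %in% names(df))) {
    abort_config("spectrum CSV %s must have columns %s", path,
                 paste(need, collapse = ", "))
  }
  mode_spectrum(parse_numeric(df$frequency_cm1), parse_numeric(df$weight),
                df$character, molecules_per_cell = molecules_per_cell,
                n_atoms = n_atoms)
}

#' Write a mode spectrum to CSV
#'
#' Inverse of [read_spectrum_csv()].
#'
#' @param spectrum a `mode_spectrum`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  readr::write_csv(
    tibble::tibble(frequency_cm1 = spectrum$frequency,
                   weight = spectrum$weight,
                   character = spectrum$character),
    path)
  invisible(path)
}
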