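#' Load and validate a compound configuration
#'
#' A compound config (YAML or JSON) describes one solute: a name, a
#' temperature, exactly one sublimation route, one or more hydration
#' routes, and optional experimental references. Sublimation routes:
#' \itemize{
#'   \item direct: `dh_sub` + `tds_sub` (kJ/mol), or `dg_sub_std` alone;
#'   \item spectra: lattice components (`lattice: {u_inter,
#'     e_mol_in_cryst, e_mol_min}` or a bare `e_latt`) together with a
#'     `gas` block (`mass`, `rotor`, `rotational_constants`,
#'     `symmetry_number`, `spectrum_csv`) and a `solid` block
#'     (`spectrum_csv` + `molecules_per_cell`, or `dos_csv` +
#'     `modes_total`).
#' }
#' Each hydration entry has a `model` label and either a direct `dg_hyd`
#' (kJ/mol), a conformer route (`conformers_csv`, `scheme`,
#' `gas_reference_id`), or a FEP route (`fep_csv`, `coupled_at`).
#' Unknown keys are rejected (strict mode) so typos cannot silently drop
#' a setting; relative file paths resolve against the config directory.
#'
#' @param path path to a YAML or JSON config file.
#' @param strict reject unknown keys (default TRUE).
#' @return A validated config list of class `compound_config`.
#' @seealso [run_pipeline()]
#' @export
load_config <- function(path, strict = TRUE) {
  if (!file.exists(path)) abort_config("config file not found: %s", path)
  txt <- readLines(path, warn = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(paste(txt, collapse = "\n"), simplifyDataFrame = FALSE)
  } else {
    yaml::yaml.load(paste(normalize_minus(txt), collapse = "\n"))
  }
  cfg$.dir <- dirname(normalizePath(path))
  cfg$.path <- path
  validate_config(cfg, strict = strict)
}

known_keys <- list(
  top = c("name", "temperature", "sublimation", "hydration", "experimental",
          ".dir", ".path"),
  sublimation = c("dh_sub", "tds_sub", "dg_sub_std", "e_latt", "lattice",
                  "gas", "solid", "molar_volume"),
  lattice = c("u_inter", "e_mol_in_cryst", "e_mol_min"),
  gas = c("mass", "rotor", "rotational_constants", "symmetry_number",
          "spectrum_csv"),
  solid = c("spectrum_csv", "molecules_per_cell", "n_atoms", "dos_csv",
            "modes_total"),
  hydration = c("model", "dg_hyd", "conformers_csv", "scheme",
                "gas_reference_id", "fep_csv", "coupled_at"),
  experimental = c("log_s0", "dh_sub", "dg_hyd"))

check_keys <- function(x, where, strict) {
  extra <- setdiff(names(x), known_keys[[where]])
  if (strict && length(extra)) {
    abort_config("unknown key(s) under `%s`: %s", where,
                 paste(extra, collapse = ", "))
  }
}

#' @rdname load_config
#' @param cfg a config list (as parsed from YAML/JSON).
#' @export
validate_config <- function(cfg, strict = TRUE) {
  check_keys(cfg, "top", strict)
  if (is.null(cfg$name)) abort_config("config requires `name`")
  if (is.null(cfg$temperature)) cfg$temperature <- .const$T_default
  cfg$temperature <- parse_numeric(cfg$temperature)
  check_positive(cfg$temperature, "temperature")

  sub <- cfg$sublimation
  if (is.null(sub)) abort_config("config requires a `sublimation` block")
  check_keys(sub, "sublimation", strict)
  if (!is.null(sub$lattice)) check_keys(sub$lattice, "lattice", strict)
  if (!is.null(sub$gas)) check_keys(sub$gas, "gas", strict)
  if (!is.null(sub$solid)) check_keys(sub$solid, "solid", strict)
  routes <- c(
    direct_dh = !is.null(sub$dh_sub) || !is.null(sub$tds_sub),
    direct_dg = !is.null(sub$dg_sub_std),
    spectra = !is.null(sub$e_latt) || !is.null(sub$lattice) ||
      !is.null(sub$gas) || !is.null(sub$solid))
  if (sum(routes) != 1) {
    abort_config(
      "exactly one sublimation route required; found: %s",
      if (any(routes)) paste(names(routes)[routes], collapse = ", ") else "none")
  }
  if (routes[["direct_dh"]] && (is.null(sub$dh_sub) || is.null(sub$tds_sub))) {
    abort_config("direct sublimation route needs both `dh_sub` and `tds_sub`")
  }
  if (routes[["spectra"]]) {
    if (is.null(sub$e_latt) && is.null(sub$lattice)) {
      abort_config("spectra route needs `e_latt` or a `lattice` block")
    }
    if (is.null(sub$gas) || is.null(sub$solid)) {
      abort_config("spectra route needs `gas` and `solid` blocks")
    }
  }
  cfg$sublimation_route <- names(routes)[routes]

  hyd <- cfg$hydration
  if (is.null(hyd) || length(hyd) == 0) {
    abort_config("config requires at least one `hydration` entry")
  }
  if (!is.null(names(hyd))) hyd <- list(hyd)  # single unnamed-list entry
  for (i in seq_along(hyd)) {
    h <- hyd[[i]]
    check_keys(h, "hydration", strict)
    nr <- sum(!is.null(h$dg_hyd), !is.null(h$conformers_csv), !is.null(h$fep_csv))
    if (nr != 1) {
      abort_config("hydration entry %d must give exactly one of `dg_hyd`, `conformers_csv`, `fep_csv`", i)
    }
    if (is.null(h$model)) hyd[[i]]$model <- sprintf("hydration_%d", i)
  }
  cfg$hydration <- hyd
  if (!is.null(cfg$experimental)) check_keys(cfg$experimental, "experimental", strict)
  class(cfg) <- "compound_config"
  cfg
}

#' Serialize a config back to YAML
#'
#' @param cfg a `compound_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  drop <- c(".dir", ".path", "sublimation_route")
  x <- unclass(cfg)[setdiff(names(cfg), drop)]
  writeLines(yaml::as.yaml(x), path)
  invisible(path)
}

resolve_path <- function(p, dir) {
  if (is.null(dir) || grepl("^(/|[A-Za-z]:)", p)) p else file.path(dir, p)
}

sublimation_leg <- function(cfg) {
  sub <- cfg$sublimation
  t <- cfg$temperature
  if (cfg$sublimation_route == "direct_dg") {
    return(tibble::tibble(dh_sub = NA_real_, tds_sub = NA_real_,
                          dg_sub_std = parse_numeric(sub$dg_sub_std),
                          dh_plus_e_latt = NA_real_, route = "direct_dg"))
  }
  if (cfg$sublimation_route == "direct_dh") {
    dh <- parse_numeric(sub$dh_sub); tds <- parse_numeric(sub$tds_sub)
    return(tibble::tibble(dh_sub = dh, tds_sub = tds, dg_sub_std = dh - tds,
                          dh_plus_e_latt = NA_real_, route = "direct_dh"))
  }
  # spectra route
  e_latt <- if (!is.null(sub$e_latt)) parse_numeric(sub$e_latt) else {
    lat <- sub$lattice
    lattice_energy(parse_numeric(lat$u_inter),
                   parse_numeric(lat$e_mol_in_cryst),
                   parse_numeric(lat$e_mol_min))$e_latt
  }
  g <- sub$gas
  gas_spec <- if (!is.null(g$spectrum_csv)) {
    read_spectrum_csv(resolve_path(g$spectrum_csv, cfg$.dir))
  } else NULL
  gas <- gas_thermo(
    mass = parse_numeric(g$mass),
    rotor = if (is.null(g$rotor)) "nonlinear" else g$rotor,
    rotational_constants = parse_numeric(unlist(g$rotational_constants)),
    spectrum = gas_spec, temperature = t,
    symmetry_number = if (is.null(g$symmetry_number)) 1 else parse_numeric(g$symmetry_number))
  s <- sub$solid
  solid <- if (!is.null(s$dos_csv)) {
    dos_thermo(read_dos_csv(resolve_path(s$dos_csv, cfg$.dir),
                            modes_total = s$modes_total), t)
  } else {
    z <- if (is.null(s$molecules_per_cell)) 1L else as.integer(s$molecules_per_cell)
    gamma_point_thermo(
      read_spectrum_csv(resolve_path(s$spectrum_csv, cfg$.dir),
                        molecules_per_cell = z, n_atoms = s$n_atoms), t)
  }
  dh <- dh_sub_full(e_latt, gas, solid)
  res <- dg_sub(dh, gas, solid, e_latt = e_latt)
  tibble::tibble(dh_sub = res$dh_sub, tds_sub = res$tds_sub,
                 dg_sub_std = res$dg_sub_std,
                 dh_plus_e_latt = res$dh_plus_e_latt, route = "spectra")
}

hydration_leg <- function(h, cfg) {
  t <- cfg$temperature
  if (!is.null(h$dg_hyd)) {
    return(tibble::tibble(model = h$model, dg_hyd = parse_numeric(h$dg_hyd),
                          stderr = NA_real_, route = "direct"))
  }
  if (!is.null(h$conformers_csv)) {
    conf <- read_conformers_csv(resolve_path(h$conformers_csv, cfg$.dir))
    dg <- hydration_sfe(conf,
                        scheme = if (is.null(h$scheme)) "SFE2" else h$scheme,
                        gas_reference_id = h$gas_reference_id,
                        temperature = t)
    return(tibble::tibble(model = h$model, dg_hyd = dg, stderr = NA_real_,
                          route = "conformers"))
  }
  fep <- read_fep_csv(resolve_path(h$fep_csv, cfg$.dir))
  res <- fep_total(fep, temperature = t,
                   coupled_at = if (is.null(h$coupled_at)) "lambda0" else h$coupled_at)
  tibble::tibble(model = h$model, dg_hyd = res$dg_hyd, stderr = res$stderr,
                 route = "fep")
}

#' Run the full solubility pipeline for one compound
#'
#' Evaluates the sublimation leg (direct values or the full spectral
#' route), every configured hydration leg, and combines them into
#' log S0. Deterministic given the config and input files; the returned
#' tibble carries provenance (input-file hashes) as an attribute so that
#' reports are reproducible.
#'
#' @param cfg a `compound_config` from [load_config()], or a path to one.
#' @return A `solubility_result` tibble, one row per hydration model,
#'   with extra columns `dh_sub`, `tds_sub`, `dg_hyd_stderr` and
#'   attribute `provenance`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  stopifnot(inherits(cfg, "compound_config"))
  sub <- sublimation_leg(cfg)
  hyd <- purrr::map(cfg$hydration, hydration_leg, cfg = cfg) |>
    purrr::list_rbind()
  expt <- cfg$experimental
  out <- solubility_result(
    dg_sub_std = sub$dg_sub_std,
    dg_hyd_star = hyd$dg_hyd,
    temperature = cfg$temperature,
    compound = cfg$name,
    sublimation_model = sub$route,
    hydration_model = hyd$model,
    log_s0_expt = if (!is.null(expt$log_s0)) parse_numeric(expt$log_s0) else NA_real_)
  out$dh_sub <- sub$dh_sub
  out$tds_sub <- sub$tds_sub
  out$dg_hyd_stderr <- hyd$stderr
  attr(out, "provenance") <- pipeline_provenance(cfg)
  out
}

pipeline_provenance <- function(cfg) {
  files <- character()
  s <- cfg$sublimation
  for (p in c(s$gas$spectrum_csv, s$solid$spectrum_csv, s$solid$dos_csv)) {
    files <- c(files, resolve_path(p, cfg$.dir))
  }
  for (h in cfg$hydration) {
    for (p in c(h$conformers_csv, h$fep_csv)) {
      files <- c(files, resolve_path(p, cfg$.dir))
    }
  }
  list(config = cfg$.path,
       input_md5 = if (length(files)) as.list(tools::md5sum(files)) else list(),
       constants = "CODATA 2018",
       package_version = as.character(utils::packageVersion("solcycle")))
}

#' Write a per-compound JSON report
#'
#' Includes legs, per-model log S0, errors against any experimental
#' reference, and provenance. Repeated runs on identical inputs give
#' byte-identical files.
#'
#' @param result a `solubility_result` from [run_pipeline()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  payload <- list(
    compound = result$compound[1],
    temperature = result$temperature[1],
    models = lapply(seq_len(nrow(result)), function(i) {
      r <- as.list(result[i, setdiff(names(result), c("compound", "temperature"))])
      r[!vapply(r, function(x) is.na(x) %in% TRUE, logical(1))]
    }),
    provenance = attr(result, "provenance"))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(path)
}

#' Merge per-compound JSON reports into a summary table
#'
#' @param paths character vector of JSON report paths.
#' @return A tibble with one row per compound x hydration model.
#' @export
merge_reports <- function(paths) {
  purrr::map(paths, function(p) {
    rep <- jsonlite::fromJSON(p, simplifyDataFrame = FALSE)
    purrr::map(rep$models, function(m) {
      tibble::tibble(
        compound = rep$compound,
        hydration_model = m$hydration_model,
        dg_sub_std = m$dg_sub_std,
        dg_hyd_star = m$dg_hyd_star,
        log_s0_calc = m$log_s0_calc,
        log_s0_expt = m$log_s0_expt %||% NA_real_,
        error = m$error %||% NA_real_)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
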