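# Seeded synthetic-fixture generators. Every generator records a ground
# truth computed by a direct analytic path (plain formula sums written out
# locally) that is independent of the production functions it is used to
# test. Same seed + parameters => identical output, byte for byte.

# direct per-mode harmonic sums, kept deliberately separate from mode_thermo()
direct_mode_sums <- function(freq, weight, temperature) {
  hcna <- 6.62607015e-34 * 2.99792458e10 * 6.02214076e23
  r <- 1.380649e-23 * 6.02214076e23
  x <- hcna * freq / (r * temperature)
  list(
    zpe = sum(weight * 0.5 * hcna * freq) / 1000,
    u = sum(weight * r * temperature * x / (exp(x) - 1)) / 1000,
    s = sum(weight * r * (x / (exp(x) - 1) - log(1 - exp(-x)))))
}

#' Generate a synthetic crystal mode spectrum with known ground truth
#'
#' Emits `6 * z` intermolecular modes drawn uniformly from a frequency
#' band (default 20-150 cm^-1, straddling the classical/quantum crossover
#' at room temperature where the 2RT approximation starts to fail), plus
#' the intramolecular modes of a supplied gas spectrum copied into the
#' crystal, optionally perturbed. The attached ground truth is computed
#' by a direct analytic mode sum independent of the package's production
#' thermochemistry functions.
#'
#' @param seed integer seed.
#' @param z molecules per cell.
#' @param band intermolecular frequency band, cm^-1, length 2 ascending.
#' @param gas_spectrum optional gas-phase [mode_spectrum()] whose modes
#'   are copied as the crystal's intramolecular modes.
#' @param perturbation sd (cm^-1) of Gaussian noise added to the copied
#'   intramolecular modes (0 = exact copy, so intramolecular
#'   contributions cancel in the enthalpy assembly by construction).
#' @param temperature temperature for the recorded ground truth, K.
#' @return A list with elements `spectrum` (crystal `mode_spectrum`),
#'   `gas_spectrum`, and `ground_truth` (per-molecule intermolecular
#'   zpe/u/s from the direct sum, kJ/mol and J/(mol K)).
#' @export
gen_crystal_spectrum <- function(seed, z = 1L, band = c(20, 150),
                                 gas_spectrum = NULL, perturbation = 0,
                                 temperature = 298.15) {
  if (band[1] >= band[2]) abort_config("frequency band bounds inverted")
  set.seed(seed)
  inter <- sort(stats::runif(6 * z, band[1], band[2]))
  intra_f <- numeric(0)
  if (!is.null(gas_spectrum)) {
    intra_f <- rep(gas_spectrum$frequency, times = z)
    if (perturbation > 0) {
      intra_f <- pmax(intra_f + stats::rnorm(length(intra_f), 0, perturbation), 1)
    }
  }
  spec <- mode_spectrum(
    c(inter, intra_f),
    character = c(rep("intermolecular", length(inter)),
                  rep("intramolecular", length(intra_f))),
    molecules_per_cell = z)
  gt <- direct_mode_sums(inter, rep(1 / z, length(inter)), temperature)
  list(spectrum = spec, gas_spectrum = gas_spectrum,
       ground_truth = tibble::tibble(
         e_zpe_inter = gt$zpe, u_thermal_inter = gt$u, s_inter = gt$s,
         temperature = temperature, seed = seed))
}

#' Generate a Crooks-consistent synthetic FEP dataset
#'
#' Builds a 20-window dataset over the 21-point lambda schedule (0 to 1
#' in steps of 0.05). For each window with true free-energy difference
#' dF_i (in RT), forward work samples are drawn from
#' Normal(dF_i + sigma^2/2, sigma^2) and backward samples from
#' Normal(-dF_i + sigma^2/2, sigma^2), which satisfies the Crooks
#' fluctuation relation exactly, so BAR is a consistent estimator of
#' dF_i.
#'
#' @param seed integer seed.
#' @param df_total_rt true total free-energy difference lambda 0 -> 1, RT
#'   units; split across windows proportionally to `profile`.
#' @param sigma work-distribution width per window, RT units (> 0).
#' @param n_samples samples per direction per window (>= 10).
#' @param n_windows number of windows (default 20).
#' @param temperature temperature, K.
#' @param profile optional positive weights (length `n_windows`) giving
#'   the shape of the per-window dF split; default uniform.
#' @return A list with `samples` (tibble in the format of
#'   [read_fep_csv()]), `df_true` (kJ/mol, lambda 0 -> 1),
#'   `df_true_per_window` (kJ/mol) and `manifest`.
#' @export
gen_fep_dataset <- function(seed, df_total_rt = -23.2, sigma = 1,
                            n_samples = 5000, n_windows = 20L,
                            temperature = 298.15, profile = NULL) {
  check_positive(sigma, "sigma")
  if (n_samples < 10) abort_config("`n_samples` must be >= 10")
  set.seed(seed)
  lam <- seq(0, 1, length.out = n_windows + 1)
  if (is.null(profile)) profile <- rep(1, n_windows)
  df_i <- df_total_rt * profile / sum(profile)
  rt <- .rt_kj(temperature)
  samples <- purrr::map(seq_len(n_windows), function(i) {
    fwd <- stats::rnorm(n_samples, df_i[i] + sigma^2 / 2, sigma)
    bwd <- stats::rnorm(n_samples, -df_i[i] + sigma^2 / 2, sigma)
    tibble::tibble(
      lambda_low = lam[i], lambda_high = lam[i + 1],
      direction = rep(c("fwd", "bwd"), each = n_samples),
      delta_u = c(fwd, bwd) * rt)
  }) |> purrr::list_rbind()
  list(samples = samples,
       df_true = df_total_rt * rt,
       df_true_per_window = df_i * rt,
       manifest = list(seed = seed, df_total_rt = df_total_rt, sigma = sigma,
                       n_samples = n_samples, n_windows = n_windows,
                       temperature = temperature))
}

#' Generate a synthetic conformer ensemble
#'
#' Evenly spaced conformer free energies in each phase with a known
#' ensemble free energy (direct log-sum-exp recorded in the manifest).
#'
#' @param seed integer seed (jitters the spacing slightly).
#' @param n_gas,n_solution conformer counts per phase.
#' @param spacing mean energy gap between successive conformers, kJ/mol.
#' @param dg_offset free-energy offset of the solution minimum below the
#'   gas minimum, kJ/mol (the dominant part of the hydration free energy).
#' @param temperature temperature, K.
#' @return A list with `conformers` (tibble: phase, conformer_id, g) and
#'   `manifest` carrying direct-sum ensemble free energies per phase.
#' @export
gen_conformer_ensemble <- function(seed, n_gas = 3, n_solution = 4,
                                   spacing = 2.5, dg_offset = -40,
                                   temperature = 298.15) {
  set.seed(seed)
  g_gas <- cumsum(c(0, stats::runif(n_gas - 1, 0.5, 1.5) * spacing))
  g_sol <- dg_offset + cumsum(c(0, stats::runif(n_solution - 1, 0.5, 1.5) * spacing))
  conf <- tibble::tibble(
    phase = c(rep("gas", n_gas), rep("solution", n_solution)),
    conformer_id = c(sprintf("g%02d", seq_len(n_gas)),
                     sprintf("s%02d", seq_len(n_solution))),
    g = c(g_gas, g_sol))
  rt <- 1.380649e-23 * 6.02214076e23 * temperature / 1000
  lse <- function(g) -rt * log(sum(exp(-g / rt)))  # direct, no production code
  list(conformers = conf,
       manifest = list(seed = seed, g_ens_gas = lse(g_gas),
                       g_ens_solution = lse(g_sol),
                       temperature = temperature))
}

#' Generate a complete synthetic compound fixture on disk
#'
#' Writes a self-consistent compound: lattice components, a gas spectrum,
#' a crystal spectrum sharing the gas intramolecular modes, a conformer
#' ensemble, and a Crooks-consistent FEP dataset whose true total equals
#' the conformer-route hydration free energy. A manifest JSON records
#' every ground-truth value, including the analytically assembled
#' log S0, all computed by direct formula sums independent of the
#' pipeline.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param temperature temperature, K.
#' @param n_fep_samples FEP samples per direction per window.
#' @return Path to the written config file, invisibly; the manifest is
#'   written alongside as `manifest.json`.
#' @export
gen_compound_fixture <- function(dir, seed, temperature = 298.15,
                                 n_fep_samples = 2000) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  # constants, locally (direct path)
  r <- 1.380649e-23 * 6.02214076e23
  rt <- r * temperature / 1000
  p0 <- 101325

  u_inter <- stats::runif(1, -160, -100)
  strain <- stats::runif(1, 0, 5)
  e_mol_min <- stats::runif(1, -80, -40)
  e_latt <- u_inter + strain

  # gas molecule: modest flexible organic
  gas_modes <- sort(stats::runif(12, 300, 3200))
  mass <- stats::runif(1, 100, 250)
  rot <- sort(stats::runif(3, 0.02, 0.15), decreasing = TRUE)

  cs <- gen_crystal_spectrum(seed + 1, z = 1, band = c(20, 150),
                             gas_spectrum = mode_spectrum(gas_modes),
                             perturbation = 0, temperature = temperature)

  # hydration ground truth from the conformer ensemble
  ens <- gen_conformer_ensemble(seed + 2, dg_offset = stats::runif(1, -60, -30),
                                temperature = temperature)
  sol_min <- min(ens$conformers$g[ens$conformers$phase == "solution"])
  dg_hyd_true <- sol_min - 0  # SFE2 vs gas reference g01 at G = 0
  # decoupling total (lambda 0 -> 1) is minus the coupling/hydration dG
  fep <- gen_fep_dataset(seed + 3, df_total_rt = -dg_hyd_true / rt,
                         sigma = 1, n_samples = n_fep_samples,
                         temperature = temperature)

  # --- analytic ground-truth sublimation/solubility (direct sums) ---
  hcna <- 6.62607015e-34 * 2.99792458e10 * 6.02214076e23
  inter <- cs$spectrum$frequency[cs$spectrum$character == "intermolecular"]
  gt_inter <- direct_mode_sums(inter, rep(1, length(inter)), temperature)
  gt_gasvib <- direct_mode_sums(gas_modes, rep(1, length(gas_modes)), temperature)
  # gas H_corr = zpe_vib + u_vib + 4RT; solid zpe+u = inter + intra(copied)
  dh_true <- -e_latt + (gt_gasvib$zpe + gt_gasvib$u + 4 * rt) -
    (gt_inter$zpe + gt_inter$u + gt_gasvib$zpe + gt_gasvib$u)
  # entropies: gas trans+rot+vib, solid all modes
  m_kg <- mass * 1e-3 / 6.02214076e23
  kb <- 1.380649e-23; h <- 6.62607015e-34
  s_tr <- r * (log(kb * temperature / (p0 * (h^2 / (2 * pi * m_kg * kb * temperature))^1.5)) + 2.5)
  theta <- hcna * rot / r
  s_rot <- r * (log(sqrt(pi) * temperature^1.5 / sqrt(prod(theta))) + 1.5)
  s_gas <- s_tr + s_rot + gt_gasvib$s
  s_solid <- gt_inter$s + gt_gasvib$s
  tds_true <- temperature * (s_gas - s_solid) / 1000
  dg_sub_true <- dh_true - tds_true
  log_s0_true <- log10(p0 / (r * temperature * 1000)) -
    (dg_sub_true + dg_hyd_true) * 1000 / (r * temperature * log(10))

  # --- write input files ---
  write_spectrum_csv(mode_spectrum(gas_modes), file.path(dir, "gas_spectrum.csv"))
  write_spectrum_csv(cs$spectrum, file.path(dir, "crystal_spectrum.csv"))
  readr::write_csv(
    tibble::tibble(phase = ens$conformers$phase,
                   conformer_id = ens$conformers$conformer_id,
                   G_kJmol = ens$conformers$g),
    file.path(dir, "conformers.csv"))
  readr::write_csv(
    tibble::tibble(lambda_low = fep$samples$lambda_low,
                   lambda_high = fep$samples$lambda_high,
                   direction = fep$samples$direction,
                   delta_u_kJmol = fep$samples$delta_u),
    file.path(dir, "fep.csv"))

  cfg <- list(
    name = sprintf("synthetic-%d", seed),
    temperature = temperature,
    sublimation = list(
      lattice = list(u_inter = u_inter, e_mol_in_cryst = e_mol_min + strain,
                     e_mol_min = e_mol_min),
      gas = list(mass = mass, rotor = "nonlinear",
                 rotational_constants = as.list(rot),
                 spectrum_csv = "gas_spectrum.csv"),
      solid = list(spectrum_csv = "crystal_spectrum.csv",
                   molecules_per_cell = 1)),
    hydration = list(
      list(model = "SFE2", conformers_csv = "conformers.csv",
           scheme = "SFE2", gas_reference_id = "g01"),
      list(model = "FEP", fep_csv = "fep.csv", coupled_at = "lambda0")))
  cfg_path <- file.path(dir, "compound.yaml")
  writeLines(yaml::as.yaml(cfg), cfg_path)

  manifest <- list(
    seed = seed, temperature = temperature,
    e_latt = e_latt, strain = strain, u_inter = u_inter,
    dh_sub_true = dh_true, tds_sub_true = tds_true,
    dg_sub_std_true = dg_sub_true, dg_hyd_true = dg_hyd_true,
    fep_df_true_kJmol = fep$df_true,
    log_s0_true = log_s0_true,
    provenance = "direct analytic sums, independent of pipeline functions")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 12, pretty = TRUE)
  invisible(cfg_path)
}

#' Write table-replay configs for the reference compounds
#'
#' Emits one YAML config per benchmark compound carrying the published
#' sublimation (`dh_sub`, `tds_sub`) and hydration (`dg_hyd` per model)
#' values verbatim, so the full pipeline reproduces the benchmark
#' solubility table from file inputs alone.
#'
#' @param dir output directory.
#' @return Character vector of config paths, invisibly.
#' @export
replay_compound_configs <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sub <- reference_sublimation()
  hyd <- reference_hydration()
  paths <- purrr::map_chr(sub$compound, function(cmp) {
    s <- sub[sub$compound == cmp, ]
    h <- hyd[hyd$compound == cmp, ]
    cfg <- list(
      name = cmp,
      temperature = 298.15,
      sublimation = list(dh_sub = s$dh_sub_calc, tds_sub = s$tds_sub),
      hydration = purrr::map2(h$hydration_model, h$dg_hyd_calc,
                              function(m, g) list(model = m, dg_hyd = g)),
      experimental = Filter(Negate(is.null), list(
        log_s0 = s$log_s0_expt,
        dh_sub = if (is.na(s$dh_sub_expt)) NULL else s$dh_sub_expt)))
    p <- file.path(dir, paste0(gsub("[^a-z0-9]+", "_", tolower(cmp)), ".yaml"))
    writeLines(yaml::as.yaml(cfg), p)
    p
  })
  invisible(paths)
}
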