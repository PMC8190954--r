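#' Boltzmann-weighted ensemble free energy
#'
#' Free energy of a conformer ensemble,
#' `G_ens = -RT ln sum_i exp(-G_i/RT)`, evaluated in log-sum-exp form so
#' that large energies cannot overflow. The result is always at or below
#' the lowest single-conformer free energy and approaches it as T -> 0.
#'
#' @param conformers a data frame with a column `g` (free energy, kJ/mol),
#'   e.g. from [read_conformers_csv()]; or a bare numeric vector of free
#'   energies.
#' @param temperature temperature, K.
#' @return Ensemble free energy, kJ/mol (scalar).
#' @examples
#' ensemble_free_energy(c(-10, -10))  # -10 - RT ln 2
#' @export
ensemble_free_energy <- function(conformers, temperature = 298.15) {
  g <- if (is.data.frame(conformers)) conformers$g else conformers
  if (length(g) == 0) abort_validation("conformer ensemble is empty")
  check_finite(g, "conformer free energies")
  check_positive(temperature, "temperature")
  rt <- .rt_kj(temperature)
  -rt * logsumexp(-g / rt)
}

#' Hydration free energy from conformer ensembles
#'
#' Computes the gas -> solution transfer free energy
#' `dG_hyd* = G_solution - G_gas` under one of three conformer-handling
#' schemes:
#' \describe{
#'   \item{SFE1}{Boltzmann-weighted solution ensemble minus a single
#'     reference gas conformer (the conformer matched to the crystal).}
#'   \item{SFE2}{single lowest-free-energy solution conformer minus the
#'     same single reference gas conformer.}
#'   \item{SFE3}{Boltzmann-weighted ensemble in each phase separately.}
#' }
#' SFE1 and SFE2 allow cancellation of errors against a sublimation leg
#' that uses the same gas conformer; SFE3 treats both phases on an equal
#' ensemble footing. A negative result means favorable hydration.
#'
#' @param conformers a data frame with columns `phase`
#'   (`"gas"`/`"solution"`), `conformer_id`, `g` (kJ/mol).
#' @param scheme `"SFE1"`, `"SFE2"` or `"SFE3"`.
#' @param gas_reference_id id of the reference gas conformer, required for
#'   SFE1/SFE2 and ignored by SFE3. Ties for the SFE2 solution minimum are
#'   broken by lexicographic conformer id.
#' @param temperature temperature, K.
#' @return Hydration free energy dG_hyd*, kJ/mol (scalar).
#' @export
hydration_sfe <- function(conformers, scheme = c("SFE1", "SFE2", "SFE3"),
                          gas_reference_id = NULL, temperature = 298.15) {
  scheme <- match.arg(scheme)
  need <- c("phase", "conformer_id", "g")
  if (!all(need %in% names(conformers))) {
    abort_config("conformer table must have columns %s", paste(need, collapse = ", "))
  }
  gas <- dplyr::filter(conformers, .data$phase == "gas")
  sol <- dplyr::filter(conformers, .data$phase == "solution")
  if (nrow(sol) == 0) abort_validation("no solution-phase conformers supplied")

  g_gas <- if (scheme == "SFE3") {
    if (nrow(gas) == 0) abort_validation("SFE3 requires gas-phase conformers")
    ensemble_free_energy(gas, temperature)
  } else {
    if (is.null(gas_reference_id)) {
      abort_config("scheme %s requires `gas_reference_id`", scheme)
    }
    hit <- gas$g[gas$conformer_id == gas_reference_id]
    if (length(hit) != 1) {
      abort_config("gas reference conformer '%s' not found (or not unique)",
                   gas_reference_id)
    }
    hit
  }

  g_sol <- switch(scheme,
    SFE1 = ,
    SFE3 = ensemble_free_energy(sol, temperature),
    SFE2 = {
      sol <- dplyr::arrange(sol, .data$g, .data$conformer_id)
      sol$g[1]
    })
  g_sol - g_gas
}

#' Read a conformer ensemble table from CSV
#'
#' Expects columns `phase`, `conformer_id`, `G_kJmol`.
#'
#' @param path file path.
#' @return A tibble with columns `phase`, `conformer_id`, `g`.
#' @export
read_conformers_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("phase", "conformer_id", "G_kJmol")
  if (!all(need %in% names(df))) {
    abort_config("conformer CSV %s must have columns %s", path,
                 paste(need, collapse = ", "))
  }
  tibble::tibble(phase = df$phase, conformer_id = df$conformer_id,
                 g = parse_numeric(df$G_kJmol))
}

# Fermi function, numerically safe on both tails
fermi <- function(x) 1 / (1 + exp(pmin(x, 700)))

#' Bennett acceptance ratio for one window
#'
#' Solves the self-consistent BAR equation for the free-energy difference
#' between two neighbouring states from forward work samples (potential
#' energy differences evaluated on samples of the low state) and backward
#' samples (evaluated on the high state). With reduced works
#' `u = dU/RT`, `M = ln(n_F/n_R)` and `C = dF/RT`, the estimate solves
#' `sum_F f(M + u_F - C) = sum_R f(-M + u_R + C)` where `f` is the Fermi
#' function. The root is bracketed and polished to |residual| < 1e-10.
#' The uncertainty is Bennett's asymptotic variance estimator.
#'
#' @param forward forward potential-energy differences dU(low->high), kJ/mol.
#' @param backward backward differences dU(high->low), kJ/mol.
#' @param temperature temperature, K.
#' @return A one-row tibble with `df` (free-energy difference low->high,
#'   kJ/mol) and `stderr` (kJ/mol).
#' @examples
#' bar_window(rep(2, 10), rep(-2, 10))  # delta distributions: df = 2
#' @export
bar_window <- function(forward, backward, temperature = 298.15) {
  if (length(forward) < 2 || length(backward) < 2) {
    abort_validation("BAR needs at least 2 samples in each direction")
  }
  check_finite(forward, "forward")
  check_finite(backward, "backward")
  rt <- .rt_kj(temperature)
  uf <- forward / rt
  ub <- backward / rt
  m <- log(length(uf) / length(ub))

  resid <- function(c0) {
    lf <- logsumexp(-log1p(exp(pmax(pmin(m + uf - c0, 700), -700))))
    lb <- logsumexp(-log1p(exp(pmax(pmin(-m + ub + c0, 700), -700))))
    lf - lb
  }

  # bracket around the exponential-averaging estimates, then widen
  span <- 10 * max(abs(c(uf, ub)), 1)
  lo <- -span; hi <- span
  if (resid(lo) * resid(hi) > 0) {
    abort_validation(
      "BAR equation has no root in [%.3g, %.3g] RT: poor phase-space overlap?",
      lo, hi)
  }
  c_hat <- stats::uniroot(resid, c(lo, hi), tol = 1e-12)$root
  # secant polish on the residual
  for (i in 1:50) {
    r0 <- resid(c_hat)
    if (abs(r0) < 1e-10) break
    r1 <- resid(c_hat + 1e-7)
    step <- r0 * 1e-7 / (r1 - r0)
    if (!is.finite(step)) break
    c_hat <- c_hat - step
  }

  # Bennett variance: (kT)^2 * sum over both samples of [<f^2>/<f>^2 - 1]/n
  xf <- fermi(m + uf - c_hat)
  xb <- fermi(-m + ub + c_hat)
  vf <- (mean(xf^2) / mean(xf)^2 - 1) / length(xf)
  vb <- (mean(xb^2) / mean(xb)^2 - 1) / length(xb)
  tibble::tibble(df = c_hat * rt, stderr = rt * sqrt(pmax(vf + vb, 0)))
}

#' Validate and structure a per-window FEP dataset
#'
#' @param samples a data frame with columns `lambda_low`, `lambda_high`,
#'   `direction` (`"fwd"`/`"bwd"`) and `delta_u` (kJ/mol), e.g. from
#'   [read_fep_csv()].
#' @return The input as a tibble, after checking that the lambda windows
#'   are ascending, contiguous, cover \[0, 1\] and have at least two
#'   samples in each direction.
#' @export
validate_fep <- function(samples) {
  need <- c("lambda_low", "lambda_high", "direction", "delta_u")
  if (!all(need %in% names(samples))) {
    abort_config("FEP table must have columns %s", paste(need, collapse = ", "))
  }
  win <- dplyr::distinct(samples, .data$lambda_low, .data$lambda_high) |>
    dplyr::arrange(.data$lambda_low)
  if (nrow(win) == 0) abort_validation("FEP dataset has no windows")
  if (abs(win$lambda_low[1]) > 1e-9 ||
      abs(win$lambda_high[nrow(win)] - 1) > 1e-9) {
    abort_validation("lambda windows must cover [0, 1]")
  }
  if (nrow(win) > 1) {
    gaps <- abs(win$lambda_low[-1] - win$lambda_high[-nrow(win)]) > 1e-9
    if (any(gaps)) {
      abort_validation("lambda schedule has gaps/overlaps after windows: %s",
                       paste(win$lambda_high[-nrow(win)][gaps], collapse = ", "))
    }
  }
  counts <- dplyr::count(samples, .data$lambda_low, .data$lambda_high,
                         .data$direction)
  if (any(counts$n < 2) || nrow(counts) != 2 * nrow(win)) {
    abort_validation("each lambda window needs >= 2 samples in each direction")
  }
  tibble::as_tibble(samples)
}

#' Total free energy over a lambda schedule by BAR
#'
#' Applies [bar_window()] to every window of an alchemical schedule and
#' sums the estimates; window variances are summed for the total
#' uncertainty. With the default convention the solute is fully coupled
#' at lambda = 0 and decoupled at lambda = 1, so the hydration (coupling)
#' free energy is minus the lambda 0 -> 1 total.
#'
#' @param samples a per-window FEP sample table (see [validate_fep()]).
#' @param temperature temperature, K.
#' @param coupled_at `"lambda0"` (default) or `"lambda1"`: where the fully
#'   coupled solute sits on the schedule.
#' @return A one-row tibble with `dg_hyd` (kJ/mol), `stderr` (kJ/mol),
#'   `n_windows`.
#' @export
fep_total <- function(samples, temperature = 298.15,
                      coupled_at = c("lambda0", "lambda1")) {
  coupled_at <- match.arg(coupled_at)
  samples <- validate_fep(samples)
  per <- samples |>
    dplyr::group_by(.data$lambda_low, .data$lambda_high) |>
    dplyr::group_modify(function(d, key) {
      bar_window(d$delta_u[d$direction == "fwd"],
                 d$delta_u[d$direction == "bwd"],
                 temperature)
    }) |>
    dplyr::ungroup()
  total <- sum(per$df)
  se <- sqrt(sum(per$stderr^2))
  dg <- if (coupled_at == "lambda0") -total else total
  tibble::tibble(dg_hyd = dg, stderr = se, n_windows = nrow(per))
}

#' Read per-window FEP samples from CSV
#'
#' Expects columns `lambda_low`, `lambda_high`, `direction` (fwd/bwd),
#' `delta_u_kJmol`.
#'
#' @param path file path.
#' @return A validated tibble (see [validate_fep()]).
#' @export
read_fep_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("lambda_low", "lambda_high", "direction", "delta_u_kJmol")
  if (!all(need %in% names(df))) {
    abort_config("FEP CSV %s must have columns %s", path, paste(need, collapse = ", "))
  }
  validate_fep(tibble::tibble(
    lambda_low = parse_numeric(df$lambda_low),
    lambda_high = parse_numeric(df$lambda_high),
    direction = df$direction,
    delta_u = parse_numeric(df$delta_u_kJmol)))
}
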