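test_that("ensemble free energy: identity, degeneracy and derived three-conformer case", {
  expect_equal(ensemble_free_energy(-10), -10)
  expect_equal(ensemble_free_energy(c(-10, -10)),
               -10 - rt_kj(298.15) * log(2), tolerance = 1e-9)
  # conformers at 0, RT, 2RT: -RT ln(1 + e^-1 + e^-2)
  g3 <- c(0, rt_kj(298.15), 2 * rt_kj(298.15))
  # -RT ln(1 + e^-1 + e^-2), evaluated independently
  expect_equal(ensemble_free_energy(g3),
               -rt_kj(298.15) * log(1 + exp(-1) + exp(-2)), tolerance = 1e-9)
  expect_equal(ensemble_free_energy(g3), -1.0104, tolerance = 1e-4)
  expect_error(ensemble_free_energy(numeric(0)),
               class = "solcycle_validation_error")
})

test_that("ensemble free energy invariants: lower bound, T -> 0, shift covariance, overflow", {
  set.seed(3)
  for (i in 1:10) {
    g <- stats::runif(sample(2:8, 1), -60, 10)
    ge <- ensemble_free_energy(g)
    expect_lte(ge, min(g))
    expect_equal(ensemble_free_energy(g, temperature = 1), min(g),
                 tolerance = 1e-3)
    shift <- stats::runif(1, -20, 20)
    expect_equal(ensemble_free_energy(g + shift), ge + shift,
                 tolerance = 1e-9)
  }
  # log-sum-exp form survives energies that would overflow exp(-G/RT)
  expect_equal(ensemble_free_energy(c(-5000, -5000)),
               -5000 - rt_kj(298.15) * log(2), tolerance = 1e-9)
})

test_that("SFE1/SFE2/SFE3 schemes implement the stated ensemble choices", {
  one_each <- tibble::tibble(
    phase = c("gas", "solution"), conformer_id = c("g1", "s1"),
    g = c(2, -38))
  for (sch in c("SFE1", "SFE2", "SFE3")) {
    expect_equal(hydration_sfe(one_each, sch, gas_reference_id = "g1"), -40)
  }

  # two degenerate solution conformers: SFE1 lower than SFE2 by RT ln 2
  degen <- tibble::tibble(
    phase = c("gas", "solution", "solution"),
    conformer_id = c("g1", "s1", "s2"), g = c(0, -38, -38))
  d1 <- hydration_sfe(degen, "SFE1", gas_reference_id = "g1")
  d2 <- hydration_sfe(degen, "SFE2", gas_reference_id = "g1")
  expect_equal(d2 - d1, rt_kj(298.15) * log(2), tolerance = 1e-9)

  # SFE3 vs SFE1 on a 3-conformer gas ensemble with an elevated reference
  gas_g <- c(0, 1, 2)
  conf <- tibble::tibble(
    phase = c(rep("gas", 3), "solution"),
    conformer_id = c("g1", "g2", "gref", "s1"),
    g = c(gas_g, -40))
  # reference 5 kJ/mol above the ensemble free energy of the gas phase
  g_ens_gas <- ensemble_free_energy(gas_g)
  conf$g[conf$conformer_id == "gref"] <- g_ens_gas + 5
  s3 <- hydration_sfe(conf, "SFE3")
  s1 <- hydration_sfe(conf, "SFE1", gas_reference_id = "gref")
  g_ens_with_ref <- ensemble_free_energy(conf$g[conf$phase == "gas"])
  expect_equal(s3 - s1, (g_ens_gas + 5) - g_ens_with_ref, tolerance = 1e-9)
  expect_gt(s3, s1)  # ensemble gas reference stabilizes the gas side

  # SFE2 tie-break by conformer id
  tie <- tibble::tibble(
    phase = c("gas", "solution", "solution"),
    conformer_id = c("g1", "sb", "sa"), g = c(0, -38, -38))
  expect_equal(hydration_sfe(tie, "SFE2", gas_reference_id = "g1"), -38)

  expect_error(hydration_sfe(one_each, "SFE1", gas_reference_id = "nope"),
               class = "solcycle_config_error")
  expect_error(hydration_sfe(one_each, "SFE1"), class = "solcycle_config_error")
})

test_that("BAR solves delta distributions exactly and is antisymmetric", {
  res <- bar_window(rep(3.2, 10), rep(-3.2, 10))
  expect_equal(res$df, 3.2, tolerance = 1e-9)

  set.seed(5)
  fwd <- stats::rnorm(200, 2, 1); bwd <- stats::rnorm(200, -1, 1)
  a <- bar_window(fwd, bwd)
  b <- bar_window(bwd, fwd)
  expect_equal(a$df, -b$df, tolerance = 1e-9)
  expect_error(bar_window(1, c(1, 2)), class = "solcycle_validation_error")
})

test_that("BAR recovers the free energy of Crooks-consistent Gaussian work", {
  rt <- rt_kj(298.15)
  set.seed(1234)
  fwd <- stats::rnorm(1e4, 1.5, 1) * rt
  bwd <- stats::rnorm(1e4, -0.5, 1) * rt
  res <- bar_window(fwd, bwd)
  expect_lt(abs(res$df - 1 * rt), 3 * res$stderr)
  expect_gt(res$stderr, 0)
})

test_that("BAR matches exponential averaging under perfect overlap", {
  # identical distributions centred on dF: both estimators consistent
  rt <- rt_kj(298.15)
  set.seed(99)
  df_true <- 0.8 * rt
  fwd <- stats::rnorm(1e4, df_true / rt, 0.3) * rt
  bwd <- stats::rnorm(1e4, -df_true / rt, 0.3) * rt
  bar <- bar_window(fwd, bwd)$df
  expa <- -rt * (log(mean(exp(-fwd / rt))))
  expect_equal(bar, expa, tolerance = 0.05 * rt)
})

test_that("BAR parameter recovery holds across seeded Gaussian fixtures", {
  rt <- rt_kj(298.15)
  hits <- 0; n_cases <- 50
  for (k in seq_len(n_cases)) {
    set.seed(1000 + k)
    df <- stats::runif(1, -5, 5)
    sg <- stats::runif(1, 0.5, 2)
    fwd <- stats::rnorm(1e4, df + sg^2 / 2, sg) * rt
    bwd <- stats::rnorm(1e4, -df + sg^2 / 2, sg) * rt
    res <- bar_window(fwd, bwd)
    if (abs(res$df - df * rt) <= 4 * res$stderr) hits <- hits + 1
  }
  expect_gte(hits / n_cases, 0.95)
})

test_that("fep_total validates the lambda schedule and adds windows", {
  mk <- function(lo, hi, df) tibble::tibble(
    lambda_low = lo, lambda_high = hi,
    direction = rep(c("fwd", "bwd"), each = 4),
    delta_u = c(rep(df, 4), rep(-df, 4)))
  three <- dplyr::bind_rows(mk(0, 1/3, 1), mk(1/3, 2/3, 2), mk(2/3, 1, 3))
  res <- fep_total(three)
  expect_equal(res$dg_hyd, -6, tolerance = 1e-9)  # coupling = -(decoupling)
  expect_equal(res$n_windows, 3)
  expect_equal(res$stderr, sqrt(sum(c(0, 0, 0))), tolerance = 1e-6)

  # sign convention flips with the coupled endpoint
  expect_equal(fep_total(three, coupled_at = "lambda1")$dg_hyd, 6,
               tolerance = 1e-9)

  # zero work everywhere -> zero total
  zero <- dplyr::bind_rows(mk(0, 0.5, 0), mk(0.5, 1, 0))
  expect_equal(fep_total(zero)$dg_hyd, 0, tolerance = 1e-9)

  # reversed schedule (swap directions and relabel lambdas) negates the total
  rev3 <- dplyr::bind_rows(mk(0, 1/3, -3), mk(1/3, 2/3, -2), mk(2/3, 1, -1))
  expect_equal(fep_total(rev3)$dg_hyd, -fep_total(three)$dg_hyd,
               tolerance = 1e-9)

  gap <- dplyr::bind_rows(mk(0, 0.4, 1), mk(0.6, 1, 2))
  expect_error(fep_total(gap), class = "solcycle_validation_error")
  expect_error(fep_total(mk(0.1, 1, 1)), class = "solcycle_validation_error")
})
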