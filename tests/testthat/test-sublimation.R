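test_that("lattice energy assembles intermolecular term plus strain", {
  rigid <- lattice_energy(-130, -50, -50)
  expect_equal(rigid$e_latt, -130)
  expect_equal(rigid$strain, 0)

  flex <- lattice_energy(-100, -50, -52.5)
  expect_equal(flex$strain, 2.5)
  expect_equal(flex$e_latt, -97.5)

  expect_error(lattice_energy(-100, -52.5, -50),
               class = "solcycle_validation_error")
})

test_that("the 2RT approximation gives -E_latt - 2RT", {
  expect_equal(dh_sub_2rt(-125.89), 120.9321, tolerance = 1e-4)
  expect_equal(dh_sub_2rt(-155.61), 150.6521, tolerance = 1e-4)
  expect_error(dh_sub_2rt(5), class = "solcycle_domain_error")
})

test_that("the full harmonic route reduces to 2RT in the classical limit", {
  gas <- gas_thermo(118, rotor = "nonlinear",
                    rotational_constants = c(0.12, 0.09, 0.05))
  # six intermolecular modes soft enough to be classical
  soft <- gamma_point_thermo(
    mode_spectrum(rep(1, 6), character = "intermolecular"), 298.15)
  e_latt <- -110
  expect_equal(dh_sub_full(e_latt, gas, soft), dh_sub_2rt(e_latt),
               tolerance = 0.05)
})

test_that("the full harmonic route matches direct assembly for quantum phonons", {
  gas <- gas_thermo(118, rotor = "nonlinear",
                    rotational_constants = c(0.12, 0.09, 0.05))
  solid <- gamma_point_thermo(
    mode_spectrum(rep(50, 6), character = "intermolecular"), 298.15)
  # -E_latt + 4RT - sum_inter(zpe + u): -(-100) + 9.916 - 14.946
  expect_equal(dh_sub_full(-100, gas, solid), 94.97, tolerance = 0.005)

  cold <- gamma_point_thermo(
    mode_spectrum(rep(50, 6), character = "intermolecular"), 100)
  expect_error(dh_sub_full(-100, gas, cold),
               class = "solcycle_validation_error")
})

test_that("intramolecular modes cancel in the enthalpy when identical in both phases", {
  intra <- c(400, 900, 1600, 3000)
  gas_sp <- mode_spectrum(intra)
  gas <- gas_thermo(118, rotor = "nonlinear",
                    rotational_constants = c(0.12, 0.09, 0.05),
                    spectrum = gas_sp)
  bare_gas <- gas_thermo(118, rotor = "nonlinear",
                         rotational_constants = c(0.12, 0.09, 0.05))
  inter <- rep(50, 6)
  solid_full <- gamma_point_thermo(mode_spectrum(
    c(inter, intra),
    character = c(rep("intermolecular", 6), rep("intramolecular", 4))), 298.15)
  solid_inter <- gamma_point_thermo(mode_spectrum(
    inter, character = "intermolecular"), 298.15)
  expect_equal(dh_sub_full(-100, gas, solid_full),
               dh_sub_full(-100, bare_gas, solid_inter), tolerance = 1e-9)
})

test_that("sublimation free energy combines enthalpy and the two entropies", {
  gas <- gas_thermo(118, rotor = "nonlinear",
                    rotational_constants = c(0.12, 0.09, 0.05))
  solid <- gamma_point_thermo(
    mode_spectrum(rep(50, 6), character = "intermolecular"), 298.15)
  dh <- dh_sub_full(-125.89, gas, solid)
  res <- dg_sub(dh, gas, solid, e_latt = -125.89)
  expect_equal(res$tds_sub, 298.15 * (gas$s - solid$s) / 1000)
  expect_equal(res$dg_sub_std, res$dh_sub - res$tds_sub, tolerance = 5e-3)
  expect_equal(res$dh_plus_e_latt, dh - 125.89)
  # gas entropy exceeds solid entropy, so dG <= dH
  expect_lte(res$dg_sub_std, res$dh_sub)
  # broom accessors stay in sync with the stored legs
  expect_equal(glance(res)$two_rt_deviation,
               res$dh_plus_e_latt + 2 * rt_kj(298.15))
  expect_setequal(tidy(res)$term,
                  c("dh_sub", "tds_sub", "dg_sub_std", "dg_sub_star",
                    "dh_plus_e_latt", "temperature"))
})

test_that("standard-state conversion has the RT/p0 fixed point and a clean round trip", {
  vm0 <- RGAS * 298.15 / 101325 * 1000  # L/mol, ~24.46
  expect_equal(convert_std_to_star(51.54, vm0), 51.54, tolerance = 1e-9)
  expect_equal(convert_std_to_star(51.54, 0.077), 65.82, tolerance = 0.005)
  set.seed(11)
  for (i in 1:20) {
    dg <- stats::runif(1, -50, 150); vm <- stats::runif(1, 0.01, 30)
    expect_equal(convert_star_to_std(convert_std_to_star(dg, vm), vm), dg,
                 tolerance = 1e-9)
  }
  expect_error(convert_std_to_star(10, -1), class = "solcycle_domain_error")
})
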