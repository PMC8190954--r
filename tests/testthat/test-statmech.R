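test_that("mode_thermo matches the harmonic-oscillator closed forms and limits", {
  # equipartition limit: u -> RT as x -> 0
  soft <- mode_thermo(1, 298.15)
  expect_equal(soft$u_thermal, rt_kj(298.15), tolerance = 3e-3)

  # frozen-mode limit: stiff modes contribute nothing thermal
  stiff <- mode_thermo(5000, 298.15)
  expect_lt(stiff$u_thermal, 1e-6)
  expect_lt(stiff$s, 1e-6)
  expect_gt(stiff$zpe, 0)

  # direct evaluation at 100 cm^-1 (frozen from the closed forms)
  m <- mode_thermo(100, 298.15)
  expect_equal(m$zpe, 0.5981328, tolerance = 1e-6)
  expect_equal(m$u_thermal, 1.9287452, tolerance = 1e-6)
  expect_equal(m$s, 14.4528643, tolerance = 1e-6)
  expect_equal(m$a, m$zpe + m$u_thermal - 298.15 * m$s / 1000)

  expect_error(mode_thermo(-5, 298.15), class = "solcycle_domain_error")
  expect_error(mode_thermo(100, 0), class = "solcycle_domain_error")
})

test_that("mode_thermo thermal energy decreases with frequency and is bounded by RT", {
  freqs <- 10^seq(0, 3.5, length.out = 40)
  u <- mode_thermo(freqs, 298.15)$u_thermal
  expect_true(all(diff(u) < 0))
  expect_true(all(u < rt_kj(298.15)))
})

test_that("spectrum_thermo is linear in weight, additive over characters, and matches brute force", {
  one <- mode_spectrum(100, weight = 6, character = "intermolecular")
  got <- spectrum_thermo(one, 298.15, characters = "intermolecular")
  per <- mode_thermo(100, 298.15)
  expect_equal(got$e_zpe, 6 * per$zpe)
  expect_equal(got$u_thermal, 6 * per$u_thermal)
  expect_equal(got$s, 6 * per$s)
  expect_equal(got$h_corr, got$e_zpe + got$u_thermal)  # no pV, condensed

  # frozen derived case: six intermolecular modes at 50 cm^-1
  six <- mode_spectrum(rep(50, 6), character = "intermolecular")
  tc <- spectrum_thermo(six, 298.15, characters = "intermolecular")
  expect_equal(tc$e_zpe + tc$u_thermal, 14.94583, tolerance = 1e-5)

  set.seed(42)
  for (i in 1:5) {
    sp <- random_spectrum(sample(5:100, 1))
    inter <- spectrum_thermo(sp, 298.15, characters = "intermolecular")
    intra <- suppressWarnings(spectrum_thermo(sp, 298.15, characters = "intramolecular"))
    both <- spectrum_thermo(sp, 298.15)
    # additivity of the character filter
    expect_equal(inter$e_zpe + intra$e_zpe, both$e_zpe)
    expect_equal(inter$s + intra$s, both$s)
    # brute-force per-mode loop oracle
    oracle <- brute_spectrum_sums(sp, 298.15)
    expect_equal(both$e_zpe, oracle$zpe, tolerance = 1e-12)
    expect_equal(both$u_thermal, oracle$u, tolerance = 1e-12)
    expect_equal(both$s, oracle$s, tolerance = 1e-12)
  }

  # empty selection warns and returns zeros
  expect_warning(z <- spectrum_thermo(one, 298.15, characters = "intramolecular"),
                 "no modes")
  expect_equal(z$e_zpe, 0)
  expect_equal(z$s, 0)
})

test_that("entropy vanishes and A_corr tends to the ZPE as T -> 0", {
  sp <- mode_spectrum(c(30, 80, 200, 1500),
                      character = c("intermolecular", "intermolecular",
                                    "intramolecular", "intramolecular"))
  tc <- spectrum_thermo(sp, 1)
  expect_lt(tc$s, 1e-3)
  expect_equal(tc$a_corr, tc$e_zpe, tolerance = 1e-3)
})

test_that("gas_thermo reproduces Sackur-Tetrode, equipartition and the x = 1 mode", {
  # argon at 1 atm: translational entropy only (closed-form value)
  ar <- gas_thermo(39.948, rotor = "atom")
  expect_equal(ar$s, 154.7362, tolerance = 1e-4)
  expect_equal(ar$e_zpe, 0)

  # nonlinear rotor, no vibrations: thermal enthalpy = 4RT
  rigid <- gas_thermo(100, rotor = "nonlinear",
                      rotational_constants = c(0.1, 0.08, 0.05))
  expect_equal(rigid$h_corr, 4 * rt_kj(298.15), tolerance = 1e-9)
  expect_equal(rigid$a_corr,
               rigid$h_corr - rt_kj(298.15) - 298.15 * rigid$s / 1000)

  # a single mode at x = 1 contributes RT/(e - 1)
  nu1 <- KB * 298.15 / (H * CC)  # ~207.2 cm^-1
  one <- gas_thermo(100, rotor = "nonlinear",
                    rotational_constants = c(0.1, 0.08, 0.05),
                    spectrum = mode_spectrum(nu1))
  u_vib <- one$h_corr - rigid$h_corr - mode_thermo(nu1)$zpe
  expect_equal(u_vib, rt_kj(298.15) / (exp(1) - 1), tolerance = 1e-9)

  # linear rotor carries RT rotational energy; symmetry number lowers S
  lin1 <- gas_thermo(28, rotor = "linear", rotational_constants = 2)
  lin2 <- gas_thermo(28, rotor = "linear", rotational_constants = 2,
                     symmetry_number = 2)
  expect_equal(lin1$h_corr, 3.5 * rt_kj(298.15))  # 3/2 trans + 1 rot + pV
  expect_equal(lin1$s - lin2$s, RGAS * log(2), tolerance = 1e-9)

  expect_error(gas_thermo(100, rotor = "nonlinear"),
               class = "solcycle_config_error")
})

test_that("physical constants are internally consistent", {
  k <- thermo_constants()
  expect_equal(k$R, k$kB * k$`NA`, tolerance = 1e-6)
  expect_equal(k$hcNA, 11.9627, tolerance = 1e-3)
})

test_that("mode_spectrum validates frequencies and guards acoustic zero modes", {
  expect_error(mode_spectrum(c(100, -20)), class = "solcycle_validation_error")
  expect_warning(sp <- mode_spectrum(c(1e-4, 50)), "acoustic")
  expect_equal(sp$character[1], "acoustic")
  # 3NZ - 3 bookkeeping warning
  expect_warning(
    mode_spectrum(rep(50, 5), molecules_per_cell = 1, n_atoms = 3),
    "3\\*N\\*Z - 3")
  expect_silent(mode_spectrum(rep(50, 6), molecules_per_cell = 1, n_atoms = 3))
})
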