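# Independent brute-force oracles used across tests. These deliberately
# re-derive the harmonic-oscillator quantities with a bare per-mode loop
# so they share no code with the package internals.

KB <- 1.380649e-23
H <- 6.62607015e-34
CC <- 2.99792458e10
NAV <- 6.02214076e23
RGAS <- KB * NAV
HCNA <- H * CC * NAV

rt_kj <- function(t) RGAS * t / 1000

# per-mode loop sum over a spectrum data frame (frequency, weight, character)
brute_spectrum_sums <- function(spec, t, chars = c("intermolecular", "intramolecular")) {
  zpe <- 0; u <- 0; s <- 0
  for (i in seq_len(nrow(spec))) {
    if (!(spec$character[i] %in% chars) || spec$character[i] == "acoustic") next
    f <- spec$frequency[i]; w <- spec$weight[i]
    x <- HCNA * f / (RGAS * t)
    zpe <- zpe + w * 0.5 * HCNA * f / 1000
    u <- u + w * RGAS * t * x / (exp(x) - 1) / 1000
    s <- s + w * RGAS * (x / (exp(x) - 1) - log(1 - exp(-x)))
  }
  list(zpe = zpe, u = u, s = s)
}

# random spectrum generator for property tests
random_spectrum <- function(n, z = 1L) {
  mode_spectrum(
    frequency = stats::runif(n, 10, 3000),
    weight = sample(1:3, n, replace = TRUE),
    character = sample(c("intermolecular", "intramolecular"), n, replace = TRUE),
    molecules_per_cell = z)
}

expect_tc_equal <- function(a, b, tol = 1e-9) {
  expect_equal(a$e_zpe, b$e_zpe, tolerance = tol)
  expect_equal(a$u_thermal, b$u_thermal, tolerance = tol)
  expect_equal(a$s, b$s, tolerance = tol)
}
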