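---
title: "Methods: the sublimation cycle, harmonic thermochemistry and BAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the sublimation cycle, harmonic thermochemistry and BAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solcycle)
```

## The thermodynamic model

Intrinsic solubility S₀ is the saturation concentration of the neutral
solute. Assuming unit activity coefficient, dissolving a crystal is the
sum of two legs through the gas phase:

* **sublimation**, crystal → ideal gas, reported here at the 1 atm gas
  standard state (ΔG°_sub);
* **hydration**, gas → aqueous solution at fixed center of mass
  (Ben-Naim convention, ΔG*_hyd).

Converting the sublimation leg from the 1 atm convention to Ben-Naim
introduces the crystal molar volume, which then cancels against the
−RT ln(S₀V_m) link between solution free energy and solubility. The
volume-free combination implemented in `log_s0()` is

S₀ = (p₀/RT) · exp[−(ΔG°_sub + ΔG*_hyd)/RT],

and `log_s0_vm()` keeps the explicit-V_m form; the two are algebraically
identical whenever the same V_m feeds `convert_std_to_star()`, a
property the test suite asserts to 1e-9 for random inputs. At 298.15 K
the prefactor contributes log₁₀(0.040874) ≈ −1.3886, and each kJ/mol of
solution free energy moves log S₀ by −1/(RT ln 10) ≈ −0.175.

## Harmonic thermochemistry and the 2RT approximation

Each harmonic mode of frequency ν contributes, with x = hcν/kBT,

* zpe = ½hcν·N_A,
* u = RT·x/(eˣ−1),
* s = R[x/(eˣ−1) − ln(1−e⁻ˣ)].

`mode_thermo()` evaluates these; `spectrum_thermo()`,
`gamma_point_thermo()` and `dos_thermo()` aggregate them over discrete
Γ-point spectra (per molecule of the cell) or a phonon density of
states (trapezoidal quadrature on the supplied grid — no re-gridding,
since any resampling policy would silently impose assumptions about
the upstream phonon sampling). The gas side (`gas_thermo()`) adds
Sackur–Tetrode translation at the chosen pressure, classical
rigid-rotor rotation, and the ideal-gas pV term, so
H_corr(gas) = E_ZPE + U_vib + 3RT/2 + U_rot + RT.

The full sublimation enthalpy is

ΔH_sub = −E_latt + H_corr(gas) − [E_ZPE(solid) + U_thermal(solid)].

If the intramolecular modes are identical in both phases they cancel
exactly in this difference (asserted in the tests by construction), and
if the six remaining intermolecular modes per molecule are classical
(x → 0) each contributes RT in the solid while the gas carries 4RT of
thermal enthalpy, so the expression collapses to the familiar
ΔH_sub = −E_latt − 2RT. Intermolecular modes of organic crystals sit at
20–200 cm⁻¹, which at room temperature is *not* deep in the classical
regime: zero-point energy survives and u < RT. The diagnostic
`dh_plus_e_latt` reported by `dg_sub()` (and its distance from −2RT in
`glance()`) makes the size of this failure visible per compound; for
the built-in benchmark compounds it reaches ~7 kJ/mol, i.e. more than
an order of magnitude in solubility.

## Parameters that matter

* **Temperature** (K, default 298.15): enters every Boltzmann factor;
  all entries of a cycle must share it (`dh_sub_full()` errors on
  mismatch).
* **Standard pressure**: 1 atm = 101325 Pa exactly, fixed by the
  convention of the sublimation leg. Gas entropies use it in
  Sackur–Tetrode; note that tabulated 1-bar entropies differ by
  R ln(101325/100000) ≈ 0.11 J/(mol K).
* **Symmetry number** (default 1): the external rotational symmetry of
  the solute. The sources of benchmark gas thermal analyses rarely
  state it, and drug-like molecules are usually C₁, so 1 is the
  conservative default; a wrong σ shifts T·S_rot by RT ln σ.
* **Frequency floor** 0.01 cm⁻¹: anything below is treated as an
  acoustic zero mode and dropped with a warning — a numerical guard,
  since the three acoustic translations carry no weight at Γ but often
  survive as ~1e-3 cm⁻¹ noise in phonon outputs.
* **Mode bookkeeping**: a crystal Γ-point spectrum of N-atom molecules
  with Z molecules per cell should carry 3NZ−3 non-acoustic modes; the
  validator warns rather than errors on mismatch because supercell
  conventions vary between codes.

## Hydration models

`ensemble_free_energy()` computes −RT ln Σ exp(−Gᵢ/RT) in log-sum-exp
form, so absolute electronic energies (≫ RT in magnitude) cannot
overflow. The three conformer schemes differ only in which side gets an
ensemble: SFE1 (solution ensemble vs crystal-matched gas conformer),
SFE2 (single minimum each side; solution minimum chosen by lowest G,
ties broken lexicographically by conformer id so results are
reproducible), SFE3 (ensembles both sides). The input format accepts
whatever per-conformer free energies the user supplies; whether they
include per-conformer vibrational corrections is the user's modelling
choice and is deliberately not inferred.

`bar_window()` implements the Bennett acceptance ratio: with reduced
works u = ΔU/RT and M = ln(n_F/n_R), the estimate C = ΔF/RT solves
Σ_F f(M + u_F − C) = Σ_R f(−M + u_R + C) with f the Fermi function.
The root is bracketed over ±10·max|u| and solved by `uniroot` with a
secant polish to |residual| < 1e-10 — bisection-style bracketing was
chosen over Newton iterations for robustness at poor overlap, where the
residual is extremely flat. The uncertainty is Bennett's asymptotic
variance. Samples are weighted equally: no autocorrelation correction
is applied, so the reported standard errors assume independent samples
and are optimistic for correlated MD output (known limitation).
`fep_total()` sums windows over a contiguous λ schedule covering [0,1]
(gaps and overlaps are rejected, naming the offending windows) and
flips the sign according to which endpoint holds the fully coupled
solute, so it always returns the *hydration* (coupling) free energy.

## Synthetic data: what it emulates, what it does not

The `gen_*` generators produce every input class with analytically
known ground truth, computed by direct formula sums kept separate from
the production code paths:

* `gen_crystal_spectrum()`: 6Z intermolecular modes uniform in
  20–150 cm⁻¹ — a band chosen to straddle the classical/quantum
  crossover at room temperature, exactly the regime where the 2RT
  approximation degrades — plus intramolecular modes copied (optionally
  perturbed) from a gas spectrum.
* `gen_fep_dataset()`: 20 windows on the 21-point λ schedule with
  Gaussian work distributions, forward N(ΔFᵢ+σ²/2, σ²) and backward
  N(−ΔFᵢ+σ²/2, σ²) in RT units, which satisfy the Crooks fluctuation
  relation exactly; defaults (σ = 1 RT, 5000 samples/direction, total
  ΔF ≈ −23 RT ≈ −57 kJ/mol) mirror a typical small-molecule hydration
  run.
* `gen_compound_fixture()`: a complete self-consistent compound with a
  manifest recording E_latt, ΔH_sub, ΔG°_sub, ΔG*_hyd and log S₀.

These fixtures validate the *estimators and the arithmetic*, not the
physics production chain: real phonon spectra have dispersion,
anharmonicity and mode mixing; real FEP work distributions are
non-Gaussian and autocorrelated; real conformer sets are incomplete.
Passing tests therefore demonstrate correctness of the thermodynamic
assembly at stated precision, not accuracy of any upstream
electronic-structure or force-field model.

## Numerical choices and degenerate inputs

* Energies in kJ/mol, entropies in J/(mol K) internally; CODATA 2018
  constants; conversions only at I/O boundaries.
* `expm1`/`log1p` forms in the oscillator functions keep soft-mode
  quantities accurate to machine precision; stiff modes underflow
  cleanly to zero rather than producing NaN.
* Empty mode selections return all-zero corrections with a warning
  (not an error): an atom has no vibrations, and a filter can be
  legitimately empty.
* DOS normalization is validated against the declared mode count at
  0.5%; a delta-like DOS reproduces the discrete result to quadrature
  accuracy.
* Report-layer rounding is half-up to 2 decimals
  (`format_solubility()`); full precision is kept internally, and
  JSON reports are byte-identical across reruns on identical inputs.
* Unicode minus signs (–, −) in pasted tables are normalized at parse
  time.

## Problem sizes in the test suite

Numeric reproduction of the benchmark tables is desk scale (single
closed-form evaluations). Property tests use ≤200-mode random spectra,
3500-point DOS grids, 50 seeded BAR fixtures at 10⁴ samples per
direction, and end-to-end fixtures with 1500–2000 FEP samples per
window — sizes at which the stochastic assertions (estimates within 4
standard errors in ≥95% of cases) are sharp while the whole suite runs
in seconds.

## Known limitations

Harmonic approximation throughout (no anharmonicity, no hindered
rotors, no quasi-harmonic cell expansion); Γ-point or user-supplied DOS
only (no dispersion interpolation); unit activity coefficient (no
ionization correction — S₀ is the *intrinsic* solubility); equal-weight
BAR samples; single-temperature evaluation. The benchmark tables embed
upstream method choices (dispersion-corrected periodic DFT phonons,
model-potential lattice energies, continuum-solvent DFT and GAFF/SPC-E
FEP hydration) that this package consumes but does not recompute.
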