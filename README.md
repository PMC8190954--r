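# solcycle

Physics-based prediction of **intrinsic aqueous solubility** — the
equilibrium concentration S₀ (mol/L) of the neutral form of a solute —
through the sublimation thermodynamic cycle
crystal → gas → aqueous solution.

The package is aimed at computational chemists in drug discovery and
crystal engineering who already have the expensive ingredients in hand
(lattice energies, harmonic phonon spectra, conformer free energies, or
alchemical FEP work samples) and need the thermodynamic bookkeeping done
correctly: harmonic mode thermochemistry beyond the 2RT approximation,
standard-state conventions, conformer Boltzmann weighting, and the
Bennett acceptance ratio.

## The model

With unit activity coefficient, the solution free energy links to
solubility via the cycle

```
ΔG*_sol = ΔG*_sub + ΔG*_hyd = −RT ln(S₀ V_m)
```

where the asterisk marks Ben-Naim (fixed center-of-mass) transfer free
energies and V_m is the crystal molar volume. Because sublimation free
energies are conventionally reported at a 1 atm gas standard state
(ΔG°_sub), converting with `ΔG*_sub = ΔG°_sub − RT ln(p₀V_m/RT)` removes
V_m entirely:

```
S₀ = (p₀ / RT) · exp[ −(ΔG°_sub + ΔG*_hyd) / RT ]
```

The prefactor p₀/RT ≈ 0.0409 mol/L at 298.15 K (log₁₀ ≈ −1.389).

**Sublimation leg.** The lattice energy is assembled as
`E_latt = U_inter + (E_mol,cryst − E_mol,min)` (intermolecular term plus
conformational strain). The classical shortcut
`ΔH_sub = −E_latt − 2RT` holds only when the six intermolecular phonon
modes per molecule are classical; instead the full harmonic route

```
ΔH_sub = −E_latt + H_corr(gas) − [E_ZPE(solid) + U_thermal(solid)]
```

uses quantum harmonic-oscillator sums over Γ-point modes or a phonon
density of states, and `ΔG°_sub = ΔH_sub − T(S_gas − S_solid)` with
Sackur–Tetrode / rigid-rotor / RRHO gas entropies. The diagnostic
`ΔH_sub + E_latt` versus −2RT ≈ −4.96 kJ/mol quantifies how badly the
2RT shortcut would do.

**Hydration leg.** Either from conformer free energies under three
Boltzmann-weighting schemes (SFE1: solution ensemble vs a single
crystal-matched gas conformer; SFE2: single minimum in each phase;
SFE3: ensembles in both phases), or from per-λ FEP samples combined
window-by-window with the self-consistent BAR estimator.

## Worked example

The built-in benchmark set covers succinic acid, coronene and
desloratadine with published sublimation energetics and four hydration
models each:

```r
library(solcycle)
res <- reference_solubility()
format_solubility(res)[, c("compound", "hydration_model",
                           "log_s0_calc", "log_s0_expt", "error")]
#>    compound      hydration_model             log_s0_calc log_s0_expt error
#>  1 succinic acid PBE/6-311++G(2d,p)/SMD           -1.78       -0.22  1.56
#>  4 succinic acid GAFF/AM1-BCC, SPC/E              -0.35       -0.22  0.13
#>  8 coronene      GAFF/AM1-BCC, SPC/E              -8.23       -9.33 -1.10
#> 10 desloratadine PBE0/6-311++G(2d,p)/SMD          -3.44       -3.42  0.02
#>    ... (12 rows)
glance(res)
#>   n_models n_compounds   mae  rmse max_abs_error
#> 1       12           3 0.950  1.21          2.63
```

Each row combines the compound's sublimation free energy (kJ/mol, 1 atm
standard state) with one hydration free energy (kJ/mol, Ben-Naim) into
log₁₀ S₀; `error` is experiment minus calculation, so +1.56 means the
PBE continuum model underestimates succinic acid's solubility by a
factor of ~36, while MD/FEP lands within 0.13 log units.
`plot_solubility_errors(res)` draws the absolute-error bar chart.

The same numbers flow through the file-based pipeline: YAML configs with
direct values, spectra/DOS tables, conformer CSVs or FEP CSVs, e.g.

```r
cfgs <- replay_compound_configs(tempdir())   # write benchmark configs
run_pipeline(cfgs[1])                        # -> 4-row solubility_result
```

or from a shell via the thin CLI: `exec/solcycle compute config.yaml`,
plus `thermo`, `bar`, `report` and `fixtures` subcommands.

Synthetic inputs with analytically known ground truths (seeded crystal
spectra, Crooks-consistent Gaussian FEP work, conformer ensembles, and
complete end-to-end compounds) come from the `gen_*` generators.

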