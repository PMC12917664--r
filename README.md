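# ligbind

Quantitative analysis of pH-dependent protein–ligand binding from four
complementary biophysical measurements, in one tested R package:

- **Fluorescence quenching titrations** — inner-filter and dilution
  corrections, quenching fractions θ = (F₀ − F)/F₀, and the double-log
  Hill fit log₁₀(θ/(1−θ)) = n·log₁₀[L] − log₁₀K_d, yielding the
  association constant K_a = 1/K_d and Hill coefficient n.
- **van't Hoff thermodynamics** — regression of ln K_a on 1/T for ΔH and
  ΔS, Gibbs free energy via ΔG = ΔH − TΔS and ΔG = −RT ln K_a, and
  condition-level summary rows (⟨K_a⟩, ⟨n⟩, ΔH, ⟨TΔS⟩, ⟨ΔG⟩).
- **STD-NMR epitope mapping** — amplification factors
  A_STD = (I₀ − I_SAT)/I₀ per ligand proton, normalized so the strongest
  proton is 100%, with cross-condition comparison (Δ%, counts above a
  saturation threshold, rank concordance).
- **DLS sizing** — cumulant fit of g₂ − 1 = β·exp(−2Γτ), D = Γ/q², and
  the Stokes–Einstein hydrodynamic diameter d_H = k_BT/(3πηD).
- **Structural contact analysis** — ligand-contact residues within a
  distance cutoff (default 3.4 Å), distance-only hydrogen-bond detection
  to ligand oxygens, Kabsch-superposition RMSD, and radius of gyration,
  for single- and multi-model PDB files.

Every stage has a synthetic-data generator with known ground truth
(`gen_titration`, `gen_std_table`, `gen_dls_trace`, `gen_toy_complex`),
so the full analysis chain is validated by exact round-trip recovery.
The package is aimed at biophysics groups characterising small-molecule
binding (e.g. a plant metabolite binding an adaptor protein under two pH
conditions) who want the entire numerical workflow reproducible from raw
intensity tables to summary rows.

## Worked example

Generate a noise-free titration under a realistic protocol (2 μM
protein, 202 μM ligand stock titrated in equal additions to a 1:1 mole
ratio, three temperatures linked by ΔH = 11.5 kcal/mol, K_a anchored at
4.5×10⁵ M⁻¹ at 299 K), then run the full analysis chain:

```r
library(ligbind)

gen  <- gen_titration(ka_ref = 4.5e5, n = 1.0, delta_h = 11.5, ph = 8, seed = 1)
fit  <- fit_titration(gen$series[["299"]], stock_conc = 202e-6)
fit
#> Hill double-log fit
#>   n (Hill slope) : 1.0000 (se 0.0000)
#>   Kd             : 2.222e-06 M
#>   Ka             : 4.5e+05 1/M
#>   R-squared      : 1.000000   points used: 10 (excluded 0)

fits <- lapply(gen$series, fit_titration, stock_conc = 202e-6)
condition_summary(fits, label = "pH 8")
#> Condition summary (pH 8)
#>   <Ka> : 4.59e+05 1/M   <n> : 1
#>   dH   : 11.50 kcal/mol   <TdS> : 19.23   <dG> : -7.73
```

The fit recovers the generator's truth exactly (K_a = 4.5×10⁵ M⁻¹,
n = 1); the condition row averages over 295/299/303 K, so ⟨K_a⟩ is
slightly above the 299 K anchor for an endothermic (ΔH > 0) interaction,
and ⟨ΔG⟩ = −7.73 kcal/mol indicates spontaneous, entropically driven
binding (ΔG = ΔH − TΔS with TΔS ≈ +19.2 kcal/mol).

An epitope map from a table of STD difference intensities:

```r
normalize_epitope(c("3","4","5","6","7","8"),
                  c(0.00155, 0.00330, 0.00285, 0.00607, 0.00132, 0.00465),
                  c(6.43, 7.98, 7.56, 7.31, 7.62, 7.37), condition = "pH 7")
#> STD epitope map (pH 7)
#>  label chemical_shift     raw   pct
#>      3           6.43 0.00155  25.5
#>      4           7.98 0.00330  54.4
#>      5           7.56 0.00285  47.0
#>      6           7.31 0.00607 100.0
#>      7           7.62 0.00132  21.7
#>      8           7.37 0.00465  76.6
```

Protons 6 and 8 dominate the saturation transfer, i.e. they sit closest
to the protein surface in the bound pose. And a DLS trace for a 6.02 nm
particle at 20 °C in water analyzes back to its generating diameter:

```r
analyze_trace(gen_dls_trace(6.02e-9))
#> DLS cumulant analysis
#>   q     : 1.867e+07 1/m   Gamma : 2.482e+04 1/s
#>   D     : 7.119e-11 m^2/s
#>   d_H   : 6.020 nm   (fit R^2 1.000000)
```

A thin command-line wrapper over these functions is included at
`inst/cli/ligbind.R` (subcommands `titrate-fit`, `vanthoff`,
`std-epitope`, `dls`, `contacts`, `simulate`).

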