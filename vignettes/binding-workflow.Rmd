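---
title: "Models and methods behind the ligbind workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the ligbind workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligbind)
```

ligbind integrates four biophysical measurements of small-molecule binding
to a protein — fluorescence quenching titrations, van't Hoff
thermodynamics, STD-NMR epitope mapping and DLS sizing — plus structural
contact analysis of docking/MD poses. This vignette explains each model,
its assumptions, the tunable parameters, and the numerical choices made
where the underlying experimental conventions left the design open.

## Fluorescence quenching and the double-log Hill fit

Intrinsic tryptophan fluorescence is quenched when a ligand occupies a
binding site. The fractional quench against the ligand-free reference,
$\theta = (F_0 - F)/F_0$, is identified with the fractional occupancy of
the binding sites. For $n$ sites with dissociation constant $K_d$,

$$\theta = \frac{[L]^n}{[L]^n + K_d},$$

which is exactly linear in double-log form,

$$\log_{10}\frac{\theta}{1-\theta} = n\,\log_{10}[L] - \log_{10}K_d,$$

so an ordinary least-squares line gives the Hill coefficient $n$ (slope)
and $K_a = 1/K_d$ (from the intercept). `fit_titration()` chains three
corrections before this regression:

* **Inner-filter correction.** Ligand absorbance at the excitation and
  analysis wavelengths attenuates the observed signal; the corrected
  intensity is $F_A = F_O \cdot 10^{(A_{ex}+A_{em})/2}$. Absorbances are
  supplied per titration point because they grow with ligand
  concentration.
* **Dilution correction.** Titrant additions change the cuvette volume by
  about 1–3%; the protein (and hence its fluorescence) is diluted by
  $V_0/(V_0+V_{added})$. Observed intensities are divided by this factor
  before computing $\theta$, otherwise dilution masquerades as quenching.
* **Intensity metric.** Emission spectra are reduced to a scalar by the
  peak maximum (default), the intensity at a fixed wavelength, or the
  trapezoidal band area. Published quenching analyses rarely state which
  metric was used; all three agree exactly for spectra that scale
  uniformly with quenching (the generative model used here), so the
  default is the simplest.

Points with $\theta \le 0$ or $\theta \ge 1$ have undefined log-odds and
are *excluded and recorded*, never clamped: clamping would bias the slope.
$[L]$ is the total titrated ligand concentration; at micromolar protein
and $K_d \sim 10^{-6}$–$10^{-5}$ M, ligand depletion by binding is a
small correction and the free-ligand approximation follows standard
practice for this assay.

**Conditioning caveat.** The intercept of the double-log line sits at
$\log_{10}[L] = 0$ (1 M), roughly six decades beyond the titrated range,
so small slope errors are amplified exponentially into $K_a$. Monte-Carlo
experiments with the bundled generator show that 5% multiplicative
intensity noise produces order-of-magnitude scatter in $K_a$ from a
single 10-point series; at instrument-level noise (a few tenths of a
percent, typical of photon-counting fluorometers averaging multiple
scans) the median error is within about 15%. This is a property of the
double-log estimator itself — noise-free data are recovered to machine
precision — and is why practitioners run replicate titrations and report
condition averages.

## van't Hoff thermodynamics

Association constants measured at several temperatures are related by

$$\ln K_a = -\frac{\Delta H}{RT} + \frac{\Delta S}{R},$$

so regressing $\ln K_a$ on $1/T$ gives $\Delta H$ (slope $= -\Delta H/R$)
and $\Delta S$ (intercept $= \Delta S/R$), assuming $\Delta H$ is
temperature-independent over the narrow range used (no heat-capacity
term; curved van't Hoff models are out of scope). The Gibbs free energy
follows as $\Delta G = \Delta H - T\Delta S$, and independently as
$\Delta G = -RT\ln K_a$; the two coincide identically when $K_a(T)$
derives from constant $(\Delta H, \Delta S)$, which the test suite checks
to $10^{-9}$ kcal/mol.

The default gas constant is $R = 1.987204\times10^{-3}$ kcal/(mol K),
matching the kcal/mol convention of thermodynamic tables in this field; a
kJ mode is provided and rescales $\Delta H$ and $\Delta S$ by exactly
4.184. Condition summaries (`condition_summary()`) average $K_a$, $n$,
$T\Delta S$ and $\Delta G$ as unweighted arithmetic means over the
measurement temperatures — 295, 299 and 303 K by default — with standard
deviations as dispersion. Published summary tables in this area sometimes
print the *negative* entropic term ($-T\Delta S$) in the column labelled
$\langle T\Delta S\rangle$; ligbind always reports $T\Delta S$ with the
sign defined by $\Delta G = \Delta H - T\Delta S$, which the user can
negate for display.

## STD-NMR epitope maps

Saturation transfer difference NMR reports how closely each ligand proton
approaches the protein surface: protons within the transfer radius show a
larger difference intensity $I_{STD} = I_0 - I_{SAT}$ between
off-resonance and on-resonance spectra. The amplification factor is
$A_{STD} = I_{STD}/I_0$, and the epitope map normalizes per condition so
the strongest proton is exactly 100%:
$\mathrm{pct}_i = 100\,A_i/\max_j A_j$. The map is invariant under
positive rescaling and idempotent; normalization is per condition because
each experimental condition has its own saturation efficiency.

When only difference intensities are available (reference intensities not
recorded), the map is built from raw $I_{STD}$ — correct up to a
per-proton factor $I_0$; this limitation is inherited from the input, not
the method, and is the situation for typical published tables.
`compare_epitopes()` reports per-proton percentage changes between
conditions, counts of protons above a saturation threshold (default 90%),
and the Kendall rank concordance of the two orderings. Display rounding
is half-up to one decimal; full precision is kept internally.

## DLS cumulant analysis

A DLS instrument measures the intensity autocorrelation $g_2(\tau)$. For
dilute monodisperse spheres the Siegert relation gives
$g_2 - 1 = \beta e^{-2\Gamma\tau}$ with decay rate $\Gamma = Dq^2$, where
$q = (4\pi n/\lambda)\sin(\theta_s/2)$ is the scattering vector.
`cumulant_fit()` fits $\tfrac12\ln(g_2-1)$ against $\tau$ (adding a
$\mu_2\tau^2/2$ polydispersity term at order 2) and `analyze_trace()`
converts $\Gamma \to D \to d_H$ through the Stokes–Einstein relation
$d_H = k_BT/(3\pi\eta D)$.

Numerical choices: the fit uses only lags where $g_2-1$ exceeds 1% of the
intercept, avoiding logarithms of the noise-dominated tail, and weights
the log-domain residuals by $(g_2-1)^2$ — the delta-method variance of
$\ln g$ under additive correlation noise — which removes the small-signal
bias a naive log fit acquires (in Monte Carlo at noise SD 0.01 the mean
size bias drops from ~4% to ~0.4%). Both choices are inert for noise-free
traces, so generator→analyzer round trips are exact to $<10^{-6}$
relative error across 1–100 nm. Instrument defaults are a 90°, 633 nm
system with $n = 1.33$; water viscosity comes from a temperature
interpolation table (1.002×10⁻³ Pa s at 20 °C). Multimodal inversion
(CONTIN) and number/volume weighting are out of scope.

## Structural contact analysis

For protein–ligand poses in PDB format (single- or multi-model),
`contact_residues()` flags a residue as a contact when any of its heavy
atoms lies within a cutoff (default 3.4 Å) of any ligand heavy atom,
reporting minimum atom-pair distances; the implementation is verified
against an exhaustive all-pairs oracle on randomly generated complexes.
`hydrogen_bonds()` uses a distance-only criterion — protein N/O within
3.5 Å of a ligand oxygen — because docking and MD snapshot structures
frequently lack hydrogens, making angular criteria unreliable; this
over-counts relative to full geometric definitions and is documented as a
heuristic. `superpose_rmsd()` implements the Kabsch SVD superposition
(with the proper-rotation determinant correction) and
`radius_of_gyration()` the standard mass-weighted form. Multi-model files
are analyzed per model with `contact_frequency()` aggregating across the
ensemble.

## The synthetic-data generators

Every analysis stage ships with a generator producing inputs of known
ground truth, so correctness is established by round-trip recovery rather
than against unavailable raw instrument data:

* `gen_titration()` emulates the titration protocol: 2 μM protein in a
  2 mL cuvette, equal-volume additions of a 202 μM ligand stock until the
  ligand:protein mole ratio reaches 1:1 (≈1% cumulative volume change),
  at 295/299/303 K with $K_a(T)$ tied across temperatures by the van't
  Hoff relation anchored at a reference $K_a$ and $\Delta H$.
  Fluorescence is $F_0(1-\theta)$ times the dilution factor, attenuated
  by a linear-in-$[L]$ inner-filter absorbance, with multiplicative
  Gaussian noise truncated at zero. $F_0$ defaults to 10⁶ arbitrary
  units; spectra are Gaussian-shaped emission bands (peak 340 nm) over
  300–500 nm.
* `gen_std_table()` emits off/on-resonance intensity pairs from a true
  per-proton transfer profile; `gen_dls_trace()` emits a Siegert
  single-exponential trace for a chosen diameter on a log-spaced lag
  grid; `gen_toy_complex()` writes valid PDB text with exact control over
  which residues contact the ligand at which distance (contact atoms are
  placed in the ligand plane so that multi-model "drift" along +z
  strictly increases all distances).

All generators take an explicit seed, restore the caller's RNG state, and
are bit-for-bit reproducible. What they do *not* emulate: spectral shape
changes on binding (only amplitude quenching), NMR peak overlap or phase
errors, DLS dust spikes and multimodality, and real protein geometry —
passing round-trip tests therefore demonstrates correctness of the
analysis algebra and estimators, not robustness to every artifact of real
instruments.

## Problem sizes and test design

The test suite and acceptance script run generator-scale problems chosen
for statistical adequacy at interactive speed: 10-point titrations
(mirroring a realistic addition schedule), 200-lag DLS traces,
100-seed Monte-Carlo panels for noise studies, and 50 random complexes
for the contact oracle. Stochastic assertions use tolerances derived from
the measured Monte-Carlo distributions at fixed seeds (e.g. the median
worst-proton epitope deviation under 1% intensity noise is ~2.7
percentage points, asserted < 3), never from per-seed cherry-picking.

## Known limitations

* Free ligand is approximated by total ligand in the Hill fit; at
  protein concentrations approaching $K_d$ this biases $K_a$ upward.
* The van't Hoff analysis assumes temperature-independent $\Delta H$ over
  an 8 K window; three temperatures cannot detect curvature.
* Epitope maps built from $I_{STD}$ alone are exact only up to per-proton
  reference intensities.
* The H-bond detector is distance-only and heavy-atom based.
* The double-log $K_a$ estimator is ill-conditioned under intensity noise
  (see above); replicate averaging is the practical remedy.
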