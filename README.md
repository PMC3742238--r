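# SpecBind

Spectroscopic analysis of small-molecule binding to serum albumin (and
similar intrinsically fluorescent proteins), for researchers who
characterise drug-protein interactions by fluorescence titration, UV-vis
and circular dichroism rather than by calorimetry or crystallography.

## What it computes

From a titration of protein fluorescence with increasing ligand
concentration [Q], measured at several temperatures:

* **Corrections** — inner filter,
  F<sub>cor</sub> = F<sub>obs</sub> e^((A<sub>ex</sub>+A<sub>em</sub>)/2),
  and ligand self-absorbance, F = F<sub>u</sub> e^(±2.303 ε l L₀)
  (both sign conventions exposed).
* **Stern-Volmer**: F₀/F = 1 + K<sub>SV</sub>[Q];
  k<sub>q</sub> = K<sub>SV</sub>/τ₀ (τ₀ = 10⁻⁸ s default). Mechanism
  classification: static if K<sub>SV</sub> falls with temperature *and*
  k<sub>q</sub> exceeds the 2.0×10¹⁰ M⁻¹s⁻¹ diffusion ceiling, dynamic for
  the mirror image, else indeterminate.
* **Modified Stern-Volmer**: F₀/ΔF = (f<sub>a</sub>K<sub>a</sub>)⁻¹[Q]⁻¹ +
  f<sub>a</sub>⁻¹ — effective constant K<sub>a</sub> and accessible
  fraction f<sub>a</sub>.
* **Double logarithm**: log[(F₀−F)/F] = log K<sub>b</sub> + n log[Q] —
  binding constant and site number.
* **Van't Hoff**: ln K vs 1/T gives ΔH⁰ and ΔS⁰; ΔG⁰ = ΔH⁰ − TΔS⁰; the
  (ΔH⁰, ΔS⁰) sign pattern maps to the dominant binding forces
  (hydrophobic / electrostatic / H-bond + Van der Waals).
* **Energy transfer**: overlap integral
  J = ∫F(λ)ε(λ)λ⁴dλ / ∫F(λ)dλ (cm³ L mol⁻¹), Förster radius
  R₀⁶ = 8.79×10⁻²⁵ K² n⁻⁴ φ J, efficiency E = 1 − F/F₀, distance
  r = R₀((1−E)/E)^(1/6), with the r < 8 nm and 0.5R₀ < r < 1.5R₀ validity
  flags.
* **Circular dichroism**: MRE = θ<sub>obs</sub>/(10 C<sub>p</sub> n l);
  α-helix(%) = (−MRE₂₀₈ − 4000)·100 / 29000.

A synthetic-data generator (`simTruth()` and friends) produces titrations,
emission/absorptivity spectra, synchronous scans and CD spectra with known
ground truth, making every stage a parameter-recovery test; `runAnalysis()`
chains everything into one deterministic JSON report.

## Worked example

```r
library(SpecBind)

tr <- simTruth(seed = 1L)            # study-condition ground truth
s  <- makeTitration(tr, 288)         # 9-point titration at 288 K
fitSternVolmer(s)
#> SternVolmerFit (T = 288 K): Ksv = 4.773e+05 /M, kq = 4.773e+13 /M/s (tau0 = 1e-08 s), r = 1.0000
fitDoubleLog(s)
#> DoubleLogFit (T = 288 K): Kb = 4.773e+05 /M, n = 1.0000, r = 1.0000

report <- runAnalysis(defaultConfig(seed = 1L))
Ks <- sapply(report$quenching, function(q) q$double_log$Kb_per_M)
thermoAnalysis(c(288, 298, 308), Ks)
#> ThermoResult: dH = -24.02 kJ/mol, dS = 25.31 J/(mol K), r = 1.0000
#>   dG(288 K) = -31.31 kJ/mol
#>   dG(298 K) = -31.56 kJ/mol
#>   dG(308 K) = -31.82 kJ/mol
#>   forces: hydrophobic + electrostatic
```

Reading: K<sub>SV</sub> ≈ 4.8×10⁵ M⁻¹ at 288 K falls to 2.5×10⁵ at 308 K
while k<sub>q</sub> ≈ 10¹³ M⁻¹s⁻¹ dwarfs the diffusion limit, so quenching
is static (complex formation); the negative ΔG⁰ values mean spontaneous
binding, and the exothermic ΔH⁰ with positive ΔS⁰ points to combined
hydrophobic and electrostatic stabilisation. The recovered site number
n ≈ 1 indicates a single binding site.

```r
fretAnalysis(makeDonorEmission(tr), makeLigandAbsorptivity(tr),
             F = 90.72, F0 = 100)
#> FretResult: J = 1.077e-14 cm^3 L/mol, R0 = 2.553 nm, E = 0.0928, r = 3.733 nm
#>   r < 8 nm: TRUE; 0.5 R0 < r < 1.5 R0: TRUE
```

The donor-acceptor distance sits well under 8 nm and inside the informative
0.5R₀-1.5R₀ window, consistent with non-radiative energy transfer to a
ligand bound near the fluorescing tryptophan.

A thin command-line wrapper lives at `inst/scripts/specbind.R`
(`simulate` / `analyze` / `report` subcommands over YAML configs); the R
functions are the primary interface.

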