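---
title: "Quantifying ligand-protein binding from titration spectroscopy"
author: "SpecBind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ligand-protein binding from titration spectroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpecBind)
```

## The experiment and the model

Serum albumin carries an intrinsic tryptophan fluorescence band near 340 nm
(excitation 280 nm). When a small molecule binds, that fluorescence is
quenched, and the concentration- and temperature-dependence of the quenching
encodes the binding constant, the stoichiometry, the thermodynamic driving
forces and even the donor-acceptor distance. SpecBind implements this whole
chain of analysis for titration data: a fixed protein concentration
(3&times;10^-7^ M in the emulated design) titrated with successive ligand
additions up to roughly 1.6&times;10^-6^ M, measured at 288, 298 and 308 K.

### Intensity corrections

Raw intensities are corrected before any fit.

* **Inner filter**: absorbance at the excitation and emission wavelengths
  attenuates the measured signal; the standard correction is
  $F_\mathrm{cor} = F_\mathrm{obs}\, e^{(A_\mathrm{ex}+A_\mathrm{em})/2}$
  (`correctInnerFilter()`).
* **Ligand absorbance**: the titrated ligand itself absorbs, corrected as
  $F = F_u\, e^{\pm 2.303\,\varepsilon\, l\, L_0}$
  (`correctLigandAbsorbance()`). The published convention carries a
  *negative* exponent, which attenuates rather than amplifies; because the
  two sign conventions circulate in the literature, both are exposed
  (`sign = "as_printed"`, the default, and `"inverted"`), and they compose
  to the identity. The absorptivity $\varepsilon$ is taken at the
  excitation wavelength by default, since the ligand's absorption there
  dominates the effect on excitation light.

### Quenching linearizations

With corrected intensities $F$ and the zero-quencher intensity $F_0$, three
ordinary-least-squares linearizations are fitted per temperature, exactly as
these data are conventionally plotted:

* Stern-Volmer: $F_0/F = 1 + K_\mathrm{SV}[Q]$; slope $K_\mathrm{SV}$,
  free intercept reported, $k_q = K_\mathrm{SV}/\tau_0$ with
  $\tau_0 = 10^{-8}$ s by default (tryptophan lifetime order of magnitude;
  overridable).
* Modified Stern-Volmer: $F_0/\Delta F = \frac{1}{f_a K_a}[Q]^{-1} +
  \frac{1}{f_a}$; accessible fraction $f_a$ = 1/intercept, $K_a$ =
  intercept/slope.
* Double logarithm: $\log\frac{F_0-F}{F} = \log K_b + n\log[Q]$; binding
  constant $K_b$ and site number $n$.

Unweighted least squares on the transformed variables is deliberate: it
reproduces the field's standard plots, and error propagation through the
transformations is out of scope. $[Q]$ is the *total* added ligand
concentration, not corrected for the bound fraction, again following
standard practice; on synthetic data generated from the same convention the
linearizations are exact.

The quenching **mechanism** is classified from the temperature trend and
the magnitude of $k_q$: static (ground-state complex) when $K_\mathrm{SV}$
falls strictly with temperature and every $k_q$ exceeds the
diffusion-controlled ceiling of 2.0&times;10^10^ M^-1^s^-1^; dynamic
(collisional) for the mirror-image pattern; anything else is reported
indeterminate with the failed condition named. The trend test is strict by
default; a relative tolerance is exposed for noisy data.

### Thermodynamics

Van't Hoff regression of $\ln K$ on $1/T$ gives $\Delta H^0 = -R\cdot$slope
and $\Delta S^0 = R\cdot$intercept ($R$ = 8.314 J mol^-1^K^-1^), assuming
$\Delta H^0$ constant over the 20 K window. $\Delta G^0 = \Delta H^0 -
T\Delta S^0$ is evaluated at each temperature. Which constant feeds the
regression is configurable (`vant_hoff_source`); the default is $K_b$, the
binding constant proper. The sign pattern of $(\Delta H^0, \Delta S^0)$
maps to the dominant non-covalent forces by the conventional rule table
(`classifyForces()`); the "enthalpy near zero" band for the electrostatic
assignment is a parameter (default 2 kJ/mol) because no canonical numeric
threshold exists.

Published multi-temperature binding tables are not always exactly
reproducible by this regression: least squares on one published
three-temperature $K_b$ series gives $\Delta H^0 \approx -24.8$ kJ/mol and
$\Delta S^0 \approx 33.3$ J mol^-1^K^-1^ where the source's own table
prints $-24.02$ and $25.31$. SpecBind reports what it computes and does not
force agreement; both routes (regression on constants, and Gibbs evaluation
from a stated $\Delta H^0/\Delta S^0$ pair) are available.

### Energy transfer distance

The overlap integral
$J = \int F(\lambda)\,\varepsilon(\lambda)\,\lambda^4 d\lambda \big/ \int
F(\lambda)\,d\lambda$ is evaluated by trapezoid on the union grid of the
two spectra over their common support, with $\lambda$ converted to cm *only
inside this integral*, so $J$ carries cm^3^ L mol^-1^. Then
$R_0^6 = 8.79\times10^{-25} K^2 n^{-4} \phi J$ (CGS convention consistent
with $J$ in cm^3^ L mol^-1^), $E = 1 - F/F_0$, and
$r = R_0\left(\frac{1-E}{E}\right)^{1/6}$, with validity flags $r < 8$ nm
and $0.5R_0 < r < 1.5R_0$. Defaults $K^2 = 2/3$, $n = 1.36$, $\phi = 0.15$
are the conventional tryptophan-donor values and are all overridable.

A caution on units: some published applications of this formula quote $J$
in cm^3^ L mol^-1^ but apparently evaluate $R_0$ under a different unit
convention (e.g. $J$ in nm^4^ M^-1^cm^-1^), which changes $R_0$ by a large
factor. SpecBind evaluates the formula literally and self-consistently in
the CGS convention; the test suite pins the arithmetic with an independent
fine-grid quadrature oracle rather than any single published triple of
$(J, R_0, r)$.

In the pipeline, $E$ for the study design is taken at the equimolar point
(acceptor concentration equal to the 3&times;10^-7^ M donor), interpolated
from the fitted Stern-Volmer line at the configured temperature.

### Circular dichroism

Observed ellipticity in millidegrees is normalised to mean residue
ellipticity, $\mathrm{MRE} = \theta_\mathrm{obs} / (10\, C_p\, n\, l)$
(residue count $n$ = 583 for bovine serum albumin), with the 208 nm value
read off by linear interpolation — instrument grids rarely hit 208.00 nm
exactly, and interpolation keeps the estimate deterministic. Helix content
follows the two-point calibration
$\alpha(\%) = \frac{(-\mathrm{MRE}_{208} - 4000)\times 100}{33000 - 4000}$,
where $-4000$ and $-33000$ deg cm^2^ dmol^-1^ are the random-coil and
pure-helix references at 208 nm. The 222 nm band is characteristic of
helix and visible in the basis shapes, but quantification uses 208 nm only,
mirroring the source analysis. Raw values outside [0, 100] (possible on
noisy data) are preserved alongside the clamped report value.

## The synthetic-data generator

No public spectra exist for this experimental design, so `simTruth()` and
its `make*()` companions generate every input with known ground truth:

* **Titrations** follow the static complexation law
  $F = F_0/(1 + K(T)[Q]^n)$ with $K(T)$ generated through the Van't Hoff
  relation from the truth's $\Delta H^0/\Delta S^0$ — by default the
  exothermic pair ($-24020$ J/mol, $25.31$ J mol^-1^K^-1^), so $K$ falls
  with temperature as in static quenching. The *observed* intensities are
  the true ones attenuated by the exact inverse of the two corrections, so
  the correction chain recovers truth exactly; this makes every fit a
  parameter-recovery test. `dynamicPreset()` provides the opposite regime
  (K rising with T, $k_q$ below the diffusion ceiling) for classifier
  tests; its millimolar quencher range and small K are what place $k_q$ in
  the collisional window.
* **Spectra** are Gaussian bands on a 1 nm, 200-500 nm grid: a donor
  emission band at 340 nm (sd 15 nm, peak 1000 a.u.) and ligand
  absorptivity bands at 220 and 340 nm (peaks 18000 and
  10000 M^-1^cm^-1^, sds 12 and 20 nm). Band centres are the emulated
  system's; widths and amplitudes are chosen once as instrument-realistic
  values of the right order for a flavonoid and are free parameters, not
  calibrated to any measurement. Excitation/emission absorbances are
  derived from the ligand spectrum alone (the dominant titrated absorber).
* **Synchronous scans** at &Delta;&lambda; = 15/60 nm reuse the same
  quenching factor with a configurable peak shift per titration step
  (default 0: no microenvironment change).
* **CD spectra** are two-state mixtures of a helix basis (negative bands at
  208 and 222 nm, pinned to $-33000$ at 208 nm) and a coil basis (pinned
  to $-4000$), converted to millidegrees by inverting the MRE
  normalisation, so `mre()` + `helixPercent()` round-trip the generating
  fraction exactly.
* **Noise** is multiplicative Gaussian on intensities, `1 + noise_rel * z`,
  driven by a single integer seed (per-temperature offset so different
  temperatures draw independent noise). Identical truth gives
  byte-identical CSV exports.

What the generator does *not* emulate — photobleaching, scatter baselines,
instrument drift, free-ligand depletion at high binding, wavelength-dependent
detector response — bounds what passing tests show: they demonstrate that
the analysis chain recovers parameters exactly from data that obey its own
model assumptions and degrades gracefully (relative RMSE on
$K_\mathrm{SV}$ about 2% at 1% intensity noise with 9 points), not that
those assumptions hold for any given instrument.

## Numerical choices

* Trapezoidal quadrature on the native grid, no splines or smoothing:
  deterministic, and adequate on ~1 nm instrument grids (grid-halving tests
  bound the error below 0.1% for smooth bands).
* Linear interpolation for resampling and point evaluation; integration
  windows interpolate their endpoints so sub-grid bounds are exact for
  piecewise-linear integrands.
* Spectral peak ties break toward the shorter wavelength; an all-flat
  window returns its lower bound flagged `flat` — both for deterministic
  peak-shift reports.
* Fits error out (naming the offending point) rather than silently dropping
  nonpositive $\Delta F$; a nonpositive modified-Stern-Volmer slope flags
  the fit invalid instead of returning a negative constant.
* All internal energies are J/mol; the report layer converts to kJ/mol.
  Wavelengths are nm everywhere except inside the overlap integral.
* JSON reports are serialised with fixed key order and 15 significant
  digits and carry no timestamps, so identical configuration and seed give
  byte-identical files (the determinism contract is tested).

## Problem sizes used in the test suite

The packaged tests run the full design: 9-point titrations at three
temperatures, 301-point spectra, 101-point CD grids, and 200 replicate
fits for the noise study — the same sizes the emulated experiment uses, so
the suite completes in seconds.

## A worked run

```{r example, eval = FALSE}
report <- runAnalysis(defaultConfig(seed = 1L))
report$mechanism$mechanism          # "static"
report$thermo$van_t_hoff            # dH ~ -24.02 kJ/mol, dS ~ 25.31 J/(mol K)
report$cd$table                     # helix percents 56.5 / 54.1 / 51.5 / 44.2
```

## Known limitations

* Single-wavelength intensity fits: the band maximum (or supplied scalar)
  stands in for the full emission spectrum.
* No global multi-temperature fitting, no weighted regression, no lifetime
  (time-resolved) analysis.
* Helix quantification is the two-point 208 nm calibration, not a full
  secondary-structure deconvolution.
* The orientation factor $K^2 = 2/3$ assumes isotropic dynamic averaging;
  no attempt is made to model it.
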