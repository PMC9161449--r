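---
title: "Models and methods behind corefuc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind corefuc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corefuc)
```

corefuc implements the quantitative stages used to characterize FUT8, the
α1,6-fucosyltransferase responsible for core fucosylation of N-glycans: enzyme
kinetics from luminescence GDP-release assays, one-site ITC thermodynamics,
STD NMR epitope mapping, NOESY-derived inter-proton distances, and
site-specific glycopeptide composition analysis. This vignette documents the
models, their assumptions, the tunable parameters, and the design choices the
package makes where the underlying experimental procedures leave them open.

## Enzyme kinetics

The GDP-release assay reports enzyme turnover as luminescence proportional to
the GDP produced. Three stages convert raw signals into kinetic constants:

1. **Calibration.** An ordinary least-squares line relates luminescence to
   pmol GDP (`fit_standard_curve`). The slope must be positive; R² is
   reported. Inversion of the line converts assay signals to product amounts.
2. **Hydrolysis correction.** GDP-fucose hydrolyzes slowly even without an
   acceptor, so the mean of the no-acceptor blank is subtracted from every
   calibrated signal (`correct_and_convert`). The correction assumes the
   hydrolysis rate is independent of acceptor concentration, which is why a
   single blank suffices. Negative corrected values (possible at low signal)
   are clipped to zero with a warning. Velocities are normalized to
   nmol·min⁻¹·mg⁻¹ using the incubation time and the enzyme mass implied by
   its concentration, the reaction volume and its molar mass (defaults:
   100 nM, 10 µL, 30 min).
3. **Nonlinear fit.** `fit_michaelis_menten` fits v = Vmax·S/(Km+S) by
   Levenberg–Marquardt least squares on the pooled replicate points —
   replicates are not averaged first, preserving the error structure.
   Starting values are Vmax⁰ = max(v) and Km⁰ interpolated as the
   concentration at half of Vmax⁰, a robust default for hyperbolic data.

**kcat conversion.** Vmax in per-mg units converts to a turnover number via
kcat = Vmax · M · 10⁻⁶ with M the enzyme molar mass in g/mol. M is an explicit
input: the reference kinetic table is internally consistent with
M ≈ 58 kg/mol (two of its three saturable rows give 58.0 exactly; the third
implies 55.4), so 58000 is the package default. Catalytic efficiency is
kcat/Km, reported at two decimals to match reference precision.

**Saturability.** Some acceptors never saturate the enzyme over the tested
range; velocity grows linearly in concentration and the hyperbola is
unidentifiable. Rather than report a meaningless Km, the fit is declared
non-saturable when the estimated Km exceeds 5× the largest tested
concentration or its standard error is unbounded. This operationalizes the
qualitative "could not be fitted" outcome; the multiplier 5 is a judgment
call — beyond it the data constrain only the ratio Vmax/Km.

## ITC one-site binding

Integrated injection heats are fitted to the standard single-site
(Wiseman) closed form. After injection *i* with cumulative injected volume
ΔV, total concentrations in the cell of volume V₀ are corrected for the
displaced volume (Mt = M₀(1 − ΔV/2V₀)/(1 + ΔV/2V₀);
Xt = X₀(ΔV/V₀)(1 − ΔV/2V₀)), the cumulative heat follows the quadratic-root
bound fraction, and per-injection heats are obtained by differencing with the
(vᵢ/V₀)(Qᵢ+Qᵢ₋₁)/2 displacement term. This is the model vendor software fits;
here it is authored explicitly so that generation and fitting share one
closed form and noiseless round trips are exact.

Design choices:

- **Dilution heat** is a constant per-mole-of-injectant offset co-fitted with
  the binding parameters, rather than subtracted from a separate blank
  titration — the simplest model consistent with per-injection heat tables.
- **Kd is fitted on the log scale**, guaranteeing positivity; its SE is
  delta-method transformed back. Four start values of Kd (0.01–10× the cell
  concentration) guard against local minima; the best-SSE fit wins.
- **"Not measurable" binding.** A flat heat series, or a fitted |ΔH| below 3×
  its standard error, is reported as not measurable instead of returning
  meaningless constants — mirroring how very weak binders are reported.
- **Temperature** defaults to 298.15 K (25 °C) and enters only the Gibbs
  dissection.

`thermo_dissection` computes ΔG = RT·ln(Kd·10⁻⁶) with
R = 1.9872×10⁻³ kcal·mol⁻¹·K⁻¹ and −TΔS = ΔG − ΔH, so ΔG = ΔH + (−TΔS) holds
to machine precision by construction. The driving-force label is
entropy-driven when the entropic term dominates and is favorable,
enthalpy-driven when the enthalpic term dominates and is favorable, and mixed
otherwise; the underlying experimental reports use qualitative language, so
these thresholds are the package's explicit operationalization.

## STD NMR epitope mapping

STD amplitudes grow with saturation time as
STD(t) = STDmax(1 − e^(−ksat·t)). The epitope map is built from **build-up
rates** STDmax·ksat — the initial slopes — not from STD values at any single
saturation time, because single-time values are biased by differential T1
relaxation. Rates are normalized so the strongest proton is exactly 100%.
Spectrally overlapping protons are summed pointwise into a pseudo-proton
before fitting (`merge_overlapping`; averaging is available via
`method = "mean"`). Comparison across conditions (±GDP) uses the
un-normalized rates, since normalization hides uniform changes; a flag
reports when every shared proton's rate increased.

Initialization: STDmax⁰ = max amplitude, ksat⁰ = 1/(time at half-max). A
series with no overall build-up (non-positive regression slope) becomes a
null fit and is excluded from the map rather than erroring.

## NOESY distances by ISPA

Cross-peak integrals versus mixing time are linear at short times with slope
σ ∝ r⁻⁶. `initial_slope` finds the "linear initial part" automatically:
starting from the minimal 3 points, the prefix grows while its linear-fit R²
stays ≥ 0.99 and stops at the first violation, so the window never reaches
into the saturating regime. The threshold is configurable; 0.99 is strict
enough to reject visible curvature on 4–6 points yet tolerant of integral
noise. A fixed window in ms can be supplied instead.

`ispa_distance` applies r = r_ref·(σ_ref/σ)^(1/6). Reference distances are
**inputs** (they come from MD simulations in practice); the package never
computes them, keeping molecular dynamics out of scope. Because the exponent
is 1/6, distances are extremely robust: a 2% slope error moves a 2.6 Å
distance by under 0.01 Å. Conformer calling (`call_conformer`) votes each
pair for the nearer of user-supplied expected syn/anti distances; a split
vote, or any pair farther than the tolerance (default 0.3 Å) from both
expectations, yields "ambiguous". No stereochemical table is hard-coded.

## Glycopeptide composition assignment

`decompose_mass` enumerates all compositions over the building blocks Hex
(162.05282), HexNAc (203.07937), dHex (146.05791), NeuAc (291.09542) and
phosphate (79.96633 Da) whose theoretical mass (peptide + blocks) matches the
observed neutral mass within the ppm tolerance (default 5 ppm, computed
against the theoretical mass). The enumeration is depth-first with
branch-and-bound on the remaining mass window and is exact: tests verify it
against a full Cartesian-product oracle. Default count bounds (Hex ≤ 9,
HexNAc ≤ 7, dHex ≤ 2, NeuAc ≤ 4, P ≤ 2) reflect mammalian N-glycan biology
and are configurable. Ties in |ppm error| are broken lexicographically on the
count vector so results are deterministic. Compositions cannot distinguish
isobaric structures; structure names ("biantennary") are annotation only.

Glycosites are located by the +0.98402 Da deamidation delta left by PNGase F:
peptides whose deamidated yield rises beyond a fold threshold (default 2)
after treatment are flagged. Site-level quantification follows the top-N
rule: fractions are intensity shares over the N (default 5) most intense
assigned features at the site, and the core-fucosylated fraction is the share
of features carrying ≥ 1 dHex. The targeted-MS/MS candidate depth (10–15)
and the quantification depth (5) are distinct parameters; the package
defaults to 5 for the denominators and exposes both.

## Synthetic data: what it emulates, and what it does not

Every generator produces data with the statistical structure the assays
assume, plus a ground-truth sidecar for recovery testing:

- kinetics: hyperbolic velocities + constant hydrolysis background, rendered
  as luminescence through the standard curve and assay geometry;
- ITC: Wiseman per-injection heats with optional constant dilution offset;
- STD: mono-exponential build-ups; NOESY: r⁻⁶-scaled slopes, exactly linear
  inside a configurable window and exponentially saturating beyond it;
- glyco-MS: protonated-adduct m/z at charges {2,3} with Gaussian ppm error
  and log-normal intensities scaled to requested fractions.

Noise models: multiplicative Gaussian (CV-parameterized) for kinetics, STD
and NOE intensities — matching roughly constant relative instrument error and
preserving positivity at low CV — and additive Gaussian in heat units for
ITC, where baseline noise dominates. Replicate noise magnitudes are not
published for these assays; the default CV of 3% is a typical plate-reader /
integral scatter and is configurable, not a claim. `Vmax = 0` is accepted as
the degenerate zero-signal case (only negative rates are rejected), so the
no-activity control scenario can be generated.

Passing recovery tests on these generators demonstrates the estimators are
correct for data obeying the stated models. Real instrument data additionally
contain baseline drift, integration error, spin diffusion (NOESY), partial
saturation transfer pathways (STD), isotopologue interference and
co-elution (MS) — none of which are emulated, so recovery here bounds, but
does not guarantee, performance on raw experimental data.

## Problem sizes and numerical choices

The validation suites use the study's own designs: 8 acceptor concentrations
spanning 5–1000 µM with duplicates for kinetics (200 simulated datasets at 3%
CV for the recovery study), 19 × 2 µL injections into a 200 µL cell at 70 µM
macromolecule for ITC (50 noisy replicates at 2% heat noise), 7 saturation
times (0.5–5 s) for STD, 10 mixing times (100–1500 ms) for NOESY, and
100 oracle-checked masses for the decomposition. Nonlinear fits run with
tight convergence tolerances (ftol = ptol ≈ 1e-14) so noiseless round trips
recover parameters to ~1e-9 relative error. All randomness flows through
`scenario_config(seed)`; fixed seeds give byte-identical outputs.

## Known limitations

- The kinetics module fits one substrate at a time (the other held
  saturating); no bi-substrate or inhibition models.
- The ITC module assumes integrated heats are given; raw power traces,
  multi-site and displacement titrations are out of scope.
- STD analysis does not model full relaxation pathways (no Corcema-ST) and
  cannot resolve overlapped protons except by merging.
- ISPA ignores spin diffusion; it is reliable only for short mixing-time
  slopes, which the auto-window is designed to isolate.
- Glycopeptide assignment is composition-level and assumes deisotoped,
  singly-protonated-per-charge features; no MS/MS scoring or FDR control.
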