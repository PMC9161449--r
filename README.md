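# corefuc

Quantitative analysis of FUT8 core-fucosylation assays in R.

FUT8 is the α1,6-fucosyltransferase that transfers fucose from GDP-fucose
onto the innermost GlcNAc of N-glycans ("core fucosylation"), a modification
with major consequences for antibody function and cancer biology. Studying
how FUT8 recognizes its acceptor substrates requires combining several
quantitative readouts, and this package implements the complete analysis
stack for them:

- **Enzyme kinetics** (`fit_standard_curve`, `correct_and_convert`,
  `fit_michaelis_menten`): luminescence-based GDP-release assays are
  calibrated through a GDP standard curve, corrected for donor hydrolysis via
  the no-acceptor blank, and fitted to v = V<sub>max</sub>·S/(K<sub>m</sub>+S)
  by nonlinear least squares, with k<sub>cat</sub> and k<sub>cat</sub>/K<sub>m</sub>
  derived. Substrates the enzyme cannot saturate are detected and reported as
  non-fittable rather than forced through the hyperbola.
- **ITC one-site binding** (`fit_one_site`, `thermo_dissection`): integrated
  injection heats are fitted to the Wiseman one-site closed form (with
  displaced-volume correction and a co-fitted dilution offset), and the
  binding free energy is dissected as
  ΔG = RT·ln K<sub>d</sub> = ΔH + (−TΔS), labelling each interaction
  enthalpy- or entropy-driven.
- **STD NMR epitope mapping** (`fit_buildup`, `build_epitope_map`,
  `compare_conditions`): per-proton saturation-transfer build-up curves
  STD(t) = STD<sub>max</sub>·(1 − e<sup>−k<sub>sat</sub>t</sup>) are fitted,
  and initial build-up rates STD<sub>max</sub>·k<sub>sat</sub> are normalized
  to the strongest proton (= 100 %) to map which parts of a glycopeptide
  ligand touch the protein, with and without bound GDP.
- **NOESY / ISPA distances** (`initial_slope`, `ispa_distance`,
  `call_conformer`): initial slopes of NOE build-up curves are converted to
  inter-proton distances by the isolated spin pair approximation
  r = r<sub>ref</sub>·(σ<sub>ref</sub>/σ)<sup>1/6</sup>, and the glycosidic
  ψ conformer (*syn*/*anti*) is called against supplied reference geometry.
- **Glycopeptide MS** (`decompose_mass`, `assign_glycopeptides`,
  `site_report`): precursor features are assigned glycan compositions by
  exhaustive bounded enumeration over Hex/HexNAc/dHex/NeuAc/phosphate within
  a 5 ppm tolerance, glycosites are located via the +0.98402 Da PNGase F
  deamidation delta, and per-site glycoform and core-fucosylated fractions
  are quantified over the top-5 most intense features.

A synthetic-data module (`gen_kinetics_dataset`, `gen_itc_titration`,
`gen_std_buildup`, `gen_noe_buildup`, `gen_glycopeptide_features`) generates
every input class under seeded, ground-truth-tagged conditions, so each
fitting stage can be validated by parameter recovery.

## Worked example

Simulate a kinetics experiment at the published G0 parameters
(K<sub>m</sub> = 113.1 µM, V<sub>max</sub> = 282.1 nmol·min⁻¹·mg⁻¹) with a
hydrolysis background, then run the full calibration → correction → fit
pipeline:

```r
library(corefuc)

cfg <- scenario_config(seed = 1, noise_cv = 0)
ds  <- gen_kinetics_dataset(Km = 113.1, Vmax = 282.1,
                            acceptor_concs = c(5, 10, 25, 50, 100, 250, 500, 1000),
                            hydrolysis_rate = 5, config = cfg)
cal <- fit_standard_curve(ds$standard_curve$gdp_pmol,
                          ds$standard_curve$luminescence)
fit <- fit_michaelis_menten(correct_and_convert(ds, cal))
fit
#> Michaelis-Menten fit
#>   Km   = 113.1 +/- 1.84e-14 uM
#>   Vmax = 282.1 +/- 1.39e-14 nmol min^-1 mg^-1
#>   kcat = 16.36 +/- 8.08e-16 min^-1  (M = 58000 g/mol)
#>   kcat/Km = 0.145 min^-1 uM^-1
```

The hydrolysis background is removed exactly by the no-acceptor blank and
both parameters are recovered. Thermodynamics of GDP binding
(K<sub>d</sub> = 6.1 µM, ΔH = −5.02 kcal/mol at 25 °C):

```r
thermo_dissection(Kd = 6.1, dH = -5.02)
#> Kd 6.1 uM at 298.15 K: dG = -7.114, dH = -5.020, -TdS = -2.094 kcal/mol (enthalpy-driven)
```

ΔG from K<sub>d</sub> is −7.11 kcal/mol, the entropic penalty −TΔS is
−2.09 kcal/mol, and GDP binding is classified enthalpy-driven — in contrast
to the acceptor glycans, whose binding is entropy-driven.

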