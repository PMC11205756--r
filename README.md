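# algadens

Spectroscopy-based estimation of algal density for dense microalgal
cultures (developed around *Chlorella vulgaris*).

Monitoring biomass in photobioreactors and high-rate algae ponds needs a
measurement that is fast and non-destructive. Optical density (OD) is
both, but for dense green-algae suspensions it is **not** linear in
concentration: once cells start shading one another, each added cell
contributes less absorbance. `algadens` packages the full calibration
workflow for that regime, for people running algal cultivation,
ecotoxicology, or wastewater-treatment labs:

- **Spectra handling** — read two-column UV–Vis scans, average
  replicates, subtract the distilled-water blank, interrogate OD at any
  wavelength (`spectrum()`, `spectra_set()`, `od_at()`).
- **Correlation scanning** — at every wavelength of a 1 nm grid, regress
  absorbance on a laboratory density parameter (biomass by filtration or
  evaporation, chlorophyll a, Mg, cell count, fluorescence) across a
  dilution series, and pick the wavelength with the highest R²
  (`scan_wavelengths()`, `best_wavelength()`).
- **Saturating calibration** — fit the shading model
  *A = A*<sub>max</sub> (1 − e<sup>−*k c*</sup>) (the Box–Lucas form of
  the Bouguer–Lambert–Beer law for mutually shading particles) and
  invert it into a biomass estimator
  *c* = ln(1 − *A*/*A*<sub>max</sub>)/(−*k*)
  (`fit_box_lucas()`, `estimate_biomass_od440()`). The shipped default
  constants (*A*<sub>max</sub> = 3.29, *k* = 0.0022 L/mg at 440 nm) are a
  published *C. vulgaris* calibration; they are culture- and
  instrument-specific, so refit them for your own system.
- **Derived composition** — Mg content per 100 g dry matter, chlorophyll
  a implied by Mg through the molar-mass ratio 36.77 (one Mg atom per
  chlorophyll a molecule), and average single-cell weight
  (`summarize_derived()`), plus best-trendline pairwise correlations
  (`pairwise_correlations()`).
- **Cell counting** — a semiautomated counting-chamber pipeline:
  rolling-ball-style background subtraction, 8-bit conversion, 0–200
  thresholding, size-filtered particle analysis, and conversion to
  cells/L from the chamber geometry (`count_pipeline()`).
- **Synthetic data** — generators for saturating spectra, dilution
  series, and counting-chamber scenes with known ground truth
  (`synth_dilution_series()`, `synth_scene()`), so the whole toolchain is
  testable without instrument data.

A reference dilution series of a dense *C. vulgaris* culture (10
dilutions, six laboratory parameters, below-detection flags) ships as a
packaged fixture: `chlorella_series()`.

## Worked example

```r
library(algadens)

## one-line biomass estimate from a 440 nm reading
estimate_biomass_od440(0.65)
#> [1] 100.0494        # mg dry matter per litre

## which wavelength calibrates best? (synthetic series, known truth)
sim <- synth_dilution_series(noise_sd = 0, seed = 1)
scan_wavelengths(sim$set, sim$series, "bme")
#> Correlation scan for 'bme': 801 wavelengths (300-1100 nm), n = 10
#>   max R-squared 0.9465 at 914 nm

## linear vs saturating calibration on a noisy saturating series
conc <- 1080 * c(1, .5, .2, .1, .05, .02, .01, .005, .002, .001)
set.seed(1)
od <- saturation_absorbance(conc) * (1 + rnorm(10, 0, 0.01))
compare_models(conc, od)
#> Calibration model comparison
#>   linear:     R2 = 0.924900
#>   saturating: R2 = 0.999969 (A_max = 3.262, k = 0.00223)
#>   preferred:  saturating

## composition quantities from the packaged reference series
summarize_derived(chlorella_series())
#> Derived quantities (dilutions up to 10x):
#>  dilution   bme    mg mg_per_100g chla_from_mg   chla       cn cell_weight
#>         1 960.0 204.5       21.30         7519 7515.6 108222.7       8.871
#>         2 436.7 109.6       25.10         4030 4163.1  61578.1       7.092
#>         5 150.0  27.6       18.40         1015 1567.0  34113.3       4.397
#>        10  66.7  10.6       15.89          390  892.4  13136.7       5.077
#> Mg content:  20.17 +/- 3.96 mg/100 g d.m.
#> Cell weight: 6.359 +/- 2.028 ug/10^6 cells

## counting a synthetic chamber image with known ground truth
sc <- synth_scene(scene_config(n_cells = 80, noise_sd = 5/255), seed = 11)
count_pipeline(sc$image)
#> Cell count: 80 particles on 0.64 mm^2 (depth 0.10 mm, dilution 1x)
#>   1.25e+09 cells/L
#>   particle area: median 47 px (range 12-131)
```

Reading the output: the scan's R² maximum marks the wavelength where a
single-wavelength calibration is most informative for that parameter;
the model comparison shows why a straight line underfits a series that
runs deep into mutual shading (R² 0.925 vs 0.99997); the derived table
gives, per dilution, the Mg content of the dry biomass (mg/100 g), the
chlorophyll a predicted from Mg alone (µg/L, to be compared with the
measured `chla` column), and the weight of one million cells (µg); and
the count result converts 80 particles found on 0.064 µL of chamber
volume into a concentration.

A command-line front end covering the same operations is installed at
`inst/cli/algadens` (subcommands `scan`, `calibrate`, `estimate`,
`correlate`, `derive`, `count`, `simulate`, `report`).

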