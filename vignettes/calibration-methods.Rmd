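---
title: "Methods: saturating OD calibration, correlation scanning, and chamber counting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: saturating OD calibration, correlation scanning, and chamber counting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(algadens)
```

## The measurement problem

Optical density is the workhorse proxy for microalgal biomass because a
spectrophotometer reading takes seconds and consumes nothing. For dilute
suspensions OD is proportional to concentration (the Beer–Lambert
regime), but production cultures of *Chlorella vulgaris* are dense
enough that cells shade one another: each added cell intercepts light
that another cell would have absorbed anyway, so OD rises ever more
slowly with concentration and approaches a ceiling. A linear calibration
fitted through such data is biased exactly where production monitoring
needs it most — at high density.

## The saturating calibration model

The package's central model treats the loss of marginal absorbance as
proportional to the remaining headroom,

$$\frac{dA}{dc} = k\,(A_{\max} - A),$$

whose solution with $A(0) = 0$ (pure solvent) is

$$A(c) = A_{\max}\,\bigl(1 - e^{-k c}\bigr).$$

Here $A$ is blank-corrected optical density (dimensionless), $c$ is
biomass concentration in mg dry matter per litre, $A_{\max}$ (> 0,
dimensionless) is the asymptotic absorbance when cells fully shade one
another (typically 3–4 absorbance units, instrument-limited), and $k$
(> 0, L per mg d.m.) is the specific light absorption coefficient
setting how fast the ceiling is approached. In the dilute limit the
model reduces to the familiar proportionality with slope
$A_{\max} k$. The inverse,

$$c = \frac{\ln\!\left(1 - A/A_{\max}\right)}{-k},$$

is the biomass estimator (`estimate_biomass_od440()`). It is undefined
at $A \ge A_{\max}$; the package signals this as "beyond the calibrated
range, dilute the sample" rather than extrapolating. The shipped
defaults $A_{\max} = 3.29$, $k = 0.0022$ come from a 440 nm calibration
of one *C. vulgaris* culture on one instrument; both are culture-,
instrument- and wavelength-specific, which is why every estimator
accepts user-fitted constants and why `fit_box_lucas()` exists.

### Fitting: variable projection

`fit_box_lucas()` minimizes the residual sum of squares of
$y = a(1 - e^{-bx})$. Two numerical facts shape the implementation:

1. For data confined to the near-linear regime only the product $ab$ is
   well identified; a 2-D optimizer crawls along the ridge
   $ab = \text{const}$ and stalls.
2. Given $b$, the optimal $a$ is a closed-form linear least-squares
   coefficient.

The fit therefore profiles $a$ out and minimizes the 1-D profiled sum
of squares over $b > 0$ with `stats::nlminb` (relative tolerance
$10^{-10}$, at most 500 iterations). The start is $a_0 = 1.05 \max(y)$
and $b_0$ from an ordinary least-squares fit of the linearization
$-\ln(1 - y/a_0)$ on $x$. On exactly noiseless data the optimizer may
report "false convergence" because the objective is flat at machine
precision around the optimum; this is accepted as convergence, while
iteration or evaluation limits are raised as errors — a silent
non-converged result is never returned. $R^2$ is computed as
$1 - \mathrm{SSE}/\mathrm{SST}$ in the original response space so the
linear and saturating families are comparable on one scale;
`compare_models()` prefers the higher $R^2$ and resolves ties (within
$10^{-9}$, e.g. exactly linear data, where the families are nested) to
the linear family by parsimony.

Small negative response values are accepted (blank subtraction
legitimately produces them at high dilution; clipping would bias the
low-concentration end), but an all-zero or constant response is a
degenerate-input error.

## Spectra handling

Spectra are strictly increasing wavelength grids with finite
absorbances. Sets of spectra for a dilution series are regridded to a
common 1 nm grid by linear interpolation before any joint operation, so
per-wavelength arithmetic always sees aligned values. Replicates are
averaged first and the blank subtracted from the average — numerically
identical to per-replicate subtraction for a mean, but the order is
fixed so results are bit-reproducible. Point queries (`od_at()`)
interpolate linearly between neighbours and refuse to extrapolate.

## Correlation scanning

`scan_wavelengths()` regresses blank-corrected mean absorbance on a
laboratory density parameter at every wavelength of the grid (default
300–1100 nm at 1 nm, 801 regressions; the range is configurable down to
190 nm, though below 300 nm UV saturation makes the readings
uninformative). Absorbance is the response, but the quantity used
downstream — $R^2$ as the squared Pearson correlation — is invariant to
swapping the axes, and to any affine rescaling of the parameter.

Design choices worth knowing:

- Rows whose parameter value is missing or flagged below the limit of
  detection are excluded for that parameter before scanning; fewer than
  three usable dilutions is an error.
- A wavelength where absorbance happens to be constant across the
  usable dilutions yields $R^2 = 0$ with a single warning, never an
  error: a scan must always produce a complete table.
- `best_wavelength()` takes the argmax of $R^2$, optionally within a
  window, breaking ties towards the lowest wavelength (a fixed,
  documented rule rather than an arbitrary one).
- The scan itself is vectorized; the test suite holds it against a
  brute-force per-wavelength regression loop at $10^{-12}$, the
  last-ulp agreement one can demand of two different summation orders.

### What selection can and cannot recover

Two regimes matter for interpreting a scan. If the absorption
coefficient $k$ is effectively wavelength-flat, all wavelengths carry
the same curve shape up to scale and their noiseless $R^2$ values are
analytically identical — there is nothing for selection to find, and
with instrument noise the argmax is dominated by per-wavelength noise
fluctuations. Informative selection requires the model's *shape* to
vary across wavelengths: when $k(\lambda)$ varies (pigment bands versus
the green transmission window) and the series reaches saturation, the
wavelength of maximal average sensitivity
$\overline{\partial A/\partial c}$ is also the wavelength of least
curvature, and a noiseless scan finds it exactly. The synthetic
band-selection check in the test suite is built on precisely this
construction (`max_sensitivity_wavelength()` computes the ground truth
from the generator's own profiles; concentrations 500–2000 mg d.m./L).

## Dilution series and derived quantities

The dilution-series container keys rows by dilution factor, stores
`ratio = 1/dilution`, and carries a per-value below-LOD flag; flagged
values never enter fits. The packaged reference series (`chlorella_series()`)
flags evaporation biomass at 200×–1000× and filtration biomass at
1000×; its magnesium readings at 20× and beyond are kept unflagged —
they are suspect but do not change the observed trends, and dropping
them would discard most of the column.

`pairwise_correlations()` emulates spreadsheet trendline practice: for
each parameter pair it fits linear ($y \sim x$), logarithmic
($y \sim \ln x$) and exponential ($\ln y \sim x$) families and reports
the best $R^2$, computed in the transformed space (that is how
spreadsheet trendlines report it; restrict `families = "linear"` for an
orientation-free matrix). Transformed families are skipped for pairs
with non-positive values where the transform is undefined.

Derived quantities (`summarize_derived()`, default rows up to 10×
dilution, where the laboratory values are still reliable):

- **Mg content**: `mg [µg/L] / biomass [mg/L] × 100` → mg per 100 g dry
  matter (the unit factors cancel).
- **Chlorophyll a from Mg**: chlorophyll a carries one central Mg atom,
  so µg/L of Mg converts by the molar-mass ratio
  $893.5 / 24.3 = 36.77$ (to two decimals). Comparing this prediction
  against directly measured chlorophyll a validates an Mg measurement —
  on the packaged series the undiluted row agrees to 0.05%.
- **Single-cell weight**: `biomass × 1000 / cn` → µg per $10^6$ cells
  (equivalently pg per cell), given `cn` in $10^6$ cells/L.

The trichromatic chlorophyll formula (`felfoldy_chla()`) is provided as
a turbidity-corrected linear combination of extract absorbances at 750,
666 and 653 nm, but its coefficients are *config-only*: the constants
are method- and pathlength-specific, and shipping invented defaults
would misattribute them.

## Counting-chamber pipeline

`count_pipeline()` composes five steps, each exposed and testable on
its own:

1. **Background subtraction** (`subtract_background()`): grayscale
   morphological closing with a disc structuring element (opening for
   dark-background imagery) estimates the slowly varying illumination;
   subtracting it leaves dark cells dark on a near-flat background. On a
   linear illumination ramp the estimate is exact wherever the disc is
   fully supported; a border strip of one radius keeps an edge bias, as
   in every rolling-ball scheme. The default radius (50 px) must exceed
   the largest cell radius by a comfortable margin.
2. **8-bit conversion** (`to_8bit()`): min–max rescale to 0–255,
   rounded; a constant image maps to zeros with a warning.
3. **Fixed-range threshold** (`threshold_mask()`): foreground iff
   intensity lies in `[lo, hi]`, defaults 0–200 — after the rescale,
   background sits near 255 and cells near 0.
4. **Particle analysis** (`analyze_particles()`): connected components
   with 8-connectivity (the underlying labeller is 4-connected; labels
   touching only diagonally are merged by a union–find pass), filtered
   to areas in `[min_area, max_area]`, defaults 6–150 px for
   Chlorella-sized cells — the filter drops specks and clumped debris.
   Border-touching particles are kept by default (`exclude_border`
   switches this).
5. **Concentration** (`counts_to_concentration()`):
   `count / (analyzed_area × depth × 10⁻⁶ L/mm³) × dilution`, with
   defaults 0.64 mm² analyzed area and 0.1 mm chamber depth (standard
   Bürker geometry); 100 particles at defaults → 1.5625 × 10⁹ cells/L.

All area/threshold defaults are magnification- and chamber-specific
and are plain configuration (`counting_config()`).

## The synthetic generators

The generators exist so that every pipeline has ground truth without
instrument data; their defaults were chosen once, before testing, to be
plausible rather than fitted to anything.

- **Spectra** (`synth_spectrum()`): the saturating model applied
  independently per wavelength. Default $A_{\max}(\lambda)$ is a flat
  scattering baseline (1.5) plus Gaussian chlorophyll-like bands at
  440 nm (sd 30 nm, height 1.8) and 680 nm (sd 20 nm, height 1.0);
  default $k(\lambda)$ is flat at 0.0022 L/mg. Noise is multiplicative
  by default (sd 0.01 — residual spread in real dilution-series spectra
  grows with signal), switchable to additive. The profiles are
  *illustrative*: they mimic the qualitative chlorophyll landscape, not
  any measured culture.
- **Dilution series** (`synth_dilution_series()`): stock parameter
  values scaled by the ratio list (defaults: the reference series' stock
  and the 2–1000× ratios), multiplicative noise per parameter, optional
  per-parameter detection limits that flag (and thereby exclude)
  censored readings, and paired replicate spectra at the implied
  biomass.
- **Scenes** (`synth_scene()`): dark discs (radius mean 4 px, sd 1,
  truncated to 2–6.5 px so areas stay inside the default size filter)
  on a light background (0.85) with a linear diagonal ramp (amplitude
  0.15) and additive pixel noise; placement by rejection sampling with
  non-overlap enforced by construction (attempt cap $10^4$ per disc,
  failure is an error). Cell depth 0.6 gives strong brightfield
  contrast. Everything is bit-reproducible under a seed.

What the generators deliberately do **not** emulate: instrument
bandwidth and stray light, fluorometer physics, overlapping or
out-of-focus cells, non-disc morphology, and spatially correlated
noise. Passing tests on synthetic data therefore demonstrate that the
algorithms are correct under their stated assumptions, not that a
particular laboratory's images or spectra will be as clean.

## Problem sizes and runtime choices

The shipped checks use sizes that keep the whole suite interactive:
scans of 801 wavelengths × 10 dilutions, calibration studies of 200
noise seeds on 10-point series, and counting studies of 200 scenes of
256 × 256 px with 10–200 cells. These sizes were chosen as the smallest
at which the statistical claims (median recovery error, fraction of
scenes within ±5%) are stable; all of them scale linearly if users want
larger studies.

## Known limitations

- The saturating model assumes a homogeneous, well-mixed suspension in
  a fixed path length; settling or flocculation violates it.
- No uncertainty intervals on $(A_{\max}, k)$ are produced; the fit is
  a point estimate.
- The counting pipeline does not split touching cells (no watershed);
  it is accurate for fields where cells are separated, as in a properly
  loaded counting chamber at the recommended dilution.
- Multivariate calibration (several wavelengths at once) is out of
  scope by design; the scan exists precisely to make a single, good
  wavelength defensible.
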