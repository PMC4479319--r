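---
title: "Calibrating sugar release from mid-infrared photoacoustic spectra"
author: "pasPLS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating sugar release from mid-infrared photoacoustic spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pasPLS)
```

## The problem

Screening straw cultivars for bioethanol potential requires knowing how much
glucose and xylose a sample releases after pretreatment and enzymatic
hydrolysis. The wet-lab assay (high-throughput pretreatment and hydrolysis,
with sugars quantified enzymatically) is accurate but slow and expensive per
sample. Mid-infrared photoacoustic (FTIR-PAS) spectra of the *untreated*,
ground straw are cheap and fast, and the fingerprint region (1800--600 cm⁻¹)
carries bands attributable to the cell-wall polymers that control
digestibility: amorphous cellulose (898 cm⁻¹), crystalline cellulose (1429,
1160, 1111, 1053 cm⁻¹), xylan (1735, 1460, 1240 cm⁻¹) and lignin (1510,
1600 cm⁻¹). pasPLS implements the full chemometric workflow that turns a
table of such spectra plus assay reference values into a validated
calibration: preprocessing, PLS1 regression, cross-validated model selection,
variable selection, outlier screening, external validation, and a
coefficient-interpretation aid.

Spectra live in a `SpectrumSet` (a `SummarizedExperiment` with spectral
points as rows and samples as columns; the wavenumber grid is stored
strictly descending, 4000 → 600 cm⁻¹ at 4 cm⁻¹, the conventional infrared
plotting order). Responses are a plain data frame in g sugar per g dry
matter, optionally with replicate-level assay values attached for
laboratory-error estimation.

## Preprocessing

Four standard variants are provided (`preprocessVariants()`), applied
per-spectrum and composable with `applyPipeline()`:

* `smooth_norm` — Savitzky–Golay smoothing (window 7, polynomial order 0,
  i.e. a centred seven-point moving average) followed by division by the
  spectrum mean. Mean *division* (not centering) is the scatter-correction
  reading of "normalisation by the mean": photoacoustic intensity varies
  multiplicatively with packing density, and a ratio removes that.
* `sg1`, `sg2` — Savitzky–Golay first and second derivatives (order-2
  polynomial, window 7). Derivatives are taken with respect to *ascending*
  wavenumber so their sign is physical, then returned on the descending
  storage grid; units are absorbance per cm⁻¹ (per cm⁻¹² for `sg2`). A
  uniform grid is required; `regridSpectra()` (linear interpolation, no
  extrapolation) co-registers grids first when needed.
* `smooth_snv` — smoothing followed by the standard normal variate (SNV):
  per-spectrum centering and scaling to unit standard deviation (n − 1
  denominator; the distinction is invisible on 851-point spectra but is
  fixed for reproducibility).

Savitzky–Golay filters use polynomial-extension edge handling: at the
boundaries the fitting window is anchored at the edge and the fitted
polynomial is evaluated off-centre, so no grid points are trimmed. The
operators are validated against a brute-force per-window least-squares
oracle, including the edges.

## The calibration model

Each response (total sugar, glucose, xylose) gets its own PLS1 model —
per-response factor counts differ in practice, so a joint PLS2 would force a
compromise. `fitPLS1()` implements NIPALS with X-deflation: for a centered
design, `w ∝ Xᵀy` (normalised), `t = Xw`, `p = Xᵀt/tᵀt`, `q = yᵀt/tᵀt`,
deflate `X ← X − tpᵀ`. The regression vector for F factors is
`b = W(PᵀW)⁻¹q`, stored on the full wavenumber grid (zeros at unselected
variables) together with the centering vectors, so
`ŷ = ȳ + (x − x̄)·b` always reproduces predictions. The test suite checks
NIPALS against an algorithmically independent Krylov-basis PLS solution and,
at full rank, against ordinary least squares.

### Factor selection

`segmentedCV()` shuffles the calibration samples with a fixed seed, splits
them into 10 contiguous segments of as-equal-as-possible size (randomised
segments avoid confounding with acquisition order, which a file-order split
would inherit), and computes out-of-segment predictions for every factor
count. `selectFactors()` then applies a parsimony rule: the smallest F whose
RMSECV is within 2 % of the global minimum. The cap `maxFactors` defaults
to 20; realistic straw calibrations select 2--5 factors, and the acceptance
workflow caps at 12 to spare compute without touching the selected models.

### Martens' uncertainty test

With M cross-validation segments the segment submodels provide a jackknife
on the regression coefficients: `s²ⱼ = Σₖ (bⱼ⁽ᵏ⁾ − bⱼ)² (M−1)/M`. Variable
j is kept when `|bⱼ|/sⱼ` exceeds the two-sided t critical value at
α = 0.05 with M − 1 degrees of freedom; a variable whose coefficient is
identical in every submodel (sⱼ = 0) is kept whenever its coefficient is
nonzero. The model is refit on the kept variables at the same factor count
(fewer only if rank forces it). The test is applied once; iterating it to
convergence is possible in principle but a single pass already yields the
stability gain the test is used for, and repeated testing on
already-selected variables has no clean significance interpretation.

### Outlier screening

`influenceStats()` computes, per sample, Hotelling's T² over the F score
dimensions (training score variances in the denominator) and the Q residual
(squared distance off the model plane). `flagOutliers()` draws the T² limit
from the F-distribution form of the Hotelling limit at quantile 0.975 and
the Q limit from the empirical 0.975 quantile of the training Q values — an
empirical quantile rather than the Jackson–Mudholkar moment approximation,
whose higher-moment estimates are fragile at moderate n. Visual
influence-plot curation cannot be reproduced programmatically, so the
workflow uses this single quantile-based screening pass; `runPipeline()`
additionally accepts an explicit exclusion list to emulate manual curation.
Degenerate inputs with zero spread produce no flags.

## Figures of merit

* `rSquared(y, f)` returns `1 − Σ(yᵢ−fᵢ)²/Σ(yᵢ−ȳ)²`. One sometimes sees
  this statistic printed without the leading "1 −", which would make it the
  *unexplained*-variance fraction (0 for a perfect fit); the package uses
  the standard coefficient of determination, for which "closer to 1 is
  better" is true.
* `rmse(y, f) = sqrt(Σ(fᵢ−yᵢ)²/n)`, in g g⁻¹ dm.
* `sdl(replicates)` pools replicate scatter around per-sample means:
  `sqrt(ΣⱼΣᵢ(yᵢⱼ−ȳⱼ)²/D)`. The conventional denominator is `D = mn − 1`
  (`denominator = "printed"`, the default); note that the sum has only
  `n(m−1)` free deviations, so this form converges to
  `σ·sqrt(n(m−1)/(mn−1))` ≈ 0.82 σ at m = 3 rather than to the replicate
  noise σ itself. `denominator = "pooled"` (`D = n(m−1)`) is the consistent
  estimator; consistency checks in the test suite use it.
* `rmseSdlRatio(rmse_ev, sdl)` — how far the prediction error sits above
  the reproducibility floor of the reference assay; 1 is the ideal.

`splitCalibration()` allocates two thirds of the samples to calibration by
seeded random sampling within variety × site strata, so the held-out third
spans all varieties and sites; external-validation metrics are computed on
that untouched set with the model frozen after variable selection.
`buildReport()` assembles the response × preprocessing matrix of figures of
merit in one call.

## Breaking the glucose–xylose correlation

Glucose and xylose release are strongly correlated across straw samples
(r ≈ 0.8 both in real campaigns and in the synthetic generator), so a
glucose calibration may lean on xylan bands and vice versa.
`partitionDecorrelate()` splits the calibration set into k = 3 equal
subsets within which the correlation is minimised; `perSubsetModels()` then
fits per-subset glucose and xylose models whose coefficients can be read
band by band (`annotateCoefficients()` labels the significant coefficient
regions — a 0.9 quantile rule on |b|, configurable — with the nearest
reference bands within 30 cm⁻¹, a tolerance wide enough to bridge the usual
material-to-material band shifts).

The partition search is a seeded pair-swap local search with two
refinements that plain random-swap descent turned out to need. First,
initialisation: samples are banded into rank-terciles of the standardized
glucose + xylose sum. Decorrelation works by letting *between*-subset
variance absorb the covariance, and the major axis of the joint
distribution is where that variance must be separated. Second, descent
runs full best-swap sweeps, first on `Σ r²ₛ` — which lets the subsets trade
minor-axis variance without being blocked by the current worst subset —
and only then on the reported objective `max |rₛ|`, which is non-increasing
from sweep to sweep; a few perturb-and-redescend restarts are kept only
when they improve the objective.

How far can this go? Rotate the standardized pair to major/minor axes s, d
with variances 1 + r and 1 − r. Within a subset,
`r_w = (Vₛ − V_d)/(Vₛ + V_d)` (any within-subset covariance between s and d
only increases |r_w|). Equal-size banding bounds how much s-variance can be
moved between subsets, and the d-variance is essentially fixed, so for
bivariate-normal data with r = 0.8 and k = 3 the achievable `max |rₛ|` has
a floor of roughly 0.3, and swap-reachable optima typically land between
0.3 and 0.5 depending on the realisation. Real straw data are not normal —
skewed, heteroscedastic, clustered by site and variety — which is why
observed decorrelations on real campaigns can do somewhat better than the
normal-theory floor suggests.

## The synthetic generator

`generateDataset()` emulates a straw campaign so the whole workflow is
testable without any measured data. Per sample it draws positive component
concentrations (lognormal) for amorphous cellulose, crystalline cellulose,
xylan, lignin and water/carboxylates; a shared latent "maturity" factor
loads on amorphous cellulose and xylan, inducing the glucose–xylose
correlation that the decorrelation module needs to have something to break.
Spectra are concentration-weighted sums of Gaussian band signatures at the
classical wheat-straw wavenumbers (FWHM parameterisation; Gaussian shapes
are the simplest adequate choice for testing a *linear* calibration — real
photoacoustic bands are Voigt-like and saturate, which is out of scope)
plus a gently sloping baseline and iid spectral noise. Responses are linear
in the concentrations — glucose rises with amorphous cellulose and falls
with lignin and crystalline cellulose; xylose rises with xylan and falls
with lignin — plus assay noise with a component shared between the two
sugars (both are measured on the same hydrolysate) and an independent
component. Total sugar is glucose + xylose exactly, at sample and replicate
level; triplicate replicates carry the replicate noise used for SDL
estimation (0.016 and 0.010 g g⁻¹ dm for glucose and xylose).

The default constants were calibrated once, by simulation, to land the
workflow in the regime a real straw campaign occupies: mean releases near
0.42/0.23/0.19 g g⁻¹ dm for total/glucose/xylose with the total range
covering 0.30--0.57, glucose–xylose correlation near 0.8, and
external-validation R² for total sugar around 0.70--0.75 with 2--4 factors
selected. The latent normal draws are winsorised at ±3 sd so extreme joint
draws cannot push a release past the physical [0, 1] range. What passing
tests on these data do *not* show: robustness to instrument drift,
atmospheric lines, site-by-year interactions, or nonlinear photoacoustic
saturation — none of which the generator emulates.

```{r example, eval = FALSE}
d <- generateDataset(defaultSyntheticConfig(), seed = 1)
res <- runPipeline(d$spectra, d$responses, response = "total",
                   preprocess = "smooth_norm", seed = 1, maxFactors = 12)
res$report
annotateCoefficients(res$model)
```

## Numerical choices and problem sizes

Tolerances: wavenumber-grid uniformity for derivatives is checked to a
relative 10⁻⁶; round-trip CSV I/O is full double precision (~15
significant digits); rank exhaustion in NIPALS is declared when the
residual weight norm falls below 10⁻¹⁰ of its initial value; degenerate
zero-variance inputs (constant spectra, constant responses) are hard errors
rather than silent NaNs. Ties in factor selection resolve to the smaller
model; ties in the decorrelation search resolve to the incumbent.

The test suite runs the full pipeline at the default campaign size
(n = 1068, 851 spectral points) across 20 seeds, the decorrelation
criterion at n = 600 across 20 seeds, and keeps unit fixtures at n ≤ 300;
`scripts/acceptance.R` regenerates the n = 1068 campaign and recomputes
every reported figure from scratch at the seed it is given.

## Limitations

PLS1/NIPALS only (no kernel, sparse or interval PLS); no multiplicative
scatter correction or rubber-band baseline correction; no JCAMP-DX/SPC
readers (wide CSV only); scan-level averaging noise is not modelled (only
averaged spectra are exposed by instruments in practice); the outlier
screen is single-pass and quantile-based, not an iterative robust fit; and
the decorrelation search is a heuristic with the feasibility floor derived
above — it reduces the correlation, it cannot abolish it.
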