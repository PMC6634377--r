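---
title: "Methods: modeling the nutritional landscape of a large browser"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modeling the nutritional landscape of a large browser}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forageshed)
```

## What the package computes

`forageshed` links forest condition to the summer nutritional landscape of
Shiras moose (*Alces alces shirasi*), a large selective browser whose
forage base is dominated by early-seral shrubs. The analysis chain is:

1. **Diet composition** — microhistological view counts from fecal samples,
   corrected for digestibility and screened for incidental species.
2. **Forage quality** — digestible energy (DE, kJ/g) and digestible protein
   (DP, g/100g) from chemistry assays, classified into quality classes.
3. **Forage quantity** — shrub crown-volume densities from transect plots,
   extrapolated over landscape polygons with penalized presence/volume
   models and aggregated to game management units (GMUs).
4. **Change over three decades** — covariates back-cast to a past epoch
   (1984) and forage re-predicted.
5. **Population linkage** — a harvest-based trend index per GMU, correlated
   with forage quantity and its change.

The repository is organized as an analysis workflow: the numbered scripts
under `analysis/` are thin narrative drivers over the package functions,
writing their tables under `results/`; every computation they perform lives
in `R/` where the tests and the acceptance script exercise it.

## Digestion model

Forage chemistry enters through four assay values per species and plant
part: crude protein CP (%), neutral detergent fiber NDF (%), lignin+cutin
as a fraction of NDF (L, %), and tannin protein-precipitating capacity
against BSA (mg/mg dry matter). The summative equations are

$$DP = d_0 + d_1\,CP - d_2\,BSA$$
$$DDM = \left(a_1 e^{-a_2 L} - c\,BSA\right)NDF + \left(b_0 + b_1\,NDS\right),
\qquad NDS = 100 - NDF$$
$$DE = GE \times DDM / 100$$

with defaults $d = (-3.87,\, 0.9283,\, 11.82)$,
$a_1 = 0.9231$, $a_2 = 0.0451$, $b_0 = -16.03$, $b_1 = 1.02$, $c = 0.03$,
and gross energy constants $GE_{leaf} = 19.0$, $GE_{stem} = 19.7$ kJ/g —
the standard browse-nutrition forms for tannin-bearing deciduous shrubs.
These coefficients are *data*, not code (`digestion_coefficients()`), so an
alternative transcription can be swapped in without touching the package.
Negative DP is biologically meaningful (protein insufficient to offset
tannin binding plus metabolic losses) and is preserved, not clamped.

**Class boundaries.** The energy classes are high (DE > 11.3 kJ/g),
moderate, and low (DE < 10.5); protein classes are high (DP > 6.5 g/100g),
moderate, and low (DP < 4.3). Both boundaries close into the *moderate*
class: a species sitting exactly at 10.5 kJ/g is moderate. This choice is
forced by consistency — with printed one-decimal values, an open interval
would reclassify a boundary species against its published listing.
Maintenance screens (10.9 kJ/g DE for summer energetic needs of a
non-lactating female; 4.3 g/100g DP to offset fecal and urinary nitrogen
losses) are *inclusive*: only values strictly below the threshold fail.

## Diet correction

Fecal fragments are undigested residue, so a species' fragment proportion
under-represents its ingested proportion in proportion to its
digestibility. The package inverts the observation process:

$$p'_i \propto \frac{p_i}{1 - DDM_i/100}$$

renormalized per sample. This residue inversion is the only correction
consistent with the fecal generative model, and the synthetic diet
generator (`generate_diet_samples()`) is its exact inverse — multinomial
view counts with fragment probabilities $q_i \propto p_i(1 - DDM_i/100)$ —
so the round trip is testable and unbiased to within Monte-Carlo error.

Two reporting conventions exist for "mean dietary proportion": the mean
over diets *containing* the species (conditional), and the mean over all
diets. The conditional convention is used for reporting (it matches how a
species occurring in a third of diets can still average a quarter of those
diets), while the GMU-averaged *unconditional* mean drives the 3%
minor-species filter (boundary inclusive: exactly 3% is retained). Both
columns are returned by `summarize_diets()`.

Class-level DDM values for grasses, forbs and conifers — needed to correct
class shares — default to 60/65/45% and sit in the configuration.

## Field vegetation

Crown volume uses the ellipsoid convention $V = (\pi/6)\,h\,d_1\,d_2$; a
box convention is available, since only relative volumes matter downstream.
Plot volume density divides summed crown volume by the fixed 12.56 m$^2$
plot area; dense species-plots (at least 20 shrubs) contribute the mean of a
measured subsample times the total count. A transect's density for a
species is the mean over its four plots, with plots lacking the species
counting zero (the plot-mean convention; pooling plot areas gives the same
value when all plots share an area, as here). Calibrations — CAG biomass
on crown volume, and crown volume on the single perpendicular diameter —
are ordinary least squares via `stats::lm`, reported as slope, intercept,
$R^2$ and n.

## Landscape models

Presence per species is an L1-penalized logistic regression (glmnet) on
standardized covariates; the default covariate set is canopy cover (with a
quadratic term, since shrubs persist below a species-specific shade
threshold), time since fire, solar radiation and elevation; categorical
covariates one-hot encode against a first-level reference. The penalty is
selected by repeated K-fold cross-validation (defaults K = 10, 30
repetitions) maximizing the AUC of pooled out-of-fold scores, then the
model is refit on all data at the winning penalty. The probability
threshold is chosen on training predictions so that specificity equals
sensitivity — operationalized as the argmin of |sens − spec| over candidate
thresholds (midpoints of adjacent sorted unique scores plus 0 and 1, ties
toward the lower threshold), since exact equality rarely exists on finite
data. Reported fit statistics (AUC, Cohen's kappa, percent correctly
classified) are means and SDs over repetitions, each repetition evaluated
on its own pooled out-of-fold predictions with its own threshold.

Volume per species (conditional on presence, strictly positive) is an
L1-penalized gamma regression with log link, cross-validated on mean
squared prediction error under the **one-standard-error rule**: the
strongest penalty whose CV error is within one SE of the minimum. A raw
argmin occasionally retains a chance covariate under pure noise; the 1-SE
convention makes the intercept-only collapse — the expected and
first-class outcome when covariates lack predictive power — robust. An
intercept-only model predicts the empirical mean of positive observed
volumes.

GMU aggregation multiplies the occupied polygon area by the species' mean
volume and divides by total GMU area; class aggregates sum member species.
This density is invariant to splitting polygons and monotone in occupied
area.

## Temporal back-cast

The past epoch replaces canopy cover with an externally supplied
past-canopy table (in the study system, from Landsat reflectance change —
out of scope here and deliberately an *input*) and recomputes time since
fire relative to the epoch year; fires after the epoch never influence it.
Polygons with no recorded fire receive a censoring cap (default 100 years)
in both epochs. Percent change is $100(\text{current} -
\text{past})/\text{past}$, with zero-past cells reported as missing rather
than infinite.

## Trend index

Each harvest metric (harvest success, permits offered, days per harvest)
is reduced to a relative change: OLS slope × period span ÷ period mean — a
scale-free fractional change over the whole period, robust to single-year
noise, invariant to uniform rescaling of permits. Gaps of at most two
years are linearly interpolated; longer gaps stay missing; at least five
non-missing years are required. The rubric maps relative change to integer
scores: success and permits in \[−2, 2\] (cutpoints 0.10 and 0.50), days in
\[−1, 1\] (cutpoint 0.25, sign inverted — more days hunted per animal is
worse), so component ranges sum to the \[−5, 5\] index envelope. Zero is
stable; sign gives direction. The exact cutpoints are conventions of this
implementation (the original scoring criteria live in an unavailable
supplement) and are fully overridable via the configuration. Correlations
with forage metrics are Pearson with two-sided tests, after excluding GMUs
whose forage predictions are dominated by recent large fires or whose
harvest series are truncated.

## The synthetic-data module

The generators emulate the statistical structure the analysis assumes, not
the study region's geography:

- **Landscape**: abstract polygon records with lognormal areas matched to
  a mean of 2,980 m$^2$ and SD of 5,300 m$^2$ (the segmentation scale of
  the study's object-oriented imagery analysis), partitioned among GMUs;
  covariates drawn from configurable distributions; fires assigned
  uniformly over a year range.
- **Shrub truth**: Bernoulli presence with logistic probability in the
  covariates; gamma volume conditional on presence.
- **Transects**: uniform-random polygon placement (the study's spatially
  balanced RRQRR design is deliberately not re-implemented — placement
  balance does not change any downstream estimator here); 4 plots per
  transect, 180 m/60 m spacing in stage 1, 90 m/30 m in stage 2 with the
  widest diameter dropped; Poisson shrub counts per occupied plot scaled so
  expected plot density equals the polygon truth; dimensions derived from
  volumes with multiplicative lognormal measurement noise (CV 10%,
  mean-one so volumes stay unbiased). No error model is published for
  these field measurements; 10% is a realistic CV for canopy dimensions.
- **Diet**: multinomial view counts biased by indigestibility (above), 60
  views per sample; grasses/forbs/conifers included as class-level
  pseudo-species so class shares are exercisable.
- **Harvest**: linear drifts with multiplicative noise; declining GMUs
  lose ~60% of success and permits while days rise ~60%; increasing GMUs
  mirror this; magnitudes chosen so the default rubric scores the extremes
  at ±5.
- **Succession**: past canopy = current canopy − GMU-level growth, clipped
  to \[0, 100\]. In the coupled study (`simulate_study()`), GMUs with the
  most canopy growth receive declining harvest trends, so the expected
  sign of the index-versus-forage-change correlation is known (positive).

What passing tests on these data do **not** show: spatial autocorrelation
(none is simulated), detectability or observer error in microhistology,
seasonal phenology of forage quality, or the behavior of the reflectance
change-detection that produces real past-canopy tables. Results on real
data inherit those additional uncertainties.

## Problem sizes and numerical choices

The test suite and acceptance script run the recovery properties at sizes
chosen to make Monte-Carlo bounds meaningful while keeping a full run in
tens of seconds: $10^4$ polygons with 500 transects for presence-model
recovery (CV AUC above 0.75 with one strong covariate, chance level under
the null); 500 fecal samples for the diet round trip (componentwise bias
within 3 SE); a 2,500-polygon, 12-GMU coupled study for the end-to-end
directional check. The published GMU-level results themselves (Table-2-scale
AUC/kappa/PCC values, per-GMU densities, the r = 0.60 headline correlation)
are not reproducible without the unreleased field and GIS data; the package
instead verifies every quantity that *is* printable (the quality-table
statistics and class lists, the 11-of-17 filter) exactly, and the rest as
recovery properties against known synthetic truth.

Other numerical choices: corrected proportions renormalize to 1 within
1e-12 per sample; thresholds are never interpolated between folds; all
generators are pure functions of (spec, seed); `glmnet` IRLS
non-convergence warnings at extreme penalties on the gamma path are
suppressed because cross-validation discards those penalties on merit.

## Known limitations

- Per-polygon volume variation is not modeled (species means only), as in
  the source analysis — GMU differences are relative, not absolute.
- The trend rubric's cutpoints are implementation conventions; index
  values are comparable within a rubric, not across rubrics.
- The digestion coefficients are global (no seasonal or site variation),
  matching the composited-assay design.
- `example_diet_proportions()` mixes published proportions for the eleven
  major taxa with synthetic placeholders for the six minor ones (flagged by
  its `synthetic` column); only the count and sub-cutoff status of the
  minor rows carry information.
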