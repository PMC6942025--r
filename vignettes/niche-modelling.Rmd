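---
title: "Modelling an invader's climatic niche from presence-only data with native contrast classes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling an invader's climatic niche from presence-only data with native contrast classes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichesvm)
```

## The model and its assumptions

`nichesvm` estimates the realised climatic niche of a recently established
invasive species from presence-only records, by contrasting them with
presence records of co-occurring native species instead of simulated
pseudo-absences. The statistical object is a binary classifier in an
8-dimensional climate space (four temperature variables in °C, three
precipitation sums in mm, one drought index):

- occurrence records of the target species form the `invasive` (positive)
  class;
- pooled records of several native species form the `native` class;
- a C-support-vector machine with an RBF kernel separates the two classes,
  and its decision values are mapped to probabilities by a fitted sigmoid
  (Platt scaling).

The central assumptions are: (i) each species' occurrence records sample its
realised niche, so class-conditional covariate distributions are meaningful;
(ii) native species are chosen so their pooled niche overlaps but differs
from the invader's — the contrast carries the signal; (iii) sampling effort
does not differ between classes in a way that correlates with climate. The
last assumption is the method's soft spot: in citizen-science data,
submission density follows population density, and the model inherits that
bias for all classes alike.

Validation is temporal rather than spatial: the model is trained on the
records of a set of earlier years (each record joined to the weather grids
of its own collection year) and evaluated against the records of a later
year it has never seen. This tests exactly the intended use — predicting
next season's suitable area from this season's weather.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `gamma` | `5e-4` | 1/(raw units)² | RBF width on raw covariate scales; at typical °C/mm magnitudes, squared distances between sites are O(10²–10³), so `gamma·d²` is O(1). |
| `C` | `1` | — | Soft-margin cost; default keeps the separator smooth on noisy ecological data. |
| `tolerance` | `1e-10` | — | Optimizer stopping criterion; strict so refits are reproducible to machine precision. |
| `per_species_cap` | `1000` | records | Uniform random subsample per species before training; prevents one very abundant contrast species from dominating the pooled class. |
| probability threshold | `0.5` | — | The calibrated probability's natural decision point; sites at exactly the threshold count as invasive-suitable. |
| suitability bins | 20%-wide | — | Legend convention for colonisation-potential maps. |

Covariates are deliberately **not** standardized by default: `gamma` is
calibrated to raw physical units, and the raw-unit kernel is the reference
behaviour. `training_config(standardize = TRUE)` exists for sensitivity
analyses; the tests assert (rather than hide) that rescaling one covariate
changes predictions.

Platt calibration uses libsvm's internal five-fold cross-validation on
decision values. The fold count is the toolkit's default, adopted here as
the package's documented choice; the calibration guarantees that predicted
probability is strictly monotone in the decision value, so probability-mode
and raw-mode classification can disagree only through the calibrated
intercept, and the tests check their agreement on separable data.

The orientation convention is fixed everywhere: **invasive = positive
class**. The dual orientation of a confusion matrix is available via
`swap_orientation()` (exchange TP↔TN, FP↔FN), never by re-fitting.

## The synthetic world

Real surveillance data and national weather grids cannot ship with a
package, so the generator builds worlds with known truth:

- **Climate fields.** Each variable is a smooth random surface (superposition
  of eight plane cosine waves with wavelengths at or above a 15-km
  correlation length) scaled to plausible central-European levels
  (e.g. spring mean temperature 8.5 ± 1.8 °C, June precipitation
  75 ± 30 mm), plus a year-specific anomaly surface at 35% of the spatial
  standard deviation. Precipitation and the drought index are truncated at
  zero.
- **Species.** A species' suitability in a cell is a product of per-variable
  Gaussian responses `exp(-w((v - opt)/b)²)` — the simplest unimodal
  response; realized record counts are Poisson draws (simplest count model,
  variance testable); points are jittered uniformly within their cell.
- **The four-species scenario.** One warm/wet-adapted invader against a
  generalist floodwater species, a tree-hole breeder and a continental
  species, with training-year abundances in ratio ≈ 5:20:3:1 and an
  expanding invader in the hold-out year. Optimum offsets are around one
  spatial standard deviation, so class distributions overlap broadly yet
  differ detectably on every variable.

Design notes, decided once and frozen:

- The domain is 100 × 100 km with a 15-km correlation length — roughly seven
  correlation lengths per axis — so each world realises a representative
  spread of climates. In smaller domains the handful of independent climate
  patches makes the realised niche separation swing wildly between world
  seeds, which defeats the scenario's purpose of providing a *configured*
  separation. The scenario's effect sizes were calibrated against that
  stated purpose (reliable recoverability at broad visual overlap) and are
  part of the scenario definition.
- The null variant (`separation = 0`) makes all four response functions
  identical **and balances the class sizes** (invader expected records =
  pooled natives). "Identical niches" is read as identical responses;
  abundance is sampling intensity, not niche. Balance matters because the
  chance-level reference value of 0.5 for weighted f1 only holds for
  balanced classes.
- Coordinates are abstract planar km with the usual raster convention (row 1
  at the top, half-open cells, points jittered within cells); there is no
  CRS machinery in the synthetic world.

What the generator does **not** emulate: spatial sampling bias, spatial
autocorrelation of records beyond the climate fields themselves, covariate
collinearity structure of real weather (fields are independent across
variables), coastlines/nodata geometry, and species interactions. Passing
tests on synthetic worlds therefore demonstrate that the pipeline's
machinery is correct and recovers known niches under its own assumptions —
not that any real species' niche is identified.

## Numerical choices and degenerate inputs

- **Zero denominators** in precision/recall/f1 yield `NA` with an
  `undefined` flag, never silently 0 and never an error: silent zeros would
  corrupt weighted means. Consequence: a classifier that collapses to a
  single class has undefined weighted f1. In replicate studies of the null
  world such replicates are counted and reported, and summaries average over
  the defined replicates; with identical niches the RBF decision surface is
  nearly flat, so a sizeable minority of replicates do collapse.
- **Quartiles** use linear interpolation between order statistics (R type
  7), the common default; checked against a sort-based oracle.
- **Report rounding** is half-up at 2 decimals (`round_half_up()`), the
  convention of printed validation tables; all computations keep full
  precision.
- **Rank tests** use the exact Mann-Whitney distribution for tie-free
  samples with at most 20 values per class, otherwise the tie-corrected
  normal approximation without continuity correction — so two identical
  samples give p = 1 exactly.
- **Genetic search**: tournament selection (size 2), uniform crossover
  (rate 0.9), per-bit mutation at 1/L, elitism 1 — standard practice.
  Empty subsets and subsets whose classifier collapses to one class get
  fitness −∞. Fitness is a single seeded stratified 75/25 hold-out with the
  per-species cap applied before the split; the best-so-far trace is
  monotone by elitism.
- **Mapping** averages climate layers first and predicts once
  ("average-then-predict"), matching the interpretation of colonisation
  potential as suitability under mean climate; predicting yearly maps and
  averaging those is a deliberately distinct operation the pipeline never
  substitutes silently. Chunked raster evaluation is bit-identical to
  whole-raster evaluation regardless of block size.
- **Model files** are versioned JSON holding support vectors, dual
  coefficients, bias, kernel and sigmoid parameters, variable list and
  configuration; a loaded model replays the decision function from the
  stored parameters and reproduces the original predictions to full
  precision.
- **Degenerate training inputs** (single class, zero-variance covariates,
  missing values) are refused with specific errors before any fitting.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
desk scale: 100 × 100-cell worlds with 8 variables and 5 years
(≈ 3 400 training records) for end-to-end experiments; 40–100 replicates for
the null study; 8 candidate variables (255 subsets) for the
search-vs-oracle comparison; and small analytic fixtures for exact
contracts. These sizes were chosen so the full pipeline, not a miniature of
it, is exercised while a complete run stays in the minutes range.

## Known limitations

- Class labels, not abundances, drive the fit; the per-species cap is a
  blunt instrument against imbalance.
- Probability calibration is only as good as libsvm's internal
  cross-validated sigmoid; with few positive records the calibrated
  probabilities are noisy even when the ranking is solid.
- The weighted f1 of an uninformative classifier depends on class balance;
  comparisons against a 0.5 chance reference are meaningful only in
  balanced designs (the null world is balanced for exactly that reason).
- Temporal hold-out across a single year tests short-range transfer only;
  climate-projection use would require re-calibration and is out of scope.
- The genetic search optimises a noisy fitness (one hold-out split); on
  small candidate pools the exhaustive oracle is preferable and provided.
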