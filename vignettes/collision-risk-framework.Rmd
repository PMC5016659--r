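---
title: "Modeling wildlife-vehicle collision risk from exposure and hazard submodels"
author: "wvcrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling wildlife-vehicle collision risk from exposure and hazard submodels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wvcrisk)
```

## The model

Wildlife-vehicle collision risk on a road segment is treated as the
product of two separately estimable components: *exposure* — the
likelihood that the animal is present — and *hazard* — the presence and
movement of vehicles. Writing the collision rate on segment $i$ as

$$C_i = e^{\beta_0 + \beta_1 \ln O_i + \beta_2 \ln V_i + \beta_3 \ln S_i},$$

with $O_i$ the relative likelihood of species occurrence, $V_i$ the
traffic volume (vehicles/day) and $S_i$ the traffic speed (km/h), the
slopes $\beta_{1..3}$ measure the relative influence of each factor and
$\beta_{1}=\beta_2=\beta_3=1$ corresponds to risk exactly proportional to
exposure times hazard, with constant of proportionality $e^{\beta_0}$.

Collision observations are binary per segment. Under a Poisson encounter
process the probability of no collision is $e^{-C_i}$, which turns the
rate model into a binomial GLM with complementary log-log link:

$$\operatorname{cloglog}(p_i) = \ln(-\ln(1-p_i))
  = \beta_0 + \beta_1 \ln O_i + \beta_2 \ln V_i + \beta_3 \ln S_i.$$

The cloglog link is not an arbitrary choice among sigmoid links: its
linear predictor *is* the log of the encounter rate, so fitted
coefficients carry the rate interpretation, and the intercept absorbs any
rescaling of the volume or speed units (we therefore keep raw units —
vehicles/day and km/h — and do not standardize predictors, so that
coefficient magnitudes remain directly comparable across refits).

Key assumptions: collisions on different segments are independent given
$(O, V, S)$; multiple collisions on one segment carry no more information
than one (outcomes are collapsed to binary, matching a coded
presence/background design); and the submodel predictions stand in for
the true $O$, $V$, $S$ without error propagation — the framework is
correlative, not mechanistic.

## Submodels

**Exposure.** The occurrence submodel is a boosted-classification-tree
ensemble on presence/background points. Defaults follow standard SDM
practice for this model family: tree complexity 5 (a per-tree limit on
terminal nodes, allowing up to moderate-order interactions), learning
rate 0.005, bag fraction 0.5, and ensemble size chosen by k-fold
cross-validated deviance with early stopping. The fold count is not
dictated by the model family; we default to 10, the convention of the
BRT literature. Covariates are pruned beforehand so that all pairwise
$|r| < 0.75$; of an offending pair the member with the larger mean
absolute correlation to the remaining covariates is dropped, which is
deterministic and order-free. Predicted probabilities are clamped at
$10^{-6}$ from below: boosted-tree probabilities are strictly inside
$(0,1)$ already, but the downstream $\ln O$ transform must never see a
zero. The ensemble is implemented on xgboost with `max_leaves` as the
terminal-node limit, single-threaded for bit reproducibility.

**Hazard.** Traffic volume (AADT) is approximately log-normal across a
network, so the volume forest is fit to $\ln(\mathrm{AADT})$ and
predictions are exponentiated back; this is the plainest reading of a
"log link" for a random forest. No smearing correction is applied by
default (a Duan smearing factor is available as an option) — the bias is
second-order relative to forest error, and the collision model consumes
$\ln V$ anyway, where the correction would only shift the intercept.
Forests use 500 trees; out-of-bag percent variance explained,
$100(1-\mathrm{MSE}_{oob}/\widehat{\mathrm{var}}(y))$, is the headline
fit metric. The speed model uses exactly two predictors — road-class
intensity and road density — reflecting how posted limits are set. Road
class enters all models as an ordered integer 1-6 (local to freeway),
treating class as a proximal measure of design intensity rather than an
unordered factor.

**Collision dataset construction.** Collision reports carry positional
uncertainty; records worse than 300 m are discarded, with the boundary
value kept (the filter retains `accuracy <= 300`). Each surviving record
is assigned to the road segment minimizing point-to-polyline distance,
ties broken by lowest segment id; a segment hit by any number of records
is coded 1 once. Background segments are a uniform draw, without
replacement and disjoint from the collision set, of twice the collision
count. Whether "background" segments truly had no collisions is
unknowable in real data; we sample from all non-collision-coded segments,
which matches how such datasets are assembled in practice.

## The synthetic scene

Real collision, traffic and survey databases are jurisdictional and not
redistributable, so the package ships a generator whose output has the
same statistical structure and known ground truth.

- **Covariates** are Gaussian white noise smoothed with a separable
  Gaussian kernel (sd = `smoothingScale` cells) and standardized; the
  smoothing scale is the single knob controlling spatial
  autocorrelation. Real covariates (elevation, greenness, climate) have
  richer anisotropic structure; only autocorrelation is emulated.
- **Roads** are correlated random walks truncated at the extent, with
  classes drawn from a configurable six-class mix. Real networks are
  connected and hierarchical; ours are not, which matters for none of the
  fitted models (they see segments, classes and distances, not
  topology).
- **Occurrence truth** is logistic in the covariates. Presence points are
  drawn cell-weighted by the truth surface (exactly the rejection-sampling
  distribution, since covariates are cellwise constant) and background
  points uniformly. Survey-bias toward roads can be switched on as a
  road-proximity weight but is off by default: the spatial sampling
  process of real atlas records is undocumented, so the unbiased
  generator is a choice, not an inference.
- **Traffic truth** sets $\ln(\mathrm{AADT})$ linear in road-class
  intensity, distance to development, distance to major roads, population
  density and road density, plus Gaussian noise (sd 0.3); the default
  coefficients make road class dominant, the configuration observed on
  real networks. Speeds are class means (50-100 km/h) with small noise,
  snapped to 5 km/h steps like posted limits.
- **Collisions** are Bernoulli draws with $p_i = 1 - e^{-C_i}$ from the
  true $(O, V, S)$ and the true risk coefficients (default
  $\beta_0 = -11$, unit slopes, which puts the mean collision probability
  near 0.25 on the default scene — the order of magnitude a real
  per-segment risk map shows). Point-format collision *records* are then
  emitted as jittered segment midpoints with a positional-accuracy
  attribute, 15% of them deliberately coarser than 300 m, so the
  accuracy filter and nearest-segment assignment are exercised
  end-to-end. These records are synthetic by construction and labelled
  as such in the scene manifest.

Every random draw flows from the single config seed through named
substreams, so changing the number of roads cannot perturb the rasters,
and a scene is a pure function of (config, truth, seed).

What passing tests on such scenes do *not* show: robustness to survey
bias, to spatially autocorrelated residuals, to misreported collision
locations beyond the modeled jitter, or to a species whose distribution
shifts over the study period. Those are properties of real data the
generator deliberately does not imitate.

## Numerical choices

- Grid cells are half-open $[x, x+w) \times [y, y+w)$, so every point
  belongs to exactly one cell and raster sampling needs no tie rule.
- Road segmentation splits each polyline at every grid-line crossing and
  groups sub-edges by the cell of their midpoint; clipping slivers below
  1 mm are merged into a neighbor. Total length is conserved to floating
  point (the tests require $10^{-6}$ relative; observed error is at
  machine precision).
- The GLM uses `stats::glm` IRLS with tolerance $10^{-8}$ and up to 100
  iterations; non-convergence, aliased columns and diverging
  coefficients (|b| > 1000, the separation signature) are reported as
  errors, not silently returned.
- `cloglog`/`cloglogInv` are computed via `log1p`/`expm1`; round-trip
  error over $p \in [10^{-9}, 1-10^{-9}]$ stays below $10^{-10}$. For
  rates above $\approx 36$, $1-e^{-C}$ rounds to 1 in double precision,
  so the theoretical guarantee $p < 1$ holds on that domain only.
- The sequential deviance decomposition refits nested models in the
  requested term order; shares are order-dependent by construction (the
  default order is exposure, volume, speed) and sum to 1 exactly because
  the last nested model is the full model.
- ROC AUC is the rank-sum estimator with ties counted one half.

## Hold-out validation

The validation batch is a fresh set of collision outcomes simulated on
the same network from the same truth (new seed), mirroring a temporally
distinct reporting year under the framework's static-equilibrium
assumption. `validateHoldout()` reports ROC AUC plus a decile calibration
table with 99% binomial envelopes.

## Problem sizes

The default scene is 40 × 40 km at 1 km resolution (1,600 cells), ~60
roads yielding ~1,600 segments, 500 presence and 2,000 background
points, and traffic observations on half the segments; a full pipeline
run fits in seconds. The test suite uses smaller scenes for geometry
properties and larger plain simulations (up to 50,000 segments, 200
replicate fits) where statistical guarantees are being measured. These
sizes were chosen so the whole suite runs comfortably on a laptop while
keeping Monte-Carlo noise well inside the asserted tolerances.

## Known limitations

- Binary outcomes only; no count or categorical variants, no spatial
  random effects or autocovariates, no temporal (diel/seasonal)
  structure.
- Segment-level independence is assumed; spatial autocorrelation of
  residuals will understate standard errors on real data.
- The alternative "flat" model is provided for comparison, not
  inference: its coefficients confound animal and traffic effects, which
  is precisely the interpretability problem the structured framework
  avoids.
- Geometry is planar; use projected coordinates in meters.
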