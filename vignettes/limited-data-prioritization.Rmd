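---
title: "Limited-data spatial prioritization: methods and design notes"
author: "salamandr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Limited-data spatial prioritization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The Chinese giant salamander (*Andrias davidianus*) is a critically
endangered amphibian for which only two kinds of occurrence information
exist: a handful of single-site records with associated environmental
measurements, and historical gazetteer records logged at county,
municipality or mountain-range resolution with no environmental data at
all. `salamandr` implements, as a reusable and fully testable pipeline,
the analysis chain such limited data support:

1. a **threshold-envelope habitat suitability model** built from the
   environmental ranges at occupied sites;
2. **zonal statistics** converting the suitability surface into percent
   suitable habitat per county;
3. a **permutation F-test** asking whether counties with historical
   records hold more predicted habitat than chance allows;
4. the **interview-survey statistics** used to ground-truth the model:
   last-sighting date normalization, a 2x2 chi-squared comparison of the
   two county-selection arms, and a battery of hierarchical models;
5. a **simulation-based power analysis** of the survey design.

Because the original rasters and raw interview responses are not publicly
deposited, every stage runs against synthetic data with known ground
truth; the generators are first-class, tested package code, not fixtures.

## The envelope model

A cell is suitable iff **all** conditions hold (the intersection of the
per-variable ranges at occupied sites):

* elevation in [190, 1330] m a.s.l.;
* mean annual temperature in [12.7, 16.8] deg C;
* annual precipitation >= 732.6 mm;
* land cover in the forest category (tree cover, shrub cover and
  tree/natural-vegetation mosaic collapsed into one class).

All comparisons are **inclusive**: the published ranges are values
attained at occupied sites, so a site exactly on a bound is, by
construction, suitable. Nodata in any input propagates to nodata in the
output — a cell with a missing predictor is *unassessed*, not unsuitable.

Two numerical conventions matter:

* **Annual precipitation is the sum of the 12 monthly totals** (default
  `precipMode: sum`). Monthly climate layers are conventionally described
  as "averaged" for both variables, but the 732.6 mm threshold is plainly
  an annual total (the occupied-site values run 732.6–1,600 mm, an order
  of magnitude above any monthly mean), so the sum is the only reading
  consistent with the threshold. `mean_x12` and the literal `mean` remain
  available as configuration switches.
* **Grid convention**: cell-centre registration, row 1 = north, upper-left
  corner origin, half-open pixel footprints. Resampling is
  nearest-neighbour for categorical layers, bilinear for continuous ones,
  with no on-the-fly reprojection (mismatched CRS tags are an error).

Rasters are read and written as ESRI ASCII grids, a plain-text exchange
format every GIS stack ingests; the CRS is carried as an opaque tag.

## Zonal statistics

County percentages use cell-centre containment and count only assessed
cells: nodata suitability cells enter neither numerator nor denominator,
so `percent_suitable` reflects assessed area. Zones whose every cell is
unassessed get a missing flag and are excluded from downstream inference.
When zones arrive as polygons they are rasterized by centre containment
(even-odd rule); a centre on a shared boundary goes to the first-listed
polygon, and a centre strictly interior to two polygons is an error —
overlap is never resolved silently. These choices keep the operation
exactly reproducible by a per-cell loop, which is how the tests verify it.

## The permutation test

The observed statistic is the overall regression F of a linear model of
percent suitable habitat on the binary presence indicator — identical to
the two-group one-way ANOVA F. Proportions are deliberately left
untransformed (they contain many zeroes, which a logit cannot carry). The
null distribution is built by permuting the presence labels **without
replacement**, preserving the number of presence counties, which is the
standard exchangeability construction; a with-replacement label bootstrap
is available as a sensitivity option. When the number of distinct label
arrangements is no larger than the iteration budget (default 10,000) the
test switches to exact exhaustive enumeration automatically.

Two reporting choices are worth making explicit. The comparison rule
defaults to `greater_equal` (ties with the observed F count as extreme,
so the p-value can never be exactly zero under enumeration); the strict
`greater` rule is available. And although the F statistic is inherently
one-sided, a signed-slope statistic with a genuinely two-tailed
comparison is provided (`statistic = "slope"`) for users who want a
directional null.

## Interview records

Respondents describe last sightings in four formats, all normalized to
whole years before the interview: calendar years directly; "years ago"
verbatim; decades via the **decade midpoint** (1985 for "the 1980s"),
which is unbiased if sightings are uniform within the decade
(configurable to the decade start); and "I was N years old" as
`age - N`. Reports decoding to a sighting *after* the interview are
flagged and excluded with a count; unparseable reports become missing
with a warning. Interview timing is resolved to the year — sub-year
information is ignored throughout.

County summaries carry the reporting proportion and two recency
responses: the minimum (most recent sighting, a count of years) and the
mean years-ago. Counties with no dated sightings have no defensible
recency value, so the minimum stays missing; the *mean* response is
zero-filled by default (`meanYearsZeroFill = TRUE`) because the Tweedie
model downstream is designed precisely for a response mixing zeroes with
noninteger positive values.

## The hierarchical model battery

All four families share one structure: county-level response, fixed
effects (intercept and the county-selection-method contrast) and a
province random intercept, fitted by **direct maximization of the exact
marginal likelihood** with adaptive Gauss–Hermite quadrature (AGQ). The
outer integral over each province intercept uses 15 nodes centred at the
conditional mode with Laplace scaling; with the observation-level random
effect (OLRE), each county contributes an inner 1-D integral, again by
15-node adaptive quadrature, exploiting the conditional independence of
counties given the province effect. AGQ rather than Laplace-only is
deliberate: several provinces contain one or two counties, exactly where
the Laplace approximation is weakest. The node count is a tested
convergence choice — estimates move by less than 1e-3 between 15 and 25
nodes on reference fits.

Numerical choices:

* Variance components are optimized on the log-SD scale with a lower
  bound of 1e-6 and, by default, three starting values (0.3, 1, 0.03) to
  dodge boundary local optima; SD estimates below 1e-4 are reported as 0.
  The power simulation uses a single start (the GLM initialization is
  reliable there, and the saved multiplications matter at hundreds of
  fits); all standalone fits keep the multi-start default.
* The negative binomial uses the quadratic NB2 parameterization
  (variance mu + mu^2/theta), matching the GLMM software families this
  battery mirrors.
* The Tweedie index p is profiled on a grid over (1.05, 1.95) and
  refined by a bounded 1-D optimizer; beta, sigma and phi are
  re-optimized at every candidate p, warm-started from the previous
  solution. The Tweedie log-density itself is the exact compound
  Poisson–gamma series with adaptive truncation (tail terms below 1e-12
  of the leading term), with the zero mass in closed form.
* Overdispersion is summarized as the sum of squared Pearson residuals,
  conditional on the estimated random-effect modes, divided by the
  residual degrees of freedom (n minus fixed effects minus variance
  components). The analysis refits the binomial model with an OLRE when
  this ratio exceeds 2.
* Likelihood-ratio tests use the naive chi-squared reference, as the
  applied literature does; for variance components tested on their
  boundary the 50:50 mixture p-value is also reported (`pBoundary`),
  informationally. A negative chi-squared from numerical noise is
  clamped to zero with a warning.
* Whether the province intercept is retained in every family is treated
  as stated: all models in the battery keep it; fits without the method
  effect (`methodEffect = FALSE`) provide the nested nulls.

## The synthetic-data generators

The generators encode the statistical structure the analysis assumes, so
passing tests demonstrate internal correctness — parameter recovery,
calibration, invariances — on data whose truth is known and stored.

* **Landscapes**: spatially autocorrelated fields are white noise
  smoothed by a separable moving-average kernel (configurable length),
  the simplest mechanism producing contiguous climate-like patches.
  Monthly temperature adds a seasonal cosine and an elevation lapse;
  monthly precipitation a wet-season cycle, floored at zero. Counties
  are the Voronoi cells of random seed points (contiguity guaranteed by
  nearest-seed assignment); provinces group county seeds by k-means.
* **Historical records**: county presence is Bernoulli with a logit link
  in percent suitable habitat, so the association the permutation test
  looks for is injected with known strength.
* **Interviews**: report flags follow a binomial GLMM with province
  intercepts and county-level extra-binomial noise — the very structure
  the model battery assumes — with the arm effect specified on the
  probability scale and converted to logit at the baseline. Reporters
  get a true years-ago value (negative binomial, mean 20 years by
  default, reflecting that most sightings date back decades) rendered
  into one of the four raw formats; for decade reports the true sighting
  year is snapped to the decade midpoint first, so normalization
  round-trips exactly. Ground truth is retained as an attribute and
  written to a JSON sidecar by the pipeline, so tests never re-derive it
  from outputs.

What the generators do **not** emulate: real Chinese geography and
climate fields (anisotropy, orographic rainfall, river networks), spatial
correlation in interview responses beyond the province/county hierarchy,
respondent recall error, and identification mistakes correlated with
sighting age. Tests passing on these data therefore demonstrate that the
implementation is correct under the stated model, not that the model
captures every feature of the real survey.

## Survey power

The power analysis simulates complete surveys at the reference design the
package mirrors: 95 counties in 15 provinces (per-province county counts
6, 3, 1, 4, 1, 10, 32, 3, 4, 12, 2, 3, 9, 1, 4), split 48 (historical) /
47 (model-selected) by alternating assignment within provinces, ~30
respondents per county, baseline reporting probability 0.45. The
province and OLRE SDs both default to 0.5 on the logit scale: no
empirical estimates of these variances are available for the original
survey, so they are declared configuration values, reported with every
result, chosen as moderate heterogeneity for this kind of multi-team
survey. Each
replicate fits the binomial model, switches to the OLRE variant when the
dispersion ratio exceeds 2, and tests the arm effect by LRT at alpha =
0.05 — the inference route of the main analysis, not a Wald shortcut.
At a true difference of 0.10 on the probability scale this design
reaches at least 80% power (200 replicates), which
`scripts/acceptance.R` recomputes from scratch.

## Problem sizes

The shipped configuration and test suite run everything at desk scale,
chosen as the smallest sizes at which each statistical property is
sharply testable: landscapes of 80 x 80 (pipeline default) down to 24 x 24
cells (property tests), 10,000 permutation iterations, 1,000 null
datasets for size calibration, 200 replicates for the power claim, and
parameter-recovery batteries of 5–12 seeded fits per family. The
country-scale inputs of the original study (30 arc-second rasters,
2,852 counties) are deliberately out of scope: those headline numbers
depend on undeposited data and are not reproducible from a desk.

## Known limitations

* The envelope model is a presence-only rectangle in environment space;
  it cannot weigh evidence, rank habitat quality within the envelope, or
  accommodate interactions — that is a property of the method, preserved
  deliberately.
* The AGQ engine handles one nesting level (province) plus an optional
  OLRE; crossed random effects are out of scope.
* Tweedie fits profile p within (1.05, 1.95); responses that are really
  Poisson-like (p -> 1) or gamma-like (p -> 2) sit on the profile
  boundary and are reported there.
* ESRI ASCII grids carry no CRS; the opaque tag must be supplied by the
  caller, and mismatches are an error rather than a reprojection.
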