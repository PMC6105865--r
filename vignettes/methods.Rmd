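---
title: "Grid sampling and ecological Poisson models of geosocial app user density"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid sampling and ecological Poisson models of geosocial app user density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(appdensity)
```

## The problem

Geosocial networking apps display nearby users as a grid ordered by
Euclidean distance. Counting the profiles visible within a fixed radius of a
set of virtual sampling locations gives an estimate of the spatial density
of app users — for apps used by gay, bisexual and other men who have sex
with men (gbMSM), a population whose spatial distribution is poorly captured
by general census counts, this is a practical instrument for planning
sexual-health services. The density surface can then be regressed on
neighbourhood-level census covariates to ask *which kinds of neighbourhoods
have more app users*.

This package implements that whole chain as a reproducible pipeline:

1. a **synthetic geography generator** (tessellated dissemination areas,
   spatially autocorrelated census-style covariates, an inhomogeneous
   Poisson point process of users);
2. the **virtual sampling protocol** (systematic grid, distance-ordered
   listings, a positional rule for location-withheld profiles, land-area
   denominators, a rounded integer density outcome);
3. **areal covariate aggregation** (combined area and population weighting);
4. **Poisson regression** with a forced sampling-time block, backward AIC
   elimination, likelihood-ratio comparison, McFadden pseudo r², incidence
   rate ratios, and a Bonferroni outlier test.

Because no real app listings or census extracts ship with the package, the
generator is first-class, tested code: it defines the study conditions under
which every downstream stage is validated.

## The generative model

The study region is a rectangle in planar statute miles (no projection
handling; a real deployment would feed projected coordinates). Dissemination
areas (DAs) are the Voronoi cells of uniform random seeds, clipped to the
region — irregular, space-filling polygons that partition the region
exactly, like census DAs partition a city.

Each covariate is an independent Gaussian random field: white noise at the
DA centroids smoothed by a Gaussian kernel (bandwidth
`covariate_smoothing_bandwidth`, default 3 miles), standardized, truncated
at ±2.5 standard deviations, and mapped affinely onto a plausible
metropolitan range — centred on the catalogue median with half-IQR
dispersion. Population density is mapped on the log scale, giving the heavy
right tail real density surfaces have. Truncation keeps the log-linear
intensity below from producing runaway counts in the extreme tail; the
quartiles of a ±2.5-truncated normal are essentially unchanged. DA
population is defined as `pop_density × area` (with the km²/mi²
conversion), so population and the density covariate can never contradict
each other.

Users form an inhomogeneous Poisson point process. For DA $j$ with scaled
covariate vector $x_j$ (density per 100 persons/km², income per Can $1000,
percentages on 0–100),

$$N_j \sim \mathrm{Poisson}(\lambda_j \, \mathrm{area}_j), \qquad
\log \lambda_j = \beta_0 + \beta^\top x_j,$$

with points uniform inside the DA polygon. The default $\beta$
(`default_beta()`) uses incidence-rate-ratio magnitudes typical of a
metropolitan app-user surface — e.g. 1.08 per percentage point of
not-married men, 0.26 per additional household member — with zeros for three
covariates (percent male, percent unemployed, percent visible minority) that
carry no independent signal, and $\beta_0 = 3.1$, which yields on the order
of 4 000–4 500 users over the default 32 × 32 mile region and roughly
2 000–2 500 counted profiles per campaign. Each user withholds their
location with probability `p_hidden` (default 0.254, matching the audit
rate the protocol was designed around); a `function(x, y)` can be supplied
instead to make privacy spatially varying.

**Sampling-time effects.** App activity varies by evening and day. The six
sampling slots (Mon/Tue/Wed × before/after 8 pm) carry log-scale effects
(`default_slot_effects()`); at each visit the user pool is thinned with
probability $\exp(e_s - \max_s e_s)$. Thinning preserves the Poisson
structure, so the fitted slot contrasts estimate differences of the slot
effects — the generative role of the forced "time-day interaction" block,
which the regression treats as one 6-level categorical with Monday-before-8
as reference.

## The sampling protocol

Sampling points are the lattice `origin + (i·s, j·s)` inside the region;
default spacing 2 miles, counting radius 1 mile, so buffers are tangent and
interior-disjoint, and the default origin (0.5, 0.5) places edge buffers
partly off-map, exercising the coastline/land-area path. The visiting order
is a uniform random permutation, partitioned chronologically into the six
slots with sizes differing by at most one.

At each point the app screen is emulated: users sorted by ascending
distance (ties by id), truncated to the nearest `max_list` (default 100 —
the order of profiles a typical grid app exposes per screen; the truncation
length is a free design parameter). A profile's distance is displayed only
if it shares location. Classification against the radius is **positional**:

* displayed distance ≤ radius → included; > radius → excluded;
* hidden, listed **before** the last displayed entry within the radius →
  included (the ordering forces it inside);
* hidden, listed **after** the first displayed entry beyond the radius →
  excluded;
* hidden between those anchors, or with no resolving anchor (including a
  fully hidden listing) → **ambiguous**, never counted.

Counted users are blocked for the rest of the campaign (first-seen-wins in
sampling order), so nobody is counted twice even when buffers overlap.

The outcome is **density**: counted users divided by the land area within
the radius — the disc intersected with the union of DA polygons, territory
outside the tessellation counting as water — rounded *half away from zero*
to an integer. Half-away was chosen over banker's rounding for
explainability; which convention the protocol intends is genuinely open.
Buffers with zero land area are dropped with a warning rather than
producing an infinite density.

## Areal covariate aggregation

Explanatory variables live on DAs; the analysis unit is the buffer. For
buffer $i$ and DA $j$, with $a_{ij}$ the DA area inside the buffer, $A_j$
the DA area and $P_j$ its population,

$$w_{ij} = P_j \frac{a_{ij}}{A_j}, \qquad
\bar{x}_i = \frac{\sum_j w_{ij} x_j}{\sum_j w_{ij}}.$$

This is our reading of a "combined area and population-weighted average";
no equation is standard, so the formula is stated prominently and tested
against brute-force summation. Weighting uses **total** population (not
male population — also an open choice, documented here). The weighted value
is a convex combination, hence always within the range of contributing DA
values, and $\sum_j (a_{ij}/A_j) A_j$ reproduces the buffer's land area
exactly — both are tested invariants. Scalings are applied after
aggregation (linear, so the order is immaterial): density per 100, income
per Can $1000.

## Models, selection, diagnostics

`fit_poisson()` is `stats::glm` with `poisson(log)` and IRLS controls
(deviance tolerance 1e-8, 100 iterations); the covariance is the inverse
Fisher information. The default outcome is the rounded density, matching
the protocol; modelling the raw count with `offset(log(land_area))` is
available behind `offset_mode = TRUE` but is deliberately not the default.

`backward_eliminate_aic()` starts from all candidate covariates plus the
forced slot block, and repeatedly removes the drop with the lowest AIC
while that improves the current AIC; ties within 1e-10 resolve to the
earliest-listed candidate. The greedy path is cross-checked step-for-step
against `MASS::stepAIC` in the tests.

Model comparison uses the likelihood ratio test
($2(\ell_f - \ell_r)$ on a $\chi^2$ with the parameter-count difference)
and McFadden's pseudo $r^2 = 1 - \ell/\ell_0$ against the **intercept-only**
null (whether the null should contain the forced time block is open; we use
intercept-only and say so). The Bonferroni outlier test studentizes
deviance residuals, $r_i = d_i / \sqrt{1 - h_i}$, refers them to the
standard normal, multiplies the two-sided p by $n$ and flags at 0.05. No
overdispersion adjustment is made (the analysis this emulates fits plain
Poisson); the quasi-Poisson Pearson scale is reported in `glance()` as a
diagnostic only.

## Numerical choices

* All polygon work is exact, not approximate: Voronoi cells by successive
  half-plane clipping with a nearest-first early stop; disc–polygon
  intersection areas by decomposing the polygon into origin-anchored
  triangles and intersecting each with the disc analytically (chord pieces
  contribute triangle area, outside pieces circular sectors). A fully
  interior 1-mile disc yields exactly $\pi$ square miles; a disc bisected
  by a straight boundary exactly $\pi/2$. Monte-Carlo integration is kept
  as an independent oracle in the tests, never as the implementation.
* Degenerate tessellation draws (a collapsed cell) are re-drawn, at most
  ten times.
* Quantiles use the linear-interpolation rule (`stats::quantile` type 7).
* Listing ties (equal distances) break by user id, making every listing a
  total order and the campaign fully deterministic given the seeds.
* Every stage seed is derived from `sim_config()$rng_seed` and recorded in
  the output manifest; two runs from one configuration are byte-identical.

## What the generator does and does not emulate

It emulates: irregular space-filling ecological units; spatially smooth,
plausibly ranged covariates; a log-linear user intensity; privacy
withholding; evening-by-day activity variation; coastline (off-map
territory). It does **not** emulate: real geography or census values,
spatial autocorrelation of *residual* density beyond the covariates,
users moving between sampling slots, correlated covariate fields (fields
are generated independently; sample correlations at buffer level can still
be substantial because of smoothing), or distance quantization/noise in the
app display. Passing tests therefore demonstrate the pipeline's
correctness and calibration under its assumed generative law — not that
the substantive field estimates would replicate.

## Statistical calibration, and one caveat about AIC

The test suite checks, among others:

* Wald 95% CI coverage per coefficient over 200 replicates of outcomes
  simulated from the fitted design at the default campaign size
  (~256 buffers), within three binomial standard errors of 0.95. This is
  run at the *model* level (outcomes drawn from the Poisson GLM on the
  realized design matrix): the buffer-level GLM is not literally the
  DA-level generative law (areal aggregation, rounding and listing
  truncation intervene), so exact coverage through the full chain is not a
  theorem. The full chain is instead validated by direction: a
  strong-signal world recovers the sign of every nonzero coefficient in
  the selected model.
* Likelihood-ratio p-values simulated under the reduced model are uniform
  (Kolmogorov–Smirnov at the 1% level, 500 replicates).
* Family-wise control of the outlier flags under a null simulation.

One property deserves honesty: with all covariate effects truly zero,
backward AIC elimination still retains a noise covariate whenever its
$\chi^2$ exceeds 2 — probability ≈ 0.157 per term — so a "selects the empty
model" expectation is not achievable with eleven candidates (the empty
model is selected in roughly one replicate in six). The tests assert the
attainable property: signals are never lost, noise is dropped first, and
the mean retained fraction of pure-noise candidates stays well below the
AIC retention rate's upper bound.

## Problem sizes

Defaults were chosen as a desk-scale analogue of a metropolitan campaign:
400 DAs and 256 sampling points over 32 × 32 miles (the scale of a
metropolitan campaign of a few hundred locations), ~4 000 synthetic users, audits of 5 × 100 profiles.
Replicate studies in the tests use either this default size (sign
recovery, CI coverage, LRT uniformity) or a reduced 80-DA / 64-buffer world
with a fixed geography and redrawn users, which keeps each replicate near a
second while preserving the spatial structure under test.

## Worked example

```{r example, eval = FALSE}
cfg <- campaign_config(sim_config(rng_seed = 1))
res <- run_pipeline(cfg, out_dir = "campaign_out")
print(res)
res$table2                 # IRR table of the selected model
autoplot(res$fits$selected)  # forest plot
plot_buffers(res$buffers, res$outliers$selected)
```

## Limitations

Ecological associations estimated at buffer level need not hold for
individuals; the positional inclusion rule undercounts where privacy is
spatially clustered; `max_list` truncation can saturate counts in extreme
hotspots; and the plain Poisson likelihood ignores overdispersion and
residual spatial autocorrelation (no CAR/SAR or negative-binomial variants
are provided, deliberately matching the emulated analysis).
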