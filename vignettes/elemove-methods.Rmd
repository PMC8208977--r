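---
title: "Movement behaviors, hidden states and behavioral syndromes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement behaviors, hidden states and behavioral syndromes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(elemove)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, the numerical choices made where a design was
genuinely open, and the limits of what its synthetic validation shows.

## Data model and cleaning

A *fix* is one GPS record: individual, sex, region (collaring area), a UTC
timestamp plus a fixed local-clock offset, and planar coordinates in
metres. Longitude/latitude input is projected once with a spherical
transverse-Mercator centred on the data centroid (adequate at regional
extents; datum pipelines are out of scope). All distances and areas are
Euclidean in this single frame.

Cleaning follows common telemetry practice:

* **Speed filter** (`filter_speed`, default 7 km/h): walking forward in
  time, a fix is dropped when its straight-line speed *from the last
  retained fix* exceeds the threshold. The sequential form (rather than
  testing raw consecutive pairs) makes the filter idempotent and robust to
  a single outlier dragging its neighbours out; only the threshold itself
  is inherited from the collar-platform convention.
* **Bursts** (`segment_bursts`, default gap 2 h): maximal runs of fixes
  with all internal gaps at or below the threshold. Steps and turning
  angles are never built across a burst boundary, so irregular sampling
  cannot masquerade as movement. The 2-h default reflects the fix-interval
  regularity that `regularity_report` verifies (hourly collars in the
  motivating data keep >95% of gaps within 2 h).
* **Duplicate timestamps** keep the first record, with a warning —
  deterministic and auditable.

## The 2-state movement HMM

Step length `x_t` (m) and turning angle `a_t` (rad, counter-clockwise
positive) are modelled per state `s`: `x_t ~ Gamma(mean μ_s, SD σ_s)` and
`a_t ~ vonMises(m_s, κ_s)`, with transition matrix `Γ` and the stationary
distribution of `Γ` as the initial law (one fewer free parameter; standard
for movement HMMs). An optional per-state point mass handles exact-zero
steps, where the gamma density is undefined; missing angles (burst starts,
zero-length neighbours) contribute a likelihood factor of 1.

The forward recursion is scaled and runs per burst (bursts multiply); it
is implemented in C++ because it is evaluated thousands of times inside
the optimizer. Fitting maximizes the likelihood over an unconstrained
working parametrization — log for `μ, σ`, the Cartesian pair
`(κ cos m, κ sin m)` for the circular parameters (removing the angular
boundary), logits for transition rows and zero masses — from a
moment-based start (median split of step lengths) plus random
perturbations (`n_restarts = 10`, default). The zero-mass parameters are
only estimated when the data actually contain exact-zero steps.

Label switching is resolved by a single rule: *exploratory is the state
with the larger step-length mean*. This makes fits invariant to
permutations of the start values, which is tested. One pooled fit across
individuals is the default, so states mean the same thing for every
animal; per-individual fits are available by passing a subset of steps.
Viterbi decoding is exact per burst, with ties broken toward encamped.

## The five behaviors

Per individual and calendar window (month or year, by the local clock):

* **Movement distance**: the sum of within-burst consecutive-fix
  displacements, in km. Because each step is assigned to the window of its
  start fix, the 12 monthly distances of a gap-free year sum *exactly* to
  the annual distance.
* **Home range**: area of the 95% isopleth of a bivariate-normal kernel
  density on a regular grid (default cell 250 m, extent padded by `3h`).
  The smoothing parameter is fixed per temporal scale as the mean of the
  bivariate normal reference bandwidth
  `h_ref = sqrt((var(x)+var(y))/2) · n^(-1/6)` across all
  individual-window point sets at that scale, overridable by
  configuration (e.g. to values a given study reports). The isopleth is
  the smallest set of highest-density cells holding 95% of the
  discretized mass; with ~1 km bandwidths, a 250-m cell keeps the
  discretization error of the area well under the 10% tolerance the KDE
  test enforces.
* **Site fidelity**: `area(R_t ∩ R_(t-1)) / area(R_(t-1))` for
  *consecutive* windows, computed on a shared grid; missing at a window
  with no preceding one. The denominator choice (previous range) is a
  documented convention; an intersection-over-union variant is available.
* **Diurnality**: per day, (day − night) / total distance, a step counted
  as day when its start fix falls in [06:00, 18:00) local; the window
  value averages the daily indices over days with nonzero distance. With
  hourly fixes, assigning a step by its start time misclassifies at most
  the boundary hours.
* **Exploratory proportion**: the fraction of decoded steps in the
  exploratory state.

Inclusion rules: monthly records require at least 50% of the month's hours
to carry a fix (the completeness threshold is configurable; no standard
exists); annual records require a full calendar year, i.e. all 12 months
at that coverage. Every excluded window is logged with its reason.

## Covariates

Rasters live on the same planar frame (plain-matrix grids; ESRI-ASCII
text I/O for interchange and fixtures). Temperature seasonality is the
per-cell population SD of 12 monthly means. Missing NDVI cells take the
previous month's (already filled) value; leading gaps stay masked, and the
annual layer is the per-cell mean of the filled months. Covariate
extraction is the mean over cells whose *centres* fall inside the 95%
region (cell-centre inclusion; the choice is invariant to padding the
raster with masked cells). Monthly records pair with that month's rainfall
and NDVI layers, annual records with the annual layers; human footprint is
static. Predictors are z-scored (1 SD); responses are z-scored after an
optional transform — home-range area is log-transformed by default, the
natural choice for a strictly positive, right-skewed area. A scale-only
("SD units") response mode exists because conventions differ.

## Univariate models

Each behavior is modelled as Gaussian on the standardized scale with fixed
effects (sex, NDVI, human footprint, temperature seasonality, rainfall)
and random intercepts for individual and region, plus month at the
monthly scale. Priors: inverse-gamma (V = 1, ν = 0.002) on the residual
variance, and the parameter-expanded prior (V = 1, ν = 1, α_V = 625) on
each random-effect variance, which keeps the sampler mobile when a
variance is near zero. MCMC defaults: the *test preset*
8,500 iterations / 500 burn-in / thinning 4 (2,000 retained draws) used
throughout the test suite; `mcmc_control_full()` gives the
850,000 / 50,000 / 400 production preset with the same retained-draw
count.

One numerical choice matters a lot: all location effects — the fixed
effects *and* every random-intercept block — are drawn in a single joint
Gaussian update from the mixed-model equations, with the cross-product
blocks precomputed once and only rescaled by the expansion multipliers.
Single-site updates are catastrophically slow precisely in the case this
design creates (sex constant within individual, hence confounded with the
individual intercepts); the joint update removes that pathology, and at
fixed variances it draws exact iid posteriors, which the test suite
compares against the closed-form GLS posterior and against REML.

Summaries per draw: equal-tailed 95% credible intervals with a
CI-excludes-zero significance flag; adjusted repeatability
`R_adj = V_ind / ΣV`; marginal/conditional R² from the realized
fixed-predictor variance; percent change across a covariate's observed
range (back-transformed through the stored scaling, closed-form checked
for the log link); and effective sample sizes via Geyer's
initial-positive-sequence estimator (a variance component with ESS < 100
triggers an explicit caution, which matters in practice for site
fidelity, the least repeatable trait).

## Multi-response model and syndrome axes

The monthly table's four repeatable traits (distance, home range,
diurnality, exploratory proportion; site fidelity is excluded for want of
among-individual variance) enter one Gaussian multi-response model with
the same fixed effects per trait and unstructured 4×4 covariance matrices
at the individual, region, month and residual levels. Updates are
matrix-normal for the coefficient block and per-group random vectors
(batched over groups of equal size) and conjugate inverse-Wishart for
every covariance level, with a weakly informative scale `0.01·I` and
`traits + 1` degrees of freedom. A proper inverse-Wishart needs
`df > p − 1`, so the univariate residual prior does not transfer
literally to matrices; published analyses of this kind report robustness
to the prior on the covariances, and the conjugate choice keeps the
sampler exactly testable. No parameter expansion is used at the matrix
level.

Among-individual correlations are computed per draw and summarized
(posterior mean, 95% CI); the conventional display puts variances on the
diagonal, covariances below and correlations above. Syndrome axes come
from eigen decomposition of the *posterior-mean* among-individual matrix;
each draw's matrix is then decomposed and its eigenvectors sign-aligned to
the point axes (positive dot product) before loading-wise and
eigenvalue-share quantiles are taken — eigenvectors are sign-ambiguous,
and without alignment the CIs would be meaningless. The largest-magnitude
loading of each point axis is made positive, and a warning is raised when
the top-two share CIs overlap (the leading axis is then not identified).

## The synthetic generator

`simulate_population` is the package's stand-in for collar data and
defines the validation conditions: 96 individuals in 7 regions, hourly
fixes over 18 months (trimmed in tests for runtime), gamma step means
100/1000 m (SD 80/600 m), κ = 0.5/2 and self-transitions 0.9 — the same
well-separated regime the recovery tests target. Each individual draws a
4-vector of latent modifiers (log step scale, exploratory-transition
logit, diurnal amplitude, log attraction) from `Sigma_I_sim`; the default
correlates step scale with the transition logit (0.7), planting one
dominant among-individual axis over distance, home range and exploration
— the structure the syndrome analysis is designed to detect. Movement is
a biased correlated random walk: bearings are von Mises draws centred on a
ρ-weighted compromise between the previous bearing and the bearing to the
individual's centre (ρ = 0.3 by default, giving stable month-scale
ranges); transition logits carry standardized raster covariates
(HFI −0.5, NDVI +0.5 per SD), an hour-of-day cosine scaled by the
individual's amplitude (0.8, day-favouring), and the individual's
modifier. Positions are clamped at the raster edge (with a warning)
rather than reflected — simpler, and irrelevant when the landscape is
large relative to the range. `simulate_behavior_table` instead draws
directly from the hierarchical model the samplers assume, giving exact
ground truth for (co)variance recovery.

What the generator does *not* emulate: GPS measurement error, fix
failures correlated with habitat, social interactions, age or musth
structure, memory beyond a single attraction centre, and real geography.
Passing recovery tests therefore demonstrates correctness of the
estimators under the assumed model class, not robustness to every field
artefact.

## Problem sizes and numerical notes

The test suite runs the samplers at the test preset with designs of
96 individuals × 18 months (model recovery), HMM fits on 4,000–20,000
steps, KDE checks on 10,000 points, and demo pipelines of 8–12
individuals over 3–6 months; these sizes were chosen so the full suite
exercises every claim at comfortable Monte-Carlo margins. Other numerical
choices: emission overflow during optimization is treated as a rejected
proposal rather than an error; near-singular covariance draws are
prevented by the proper inverse-Wishart prior; KDE isopleths normalize by
the total grid mass so the 95% region is an isopleth of the discretized
distribution; and exact ties in Viterbi break toward encamped.

## Known limitations

Two movement states only; no covariates on the HMM transition
probabilities (environmental effects enter the behavior models, not the
state process); Gaussian responses only (site fidelity and proportions
are modelled on the identity scale, adequate away from the boundaries);
no random slopes or individual-by-environment interaction terms; and the
home-range estimator is a plain fixed-bandwidth KDE, not an
autocorrelation-corrected one — with hourly fixes over month-long
windows, effective sample sizes are large and the bias is modest, but
short windows would inherit the usual KDE optimism.
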