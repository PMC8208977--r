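# elemove

Landscape-scale analysis of animal GPS telemetry, developed around
forest-elephant collar data sampled at one-hour fix intervals. The package
takes raw fix tables to population-level behavioral inference in one
pipeline:

1. **Track cleaning** — a 7 km/h sequential speed filter, fix-regularity
   reporting, and segmentation into bursts at gaps > 2 h so that no step or
   turning angle spans missing data.
2. **Movement states** — a 2-state hidden Markov model with gamma step
   lengths and von Mises turning angles. Writing `x_t` for a step and
   `a_t` for its turning angle, state `s ∈ {encamped, exploratory}` emits
   `x_t ~ Gamma(μ_s, σ_s)` (mean/SD parametrization) and
   `a_t ~ vonMises(m_s, κ_s)`, with a 2×2 transition matrix `Γ` and
   stationary initial law. The likelihood is maximized numerically
   (forward algorithm in C++, multiple restarts) and the most likely state
   path is recovered with the Viterbi algorithm. "Exploratory" is, by
   convention, the state with the larger step-length mean.
3. **Five behaviors** per individual × calendar month (and year):
   movement distance (km), 95% kernel-density home-range area (km², fixed
   smoothing parameter per temporal scale), site fidelity (fraction of the
   previous step's range re-used), diurnality
   `D = (day − night) / total` daily distance averaged over days
   (day = 06:00–18:00 local), and the proportion of steps decoded
   exploratory.
4. **Covariates** — human footprint, temperature seasonality (SD of
   monthly temperature), rainfall and NDVI rasters, forward gap-fill of
   missing NDVI months, and the mean of each layer inside each home range.
5. **Hierarchical models** — bespoke conjugate Gibbs samplers for Gaussian
   mixed models with individual/region/month random intercepts
   (parameter-expanded variance priors), giving standardized effect sizes
   with 95% credible intervals, adjusted repeatability
   `R_adj = V_ind / (V_ind + V_region + V_month + V_resid)`, marginal and
   conditional R²; and a 4-trait multi-response model with unstructured
   covariance matrices at the individual, region, month and residual
   levels, from which among-individual correlations
   `r_I = COV_I / sqrt(V_I(x) V_I(y))` and behavioral-syndrome eigen axes
   (with per-draw sign-aligned loading CIs) are derived.

A synthetic-population generator (state-switching biased correlated random
walks over simulated covariate rasters, with known individual-level ground
truth) backs every recovery test and provides demo data; real data are not
required to exercise any part of the package.

## Worked example

Fit the movement HMM to a simulated step series and decode states:

```r
library(elemove)
truth <- hmm_params(mu = c(100, 1000), sigma = c(80, 600), kappa = c(0.5, 2),
                    Gamma = matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2))
sim <- simulate_hmm_track(truth, 5000, seed = 1)
fit <- fit_hmm(sim$steps, n_restarts = 5, seed = 1)
print(fit)
```

```
2-state movement HMM fit: 5000 steps, log-likelihood -42075.61
<hmm_params> 2-state movement model
                 encamped exploratory
step mean (m)    101.3615   1014.1212
step SD (m)       81.0329    587.4884
angle mean (rad)   0.1176      0.0273
kappa              0.5249      2.0040
zero mass          0.0000      0.0000
transition matrix:
       [,1]   [,2]
[1,] 0.8941 0.1059
[2,] 0.1144 0.8856
initial distribution: 0.5192 0.4808
5 of 5 restarts converged
```

Every generating parameter is recovered within a few percent: short
encamped steps (mean ~100 m) with weak directional persistence
(κ ≈ 0.5) against long exploratory steps (mean ~1000 m, κ ≈ 2), and ~0.9
self-transition probabilities. Decoding then agrees with the simulated
truth at 98.6%:

```r
states <- viterbi_decode(fit)
mean(states == sim$states)
#> [1] 0.986
```

The whole pipeline — simulation (or `read_tracks()` on your own fixes),
cleaning, HMM, behavior tables with covariate extraction, univariate and
multi-response models, syndrome axes — runs from one config:

```r
out <- run_pipeline(pipeline_config(n_individuals = 12, months = 6,
                                    n_regions = 4, seed = 1,
                                    out_dir = "elemove_out"))
out$repeatability      # R_adj and R² per behavior
out$syndrome           # eigenvalue shares and loadings with 95% CIs
```

`elemove_out/` then holds the regularity report, behavior tables,
effect-size / repeatability tables, the among-individual matrix
(variances on the diagonal, covariances below, correlations above),
syndrome loadings and a JSON run manifest. A command-line wrapper with
the same options is installed at `inst/scripts/elemove-pipeline.R`.

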