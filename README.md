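# lerouxmap

Bayesian small-area disease mapping in R: indirect age–sex
standardization, spatially smoothed standardized mortality ratios
(SMRs), and covariate-adjusted relative risks from a hierarchical
Poisson model with Leroux conditional autoregressive (CAR) random
effects — plus the diagnostics that belong with such an analysis
(Moran's I permutation tests, variance-inflation-factor screening,
Geweke convergence checks).

The package is aimed at epidemiologists and health-services researchers
analyzing event counts (e.g. suicide deaths) over many administrative
areas, where small populations make raw rates unstable and neighboring
areas are too similar for independence assumptions to hold.

## The model

For area *i* with observed count *O*<sub>*i*</sub> and expected count
*E*<sub>*i*</sub> from indirect standardization over 2 sexes × 8 age
bands,

- *O*<sub>*i*</sub> ~ Poisson(*E*<sub>*i*</sub> exp(**x**<sub>*i*</sub>′**β** + φ<sub>*i*</sub>)),
  with log *E*<sub>*i*</sub> as offset, so exp(β<sub>*j*</sub>) is the
  relative risk (RR) per unit of covariate *j*;
- **φ** ~ MVN(0, τ² *Q*(ρ, *W*)⁻¹) with the Leroux precision
  *Q* = ρ(diag(*w*₊) − *W*) + (1 − ρ)*I* on the binary contiguity
  matrix *W*; ρ ∈ [0, 1) interpolates between independent effects and
  the intrinsic CAR;
- priors β<sub>*j*</sub> ~ N(0, 10⁵), τ² ~ IG(1, 0.01), ρ ~ U[0, 1).

Sampling is adaptive Metropolis-within-Gibbs (Rcpp core): a
GLM-preconditioned block random walk for **β**, single-site updates for
each φ<sub>*i*</sub> using the Leroux full conditional, conjugate
inverse-gamma updates for τ², and a logit-scale random walk for ρ using
the eigenvalue form of log det *Q*. The smoothed SMR of area *i* is the
posterior median of exp(β₀ + φ<sub>*i*</sub>) from the intercept-only
model. See the vignette in `vignettes/` for assumptions, parameter
choices, and limitations.

## Worked example

Simulate a 10 × 10 lattice of areas from the generative model (stratum
populations spanning three orders of magnitude, spatial effects with
ρ = 0.8, τ² = 0.1), then run the analysis:

```r
library(lerouxmap)

d <- simulateAreaData(simConfig(rows = 10, cols = 10, seed = 42))
s <- smr(d$table)                      # indirect standardization
head(s, 3)
#>   area_id observed expected    smr flag
#> 1      a1       45    39.34 1.1438
#> 2      a2       53    51.87 1.0218
#> 3      a3       42    59.19 0.7096

ss <- smoothedSMR(d$table, d$adjacency, nIter = 20000, nBurnin = 5000,
                  seed = 1)
sd(s$smr); sd(ss$ssmr)                 # shrinkage: 0.329 -> 0.256

moransI(ss$ssmr, d$adjacency, nPerm = 999, seed = 2)
#> Moran's I permutation test (style = W )
#>   I = 0.5898  (null expectation -0.0101)
#>   p = 0.001  (two.sided, 999 permutations)

fit <- fitLeroux(d$table, d$adjacency,
                 covariates = c("physicians_per_1000", "psych_presence"),
                 nIter = 20000, nBurnin = 5000, seed = 3)
posteriorSummary(fit)
#>             parameter  median   lower  upper geweke    rr rr_lower rr_upper
#> 1         (Intercept)  0.0130 -0.0498 0.0735  0.155    NA       NA       NA
#> 2 physicians_per_1000  0.0104 -0.0466 0.0613  1.389 1.010    0.954     1.06
#> 3      psych_presence -0.0866 -0.1877 0.0138 -0.135 0.917    0.829     1.01
#> 4                tau2  0.1156  0.0761 0.1754 -0.475    NA       NA       NA
#> 5                 rho  0.8159  0.4989 0.9777  2.040    NA       NA       NA
```

The raw SMR of each area is observed/expected; the smoothed SMR borrows
strength from contiguous neighbors, so its spread is smaller and the
map is stable in small areas. The positive Moran's I of the smoothed
surface reflects the simulated spatial dependence. In the fit summary,
`rr` columns exponentiate each covariate's posterior median and 95%
credible bounds: here the psychiatrist-presence indicator has RR 0.92
(true simulated value exp(−0.10) ≈ 0.90), and the Geweke column is the
convergence z-score per parameter (|z| < 1.96 indicates no detectable
drift between early and late chain segments).

`runPipeline()` (or `inst/scripts/pipeline.R` from a shell) chains the
whole sequence — SMR → smoothed SMR → Moran's I → VIF screen →
covariate fit — writing per-stage artifacts and a reproducibility
manifest.

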