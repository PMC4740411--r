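---
title: "Disease mapping with Leroux CAR models: methods and design notes"
author: "lerouxmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease mapping with Leroux CAR models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lerouxmap)
```

This vignette explains the statistical machinery the package
implements, the choices made where several defensible options existed,
and what the accompanying tests do and do not establish.

## The problem

Area-level event counts — the motivating case is suicide deaths across
~1,900 Japanese municipalities — face two coupled difficulties. First,
raw standardized mortality ratios (SMR = observed/expected) are
unstable in small areas: an area expecting half an event that records
three has a raw SMR of 6 that no one should map. Second, contiguous
areas are alike, so models that assume independent residuals
misrepresent the uncertainty of covariate effects. Hierarchical
spatial smoothing addresses both: the area effects borrow strength
from neighbors, and the spatial dependence is a modeled quantity
rather than a nuisance.

## Indirect standardization

Counts and populations are stratified by sex and eight age bands
(under 20, 21–30, ..., over 80; 16 strata). National stratum rates are
the pooled ratios $r_s = \sum_i O_{is} / \sum_i n_{is}$, expected
counts are $E_i = \sum_s r_s n_{is}$, and $\mathrm{SMR}_i = O_i / E_i$.
When the rates are computed from the analysis table itself —
the default — conservation holds by construction: $\sum_i E_i = \sum_i
O_i$, so the population-weighted national SMR is exactly 1. The
alternative, externally published rates, is supported via the `rates`
argument of `expectedCounts()`; conservation then need not hold, and
`smr()` treats an area with $E_i = 0$ but $O_i > 0$ under such rates as
an inconsistency error rather than producing an infinite ratio. Areas
with no population in any stratum get $E_i = 0$, a flagged undefined
SMR (never a silent zero), and are excluded from model fitting with a
warning, because the offset $\log E_i$ is undefined.

Stratum labels are opaque strings: the sex-by-age cross is the
default schema, but the arithmetic never parses band edges, so any
stratification can be supplied.

## The hierarchical model

With covariate row $\mathbf{x}_i$ (the motivating analysis used
physicians per 1,000 population, a psychiatrist-presence indicator,
and socioeconomic covariates),

$$O_i \sim \mathrm{Poisson}\!\big(E_i \exp(\mathbf{x}_i'\beta + \phi_i)\big),
\qquad \phi \sim \mathrm{MVN}\!\big(0,\ \tau^2 Q(\rho, W)^{-1}\big),$$

$$Q(\rho, W) = \rho\,(\mathrm{diag}(w_+) - W) + (1-\rho)\,I,$$

where $W$ is binary contiguity and $w_+$ the neighbor counts. The
Leroux precision is positive definite for every $\rho \in [0,1)$ on
any graph; $\rho = 0$ gives independent effects, and $\rho \to 1$
approaches the intrinsic CAR (the graph Laplacian). The full
conditional of $\phi_i$ is Gaussian with mean
$\rho \sum_j w_{ij}\phi_j / (\rho w_{i+} + 1 - \rho)$ and variance
$\tau^2/(\rho w_{i+} + 1 - \rho)$ — for an isolated area (islands are a
real feature of municipal contiguity) this reduces to
$N(0, \tau^2/(1-\rho))$, still proper, so isolated areas stay in the
model.

**Priors.** The source analysis does not state its priors, so the
package uses weakly informative defaults that are conventional in CAR
disease mapping and exposed as arguments: $\beta_j \sim N(0, 10^5)$,
$\tau^2 \sim \mathrm{IG}(1, 0.01)$, $\rho \sim U[0,1)$. The support of
$\rho$ excludes negative spatial dependence deliberately: the Leroux
construction targets positive autocorrelation, which is the empirical
situation in this domain.

**Relative risks.** Covariate summaries are reported as
$\mathrm{RR} = \exp(\text{posterior median})$ with exponentiated 2.5%
and 97.5% quantiles. Because $\exp$ is monotone the bounds stay
ordered. (Exponentiating a published coefficient table can disagree in
the last digit with independently rounded published RR intervals;
the package always exponentiates.)

**Smoothed SMR.** $\mathrm{sSMR}_i$ is the posterior median of
$\exp(\beta_0 + \phi_i)$ from the intercept-only model. The median
(not the mean) keeps the definition consistent with the median-based
coefficient reporting. Shrinkage is a theorem-like property here —
the tests check on every simulated dataset that
$\mathrm{var}(\mathrm{sSMR}) \le \mathrm{var}(\mathrm{SMR})$ and that
areas with smaller $E_i$ are pulled further.

## The sampler

Metropolis-within-Gibbs, implemented in C++ (Rcpp/RcppArmadillo), all
randomness drawn from R's RNG so a seed makes chains bit-reproducible:

- **$\beta$ block update.** Random-walk proposal preconditioned by the
  Cholesky factor of the inverse Fisher information of the Poisson GLM
  (no random effects), scaled by the classic $2.38/\sqrt{p}$ and
  adapted toward acceptance 0.23. The GLM estimate is also the chain's
  starting point. Preconditioning matters: with collinear covariates an
  isotropic random walk mixes an order of magnitude more slowly.
- **$\phi_i$ single-site updates**, target acceptance 0.40, one
  adaptive scale per site, using the Leroux full conditional as the
  prior contribution.
- **Identifiability.** After each sweep $\phi$ is recentred to mean
  zero and the mean moves into the intercept; without this the
  intercept and the field level trade off freely. A consequence worth
  knowing when testing recovery: the identified intercept is
  $\beta_0 + \bar\phi_{\mathrm{true}}$, not $\beta_0$.
- **$\tau^2$** is conjugate: $\mathrm{IG}(a + n/2,\ b + \phi'Q\phi/2)$,
  with $\phi'Q\phi = \rho \sum_{i<j} w_{ij}(\phi_i-\phi_j)^2 +
  (1-\rho)\sum_i \phi_i^2$ accumulated over the edge list.
- **$\rho$** moves by a random walk on the logit scale (target 0.40)
  with the determinant evaluated spectrally: $\log\det Q(\rho) =
  \sum_k \log(\rho\lambda_k + 1 - \rho)$, where $\lambda_k$ are the
  eigenvalues of $\mathrm{diag}(w_+) - W$, computed once per fit. The
  tests verify this equals the dense log-determinant to $10^{-8}$.
- **Adaptation** runs in batches of 50 during burn-in only and freezes
  afterwards, so the post-burn-in chain is a fixed Markov kernel.
- Proposal or state values producing a non-finite log-posterior abort
  with the iteration index rather than continuing silently.

Defaults follow the motivating analysis: 110,000 iterations, 10,000
burn-in, no thinning, a single chain (a multi-seed rerun is the
recommended check, but one chain per fit is the reporting convention
the Geweke diagnostic serves). Covariates are centered and scaled
internally for sampling and coefficient draws are transformed back, so
reported summaries are in the units of the supplied data. $\phi$ draws
can be kept at a coarser interval (`phiEvery`) to bound memory at full
scale; smoothed-SMR medians use the $\beta_0$ draws from the same kept
sweeps.

## Diagnostics

**Moran's I** for an area vector $x$ uses
$I = (n/S_0)\, \sum_{ij} w_{ij} z_i z_j / \sum_i z_i^2$ with $z = x -
\bar x$. The default weight style row-standardizes each area's
neighbor weights (`"W"`), the common convention for irregular
contiguity; binary (`"B"`) is selectable, and the style is recorded in
the result so the (often unstated) convention is explicit. Inference
is by random permutation of values over areas — robust for skewed SMR
distributions — with $p = (1 + \#\{|I^*| \ge |I|\})/(1 + n_{perm})$,
999 permutations by default, a one-sided option, and the analytic null
expectation $-1/(n-1)$ reported alongside. Constant vectors and
edgeless graphs are errors, not NaNs. Isolated areas contribute
nothing to the numerator.

**VIF screening.** $\mathrm{VIF}_j = 1/(1 - R^2_j)$ from regressing
covariate $j$ on the others with intercept. The screen iteratively
removes the largest-VIF covariate while any exceeds the threshold
(default 2.5, a conventional level of concern), recomputing after each
removal; ties break by column order and every step is recorded. The
one-at-a-time rule generalizes the single removal the motivating
analysis performed. Exact linear dependence reports an infinite VIF
rather than erroring; a constant column is an error because its VIF is
undefined. Two covariates correlated at exactly $r$ both have VIF
$1/(1-r^2)$ — at $r = 0.829$ that is 3.20 — which the tests use as a
closed-form anchor.

**Geweke diagnostic.** $z$ compares the mean of the first 10% of a
chain with the last 50%, with each window's variance taken from its
spectral density at frequency zero — a Bartlett lag-window sum of
autocovariances. The truncation lag uses the Andrews AR(1) plug-in, so
near-white chains get a short window (keeping the false-alarm rate of
the $|z| \ge 1.96$ flag near its nominal 5% on independent draws — the
acceptance suite checks 3–7% over 1,000 replicates) while sticky
chains get a window long enough to cover their autocorrelation.
Windows with zero variance are an error for a directly supplied chain;
inside whole-fit summaries a stuck parameter gets an NA z rather than
aborting the summary table.

## The simulator

`simulateAreaData()` draws from exactly the model above, so recovery
tests are well-posed end to end. Its defaults are the study
conditions: stratum populations log-uniform over three orders of
magnitude ($10^2$–$10^5$); national stratum rates of realistic
magnitude (tens per 100,000 person-years, male rates about 2.5 times
female, rising with age); a psychiatrist-presence indicator thresholded
from a latent Gaussian at presence probability 0.55; eight covariates
including one engineered pair (income, university) at correlation
0.829 with modest spillover correlations so the pair's VIFs land above
the 2.5 threshold; $\rho = 0.8$ and $\tau^2 = 0.1$, a strongly
autocorrelated field of moderate amplitude consistent with the strong
spatial autocorrelation reported for smoothed SMR surfaces. Simulated
area totals are allocated to strata by a multinomial on stratum
expected shares (preserving the totals the model sees while producing
realistic stratum tables), with a deterministic repair in the rare
case a draw exceeds a stratum's population.

The default spatial scale for tests is a 20 × 20 rook lattice (400
areas); full scale (~1,900 areas, or the irregular-graph option with
`type = "irregular"`) is supported but not required by the suite —
test and acceptance problem sizes were chosen so the whole suite runs
in a few minutes while leaving Monte-Carlo margins comfortable.

`expectationDataset()` replaces every stochastic element with a
deterministic counterpart — covariates, populations and $\phi$ come
from a fixed internal stream, and counts are rounded expectations — so
downstream tests can assert exact values; its output is by design
independent of the config seed.

What the simulator does **not** emulate: real geography (no municipal
boundary shapes, no mergers or district splits), covariate marginals
matched to published descriptive tables beyond order of magnitude, or
model misspecification (risk surfaces not generated by a log-linear
Leroux model). Passing recovery tests therefore demonstrates
correctness of the implementation under its own assumptions, not
robustness to violations of them.

## Design decisions and open points

- **Adjacency is a file, not polygons.** Contiguity arrives as a GAL
  neighbor list (or any symmetric binary matrix), keeping GIS
  dependencies out. Whether the source maps used rook or queen
  contiguity, and how islands were joined, materially changes $W$;
  users deriving their own $W$ should treat that choice as part of the
  analysis. Asymmetric GAL listings are symmetrized by union with a
  warning (they are common in circulated files); area order is always
  re-indexed to the area table's order.
- **National rates default to self-computed.** This forces the
  conservation identity and needs no external inputs; published
  vital-statistics rates can be injected where comparability across
  studies matters.
- **Which covariates enter the VIF screen** is the caller's choice
  (the motivating analysis screened the socioeconomic block only); the
  pipeline screens exactly the covariate list it is given.
- **Numerical edges.** $E_i = 0$ areas are excluded from fits (with a
  warning) rather than given pseudo-counts; rank-deficient designs and
  negative offsets are hard errors; `vif` treats $R^2 \ge 1 -
  10^{-12}$ as exact dependence.

## Limitations

Single-chain inference by default (between-chain diagnostics like
R-hat require a multi-run wrapper); no spatially varying coefficients;
no alternative CAR families (BYM, Cressie) beyond the $\rho = 0$ and
$\rho \to 1$ limits used as test oracles; no model-comparison criteria
(DIC/WAIC); $\rho$ is weakly identified at a few hundred areas, so its
posterior is broad even when $\beta$, $\tau^2$ and the smoothed surface
are well recovered — the tests assert coverage for $\beta$ and bounded
bias for $\tau^2$, not point recovery of $\rho$.
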