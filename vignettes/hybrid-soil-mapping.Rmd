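---
title: "Hybrid geostatistical mapping of soil properties and fertility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid geostatistical mapping of soil properties and fertility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilfertmap)
```

# The problem

Continuous maps of soil chemical properties (SCPs) — total and available
nitrogen, phosphorus and potassium, organic matter and pH — are needed for
land management in hilly terrain, but plot sampling is sparse and
expensive. `soilfertmap` implements the standard hybrid answer: interpolate
each property per depth layer by **ordinary kriging** (OK) and by
**regression kriging** (RK) with terrain covariates as drift, pick the
better method per property by leave-one-out cross-validation, and combine
the preferred surfaces into a single comprehensive fertility index.

Because no suitable field dataset is freely available at this scale, the
package ships a seeded synthetic-landscape generator that reproduces the
statistical structure the method assumes. Everything downstream — terrain
derivation, variogram fitting, kriging, validation, fertility grading — is
ordinary production code that would run unchanged on real plot tables and a
real DEM.

# The model

Each property–layer combination is treated as a random field

$$Z(s) = \beta_0 + \sum_k \beta_k q_k(s) + \varepsilon(s),$$

where the $q_k$ are terrain covariates and $\varepsilon$ is a zero-mean,
second-order stationary residual described by a semivariogram
$\gamma(h) = \tfrac{1}{2}\,\mathrm{E}[Z(s)-Z(s+h)]^2$ with nugget $C_0$,
partial sill $C$ and range $a$. OK ignores the drift and kriges $Z$
directly with weights constrained to sum to one; RK estimates the drift by
stepwise ordinary least squares, kriges the OLS residuals, and adds the two
parts. With an intercept-only drift RK collapses to OK, which the code and
tests treat as an exact identity.

## Transform rule

Following common practice for right-skewed soil nutrients, a property is
natural-log transformed when its adjusted Fisher–Pearson skewness exceeds
1.0 and all values are positive; the decision is re-made inside every
cross-validation fold. Log-scale predictions are back-transformed by plain
exponentiation by default; the lognormal correction
$\exp(\hat Z + \sigma^2_{OK}/2)$ is available (`back_transform(mode =
"lognormal")`) and demonstrably reduces mean bias on simulated lognormal
fields, but plain exponentiation is the default because validation errors
are compared on the measurement scale where the naive transform is the
conventional reference.

## Variogram estimation and fitting

The classical binned estimator uses 12 equal-width bins to half the maximum
pairwise distance by default (both configurable). Each bin records its
**mean pair separation**, and model curves are evaluated there rather than
at the nominal bin centre — on gridded samples the shortest bin's pairs sit
at the grid spacing, far from the bin centre, and evaluating at the centre
would bias the fit.

Four permissible models (spherical, exponential, Gaussian, linear) are
fitted by bounded nonlinear least squares; `kind = "auto"` keeps the lowest
weighted residual sum of squares. The default weights are **iteratively
reweighted Cressie weights** $N_j/\gamma(h_j)^2$: in recovery experiments at
the package's own acceptance conditions (spherical $C_0=0.1$, $C=0.9$,
$a=30$, 200 samples, 20 seeds) plain pair-count weights underestimated the
median nugget by nearly 40% because they concentrate weight in the
long-lag, pair-rich bins, while Cressie weights recover all three
parameters well within 30%. Pair-count weights remain available
(`weights = "np"`).

The nugget-to-sill ratio $C_0/(C_0+C)$ classes spatial dependency with the
conventional cutoffs: strong below 0.25, moderate up to 0.75 (inclusive),
weak above.

## Stepwise drift and collinearity

Drift selection is forward–backward on t-test p-values with a common entry
and stay level of 0.05, plus a variance-inflation-factor cap of 10: a
candidate whose entry pushes any VIF over the cap (including an exact
duplicate of a retained column) is not admitted. Two numerical guards
matter in practice:

* forward selection stops once the model fits to numerical precision
  (residual SD below $10^{-8}$ of the response SD) — p-values computed
  against machine-epsilon residuals are meaningless and otherwise admit
  junk covariates on noiseless data;
* backward elimination treats a NaN p-value (zero coefficient with zero
  standard error, the signature of a vacuous term after an exact fit) as 1
  and drops the term.

The model reports $R^2$, per-covariate VIF, and PRESS (the sum of squared
leave-one-out residuals, computed from the hat matrix).

Greedy selection with a VIF cap is not guaranteed to recover a generating
covariate set when a strong collinear proxy exists (on this package's
terrain stacks, local relief QFD is nearly proportional to slope); the
recovery tests therefore use generating sets without such proxies, and the
same caveat applies to interpretation on real data.

## Kriging numerics

The full (global) kriging system is solved exactly for all targets at once
— with ~70 plots there is no reason for moving neighbourhoods. Duplicate
coordinates are averaged first. $\gamma(0)=0$ is used on the diagonal, so
OK interpolates exactly when $C_0 = 0$. Two degenerate paths are handled
explicitly: a zero-sill model (for example the residuals of a
machine-precision drift fit) short-circuits to the sample mean; and an
ill-conditioned system — typically a Gaussian model whose fitted range far
exceeds the domain — is retried once with a $10^{-8}$-of-sill nugget
jitter before failing.

## Validation and method choice

Leave-one-out cross-validation redoes the *entire* fit per fold: transform
decision, empirical variogram, model fit, stepwise drift, residual
variogram. Errors are summarized as ME (bias), MRE (reported as a
fraction; a percent option exists) and RMSE, always on the measurement
scale. The preferred method is the one with lower RMSE; exact ties fall
through MRE, then |ME|, then OK by parsimony. A 70/25 modelling/validation
split mode is provided as an alternative (`run_all(validation =
"split")`), with leave-one-out the default.

## Fertility index

Each property value $c_i$ is non-dimensionalized by a continuous piecewise
score $F_i \in (0, 3]$ anchored at thresholds $x_a < x_c < x_p$ (value 1,
2, 3 at the three anchors, proportional below $x_a$). pH is scored on the
mirrored branches with descending anchors (9, 8, 7) so that lower
alkalinity scores higher; the mirror preserves continuity and the
worse-when-higher reading of alkaline soils. The comprehensive index is
the minimum-based Nemerow form

$$F = \sqrt{\tfrac{\bar F_i^2 + F_{i,\min}^2}{2}}\cdot\frac{n-1}{n},$$

a law-of-the-minimum reading: the scarcest nutrient governs. Two
consequences are surfaced rather than hidden: the classical maximum-based
form dominates this one on every input (property-tested), and with $n = 8$
the amendment caps $F$ at $3\cdot 7/8 = 2.625$, so the top class
($F \ge 2.70$) is unreachable — the code warns about this instead of
"fixing" it. Grade tables use lower-open, upper-closed intervals so a
value printed as a shared boundary falls in the lower grade; values below
a property's lowest defined bound take the lowest defined grade.
Kriged concentration surfaces can undershoot zero in sparse corners;
`fertility_surface()` floors such cells at the surface's smallest positive
value by default (with a warning), with `na` and `error` policies
available.

# Terrain covariates

Twelve covariates are derived from the DEM with a 3×3 finite-difference
stencil: slope $\beta$ (degrees), aspect $A$ (compass azimuth of steepest
descent, NA when flat), $\cos A$, $\sin A$, slope-of-slope $C_v$ and
slope-of-aspect $C_h$ (the latter with circular differences so the 360°
wrap does not create spurious gradients), relative elevation $H_r$ (global
maximum minus elevation), moving-window relief QFD (3×3 default), surface
roughness $M = 1/\cos\beta$, and flow-derived TWI, SPI and RPI. The
roughness formula is deliberately read as the secant of slope — the
reciprocal-cosine form that is 1 on flat ground and grows with slope,
consistent with its description as surface roughness; an arccos reading
would decrease with steepness and is rejected.

Flow routing is single-direction D8 over a Planchon–Darboux-style filled
surface; specific catchment area is contributing cell count (including the
cell itself) times cell size. TWI floors $\tan\beta$ at $10^{-3}$ so flat
cells stay finite; SPI uses the raw $\tan\beta$ so it is exactly zero on
flat ground (and $e^{TWI}\cdot SPI = A_s^2$ holds wherever the floor is
inactive). RPI extracts valley cells as the top 5% of flow accumulation,
ridge cells the same on the inverted DEM, and scores each cell by the
ratio of Euclidean distances, 0 at valleys to 1 at ridges. $H_r$ uses the
global maximum (not per-catchment), and isotropy is assumed throughout.

# The synthetic study

`study_config()` fixes the study conditions: a 64×64-cell, 30 m landscape
(a tilted plane plus seeded Gaussian hills, ~1.9 km across), 95 plots
split 70/25 into modelling and validation subsets, noise-free plot values,
and eight properties × three depth layers. Per property the generator
prescribes a linear terrain drift, a spherical residual variogram, layer
intercept offsets, and additive vegetation-cover offsets over ten
categories, with magnitudes chosen once to be realistic for loess-hill
forest soils: e.g. total nitrogen ~1 g/kg at the surface declining to
~0.4 g/kg at depth with negative dependence on valley-to-ridge position;
available nitrogen, available phosphorus and organic matter simulated as
lognormal fields (their field coefficients of variation of 50–90% and
right skew are what triggers the log-transform rule); pH drift-free so
that the pipeline's method selection has a known drift-free control.
Layer means decline strictly with depth for TN, TP, AN, AK and OM;
total potassium peaks in the middle layer and pH increases with depth.

Two generator design choices deserve note. First, the three layers of one
property share a single structured residual field with independent
per-layer nugget noise: soil profiles are vertically correlated (the same
plots are resampled at depth), and the sharing makes the declared
depth-ordering of layer means exact by construction instead of
probabilistic. Second, measurement noise defaults to zero because each
plot value represents a composite of sub-samples; a noise SD parameter is
exposed for sensitivity work rather than asserted.

Residual fields are drawn by exact Cholesky factorization of the model
covariance up to 4096 cells (the default grid size), with an FFT
circulant-embedding sampler above that (negative embedding eigenvalues are
clamped with a warning). Every generator is deterministic under its seed.

What the generator does **not** emulate: anisotropy, non-linear
terrain–soil relationships, covariate measurement error, spatially
clustered sampling designs, and vegetation–terrain interactions. Passing
tests therefore demonstrate correctness of the machinery and behaviour
under the assumed model, not performance on real soils where those
features occur.

# Problem sizes and runtime choices

The test-suite and acceptance-script runs use deliberately scaled problem
sizes: full-pipeline checks run on 24×24–64×64 grids with 28–95 plots,
recovery experiments use 20 seeds, and leave-one-out validation at n = 70
is the largest repeated computation. These sizes keep every property of
interest measurable (ranges well inside the domain, enough plots for
stable variograms) while the whole suite completes in minutes.

# Known limitations

* Single-pass OLS drift (no GLS iteration after estimating the residual
  structure); the classic iterated-RK refinement is out of scope.
* Isotropic, non-nested variograms only.
* D8 routing only; no multiple-flow-direction option.
* The grading tables' blank low rows (TN grade 8, TP/TK grades 7–8) are
  resolved by assigning the lowest defined grade; scoring of pH below 7
  extrapolates the mirrored branches ($F_i = 3$ below the optimum anchor).
* Planar coordinates are assumed; no projection handling.
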