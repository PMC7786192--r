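---
title: "Reaction norm models for environment-modulated genetic and residual variance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction norm models for environment-modulated genetic and residual variance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrnm)
```

## The scientific problem

In livestock populations the phenotypic variance of a quantitative trait
need not be constant across an environmental gradient. When the gradient
is the temperature-humidity index (THI) — the standard scalar summary of
heat load — two distinct kinds of heterogeneity matter for genetic
evaluation:

* **G×E interaction**: the additive genetic variance changes with THI,
  i.e. animals' breeding values depend on the environment in which they
  are expressed;
* **R×E interaction**: the residual (non-genetic) variance changes with
  THI, e.g. through management factors such as feed intake responding to
  heat.

A third phenomenon contaminates naive tests for either: a
**genotype–environment (G–E) correlation**. The environmental covariate
itself can be predictable from the genomic relationships among animals —
not because THI is heritable, but because related animals cluster on
farms, and farms differ systematically in climate. If this correlation is
not modeled, it masquerades as interaction and biases both tests and
variance estimates.

`mrnm` implements the multivariate reaction norm model (MRNM) that
addresses all three at once, together with the surrounding pipeline
(THI computation, genotype QC and GRM construction, fixed-effect
pre-adjustment) and a synthetic-data generator for calibration and power
studies.

## Models

For one record per animal, with `c` the standardized THI covariate and
`A = WW'/m` the genomic relationship matrix from column-standardized
genotypes, the full univariate reaction norm model (URNM) is

    y = mu + alpha0 + alpha1 * c + tau0 + tau1 * c

where `(alpha0, alpha1) ~ N(0, K_g (x) A)` are random genetic
regression coefficients and `(tau0, tau1) ~ N(0, K_e (x) I)` their
residual counterparts. The implied phenotype covariance is

    Cov(y_i, y_j) = A_ij * (phi_i' K_g phi_j) + [i = j] * (phi_i' K_e phi_i)

with `phi_i = (1, c_i)`. The genetic part carries the GRM Hadamard
structure; the residual part is diagonal because records are
unreplicated.

The MRNM adds the fixed-effect-adjusted covariate `c*` as a second trait,

    c* = mu_c + beta + epsilon,

with `beta ~ N(0, sigma_beta^2 A)` and `epsilon ~ N(0, sigma_eps^2 I)`,
and frees the cross-covariances `cov(alpha0, beta)`, `cov(alpha1, beta)`,
`cov(tau0, epsilon)`, `cov(tau1, epsilon)`. Those four parameters are the
G–E and R–E correlation channels: with them in the model, a likelihood
ratio test for the slope variances measures interaction net of
correlation.

Masking subsets of parameters yields the eight named models
(`greml`, `urnm-gxe`, `urnm-rxe`, `urnm-full`, `bigreml`, `mrnm-gxe`,
`mrnm-rxe`, `mrnm-full`; see `model_spec()`), compared along the
six-row ladder `run_ladder()` reports:

| index | null | alternative | tested | df |
|---|---|---|---|---|
| M1 | univariate GREML | URNM full | combined G×E and R×E | 4 |
| M2 | URNM R×E | URNM full | orthogonal G×E | 2 |
| M3 | URNM G×E | URNM full | orthogonal R×E | 2 |
| M4 | bivariate GREML | MRNM full | combined G×E and R×E | 6 |
| M5 | MRNM R×E | MRNM full | orthogonal G×E | 3 |
| M6 | MRNM G×E | MRNM full | orthogonal R×E | 3 |

The collinearity magnitude
`M(GxE & RxE) - M(GxE | RxE) - M(RxE | GxE)`, with `M(.)` twice a
log-likelihood difference, quantifies how much of the interaction
evidence the two channels share; `M(.)` is defined on the
likelihood-ratio scale so the statistic coincides with the LRT
statistics it is assembled from.

## REML engine

`rnm_fit()` maximizes the restricted likelihood

    logL = -1/2 [ (N - p) log 2pi + log|V| + log|X' V^-1 X| + r' V^-1 r ]

over the free variance parameters, with `X` holding one intercept per
modeled trait and `r` the GLS residual. Design choices:

* **Parameterization.** The free parameters are the active blocks of the
  joint 3×3 genetic covariance `[[K_g, K_gb], [K_gb', sigma_beta^2]]` and
  its residual analogue. Each active block is optimized on its
  log-Cholesky scale, so every iterate is positive semi-definite and the
  boundary (a zero slope variance) is approached smoothly rather than
  crossed. Model masks always remove whole rows/columns of the joint
  matrices, so the Cholesky factor of the active submatrix represents
  exactly the free set.
* **Optimizer.** BFGS with analytic gradients (`dl/dtheta =
  -1/2 [tr(P dV) - y'P dV P y]` chained through the Cholesky map).
  Convergence requires a relative likelihood change below `tol`
  (default 1e-8); on failure the fit restarts from perturbed values up
  to `max_restarts` times, keeping the best optimum.
* **Degenerate evaluations.** A non-positive-definite `V` or a singular
  intercept system during an optimizer excursion scores as a large
  penalty rather than an error; the count of such boundary hits is
  reported in the convergence diagnostics.
* **Standard errors.** Inverse observed information, with the Hessian
  obtained by central differences of the analytic gradient on the
  natural (covariance-entry) scale. At a boundary optimum the
  information matrix can be singular; a pseudo-inverse is used and the
  affected standard errors should be read as approximate.
* **BLUPs.** Conditional means of `(alpha0, alpha1)` given the data at
  the estimates; the per-animal total genetic effect is
  `g_i = alpha0_i + alpha1_i c_i`, the quantity whose re-ranking across
  models `ebv_rank_correlation()` measures.

Plain multi-trait GREML (`multi_trait_greml()`) exploits the shared
eigenvectors of `Sigma_g (x) A + Sigma_e (x) I`: after one rotation the
likelihood factorizes over GRM eigenvalues, so evaluations cost
`O(n t^3)` and the same quasi-Newton machinery applies.

## Likelihood-ratio reference and boundary conservatism

`lrt()` uses a plain chi-square reference with df equal to the
free-parameter difference, matching common practice for these ladders.
Every ladder null hypothesis pins at least one variance to the boundary
of its parameter space, so the true null distribution of the statistic
is a chi-bar-square mixture with substantial mass at zero; the plain
reference is therefore conservative, increasingly so in small samples
where slope variances are weakly identified (their information comes
from the `n^2/m`-scale off-diagonal GRM entries). Empirically, at the
simulation sizes used in this package's calibration studies the ladder's
type-I error at nominal 5% sits near or below 2%, and null p-values are
far from uniform (they pile up near 1). A 50:50 mixture reference with
one fewer df is available via `boundary_mixture = TRUE` for sensitivity
analysis; the default remains the plain reference.

The same boundary truncation leaves a small positive imprint on
variance summaries: on data without interaction, the fitted slope
variance is non-negative by construction, so the interaction model's
averaged genetic variance exceeds the no-interaction model's estimate by
roughly `0.8 * SE(sigma2_a1_hat)` on average (about 0.03 on a genetic
variance of 0.4 at n = 200). The invariance of the genetic variance
across model choice therefore holds to within one per-replicate standard
deviation — the practically relevant sense — but the systematic
component does not vanish with replication, because it is proportional
to the same sampling noise that defines the comparison scale.

## Heritability under a reaction norm

Under the interaction model the genetic and residual variances are
functions of the covariate: `v_g(c) = phi' K_g phi`, `v_e(c) = phi' K_e
phi`. `heritability_summary()` reports two conventions:

* **Mean-environment heritability (headline)**:
  `h2 = sigma2_a0 / (sigma2_a0 + sigma2_t0)`, the ratio at `c = 0` (the
  covariate mean, where the slope terms vanish). This is the convention
  under which ignoring a real interaction biases heritability downward:
  a no-interaction model absorbs the slope variance into its single
  residual (or, for G×E, fails to credit it to the genetic side), so its
  `h2` understates the mean-environment value. It is also the convention
  under which the companion statement "the genetic variance estimate is
  invariant to adding interaction terms, so the heritability difference
  is a residual-variance difference" is coherent.
* **Averaged variances**: `mean_i(v_g(c_i))`, `mean_i(v_e(c_i))` and
  their ratio `h2_avg`. These integrate the variance profile over the
  observed covariate distribution. Under this convention a no-slope
  model's residual estimate converges to the same average, so the
  bias-direction phenomenon above largely cancels; we report it for
  completeness and use the mean-environment form as the headline.

The two coincide exactly for no-interaction models.

## The synthetic-data generator

`scenario()` generates data under the model's own generative process:
Balding–Nichols genotypes (ancestral frequencies uniform in
`maf_range`), a GRM built by the package's own QC-free standardization
path, random effects drawn exactly from `N(0, G3 (x) A)` and
`N(0, E3 (x) I)` via matrix square roots (a `1e-8` diagonal jitter
covers rank-deficient GRMs), the covariate as location shift + `beta` +
`epsilon`, and the phenotype assembled term by term, so `y` reconstructs
exactly from the stored truth.

Preset conditions (trait scale chosen so the phenotypic variance is
near 1, matching a rank-inverse-normal-transformed trait; covariate
variance `sigma_beta2 = sigma_eps2 = 0.5` so the raw covariate has unit
variance and a "spurious heritability" of 0.5 when confounding is
enabled):

* `null`: `K_g = diag(0.4, 0)`, `K_e = diag(0.6, 0)` — heritability 0.4,
  no interaction, no correlation.
* `gxe` / `rxe` / `combined`: slope blocks switched on with
  `K_g = [[0.4, 0.1], [0.1, 0.2]]` and/or
  `K_e = [[0.5, -0.05], [-0.05, 0.15]]`.
* `corr_only`: no interaction variance, but `cov(alpha0, beta) =
  0.3 * sqrt(0.4 * 0.5)` (a G–E correlation of 0.3) in a single
  unstructured population.
* `corr_strat`: the same correlation plus two subpopulations at
  Fst = 0.1 whose locations shift the raw covariate by ±1 — population
  structure, relatedness and environment confounded the way regional
  farm geography confounds them in practice.

What the generator does **not** emulate: linkage disequilibrium,
pedigree/family structure beyond the SNP-derived GRM, repeated records,
selection, and any calibration of the presets to a real cattle
population — the joint distribution of THI and breeding values across
real farms is unknown, so the presets are illustrative conditions, not
estimates. Passing calibration tests on these presets demonstrates
internal correctness of the machinery, not field realism.

A note on the confounding presets, found while validating the
spurious-signal control. Conditional on the covariate, a
`cov(alpha0, beta)` correlation of size `gamma = cov / var(c)` induces a
fixed mean shift `gamma * c` in the phenotype plus an `O(gamma^2)`
variance perturbation. A reaction norm model with no fixed covariate
term must absorb that shift through its variance structure, whose only
matching directions are the `O(gamma^2)` diagonal terms — so the
noncentrality of the spurious interaction signal scales like
`n * gamma^4`. With a correlation of 0.3 (`gamma ~ 0.13`) this is ~0.04
at n = 500 and reaches interesting size only for n in the several
thousands, i.e. at real-cohort scale. Simulation at package scale
confirms it: on both `corr_only` and `corr_strat` the univariate
ladder's rejection rates are indistinguishable from the null scenario's
(all at or below 2% for nominal 5% at n up to 500). What the package
demonstrates at desk scale is therefore (a) that the
correlation-aware MRNM ladder remains calibrated under confounding, and
(b) that the correlation parameters themselves (`cov(alpha0, beta)` and
friends) are estimated where the univariate models cannot even express
them; the dramatic inflation of univariate interaction tests under
confounding is a large-sample phenomenon that these presets will
reproduce only at cohort-scale n.

## Pre-adjustment pipeline

The analysis operates on pre-adjusted phenotypes, mirroring the
two-stage practice of large evaluation pipelines: ordinary
least-squares adjustment for sex, contemporary group, farm location,
age, optional linear/quadratic THI terms and optional 10 genomic PCs
(the 2×4 candidate grid of `candidate_models()`, selected by AIC with
`k` counting coefficients plus the residual variance), followed by a
rank-based inverse normal transform (`(r - 0.5)/n` offset by default;
Blom's available) to protect the normality assumption. The ±3 SD outlier
filter is applied to raw phenotypes before adjustment, and the minimum
contemporary-group/location size of 5 is applied once after it (the
strictly-greater-than reading is available via `strict = TRUE`).
Covariate standardization uses the population (divide-by-n) standard
deviation, computed on the post-filter analysis set, to match the
genotype-standardization convention that makes the GRM's mean diagonal
exactly 1.

Window choices for THI: both endpoints of the pre-slaughter window are
inclusive; the default window is 15–45 days before slaughter, and the
whole-growth-period variant averages month by month before averaging
months, so short edge months are not underweighted.

## Problem sizes used in the shipped studies

The calibration and power studies run by the test suite and the
acceptance script are sized for a single CPU: oracle comparisons at
n = 20–30 with 50–60 SNPs; parameter recovery with 10 replicates at
n = 500, m = 1000; type-I-error and spurious-signal studies with
100–200 replicates at n = 150–300, m = 2n. The vignette text above
states the qualitative conclusions these sizes support; re-running at
larger n sharpens the same patterns.

## Known limitations

* Only first-order (linear) reaction norms; higher-order polynomials of
  the covariate are out of scope.
* One record per animal; no repeated measures, hence the residual
  structure is diagonal and R×E interaction is identified only through
  the covariate, not an environmental relationship matrix.
* The residual-variance contrast between models
  (`residual_variance_contrast()`) is a Wald approximation that treats
  the two fits as independent although they share data; it is labeled
  as such in its output.
* Dense linear algebra throughout: fitting cost grows as `O(n^3)` per
  iteration (on `2n` for second-trait models), practical to a few
  thousand individuals.
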