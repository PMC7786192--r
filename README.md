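# mrnm: reaction norm models for environment-modulated genetic and residual variance

`mrnm` asks a question central to genetic evaluation under climate
stress: **does the environment modulate the genetic and residual
variance of a quantitative trait, and can you tell real modulation from
confounding?** The motivating setting is beef-cattle carcass traits
along a temperature–humidity index (THI) gradient, but the machinery
applies to any continuous environmental covariate with one record per
genotyped individual.

It is written for quantitative geneticists and breeders who would
otherwise reach for GREML tools (GCTA, MTG2) and want, in R, the full
reaction-norm ladder:

* **G×E interaction** — random genetic regression slopes on the
  covariate: genetic variance `v_g(c) = phi' K_g phi`, `phi = (1, c)`;
* **R×E interaction** — random residual regression slopes: residual
  variance `v_e(c) = phi' K_e phi`;
* **G–E / R–E correlation** — the covariate itself modeled as a second
  trait `c* = mu_c + beta + eps` with free cross-covariances
  `cov(alpha_0, beta)`, `cov(alpha_1, beta)`, `cov(tau_0, eps)`,
  `cov(tau_1, eps)`, so that relatedness-environment confounding cannot
  masquerade as interaction.

The phenotype covariance implied by the full multivariate reaction norm
model (MRNM) is

```
Cov(y_i, y_j) = A_ij (phi_i' K_g phi_j) + 1[i=j] (phi_i' K_e phi_i)
Cov(y_i, c*_j) = A_ij (phi_i' K_gb)     + 1[i=j] (phi_i' K_ee)
Cov(c*_i, c*_j) = A_ij sigma_b^2        + 1[i=j] sigma_e^2
```

with `A = WW'/m` the genomic relationship matrix. Models are fitted by
REML (quasi-Newton with analytic gradients on a log-Cholesky
parameterization), compared with the six-row likelihood-ratio ladder
M1–M6 (univariate vs multivariate, combined vs orthogonal tests), and
summarized by heritability profiles, a collinearity magnitude separating
shared G×E/R×E evidence, and breeding-value re-ranking diagnostics. The
surrounding pipeline — THI from station weather over a pre-slaughter
window, SNP QC and GRM construction, AIC-selected fixed-effect
pre-adjustment with rank-based inverse normal transformation — is
included, as is a synthetic-data generator that reproduces the exact
generative model for calibration and power studies.

## Worked example

```r
library(mrnm)

# synthetic study: both G x E and R x E interactions present
sim <- scenario("combined", n = 300, m = 600, seed = 5)
lad <- run_ladder(sim$y, sim$A, sim$c, sim$c_star)
lad
```

```
Likelihood-ratio ladder (REML)
 index     null       alt                 type   statistic df        p
    M1    greml urnm-full combined GxE and RxE 26.86303777  4 2.12e-05
    M2 urnm-rxe urnm-full       orthogonal GxE  0.00083148  2 1.00e+00
    M3 urnm-gxe urnm-full       orthogonal RxE  6.32995532  2 4.22e-02
    M4  bigreml mrnm-full combined GxE and RxE 28.29632750  6 8.26e-05
    M5 mrnm-rxe mrnm-full       orthogonal GxE  2.84861130  3 4.16e-01
    M6 mrnm-gxe mrnm-full       orthogonal RxE  8.43885562  3 3.78e-02
Collinearity magnitude: URNM 20.5323, MRNM 17.0089
```

Reading the output: M1/M4 test the combined interactions (here clearly
present, p < 1e-4), M2/M5 the G×E signal net of R×E, M3/M6 the reverse.
The large collinearity magnitudes say most of the interaction evidence
is shared between the G×E and R×E channels at this sample size — the
combined test is strong while each orthogonal test is much weaker,
exactly the pattern the collinearity statistic is designed to expose.

```r
h_null <- heritability_summary(lad$fits[["bigreml"]])
h_full <- heritability_summary(lad$fits[["mrnm-full"]])
round(c(null = h_null$h2, interaction = h_full$h2), 3)
#>        null interaction
#>       0.376       0.562
ebv_rank_correlation(lad$fits[["bigreml"]], lad$fits[["mrnm-full"]])
#> [1] 0.9180546
```

The no-interaction model reports the lower mean-environment
heritability (its residual variance absorbs the interaction variance),
and breeding-value ranks shift when the interaction terms enter — the
two practical consequences of fitting the wrong model.

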