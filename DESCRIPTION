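Package: mrnm
Title: Multivariate Reaction Norm Models for Environment-Modulated Genetic
    and Residual Variance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for testing whether the genetic and residual variance of
    quantitative traits is modulated by a continuous environmental gradient
    such as the temperature-humidity index (THI). Implements genomic
    restricted maximum likelihood (GREML) with a dense genomic relationship
    matrix, univariate and multivariate first-order reaction norm models in
    which random-regression slopes of genetic (G x E) and residual (R x E)
    effects on the covariate are fitted jointly with genotype-environment
    and residual-environment correlations, the associated likelihood-ratio
    ladder of nested model comparisons, and a collinearity-magnitude
    statistic separating overlapping G x E and R x E evidence. Includes THI
    computation from station weather records over a configurable
    pre-slaughter window, SNP quality control and GRM construction, fixed
    effect pre-adjustment with AIC model selection and rank-based inverse
    normal transformation, and a synthetic-data generator reproducing the
    full generative model for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
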