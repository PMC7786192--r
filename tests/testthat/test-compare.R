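# a small fitted ladder reused across several tests in this file
ladder_cache <- local({
  sim <- scenario("combined", n = 160, m = 300, seed = 91)
  lad <- run_ladder(sim$y, sim$A, sim$c, sim$c_star)
  list(sim = sim, lad = lad)
})

test_that("likelihood-ratio mechanics: statistic, df, p", {
  lad <- ladder_cache$lad
  f0 <- lad$fits$`greml`; f1 <- lad$fits$`urnm-full`
  cmp <- lrt(f0, f1)
  expect_equal(cmp$statistic, 2 * (f1$logL - f0$logL))
  expect_equal(cmp$df, 4)
  expect_equal(cmp$p, pchisq(cmp$statistic, 4, lower.tail = FALSE))
  # identical fits give statistic 0, p 1 (self-comparison via a copy with
  # an inflated parameter count to satisfy nesting)
  f1b <- f1; f1b$logL <- f0$logL
  cmp0 <- lrt(f0, f1b)
  expect_equal(cmp0$statistic, 0)
  expect_equal(cmp0$p, 1)
  # chi-square tail oracle: 5.99 on 2 df is the 5% point
  f1c <- f1; f1c$logL <- f0$logL + 5.99 / 2
  f1c$n_free <- f0$n_free + 2
  expect_equal(lrt(f0, f1c)$p, 0.05, tolerance = 1e-3)
  # non-nested comparisons are refused
  expect_error(lrt(lad$fits$`urnm-gxe`, lad$fits$`mrnm-gxe`),
               class = "mrnm_config_error")
  expect_error(lrt(lad$fits$`urnm-gxe`, lad$fits$`urnm-rxe`),
               class = "mrnm_config_error")
})

test_that("the ladder has the canonical df vector and magnitude identity", {
  lad <- ladder_cache$lad
  expect_equal(lad$comparisons$df, c(4, 2, 2, 6, 3, 3))
  expect_equal(lad$comparisons$index, paste0("M", 1:6))
  # M4 compares bivariate GREML (6 free) with full MRNM (12 free)
  expect_equal(lad$fits$`bigreml`$n_free, 6)
  expect_equal(lad$fits$`mrnm-full`$n_free, 12)
  # nesting: the full models dominate their submodels
  expect_gte(lad$fits$`urnm-full`$logL, lad$fits$`greml`$logL - 1e-6)
  expect_gte(lad$fits$`mrnm-full`$logL, lad$fits$`bigreml`$logL - 1e-6)
  # orthogonal magnitudes are non-negative
  expect_gte(2 * (lad$fits$`urnm-full`$logL - lad$fits$`urnm-gxe`$logL),
             -1e-6)
  expect_gte(2 * (lad$fits$`urnm-full`$logL - lad$fits$`urnm-rxe`$logL),
             -1e-6)
})

test_that("collinearity magnitude: identity and recomputation oracle", {
  lad <- ladder_cache$lad
  f <- lad$fits
  # recomputation from the four stored log-likelihoods
  expect_equal(lad$collinearity$urnm,
               2 * (f$`urnm-gxe`$logL + f$`urnm-rxe`$logL -
                      f$`greml`$logL - f$`urnm-full`$logL))
  # algebraic identity: M(combined) - M(GxE|RxE) - M(RxE|GxE)
  M_comb <- 2 * (f$`urnm-full`$logL - f$`greml`$logL)
  M_g_given_r <- 2 * (f$`urnm-full`$logL - f$`urnm-rxe`$logL)
  M_r_given_g <- 2 * (f$`urnm-full`$logL - f$`urnm-gxe`$logL)
  expect_equal(lad$collinearity$urnm, M_comb - M_g_given_r - M_r_given_g,
               tolerance = 1e-10)
  # four equal likelihoods give zero
  f_eq <- f$`greml`
  f_eq2 <- f$`urnm-gxe`; f_eq2$logL <- f_eq$logL
  f_eq3 <- f$`urnm-rxe`; f_eq3$logL <- f_eq$logL
  f_eq4 <- f$`urnm-full`; f_eq4$logL <- f_eq$logL
  expect_equal(collinearity_magnitude(f_eq, f_eq2, f_eq3, f_eq4), 0)
})

test_that("heritability summaries expose both conventions", {
  lad <- ladder_cache$lad
  # no-slope model: ratio of the two intercept variances, conventions agree
  f0 <- lad$fits$`greml`
  hs0 <- heritability_summary(f0, ladder_cache$sim$c)
  expect_equal(hs0$h2,
               f0$params$K_g[1, 1] /
                 (f0$params$K_g[1, 1] + f0$params$K_e[1, 1]))
  expect_equal(hs0$h2, hs0$h2_avg, tolerance = 1e-10)
  expect_true(hs0$h2 >= 0 && hs0$h2 <= 1)
  # averaged variances with standardized c and diagonal K: a + b
  f1 <- lad$fits$`urnm-full`
  hs1 <- heritability_summary(f1, ladder_cache$sim$c)
  Kg <- f1$params$K_g
  cvec <- ladder_cache$sim$c
  expect_equal(hs1$sigma2_g_avg,
               Kg[1, 1] + 2 * Kg[1, 2] * mean(cvec) +
                 Kg[2, 2] * mean(cvec^2), tolerance = 1e-10)
  expect_equal(mean(cvec^2), 1, tolerance = 1e-12)
})

test_that("EBV rank correlation: identity, reversal, attenuation", {
  lad <- ladder_cache$lad
  f0 <- lad$fits$`greml`; f1 <- lad$fits$`urnm-full`
  expect_equal(ebv_rank_correlation(f1, f1), 1)
  f_rev <- f1; f_rev$blup <- f1$blup; f_rev$blup$g <- -f1$blup$g
  expect_equal(ebv_rank_correlation(f1, f_rev), -1)
  r01 <- ebv_rank_correlation(f0, f1)
  expect_lt(r01, 1)
  expect_gt(r01, 0.3)  # same data: strongly related rankings
})

test_that("residual variance contrast is a two-sided normal Wald test", {
  sim <- scenario("rxe", n = 160, m = 300, seed = 92)
  fa <- rnm_fit(sim$y, sim$A, sim$c, "greml", se = TRUE, blup = FALSE)
  fb <- rnm_fit(sim$y, sim$A, sim$c, "urnm-full", se = TRUE, blup = FALSE)
  ct <- residual_variance_contrast(fa, fb)
  expect_equal(ct$z,
               (fa$params$K_e[1, 1] - fb$params$K_e[1, 1]) /
                 sqrt(fa$se[["sigma2_t0"]]^2 + fb$se[["sigma2_t0"]]^2))
  expect_equal(ct$p, 2 * pnorm(-abs(ct$z)))
  expect_match(ct$approximation, "independent")
  # identical estimates give z = 0, p = 1
  ct0 <- residual_variance_contrast(fa, fa)
  expect_equal(ct0$z, 0); expect_equal(ct0$p, 1)
  # 1.96 pooled-SE difference gives p = 0.05
  fc <- fa
  fc$params$K_e[1, 1] <- fa$params$K_e[1, 1] +
    1.96 * sqrt(2) * fa$se[["sigma2_t0"]]
  ct196 <- residual_variance_contrast(fc, fa)
  expect_equal(ct196$p, 0.05, tolerance = 1e-3)
})

test_that("boundary-mixture reference is available for sensitivity work", {
  lad <- ladder_cache$lad
  f0 <- lad$fits$`urnm-rxe`; f1 <- lad$fits$`urnm-full`
  cmp_plain <- lrt(f0, f1)
  cmp_mix <- lrt(f0, f1, boundary_mixture = TRUE)
  expect_equal(cmp_mix$statistic, cmp_plain$statistic)
  expect_lte(cmp_mix$p, cmp_plain$p + 1e-12)
})
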