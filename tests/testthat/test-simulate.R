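test_that("genotype simulation honors allele-frequency settings", {
  # fixed frequency 0.5: sample mean genotype inside the binomial band
  g <- simulate_genotypes(2000, 1, maf_range = c(0.5, 0.5), seed = 41)$genotypes
  expect_gt(mean(g), 0.93); expect_lt(mean(g), 1.07)

  # no drift: two subpops at fst = 0 share frequencies
  sim <- simulate_genotypes(400, 500, maf_range = c(0.1, 0.5),
                            n_subpops = 2, fst = 0, seed = 42)
  p1 <- colMeans(sim$genotypes[sim$subpop == 1, ]) / 2
  p2 <- colMeans(sim$genotypes[sim$subpop == 2, ]) / 2
  expect_lt(abs(mean(p1 - p2)), 0.01)

  # emitted truth record matches allele counts from the matrix
  sim2 <- simulate_genotypes(100, 50, seed = 43)
  expect_equal(dim(sim2$genotypes), c(100, 50))
  freqs <- colMeans(sim2$genotypes) / 2
  # frequencies drawn within the configured range (up to sampling noise)
  expect_true(all(freqs > 0 & freqs < 1))
  # Balding-Nichols divergence grows with fst
  sim3 <- simulate_genotypes(400, 500, maf_range = c(0.2, 0.5),
                             n_subpops = 2, fst = 0.2, seed = 44)
  q1 <- colMeans(sim3$genotypes[sim3$subpop == 1, ]) / 2
  q2 <- colMeans(sim3$genotypes[sim3$subpop == 2, ]) / 2
  expect_gt(mean(abs(q1 - q2)), mean(abs(p1 - p2)))

  expect_error(simulate_genotypes(10, 5, maf_range = c(0, 0.5)),
               class = "mrnm_config_error")
  expect_error(simulate_genotypes(10, 5, fst = -0.1),
               class = "mrnm_config_error")
  expect_error(simulate_genotypes(10, 5, n_subpops = 1, fst = 0.1),
               class = "mrnm_config_error")
})

test_that("random effects have the configured joint covariance", {
  cfg0 <- sim_config(n_individuals = 50, K_g = matrix(0, 2, 2),
                     K_e = matrix(0, 2, 2), sigma_beta2 = 0, sigma_eps2 = 0)
  eff0 <- simulate_random_effects(diag(50), cfg0, seed = 45)
  for (v in eff0) expect_equal(v, rep(0, 50))

  # independence under a diagonal K_g with A = I
  cfg1 <- sim_config(n_individuals = 2000, K_g = diag(c(0.4, 0.2)))
  eff1 <- simulate_random_effects(diag(2000), cfg1, seed = 46)
  expect_lt(abs(cor(eff1$alpha0, eff1$alpha1)), 0.05)

  # Monte-Carlo covariance oracle: empirical covariance of (alpha0, alpha1)
  # over replicates matches K_g within 3 MC standard errors
  Kg <- matrix(c(0.4, 0.1, 0.1, 0.2), 2)
  cfg2 <- sim_config(n_individuals = 500, K_g = Kg)
  reps <- 60
  cov_hat <- matrix(0, 2, 2)
  draws <- array(NA_real_, c(reps, 3))
  for (r in seq_len(reps)) {
    e <- simulate_random_effects(diag(500), cfg2, seed = 500 + r)
    cov_hat <- cov_hat + cbind(c(mean(e$alpha0^2), mean(e$alpha0 * e$alpha1)),
                               c(mean(e$alpha0 * e$alpha1), mean(e$alpha1^2)))
  }
  cov_hat <- cov_hat / reps
  n_eff <- reps * 500
  for (i in 1:2) for (j in 1:2) {
    se <- sqrt((Kg[i, i] * Kg[j, j] + Kg[i, j]^2) / n_eff)
    expect_lt(abs(cov_hat[i, j] - Kg[i, j]), 3 * se + 1e-12)
  }

  # GRM-structured draws: cov(alpha0) tracks A, not I
  A <- toy_grm(300, 200, seed = 47)
  cfgA <- sim_config(n_individuals = 300)
  effA <- simulate_random_effects(A, cfgA, seed = 48)
  # regression of alpha0 alpha0' products on A has slope near sigma2_a0
  offd <- which(upper.tri(A) & abs(A) > 0.05)
  prod_od <- tcrossprod(effA$alpha0)[offd]
  slope <- coef(lm(prod_od ~ A[offd]))[2]
  expect_gt(slope, 0.1)  # positive relatedness-effect coupling

  # PSD violation is rejected with a helpful error
  expect_error(
    sim_config(K_g = diag(c(0.1, 0.1)), K_g_beta = c(0.9, 0),
               sigma_beta2 = 0.1),
    class = "mrnm_config_error")
})

test_that("covariate construction decomposes as configured", {
  set.seed(49)
  beta <- rnorm(2000); eps <- rnorm(2000)
  # no location effects: c_star equals raw and c is its z-score
  thi0 <- simulate_thi(rep(1, 2000), 0, beta, eps)
  expect_equal(thi0$raw_thi, beta + eps)
  expect_equal(thi0$c_star, thi0$raw_thi)
  expect_equal(thi0$c, (thi0$raw_thi - mean(thi0$raw_thi)) /
                 sqrt(mean((thi0$raw_thi - mean(thi0$raw_thi))^2)))
  # beta = 0: c_star is exactly eps
  thi1 <- simulate_thi(rep(1, 100), 0, rep(0, 100), eps[1:100])
  expect_equal(cor(thi1$c_star, eps[1:100]), 1)
  # variance decomposition with two shifted subpops
  subpop <- rep(1:2, each = 1000)
  thi2 <- simulate_thi(subpop, c(5, -5), beta, eps)
  v <- var(thi2$raw_thi)
  expect_gt(v, 25 + 2 - 3 * 1.7); expect_lt(v, 25 + 2 + 3 * 1.7)
})

test_that("phenotypes reconstruct exactly from truth components", {
  sim <- scenario("combined", n = 120, m = 150, seed = 50)
  with(sim, {
    y_rebuilt <- truth$config$grand_mean + truth$alpha0 +
      truth$alpha1 * c + truth$tau0 + truth$tau1 * c
    expect_identical(y, y_rebuilt)
  })
  # zero effects give a constant; zero covariate kills interaction terms
  cfg <- sim$truth$config
  zero_truth <- lapply(sim$truth[1:6], function(x) x * 0)
  expect_equal(simulate_phenotype(cfg, zero_truth, sim$c),
               rep(cfg$grand_mean, 120))
  y0 <- simulate_phenotype(cfg, sim$truth, rep(0, 120))
  expect_equal(y0, cfg$grand_mean + sim$truth$alpha0 + sim$truth$tau0)
})

test_that("scenario presets switch on the advertised components", {
  s_null <- scenario("null", n = 40, m = 60, seed = 51)
  expect_equal(s_null$truth$config$K_g[2, 2], 0)
  expect_equal(s_null$truth$config$K_e[2, 2], 0)
  expect_equal(s_null$truth$config$K_g_beta, c(0, 0))

  s_corr <- scenario("corr_only", n = 40, m = 60, seed = 51)
  expect_equal(s_corr$truth$config$K_g[2, 2], 0)
  expect_equal(s_corr$truth$config$K_e[2, 2], 0)
  expect_gt(s_corr$truth$config$K_g_beta[1], 0)

  s_gxe <- scenario("gxe", n = 40, m = 60, seed = 51)
  expect_gt(s_gxe$truth$config$K_g[2, 2], 0)
  expect_equal(s_gxe$truth$config$K_e[2, 2], 0)

  expect_error(scenario("nope", n = 10, m = 10), "arg")
})

test_that("simulation is deterministic in the seed", {
  a <- scenario("gxe", n = 30, m = 40, seed = 52)
  b <- scenario("gxe", n = 30, m = 40, seed = 52)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$y, b$y)
  expect_identical(a$c_star, b$c_star)
  d <- scenario("gxe", n = 30, m = 40, seed = 53)
  expect_false(identical(a$genotypes, d$genotypes))
})

test_that("datasets round-trip through plain-text export", {
  dir <- withr::local_tempdir()
  sim <- scenario("null", n = 20, m = 25, seed = 54)
  paths <- write_dataset(sim, dir)
  g2 <- read_plink_additive(paths[["genotypes"]])
  expect_equal(g2, sim$genotypes)
  phen <- read.delim(paths[["phen"]])
  expect_equal(phen$y, sim$y, tolerance = 1e-12)
  truth <- read.delim(paths[["truth"]])
  expect_equal(truth$alpha0, sim$truth$alpha0, tolerance = 1e-12)
})
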