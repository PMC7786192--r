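test_that("polynomial matrix has the required structure", {
  expect_equal(unname(build_phi(c(0, 0))), cbind(c(1, 1), c(0, 0)))
  expect_equal(unname(build_phi(c(-1, 2))), cbind(c(1, 1), c(-1, 2)))
  Phi <- build_phi(rnorm(10))
  expect_equal(as.numeric(Phi %*% c(1, 0)), rep(1, 10))
})

test_that("model specifications map to the expected free-parameter counts", {
  counts <- c("greml" = 2, "urnm-gxe" = 4, "urnm-rxe" = 4, "urnm-full" = 6,
              "bigreml" = 6, "mrnm-gxe" = 9, "mrnm-rxe" = 9, "mrnm-full" = 12)
  for (nm in names(counts)) {
    spec <- model_spec_by_name(nm)
    expect_equal(spec$name, nm)
    expect_length(mrnm:::free_param_names(spec), counts[[nm]])
  }
  expect_error(model_spec_by_name("bogus"), class = "mrnm_config_error")
})

test_that("assembled covariance matches a scalar-loop oracle for all models", {
  n <- 4
  A <- toy_grm(n, 30, seed = 61)
  cvec <- standardize_covariate(rnorm(n))
  Phi <- build_phi(cvec)
  for (nm in all_model_names) {
    spec <- model_spec_by_name(nm)
    params <- random_params(spec, seed = 62)
    V <- assemble_covariance(params, A, Phi, spec)
    V_oracle <- oracle_covariance(params, A, cvec, spec$second_trait)
    expect_equal(V, V_oracle, tolerance = 1e-12, ignore_attr = TRUE,
                 label = nm)
  }
})

test_that("covariance reduces to standard GREML without slope terms", {
  n <- 6
  A <- toy_grm(n, 30, seed = 63)
  cvec <- standardize_covariate(rnorm(n))
  params <- rnm_params(K_g = diag(c(0.4, 0)), K_e = diag(c(0.6, 0)))
  V <- assemble_covariance(params, A, build_phi(cvec),
                           model_spec_by_name("greml"))
  expect_equal(V, 0.4 * unclass(A) + diag(0.6, n), tolerance = 1e-12,
               ignore_attr = TRUE)
  # zero covariate: slope variances do not enter the phenotype block
  params2 <- rnm_params(K_g = matrix(c(0.4, 0, 0, 0.9), 2),
                        K_e = matrix(c(0.6, 0, 0, 0.7), 2))
  V2 <- assemble_covariance(params2, A, build_phi(rep(0, n)),
                            model_spec_by_name("urnm-full"))
  expect_equal(V2, 0.4 * unclass(A) + diag(0.6, n), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("every model's likelihood matches the dense MVN oracle", {
  n <- 20
  sim <- scenario("combined", n = n, m = 50, seed = 64)
  for (criterion in c("REML", "ML")) {
    for (nm in all_model_names) {
      spec <- model_spec_by_name(nm, criterion)
      params <- random_params(spec, seed = 65)
      ll <- rnm_loglik(params, sim$y, sim$A, sim$c, spec,
                       c_star = sim$c_star)
      V <- oracle_covariance(params, sim$A, sim$c, spec$second_trait)
      yj <- if (spec$second_trait) c(sim$y, sim$c_star) else sim$y
      X <- if (spec$second_trait) {
        kronecker(diag(2), matrix(1, n, 1))
      } else {
        matrix(1, n, 1)
      }
      expect_equal(ll, oracle_loglik(V, X, yj, criterion),
                   tolerance = 1e-6, label = paste(nm, criterion))
    }
  }
})

test_that("likelihood nesting identities hold exactly", {
  n <- 25
  sim <- scenario("combined", n = n, m = 60, seed = 66)
  # masked interaction model equals univariate GREML at matched params
  p_ur <- rnm_params(K_g = diag(c(0.37, 0)), K_e = diag(c(0.55, 0)))
  ll_full <- rnm_loglik(p_ur, sim$y, sim$A, sim$c,
                        model_spec_by_name("urnm-full"))
  ll_greml <- rnm_loglik(p_ur, sim$y, sim$A, sim$c,
                         model_spec_by_name("greml"))
  expect_equal(ll_full, ll_greml, tolerance = 1e-8)
  # masked MRNM equals bivariate GREML
  p_bi <- rnm_params(K_g = diag(c(0.37, 0)), K_e = diag(c(0.55, 0)),
                     K_g_beta = c(0.1, 0), K_e_eps = c(-0.05, 0),
                     sigma_beta2 = 0.4, sigma_eps2 = 0.6)
  ll_mrnm <- rnm_loglik(p_bi, sim$y, sim$A, sim$c,
                        model_spec_by_name("mrnm-full"), c_star = sim$c_star)
  ll_bi <- rnm_loglik(p_bi, sim$y, sim$A, sim$c,
                      model_spec_by_name("bigreml"), c_star = sim$c_star)
  expect_equal(ll_mrnm, ll_bi, tolerance = 1e-8)
})

test_that("REML likelihood is invariant to phenotype translation", {
  sim <- scenario("gxe", n = 22, m = 40, seed = 67)
  spec <- model_spec_by_name("urnm-full")
  params <- random_params(spec, seed = 68)
  l1 <- rnm_loglik(params, sim$y, sim$A, sim$c, spec)
  l2 <- rnm_loglik(params, sim$y + 7.3, sim$A, sim$c, spec)
  expect_equal(l1, l2, tolerance = 1e-8)
})

test_that("analytic gradients agree with finite differences", {
  sim <- scenario("combined", n = 30, m = 60, seed = 69)
  for (nm in c("urnm-full", "mrnm-full", "bigreml")) {
    spec <- model_spec_by_name(nm)
    eng <- mrnm:::make_engine(sim$y, sim$A, sim$c, spec, sim$c_star)
    set.seed(70)
    d_g <- length(eng$act$g); d_e <- length(eng$act$e)
    th <- c(mrnm:::pack_logchol(crossprod(matrix(rnorm(d_g * d_g, sd = 0.4),
                                                 d_g)) + diag(0.2, d_g)),
            mrnm:::pack_logchol(crossprod(matrix(rnorm(d_e * d_e, sd = 0.4),
                                                 d_e)) + diag(0.2, d_e)))
    g_an <- eng$gr(th)
    h <- 1e-6
    g_num <- vapply(seq_along(th), function(i) {
      tp <- th; tp[i] <- tp[i] + h
      tm <- th; tm[i] <- tm[i] - h
      (eng$fn(tp) - eng$fn(tm)) / (2 * h)
    }, numeric(1))
    expect_equal(g_an, g_num, tolerance = 1e-4, label = nm)
  }
})

test_that("fitting recovers a no-genetic-variance boundary", {
  set.seed(71)
  n <- 600
  A <- toy_grm(n, 400, seed = 71)
  y <- rnorm(n)  # pure noise: no genetic variance
  f <- rnm_fit(y, A, standardize_covariate(rnorm(n)), "greml", se = FALSE,
               blup = FALSE)
  expect_lte(f$params$K_g[1, 1], 0.02)
})

test_that("optimum dominates the generating parameters", {
  sim <- scenario("combined", n = 150, m = 300, seed = 72)
  cfg <- sim$truth$config
  truth_params <- rnm_params(K_g = cfg$K_g, K_e = cfg$K_e,
                             K_g_beta = cfg$K_g_beta,
                             K_e_eps = cfg$K_e_eps,
                             sigma_beta2 = cfg$sigma_beta2,
                             sigma_eps2 = cfg$sigma_eps2)
  spec <- model_spec_by_name("mrnm-full")
  ll_truth <- rnm_loglik(truth_params, sim$y, sim$A, sim$c, spec,
                         c_star = sim$c_star)
  f <- rnm_fit(sim$y, sim$A, sim$c, "mrnm-full", c_star = sim$c_star,
               se = FALSE, blup = FALSE)
  expect_gte(f$logL, ll_truth - 1e-6)
})

test_that("BLUPs shrink relative to the true genetic effects", {
  sim <- scenario("gxe", n = 300, m = 600, seed = 73)
  f <- rnm_fit(sim$y, sim$A, sim$c, "urnm-full", se = FALSE)
  g_true <- sim$truth$alpha0 + sim$truth$alpha1 * sim$c
  expect_lt(var(f$blup$g), var(g_true) * 1.05)
  expect_gt(cor(f$blup$g, g_true), 0.5)
})

test_that("standard errors come from a sane observed information", {
  sim <- scenario("null", n = 250, m = 400, seed = 74)
  f <- rnm_fit(sim$y, sim$A, sim$c, "greml", se = TRUE, blup = FALSE)
  expect_named(f$se, c("sigma2_a0", "sigma2_t0"))
  expect_true(all(is.finite(f$se)))
  # SEs of variance components at n = 250 should be roughly of order
  # sqrt(2/n) on standardized traits: sanity band, not a calibration
  expect_true(all(f$se > 0.01 & f$se < 1))
  expect_equal(dim(f$vcov), c(2, 2))
})

test_that("fit errors when free parameters exceed sample size", {
  A <- toy_grm(8, 30, seed = 75)
  y <- rnorm(8)
  cvec <- standardize_covariate(rnorm(8))
  cs <- rnorm(8)
  expect_error(rnm_fit(y[1:8], A, cvec, "mrnm-full", c_star = cs,
                       se = FALSE, blup = FALSE),
               class = "mrnm_config_error")
  expect_error(rnm_fit(y, A, cvec, "bigreml", se = FALSE),
               class = "mrnm_config_error")  # missing c_star
})
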