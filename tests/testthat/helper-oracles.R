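# Independent oracles used across the suite. These deliberately avoid the
# package's linear-algebra paths: covariances are assembled entry by entry
# with scalar loops, and likelihoods use determinant()/solve() instead of
# the engine's Cholesky pipeline.

# scalar-loop assembly of the joint covariance of (y, c*) under the full
# parameterization; masked models are covered by passing masked params
oracle_covariance <- function(params, A, cvec, second_trait) {
  n <- nrow(A)
  Kg <- params$K_g; Ke <- params$K_e
  kgb <- params$K_g_beta; kee <- params$K_e_eps
  phi <- function(i) c(1, cvec[i])
  Vyy <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    Vyy[i, j] <- A[i, j] * (phi(i) %*% Kg %*% phi(j)) +
      (i == j) * (phi(i) %*% Ke %*% phi(i))
  }
  if (!second_trait) return(Vyy)
  Vyc <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    Vyc[i, j] <- A[i, j] * sum(phi(i) * kgb) + (i == j) * sum(phi(i) * kee)
  }
  Vcc <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    Vcc[i, j] <- A[i, j] * params$sigma_beta2 +
      (i == j) * params$sigma_eps2
  }
  rbind(cbind(Vyy, Vyc), cbind(t(Vyc), Vcc))
}

# restricted (or full) multivariate-normal log-likelihood from first
# principles: GLS mean, determinant() and solve()
oracle_loglik <- function(V, X, y, criterion = "REML") {
  N <- length(y); p <- ncol(X)
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  b <- solve(XVX, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  quad <- as.numeric(t(r) %*% Vi %*% r)
  ldV <- as.numeric(determinant(V)$modulus)
  if (criterion == "REML") {
    -0.5 * (ldV + as.numeric(determinant(XVX)$modulus) + quad +
              (N - p) * log(2 * pi))
  } else {
    -0.5 * (ldV + quad + N * log(2 * pi))
  }
}

# random masked parameter set guaranteed PSD: draw a full 3x3 factor and
# zero the masked rows/columns
random_params <- function(spec, seed, scale = 1) {
  set.seed(seed)
  mk <- function(active) {
    L <- matrix(rnorm(9, sd = 0.4), 3, 3)
    M <- tcrossprod(L) * scale + diag(0.3, 3)
    mask <- setdiff(1:3, active)
    M[mask, ] <- 0; M[, mask] <- 0
    M
  }
  ag <- c(1, if (spec$genetic_slope) 2, if (spec$second_trait) 3)
  ae <- c(1, if (spec$residual_slope) 2, if (spec$second_trait) 3)
  G3 <- mk(ag); E3 <- mk(ae)
  rnm_params(K_g = G3[1:2, 1:2], K_e = E3[1:2, 1:2],
             K_g_beta = G3[1:2, 3], K_e_eps = E3[1:2, 3],
             sigma_beta2 = G3[3, 3], sigma_eps2 = E3[3, 3])
}

all_model_names <- c("greml", "urnm-gxe", "urnm-rxe", "urnm-full",
                     "bigreml", "mrnm-gxe", "mrnm-rxe", "mrnm-full")

# small dense GRM with off-diagonal structure (not a near-identity), for
# likelihood oracle tests
toy_grm <- function(n, m = 3 * n, seed = 1) {
  g <- simulate_genotypes(n, m, seed = seed)$genotypes
  poly <- apply(g, 2, function(x) length(unique(x)) > 1)
  compute_grm(standardize_genotypes(g[, poly, drop = FALSE]))
}
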