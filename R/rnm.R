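#' Zero/first-order polynomial matrix
#'
#' Builds the n x 2 matrix with rows `(1, c_i)` carrying the zero- and
#' first-order polynomials of the standardized environmental covariate.
#'
#' @param c standardized covariate vector.
#' @return n x 2 matrix, first column all ones.
#' @export
build_phi <- function(c) {
  stopifnot(all(is.finite(c)))
  cbind(intercept = rep(1, length(c)), slope = as.numeric(c))
}

#' Reaction norm model specification
#'
#' Three flags span the model ladder: `genetic_slope` (random genetic
#' regression on the covariate, G x E), `residual_slope` (random residual
#' regression, R x E), and `second_trait` (the adjusted covariate jointly
#' modeled as a second trait, absorbing genotype-environment and
#' residual-environment correlations). The eight combinations are the
#' named models:
#'
#' | name | genetic_slope | residual_slope | second_trait | free params |
#' |------|---|---|---|---|
#' | `greml`     | no  | no  | no  | 2 |
#' | `urnm-gxe`  | yes | no  | no  | 4 |
#' | `urnm-rxe`  | no  | yes | no  | 4 |
#' | `urnm-full` | yes | yes | no  | 6 |
#' | `bigreml`   | no  | no  | yes | 6 |
#' | `mrnm-gxe`  | yes | no  | yes | 9 |
#' | `mrnm-rxe`  | no  | yes | yes | 9 |
#' | `mrnm-full` | yes | yes | yes | 12 |
#'
#' With one record per individual the residual coefficient structure is
#' identity-indexed, so the residual contribution to the phenotype
#' covariance is diagonal.
#'
#' @param genetic_slope,residual_slope,second_trait logical flags.
#' @param criterion `"REML"` (default) or `"ML"`.
#' @return object of class `rnm_model_spec`.
#' @export
model_spec <- function(genetic_slope = FALSE, residual_slope = FALSE,
                       second_trait = FALSE, criterion = c("REML", "ML")) {
  criterion <- match.arg(criterion)
  key <- paste0(as.integer(genetic_slope), as.integer(residual_slope),
                as.integer(second_trait))
  name <- c(`000` = "greml", `100` = "urnm-gxe", `010` = "urnm-rxe",
            `110` = "urnm-full", `001` = "bigreml", `101` = "mrnm-gxe",
            `011` = "mrnm-rxe", `111` = "mrnm-full")[[key]]
  structure(list(name = name, genetic_slope = genetic_slope,
                 residual_slope = residual_slope,
                 second_trait = second_trait, criterion = criterion),
            class = "rnm_model_spec")
}

#' @rdname model_spec
#' @param name model name from the table above.
#' @export
model_spec_by_name <- function(name, criterion = c("REML", "ML")) {
  criterion <- match.arg(criterion)
  flags <- switch(name,
    "greml" = c(FALSE, FALSE, FALSE), "urnm-gxe" = c(TRUE, FALSE, FALSE),
    "urnm-rxe" = c(FALSE, TRUE, FALSE), "urnm-full" = c(TRUE, TRUE, FALSE),
    "bigreml" = c(FALSE, FALSE, TRUE), "mrnm-gxe" = c(TRUE, FALSE, TRUE),
    "mrnm-rxe" = c(FALSE, TRUE, TRUE), "mrnm-full" = c(TRUE, TRUE, TRUE),
    stop_mrnm("unknown model name '%s'", name, class = "mrnm_config_error"))
  model_spec(flags[1], flags[2], flags[3], criterion)
}

#' @export
print.rnm_model_spec <- function(x, ...) {
  cat(sprintf("Model '%s' (G-slope: %s, R-slope: %s, covariate as trait: %s, %s)\n",
              x$name, x$genetic_slope, x$residual_slope, x$second_trait,
              x$criterion))
  invisible(x)
}

#' Reaction norm variance parameters
#'
#' Container for the full parameter set of the multivariate reaction norm
#' model: the 2 x 2 coefficient covariances, cross-covariances of the
#' coefficients with the covariate's genetic and residual components, and
#' the covariate variances. Entries masked out by a model specification
#' are exactly zero.
#'
#' @param K_g,K_e 2 x 2 symmetric coefficient covariance matrices.
#' @param K_g_beta,K_e_eps length-2 cross-covariance vectors.
#' @param sigma_beta2,sigma_eps2 covariate variances.
#' @return object of class `rnm_params`.
#' @export
rnm_params <- function(K_g, K_e, K_g_beta = c(0, 0), K_e_eps = c(0, 0),
                       sigma_beta2 = 0, sigma_eps2 = 0) {
  structure(list(K_g = K_g, K_e = K_e, K_g_beta = K_g_beta,
                 K_e_eps = K_e_eps, sigma_beta2 = sigma_beta2,
                 sigma_eps2 = sigma_eps2), class = "rnm_params")
}

params_from_joint <- function(G3, E3) {
  rnm_params(K_g = G3[1:2, 1:2], K_e = E3[1:2, 1:2],
             K_g_beta = G3[1:2, 3], K_e_eps = E3[1:2, 3],
             sigma_beta2 = G3[3, 3], sigma_eps2 = E3[3, 3])
}

#' Joint covariance of trait and covariate
#'
#' Assembles the model-implied covariance matrix of `(y, c_star)`:
#' phenotype block `A_ij (phi_i' K_g phi_j) + 1[i = j] (phi_i' K_e phi_i)`
#' (genetic part Hadamard-structured by the GRM, residual part diagonal
#' because records are unreplicated), cross block
#' `A_ij (phi_i' K_g_beta) + 1[i = j] (phi_i' K_e_eps)`, and covariate
#' block `A sigma_beta2 + I sigma_eps2`. Without the second trait only the
#' phenotype block is returned.
#'
#' @param params `rnm_params`.
#' @param A GRM.
#' @param Phi polynomial matrix from [build_phi()] (its second column is
#'   the covariate).
#' @param spec `rnm_model_spec`; only `second_trait` matters here.
#' @return n x n or 2n x 2n covariance matrix.
#' @export
assemble_covariance <- function(params, A, Phi, spec) {
  if (any(!vapply(params, function(p) all(is.finite(p)), logical(1)))) {
    stop_mrnm("non-finite variance parameter", class = "mrnm_numeric_error")
  }
  G3 <- joint_cov(params$K_g, params$K_g_beta, params$sigma_beta2)
  E3 <- joint_cov(params$K_e, params$K_e_eps, params$sigma_eps2)
  assemble_V(G3, E3, A, Phi[, 2], spec$second_trait)
}

assemble_V <- function(G3, E3, A, cvec, second_trait) {
  n <- nrow(A)
  Phi <- cbind(1, cvec)
  Vyy <- A * (Phi %*% G3[1:2, 1:2] %*% t(Phi))
  dres <- rowSums((Phi %*% E3[1:2, 1:2]) * Phi)
  diag(Vyy) <- diag(Vyy) + dres
  if (!second_trait) return(Vyy)
  vg <- as.numeric(Phi %*% G3[1:2, 3])
  ve <- as.numeric(Phi %*% E3[1:2, 3])
  Vyc <- A * vg                     # A_ij * vg_i
  diag(Vyc) <- diag(Vyc) + ve
  Vcc <- G3[3, 3] * A
  diag(Vcc) <- diag(Vcc) + E3[3, 3]
  rbind(cbind(Vyy, Vyc), cbind(t(Vyc), Vcc))
}

# --- internal engine -------------------------------------------------------

active_sets <- function(spec) {
  list(g = c(1L, if (spec$genetic_slope) 2L, if (spec$second_trait) 3L),
       e = c(1L, if (spec$residual_slope) 2L, if (spec$second_trait) 3L))
}

# lower-triangle column-major pairs of an active index set
entry_pairs <- function(act) {
  d <- length(act)
  out <- list()
  for (j in seq_len(d)) for (i in j:d) {
    out[[length(out) + 1L]] <- c(act[i], act[j])  # (u >= v in submatrix order)
  }
  out
}

free_param_names <- function(spec) {
  comp_g <- c("a0", "a1", "beta")
  comp_e <- c("t0", "t1", "eps")
  act <- active_sets(spec)
  nm <- function(pairs, comp) {
    vapply(pairs, function(p) {
      if (p[1] == p[2]) sprintf("sigma2_%s", comp[p[1]])
      else sprintf("cov_%s_%s", comp[p[2]], comp[p[1]])
    }, character(1))
  }
  c(nm(entry_pairs(act$g), comp_g), nm(entry_pairs(act$e), comp_e))
}

# pack a PSD submatrix as log-Cholesky parameters (lower tri, col-major,
# log on the diagonal); ridge regularization for semi-definite inits
pack_logchol <- function(M, floor_diag = 1e-6) {
  d <- nrow(M)
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- chol(M + diag(floor_diag * max(mean(diag(M)), 1), d))
  }
  L <- t(ch)
  theta <- numeric(0)
  for (j in seq_len(d)) for (i in j:d) {
    theta <- c(theta, if (i == j) log(max(L[i, i], 1e-12)) else L[i, j])
  }
  theta
}

unpack_logchol <- function(theta, d) {
  L <- matrix(0, d, d)
  k <- 1L
  for (j in seq_len(d)) for (i in j:d) {
    L[i, j] <- if (i == j) exp(theta[k]) else theta[k]
    k <- k + 1L
  }
  L
}

theta_to_joint <- function(theta, act) {
  d <- length(act)
  L <- unpack_logchol(theta, d)
  M3 <- matrix(0, 3, 3)
  M3[act, act] <- L %*% t(L)
  list(M3 = M3, L = L)
}

# Shared state for one fit: data, design, spec, and a memo of the
# expensive pieces (Cholesky, inverse, projection) at the last theta.
make_engine <- function(y, A, cvec, spec, c_star = NULL) {
  n <- length(y)
  second <- spec$second_trait
  if (second && is.null(c_star)) {
    stop_mrnm("model '%s' needs the adjusted covariate c_star", spec$name,
              class = "mrnm_config_error")
  }
  yj <- if (second) c(y, c_star) else y
  N <- length(yj)
  X <- if (second) {
    cbind(c(rep(1, n), rep(0, n)), c(rep(0, n), rep(1, n)))
  } else {
    matrix(1, n, 1)
  }
  p <- ncol(X)
  act <- active_sets(spec)
  ng <- length(act$g) * (length(act$g) + 1) / 2
  ne <- length(act$e) * (length(act$e) + 1) / 2
  env <- new.env(parent = emptyenv())
  env$last_theta <- NULL
  env$boundary_hits <- 0L

  split_theta <- function(theta) {
    list(g = theta[seq_len(ng)], e = theta[ng + seq_len(ne)])
  }

  # core computation at theta; cached between fn and gr calls
  compute <- function(theta, need_P = FALSE) {
    if (!is.null(env$last_theta) && identical(env$last_theta, theta) &&
        (!need_P || !is.null(env$P))) {
      return(env$state)
    }
    th <- split_theta(theta)
    jg <- theta_to_joint(th$g, act$g)
    je <- theta_to_joint(th$e, act$e)
    V <- assemble_V(jg$M3, je$M3, A, cvec, second)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) {
      env$boundary_hits <- env$boundary_hits + 1L
      env$last_theta <- NULL
      return(NULL)
    }
    ldV <- 2 * sum(log(diag(ch)))
    ViY <- backsolve(ch, backsolve(ch, cbind(yj, X), transpose = TRUE))
    Viy <- ViY[, 1]
    ViX <- ViY[, -1, drop = FALSE]
    XVX <- crossprod(X, ViX)
    XVy <- crossprod(X, Viy)
    b <- tryCatch(solve(XVX, XVy), error = function(e) NULL)
    if (is.null(b) || !all(is.finite(b)) || !all(is.finite(ldV))) {
      env$boundary_hits <- env$boundary_hits + 1L
      env$last_theta <- NULL
      return(NULL)
    }
    quad <- sum(yj * Viy) - sum(XVy * b)
    nll <- if (spec$criterion == "REML") {
      0.5 * (ldV + as.numeric(determinant(XVX)$modulus) + quad +
               (N - p) * log(2 * pi))
    } else {
      0.5 * (ldV + quad + N * log(2 * pi))
    }
    state <- list(theta = theta, jg = jg, je = je, ch = ch, nll = nll,
                  b = b, Viy = Viy, ViX = ViX, XVX = XVX)
    if (need_P) {
      Vi <- chol2inv(ch)
      if (spec$criterion == "REML") {
        Tm <- Vi - ViX %*% solve(XVX, t(ViX))
        q <- as.numeric(Tm %*% yj)
      } else {
        Tm <- Vi
        q <- as.numeric(Viy - ViX %*% b)
      }
      state$Tm <- Tm
      state$q <- q
      env$P <- TRUE
    } else {
      env$P <- NULL
    }
    env$state <- state
    env$last_theta <- theta
    state
  }

  # gradient of the negative log-likelihood wrt the natural free entries
  natural_grad <- function(state) {
    Tm <- state$Tm; q <- state$q
    iy <- seq_len(n)
    ic <- if (second) n + seq_len(n) else integer(0)
    Tyy <- Tm[iy, iy]
    qy <- q[iy]
    if (second) {
      Tyc <- Tm[iy, ic]; Tcc <- Tm[ic, ic]; qc <- q[ic]
      Aqc <- as.numeric(A %*% qc)
    }
    xs <- list(rep(1, n), cvec)
    Aqx <- list(as.numeric(A %*% qy), as.numeric(A %*% (qy * cvec)))
    PAyy <- Tyy * A
    if (second) PAyc_rs <- rowSums(Tyc * A)

    grad_block <- function(pairs, genetic) {
      vapply(pairs, function(pr) {
        u <- pr[1]; v <- pr[2]
        if (genetic) {
          if (u <= 2 && v <= 2) {
            tr <- sum(xs[[u]] * (PAyy %*% xs[[v]]))
            qd <- sum((qy * xs[[u]]) * Aqx[[v]])
            if (u != v) { tr <- 2 * tr; qd <- 2 * qd }
          } else if (v <= 2) {            # u == 3: cov(coef_v, beta)
            tr <- 2 * sum(xs[[v]] * PAyc_rs)
            qd <- 2 * sum((qy * xs[[v]]) * Aqc)
          } else {                        # sigma_beta2
            tr <- sum(Tcc * A)
            qd <- sum(qc * Aqc)
          }
        } else {
          if (u <= 2 && v <= 2) {
            mvec <- xs[[u]] * xs[[v]]
            if (u != v) mvec <- 2 * mvec
            tr <- sum(diag(Tyy) * mvec)
            qd <- sum(qy^2 * mvec)
          } else if (v <= 2) {            # cov(coef_v, eps)
            tr <- 2 * sum(diag(Tyc) * xs[[v]])
            qd <- 2 * sum(qy * qc * xs[[v]])
          } else {                        # sigma_eps2
            tr <- sum(diag(Tcc))
            qd <- sum(qc^2)
          }
        }
        0.5 * (tr - qd)
      }, numeric(1))
    }
    list(g = grad_block(entry_pairs(act$g), TRUE),
         e = grad_block(entry_pairs(act$e), FALSE))
  }

  # chain natural entry gradients through the log-Cholesky map
  chain_logchol <- function(g_entries, L) {
    d <- nrow(L)
    S <- matrix(0, d, d)
    k <- 1L
    for (j in seq_len(d)) for (i in j:d) {
      if (i == j) S[i, i] <- g_entries[k]
      else { S[i, j] <- g_entries[k] / 2; S[j, i] <- g_entries[k] / 2 }
      k <- k + 1L
    }
    GL <- 2 * S %*% L
    out <- numeric(0)
    for (j in seq_len(d)) for (i in j:d) {
      out <- c(out, if (i == j) GL[i, i] * L[i, i] else GL[i, j])
    }
    out
  }

  fn <- function(theta) {
    st <- compute(theta)
    if (is.null(st)) return(1e10)
    st$nll
  }
  gr <- function(theta) {
    st <- compute(theta, need_P = TRUE)
    if (is.null(st)) return(rep(0, ng + ne))
    g <- natural_grad(st)
    c(chain_logchol(g$g, st$jg$L), chain_logchol(g$e, st$je$L))
  }
  # negative log-likelihood and gradient on the natural (entry) scale,
  # for observed-information standard errors
  natural_fn <- function(entries) {
    mats <- entries_to_joint(entries, act)
    V <- assemble_V(mats$G3, mats$E3, A, cvec, second)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NA_real_)
    ldV <- 2 * sum(log(diag(ch)))
    ViY <- backsolve(ch, backsolve(ch, cbind(yj, X), transpose = TRUE))
    Viy <- ViY[, 1]; ViX <- ViY[, -1, drop = FALSE]
    XVX <- crossprod(X, ViX); XVy <- crossprod(X, Viy)
    b <- tryCatch(solve(XVX, XVy), error = function(e) NULL)
    if (is.null(b)) return(NA_real_)
    quad <- sum(yj * Viy) - sum(XVy * b)
    if (spec$criterion == "REML") {
      0.5 * (ldV + as.numeric(determinant(XVX)$modulus) + quad +
               (N - p) * log(2 * pi))
    } else {
      0.5 * (ldV + quad + N * log(2 * pi))
    }
  }
  natural_gr <- function(entries) {
    mats <- entries_to_joint(entries, act)
    V <- assemble_V(mats$G3, mats$E3, A, cvec, second)
    ch <- chol(V)
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XVX <- crossprod(X, ViX)
    if (spec$criterion == "REML") {
      Tm <- Vi - ViX %*% solve(XVX, t(ViX))
      q <- as.numeric(Tm %*% yj)
    } else {
      Tm <- Vi
      b <- solve(XVX, crossprod(ViX, yj))
      q <- as.numeric(Vi %*% (yj - X %*% b))
    }
    st <- list(Tm = Tm, q = q)
    g <- natural_grad(st)
    c(g$g, g$e)
  }

  list(fn = fn, gr = gr, natural_fn = natural_fn, natural_gr = natural_gr,
       compute = compute, act = act, ng = ng, ne = ne, X = X, yj = yj,
       N = N, p = p, n = n, env = env, split_theta = split_theta)
}

entries_to_joint <- function(entries, act) {
  fill <- function(vals, a) {
    M <- matrix(0, 3, 3)
    k <- 1L
    d <- length(a)
    for (j in seq_len(d)) for (i in j:d) {
      M[a[i], a[j]] <- vals[k]; M[a[j], a[i]] <- vals[k]
      k <- k + 1L
    }
    M
  }
  ng <- length(act$g) * (length(act$g) + 1) / 2
  list(G3 = fill(entries[seq_len(ng)], act$g),
       E3 = fill(entries[-seq_len(ng)], act$e))
}

joint_to_entries <- function(G3, E3, act) {
  take <- function(M, a) {
    out <- numeric(0)
    d <- length(a)
    for (j in seq_len(d)) for (i in j:d) out <- c(out, M[a[i], a[j]])
    out
  }
  c(take(G3, act$g), take(E3, act$e))
}

default_init <- function(y, c_star, spec) {
  vy <- stats::var(y)
  G3 <- diag(c(0.45 * vy, 0.05 * vy, 0))
  E3 <- diag(c(0.45 * vy, 0.05 * vy, 0))
  if (spec$second_trait) {
    vc <- stats::var(c_star)
    G3[3, 3] <- 0.45 * vc
    E3[3, 3] <- 0.55 * vc
  }
  list(G3 = G3, E3 = E3)
}

#' Log-likelihood of a reaction norm model at given parameters
#'
#' Evaluates the restricted (or full) Gaussian log-likelihood of the model
#' defined by `spec` at fixed variance parameters, profiling only the
#' per-trait grand means. REML:
#' `-1/2 [ (N - p) log 2 pi + log|V| + log|X' V^-1 X| + r' V^-1 r ]` with
#' `X` the per-trait intercept design and `r` the GLS residual.
#'
#' @param params `rnm_params`.
#' @param y phenotype vector.
#' @param A GRM.
#' @param c standardized covariate.
#' @param spec `rnm_model_spec`.
#' @param c_star adjusted covariate (second-trait phenotype), required
#'   when `spec$second_trait`.
#' @return log-likelihood value (`-Inf` if the implied covariance is not
#'   positive definite).
#' @export
rnm_loglik <- function(params, y, A, c, spec, c_star = NULL) {
  eng <- make_engine(y, A, c, spec, c_star)
  G3 <- joint_cov(params$K_g, params$K_g_beta, params$sigma_beta2)
  E3 <- joint_cov(params$K_e, params$K_e_eps, params$sigma_eps2)
  val <- eng$natural_fn(joint_to_entries(G3, E3, eng$act))
  if (is.na(val)) -Inf else -val
}

#' Fit a reaction norm model by REML or ML
#'
#' Maximizes the (restricted) likelihood over the free variance
#' parameters of the chosen model by quasi-Newton (BFGS) iteration with
#' analytic gradients on an unconstrained log-Cholesky parameterization of
#' the active blocks of the joint genetic and residual covariances, which
#' keeps every iterate positive semi-definite including near the boundary.
#' On convergence failure the optimization restarts from perturbed
#' starting values. Standard errors come from the inverse observed
#' information (numerically differentiated analytic gradient on the
#' natural scale); BLUPs of the random regression coefficients are the
#' mixed-model conditional means at the estimates.
#'
#' @param y phenotype vector (pre-adjusted, transformed scale).
#' @param A GRM.
#' @param c standardized covariate.
#' @param model model name (see [model_spec()]) or an `rnm_model_spec`.
#' @param c_star adjusted covariate, required for second-trait models.
#' @param criterion `"REML"` or `"ML"` (ignored if `model` is a spec).
#' @param init optional list with `G3`, `E3` joint 3 x 3 starting values.
#' @param se compute standard errors and the parameter covariance matrix
#'   (adds a numerical-Hessian pass; skip for pure likelihood-ratio work).
#' @param blup compute coefficient BLUPs.
#' @param tol relative convergence tolerance on the log-likelihood.
#' @param grad_tol gradient-norm threshold declaring convergence.
#' @param max_restarts perturbed restarts attempted on failure.
#' @param max_iter BFGS iteration cap per start.
#' @return object of class `rnm_fit`: estimates (`params`, `G3`, `E3`),
#'   `logL`, `n_free`, `se`, `vcov`, `blup` (data frame with `alpha0`,
#'   `alpha1`, `g`), and `convergence` diagnostics.
#' @export
rnm_fit <- function(y, A, c, model = "greml", c_star = NULL,
                    criterion = c("REML", "ML"), init = NULL, se = TRUE,
                    blup = TRUE, tol = 1e-8, grad_tol = 1e-4,
                    max_restarts = 5, max_iter = 500) {
  criterion <- match.arg(criterion)
  spec <- if (inherits(model, "rnm_model_spec")) model
          else model_spec_by_name(model, criterion)
  n <- length(y)
  eng <- make_engine(y, A, c, spec, c_star)
  if (eng$ng + eng$ne > n) {
    stop_mrnm("more free parameters (%d) than individuals (%d)",
              eng$ng + eng$ne, n, class = "mrnm_config_error")
  }
  init <- init %||% default_init(y, c_star, spec)
  theta0 <- c(pack_logchol(init$G3[eng$act$g, eng$act$g, drop = FALSE]),
              pack_logchol(init$E3[eng$act$e, eng$act$e, drop = FALSE]))

  run_opt <- function(th0) {
    stats::optim(th0, eng$fn, eng$gr, method = "BFGS",
                 control = list(maxit = max_iter, reltol = tol))
  }
  best <- run_opt(theta0)
  grad_norm <- sqrt(sum(eng$gr(best$par)^2))
  restarts <- 0L
  while ((best$convergence != 0 && grad_norm > grad_tol) &&
         restarts < max_restarts) {
    restarts <- restarts + 1L
    # deterministic perturbation ladder that leaves the caller's RNG alone
    rng_state <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    set.seed(1000L + restarts)
    perturb <- stats::rnorm(length(theta0), sd = 0.3)
    if (!is.null(rng_state)) assign(".Random.seed", rng_state, globalenv())
    cand <- run_opt(best$par + perturb)
    if (cand$value < best$value) best <- cand
    grad_norm <- sqrt(sum(eng$gr(best$par)^2))
  }
  status <- if (grad_norm <= grad_tol || best$convergence == 0) {
    "converged"
  } else {
    "max_iterations"
  }

  st <- eng$compute(best$par, need_P = TRUE)
  G3 <- st$jg$M3; E3 <- st$je$M3
  params <- params_from_joint(G3, E3)
  nms <- free_param_names(spec)
  entries <- joint_to_entries(G3, E3, eng$act)
  names(entries) <- nms

  se_vec <- NULL; vcov_mat <- NULL
  if (se) {
    H <- numeric_hessian(eng$natural_gr, entries)
    vcov_mat <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(vcov_mat) || any(diag(vcov_mat) < 0)) {
      vcov_mat <- psd_pseudo_inverse(H)
    }
    dimnames(vcov_mat) <- list(nms, nms)
    se_vec <- sqrt(pmax(diag(vcov_mat), 0))
    names(se_vec) <- nms
  }

  blup_df <- NULL
  if (blup) {
    Vir <- as.numeric(st$Viy - st$ViX %*% st$b)
    w0 <- G3[1, 1] + G3[1, 2] * c
    w1 <- G3[1, 2] + G3[2, 2] * c
    C0 <- sweep(A, 2, w0, "*")
    C1 <- sweep(A, 2, w1, "*")
    if (spec$second_trait) {
      C0 <- cbind(C0, G3[1, 3] * A)
      C1 <- cbind(C1, G3[2, 3] * A)
    }
    a0 <- as.numeric(C0 %*% Vir)
    a1 <- as.numeric(C1 %*% Vir)
    blup_df <- data.frame(alpha0 = a0, alpha1 = a1, g = a0 + a1 * c)
  }

  structure(list(
    spec = spec, criterion = criterion, params = params, G3 = G3, E3 = E3,
    mu = as.numeric(st$b), logL = -st$nll, n_free = eng$ng + eng$ne,
    estimates = entries, se = se_vec, vcov = vcov_mat, blup = blup_df,
    n = n, c = c,
    convergence = list(status = status, optim_convergence = best$convergence,
                       counts = best$counts, gradient_norm = grad_norm,
                       restarts = restarts,
                       boundary_hits = eng$env$boundary_hits)),
    class = "rnm_fit")
}

#' @export
print.rnm_fit <- function(x, ...) {
  cat(sprintf("Reaction norm model fit: '%s' (%s), n = %d\n",
              x$spec$name, x$criterion, x$n))
  cat(sprintf("  logL = %.4f   free parameters = %d   status = %s\n",
              x$logL, x$n_free, x$convergence$status))
  est <- x$estimates
  tab <- data.frame(estimate = round(est, 4))
  if (!is.null(x$se)) tab$se <- round(x$se, 4)
  print(tab)
  invisible(x)
}

numeric_hessian <- function(grad_fun, x, h_rel = 1e-4) {
  p <- length(x)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    h <- h_rel * (abs(x[j]) + 1e-3)
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    gp <- tryCatch(grad_fun(xp), error = function(e) rep(NA_real_, p))
    gm <- tryCatch(grad_fun(xm), error = function(e) rep(NA_real_, p))
    H[, j] <- (gp - gm) / (2 * h)
  }
  (H + t(H)) / 2
}

psd_pseudo_inverse <- function(H, tol = 1e-10) {
  ed <- eigen(H, symmetric = TRUE)
  pos <- ed$values > tol * max(abs(ed$values))
  inv_vals <- ifelse(pos, 1 / ed$values, 0)
  ed$vectors %*% (inv_vals * t(ed$vectors))
}
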