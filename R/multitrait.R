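#' Multi-trait GREML
#'
#' Unstructured t-trait genomic REML: genetic covariance `Sigma_g (x) A`
#' plus residual covariance `Sigma_e (x) I`, one record per individual,
#' per-trait intercepts as fixed effects. Because both kernels share the
#' GRM's eigenvectors, the likelihood factorizes over eigenvalues after a
#' one-off rotation, making each evaluation O(n t^3); the two covariance
#' matrices are parameterized by their Cholesky factors (log-diagonal) and
#' maximized by quasi-Newton iteration.
#'
#' Derived quantities: per-trait heritabilities
#' `h2_i = sigma2_g_i / (sigma2_g_i + sigma2_e_i)` and genetic correlations
#' `r_g_ij = sigma_g_ij / sqrt(sigma2_g_i sigma2_g_j)`.
#'
#' @param Y n x t matrix of trait phenotypes (complete cases are used;
#'   rows with any missing value are dropped with a message).
#' @param A GRM.
#' @param criterion `"REML"` (default) or `"ML"`.
#' @param se compute observed-information standard errors.
#' @param tol relative convergence tolerance.
#' @param max_iter iteration cap.
#' @return object of class `mt_greml_fit` with `Sigma_g`, `Sigma_e`,
#'   `h2`, `genetic_correlations`, `logL`, `n_free`, `se` (named vector
#'   over the unique elements of both matrices) and convergence info.
#' @export
multi_trait_greml <- function(Y, A, criterion = c("REML", "ML"), se = TRUE,
                              tol = 1e-10, max_iter = 1000) {
  criterion <- match.arg(criterion)
  Y <- as.matrix(Y)
  t_tr <- ncol(Y)
  cc <- stats::complete.cases(Y)
  if (!all(cc)) {
    message(sprintf("dropping %d incomplete rows", sum(!cc)))
    Y <- Y[cc, , drop = FALSE]
    A <- A[cc, cc, drop = FALSE]
  }
  n <- nrow(Y)
  ed <- eigen(A, symmetric = TRUE)
  d <- pmax(ed$values, 0)
  Yt <- crossprod(ed$vectors, Y)              # n x t rotated phenotypes
  xt <- as.numeric(crossprod(ed$vectors, rep(1, n)))
  N <- n * t_tr
  p <- t_tr

  idx <- which(lower.tri(diag(t_tr), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
  npar_half <- nrow(idx)

  mats_from_theta <- function(theta) {
    list(Sg = tcrossprod(unpack_logchol(theta[seq_len(npar_half)], t_tr)),
         Se = tcrossprod(unpack_logchol(theta[-seq_len(npar_half)], t_tr)))
  }

  # negative log-likelihood via simultaneous diagonalization of
  # (Sigma_g, Sigma_e): V_k = d_k Sigma_g + Sigma_e for eigenvalue d_k
  nll_mats <- function(Sg, Se) {
    che <- tryCatch(chol(Se), error = function(e) NULL)
    if (is.null(che)) return(1e10)
    Se_isqrt <- backsolve(che, diag(t_tr))    # Se^{-1/2}' (upper inverse)
    M <- t(Se_isqrt) %*% Sg %*% Se_isqrt
    if (!all(is.finite(M))) return(1e10)
    em <- eigen((M + t(M)) / 2, symmetric = TRUE)
    lam <- pmax(em$values, 0)
    Tr <- t(em$vectors) %*% t(Se_isqrt)       # y* = Tr y diagonalizes all V_k
    Ystar <- Yt %*% t(Tr)                     # n x t
    Wk <- 1 / (outer(d, lam) + 1)             # n x t weights
    ldet <- n * 2 * sum(log(diag(che))) + sum(log(outer(d, lam) + 1))
    yVy <- sum(Ystar^2 * Wk)
    # X = I_t (x) 1_n rotates to columns xt; X'V^-1X = Tr' diag(sw) Tr
    sw <- colSums(xt^2 * Wk)                  # length t
    XVX <- t(Tr) %*% (sw * Tr)
    XVy <- as.numeric(t(Tr) %*% colSums(xt * Wk * Ystar))
    b <- tryCatch(solve(XVX, XVy), error = function(e) NULL)
    if (is.null(b) || !all(is.finite(b)) || !is.finite(ldet)) return(1e10)
    quad <- yVy - sum(XVy * b)
    if (criterion == "REML") {
      0.5 * (ldet + as.numeric(determinant(XVX)$modulus) + quad +
               (N - p) * log(2 * pi))
    } else {
      0.5 * (ldet + quad + N * log(2 * pi))
    }
  }
  fn <- function(theta) {
    m <- mats_from_theta(theta)
    nll_mats(m$Sg, m$Se)
  }

  vY <- stats::cov(Y)
  theta0 <- c(pack_logchol(vY / 2 + diag(1e-4, t_tr)),
              pack_logchol(vY / 2 + diag(1e-4, t_tr)))
  best <- stats::optim(theta0, fn, method = "BFGS",
                       control = list(maxit = max_iter, reltol = tol))
  m <- mats_from_theta(best$par)
  Sg <- m$Sg; Se <- m$Se
  trait_names <- colnames(Y) %||% paste0("trait", seq_len(t_tr))
  dimnames(Sg) <- dimnames(Se) <- list(trait_names, trait_names)

  h2 <- diag(Sg) / (diag(Sg) + diag(Se))
  dg <- sqrt(diag(Sg))
  rg <- Sg / outer(dg, dg)
  if (min(eigen(Se, symmetric = TRUE, only.values = TRUE)$values) <
      1e-6 * max(diag(Se))) {
    stop_mrnm("residual covariance is singular (duplicated trait?)",
              class = "mrnm_degeneracy_error")
  }

  ent_names <- c(
    apply(idx, 1, function(r) if (r[1] == r[2])
      sprintf("sigma2_g_%s", trait_names[r[1]])
      else sprintf("cov_g_%s_%s", trait_names[r[2]], trait_names[r[1]])),
    apply(idx, 1, function(r) if (r[1] == r[2])
      sprintf("sigma2_e_%s", trait_names[r[1]])
      else sprintf("cov_e_%s_%s", trait_names[r[2]], trait_names[r[1]])))
  entries <- c(Sg[cbind(idx[, 1], idx[, 2])], Se[cbind(idx[, 1], idx[, 2])])
  names(entries) <- ent_names

  se_vec <- NULL
  if (se) {
    nat_fn <- function(ent) {
      Sg_ <- matrix(0, t_tr, t_tr); Se_ <- matrix(0, t_tr, t_tr)
      Sg_[cbind(idx[, 1], idx[, 2])] <- ent[seq_len(npar_half)]
      Sg_[cbind(idx[, 2], idx[, 1])] <- ent[seq_len(npar_half)]
      Se_[cbind(idx[, 1], idx[, 2])] <- ent[-seq_len(npar_half)]
      Se_[cbind(idx[, 2], idx[, 1])] <- ent[-seq_len(npar_half)]
      nll_mats(Sg_, Se_)
    }
    H <- stats::optimHess(entries, nat_fn)
    vc <- tryCatch(solve(H), error = function(e) psd_pseudo_inverse(H))
    if (any(diag(vc) < 0)) vc <- psd_pseudo_inverse(H)
    se_vec <- sqrt(pmax(diag(vc), 0))
    names(se_vec) <- ent_names
  }

  structure(list(
    Sigma_g = Sg, Sigma_e = Se, h2 = h2, genetic_correlations = rg,
    logL = -best$value, n_free = 2 * npar_half, estimates = entries,
    se = se_vec, n = n, t = t_tr, criterion = criterion,
    convergence = list(optim_convergence = best$convergence,
                       counts = best$counts)),
    class = "mt_greml_fit")
}

#' @export
print.mt_greml_fit <- function(x, ...) {
  cat(sprintf("Multi-trait GREML fit: %d trait(s), n = %d, logL = %.4f\n",
              x$t, x$n, x$logL))
  cat("Heritabilities:\n"); print(round(x$h2, 4))
  if (x$t > 1) {
    cat("Genetic correlations:\n"); print(round(x$genetic_correlations, 4))
  }
  invisible(x)
}
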