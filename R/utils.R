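`%||%` <- function(x, y) if (is.null(x)) y else x

#' Population standard deviation
#'
#' Divide-by-n standard deviation, the convention used throughout the
#' package for covariate standardization and genotype column scaling so
#' that derived identities (unit variance of the standardized covariate,
#' mean GRM diagonal of one) hold exactly.
#'
#' @param x numeric vector.
#' @return scalar standard deviation with denominator `length(x)`.
#' @keywords internal
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

stop_mrnm <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "mrnm_error")))
}

#' @keywords internal
is_psd <- function(m, tol = 1e-8) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= -tol * max(abs(ev), 1)
}

check_psd <- function(m, what, tol = 1e-8) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1)) {
    stop_mrnm("%s is not positive semi-definite (smallest eigenvalue %.3g)",
              what, min(ev), class = "mrnm_config_error")
  }
  invisible(TRUE)
}

# Matrix square root of a PSD matrix via eigendecomposition, with
# optional diagonal jitter for rank-deficient inputs (e.g. a GRM built
# from fewer SNPs than individuals).
psd_sqrt <- function(m, jitter = 0) {
  if (jitter > 0) m <- m + diag(jitter, nrow(m))
  ed <- eigen(m, symmetric = TRUE)
  ev <- pmax(ed$values, 0)
  ed$vectors %*% (sqrt(ev) * t(ed$vectors))
}
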