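#' Likelihood-ratio test between nested reaction norm models
#'
#' `statistic = 2 (logL_alt - logL_null)`, degrees of freedom equal to the
#' difference in free-parameter counts, p-value from the chi-square upper
#' tail. Small negative statistics (within convergence tolerance) are
#' clipped to zero; a larger deficit signals a failed alternative fit and
#' raises an error. The plain chi-square reference follows common practice
#' for these model ladders; variance components sitting on the boundary
#' under the null make it conservative, and `boundary_mixture = TRUE`
#' applies the 50:50 chi-square mixture with one fewer df for sensitivity
#' analysis.
#'
#' @param fit_null,fit_alt `rnm_fit` objects on the same data and
#'   criterion, with the null's flags nested in the alternative's.
#' @param boundary_mixture use the chi-square mixture reference.
#' @return object of class `rnm_comparison` (one-row data frame with
#'   `null`, `alt`, `logL_null`, `logL_alt`, `statistic`, `df`, `p`).
#' @export
lrt <- function(fit_null, fit_alt, boundary_mixture = FALSE) {
  s0 <- fit_null$spec; s1 <- fit_alt$spec
  nested <- (!s0$genetic_slope | s1$genetic_slope) &&
    (!s0$residual_slope | s1$residual_slope) &&
    s0$second_trait == s1$second_trait &&
    fit_null$n_free < fit_alt$n_free
  if (!nested) {
    stop_mrnm("'%s' is not nested in '%s'", s0$name, s1$name,
              class = "mrnm_config_error")
  }
  if (fit_null$criterion != fit_alt$criterion) {
    stop_mrnm("fits use different criteria (%s vs %s)",
              fit_null$criterion, fit_alt$criterion,
              class = "mrnm_config_error")
  }
  stat <- 2 * (fit_alt$logL - fit_null$logL)
  if (stat < -1e-6) {
    stop_mrnm("alternative fit '%s' has lower log-likelihood than null '%s' (%.3g); refit with restarts",
              s1$name, s0$name, stat, class = "mrnm_fit_error")
  }
  stat <- max(stat, 0)
  df <- fit_alt$n_free - fit_null$n_free
  p <- if (boundary_mixture) {
    0.5 * stats::pchisq(stat, df - 1, lower.tail = FALSE) +
      0.5 * stats::pchisq(stat, df, lower.tail = FALSE)
  } else {
    stats::pchisq(stat, df, lower.tail = FALSE)
  }
  structure(data.frame(null = s0$name, alt = s1$name,
                       logL_null = fit_null$logL, logL_alt = fit_alt$logL,
                       statistic = stat, df = df, p = p),
            class = c("rnm_comparison", "data.frame"))
}

ladder_rows <- data.frame(
  index = paste0("M", 1:6),
  null = c("greml", "urnm-rxe", "urnm-gxe",
           "bigreml", "mrnm-rxe", "mrnm-gxe"),
  alt = c("urnm-full", "urnm-full", "urnm-full",
          "mrnm-full", "mrnm-full", "mrnm-full"),
  type = c("combined GxE and RxE", "orthogonal GxE", "orthogonal RxE",
           "combined GxE and RxE", "orthogonal GxE", "orthogonal RxE"),
  stringsAsFactors = FALSE)

#' The M1-M6 likelihood-ratio ladder
#'
#' Fits all eight component models (univariate GREML, the three univariate
#' reaction norm models, bivariate GREML, and the three multivariate
#' reaction norm models) on one dataset and assembles the six standard
#' comparisons:
#' M1 univariate GREML vs URNM full (combined, df 4); M2 URNM RxE vs URNM
#' full (orthogonal GxE, df 2); M3 URNM GxE vs URNM full (orthogonal RxE,
#' df 2); M4 bivariate GREML vs MRNM full (combined, df 6); M5 MRNM RxE vs
#' MRNM full (orthogonal GxE, df 3); M6 MRNM GxE vs MRNM full (orthogonal
#' RxE, df 3). The univariate rows ignore correlations between trait and
#' covariate; the multivariate rows absorb them, which is what protects
#' the interaction tests from genotype-environment confounding.
#'
#' Nested fits are warm-started from their parents' estimates, and an
#' alternative that lands below its null is refitted from the null's
#' parameters before the comparison is declared.
#'
#' @param y phenotype vector.
#' @param A GRM.
#' @param c standardized covariate.
#' @param c_star adjusted covariate (second-trait phenotype).
#' @param criterion `"REML"` or `"ML"`.
#' @param se compute standard errors in the component fits.
#' @param boundary_mixture see [lrt()].
#' @return object of class `mrnm_ladder`: list with `comparisons` (six-row
#'   data frame), `fits` (named list of the eight `rnm_fit`s) and
#'   `collinearity` (list with the URNM and MRNM collinearity magnitudes).
#' @export
run_ladder <- function(y, A, c, c_star, criterion = c("REML", "ML"),
                       se = FALSE, boundary_mixture = FALSE) {
  criterion <- match.arg(criterion)
  fits <- list()
  fit1 <- function(name, parent = NULL) {
    init <- if (!is.null(parent)) warm_init(fits[[parent]], name)
    rnm_fit(y, A, c, model = name, c_star = c_star, criterion = criterion,
            se = se, blup = TRUE, init = init)
  }
  fits$`greml` <- fit1("greml")
  fits$`urnm-gxe` <- fit1("urnm-gxe", "greml")
  fits$`urnm-rxe` <- fit1("urnm-rxe", "greml")
  fits$`urnm-full` <- fit1("urnm-full", "urnm-gxe")
  fits$`bigreml` <- fit1("bigreml", "greml")
  fits$`mrnm-gxe` <- fit1("mrnm-gxe", "bigreml")
  fits$`mrnm-rxe` <- fit1("mrnm-rxe", "bigreml")
  fits$`mrnm-full` <- fit1("mrnm-full", "mrnm-gxe")

  # guarantee monotone likelihoods along every nesting edge: refit an
  # alternative from a parent that beats it
  edges <- rbind(ladder_rows[, c("null", "alt")],
                 data.frame(null = c("urnm-rxe", "mrnm-rxe"),
                            alt = c("urnm-full", "mrnm-full")))
  for (pass in 1:2) {
    for (k in seq_len(nrow(edges))) {
      n0 <- edges$null[k]; n1 <- edges$alt[k]
      if (fits[[n1]]$logL < fits[[n0]]$logL - 1e-7) {
        refit <- rnm_fit(y, A, c, model = n1, c_star = c_star,
                         criterion = criterion, se = se, blup = TRUE,
                         init = warm_init(fits[[n0]], n1))
        if (refit$logL > fits[[n1]]$logL) fits[[n1]] <- refit
      }
    }
  }

  comparisons <- do.call(rbind, lapply(seq_len(nrow(ladder_rows)),
                                       function(k) {
    row <- ladder_rows[k, ]
    cmp <- lrt(fits[[row$null]], fits[[row$alt]],
               boundary_mixture = boundary_mixture)
    cbind(data.frame(index = row$index, type = row$type), cmp)
  }))
  rownames(comparisons) <- NULL

  coll <- list(
    urnm = collinearity_magnitude(fits$`greml`, fits$`urnm-gxe`,
                                  fits$`urnm-rxe`, fits$`urnm-full`),
    mrnm = collinearity_magnitude(fits$`bigreml`, fits$`mrnm-gxe`,
                                  fits$`mrnm-rxe`, fits$`mrnm-full`))

  structure(list(comparisons = comparisons, fits = fits,
                 collinearity = coll, criterion = criterion),
            class = "mrnm_ladder")
}

#' @export
print.mrnm_ladder <- function(x, ...) {
  cat(sprintf("Likelihood-ratio ladder (%s)\n", x$criterion))
  tab <- x$comparisons
  tab$p <- format(tab$p, digits = 3)
  print(tab[, c("index", "null", "alt", "type", "statistic", "df", "p")],
        row.names = FALSE)
  cat(sprintf("Collinearity magnitude: URNM %.4f, MRNM %.4f\n",
              x$collinearity$urnm, x$collinearity$mrnm))
  invisible(x)
}

# translate a fitted (smaller) model into starting values for a larger
# one: copy the estimated joint blocks, seed newly freed slope variances
# at a fraction of the parent intercept variance
warm_init <- function(fit, target_name) {
  spec_t <- model_spec_by_name(target_name)
  G3 <- fit$G3; E3 <- fit$E3
  if (spec_t$genetic_slope && G3[2, 2] == 0) G3[2, 2] <- 0.05 * G3[1, 1]
  if (spec_t$residual_slope && E3[2, 2] == 0) E3[2, 2] <- 0.05 * E3[1, 1]
  if (spec_t$second_trait && G3[3, 3] == 0) {
    G3[3, 3] <- 0.5; E3[3, 3] <- 0.5
  }
  list(G3 = G3, E3 = E3)
}

#' Collinearity magnitude between GxE and RxE evidence
#'
#' With the magnitude of significance `M(.)` defined as twice the
#' log-likelihood difference between a larger and a reduced model, the
#' overlap (collinearity) between the GxE and RxE interaction evidence is
#' `M(GxE & RxE) - M(GxE | RxE) - M(RxE | GxE)`, algebraically
#' `2 (logL_gxe_only + logL_rxe_only - logL_null - logL_full)`. The sign
#' is reported as computed: positive overlap means the two interactions
#' explain shared signal.
#'
#' @param fit_null,fit_gxe,fit_rxe,fit_full fits of the no-interaction,
#'   GxE-only, RxE-only and combined models on the same data/criterion.
#' @return scalar collinearity magnitude.
#' @export
collinearity_magnitude <- function(fit_null, fit_gxe, fit_rxe, fit_full) {
  fits <- list(fit_null, fit_gxe, fit_rxe, fit_full)
  if (any(vapply(fits, is.null, logical(1)))) {
    stop_mrnm("all four fits are required", class = "mrnm_config_error")
  }
  crits <- vapply(fits, function(f) f$criterion, character(1))
  if (length(unique(crits)) != 1) {
    stop_mrnm("fits mix criteria", class = "mrnm_config_error")
  }
  2 * (fit_gxe$logL + fit_rxe$logL - fit_null$logL - fit_full$logL)
}

#' Heritability summary of a reaction norm fit
#'
#' Reports both conventions used for reaction norm models:
#' \describe{
#'   \item{mean environment (headline)}{`h2 = sigma2_a0 / (sigma2_a0 +
#'     sigma2_t0)`, the variance ratio at the covariate mean (`c = 0`,
#'     where the slope terms vanish). For models without slopes this is
#'     the ordinary GREML heritability.}
#'   \item{averaged}{`sigma2_g_avg = mean_i(phi_i' K_g phi_i)` and its
#'     residual analogue, averaging the individual-level variances over
#'     the observed covariate distribution; `h2_avg` is their ratio.}
#' }
#' The two coincide for models without interaction terms. Standard errors
#' for the headline `h2` come from the delta method on the fit's
#' parameter covariance matrix.
#'
#' @param fit `rnm_fit`.
#' @param c standardized covariate (defaults to the one stored in the fit).
#' @return list with `h2`, `h2_se`, `sigma2_g0`, `sigma2_e0`,
#'   `sigma2_g_avg`, `sigma2_e_avg`, `h2_avg`.
#' @export
heritability_summary <- function(fit, c = fit$c) {
  Phi <- build_phi(c)
  vg_i <- rowSums((Phi %*% fit$params$K_g) * Phi)
  ve_i <- rowSums((Phi %*% fit$params$K_e) * Phi)
  vg_avg <- mean(vg_i); ve_avg <- mean(ve_i)
  vg0 <- fit$params$K_g[1, 1]; ve0 <- fit$params$K_e[1, 1]
  tot0 <- vg0 + ve0
  if (tot0 <= 0) {
    stop_mrnm("zero total variance", class = "mrnm_degeneracy_error")
  }
  h2 <- vg0 / tot0
  h2_se <- NA_real_
  if (!is.null(fit$vcov)) {
    nm <- rownames(fit$vcov)
    i_g <- match("sigma2_a0", nm); i_e <- match("sigma2_t0", nm)
    if (!is.na(i_g) && !is.na(i_e)) {
      grad <- c(ve0, -vg0) / tot0^2
      sub <- fit$vcov[c(i_g, i_e), c(i_g, i_e)]
      h2_se <- sqrt(max(as.numeric(t(grad) %*% sub %*% grad), 0))
    }
  }
  list(h2 = h2, h2_se = h2_se, sigma2_g0 = vg0, sigma2_e0 = ve0,
       sigma2_g_avg = vg_avg, sigma2_e_avg = ve_avg,
       h2_avg = vg_avg / (vg_avg + ve_avg))
}

#' Rank correlation of estimated breeding values across models
#'
#' Spearman correlation of the per-animal total genetic effects
#' `g_hat_i = alpha0_hat_i + alpha1_hat_i c_i` between two fits on the
#' same animals (a no-slope model contributes `alpha1_hat = 0`). Values
#' below 1 quantify re-ranking of selection candidates induced by the
#' interaction terms.
#'
#' @param fit_a,fit_b `rnm_fit` objects with BLUPs, same animals.
#' @return Spearman correlation.
#' @export
ebv_rank_correlation <- function(fit_a, fit_b) {
  if (is.null(fit_a$blup) || is.null(fit_b$blup)) {
    stop_mrnm("fits lack BLUPs (rerun with blup = TRUE)",
              class = "mrnm_config_error")
  }
  if (nrow(fit_a$blup) != nrow(fit_b$blup)) {
    stop_mrnm("fits cover different numbers of animals",
              class = "mrnm_config_error")
  }
  stats::cor(fit_a$blup$g, fit_b$blup$g, method = "spearman")
}

#' Wald contrast of residual variances between two fits
#'
#' Approximate two-sided test of equality of the (mean-environment)
#' residual variance between two models fitted to the same data:
#' `z = (e_a - e_b) / sqrt(se_a^2 + se_b^2)`. This treats the two fits as
#' independent, which they are not on shared data, so the p-value is an
#' approximation and is labeled as such in the result.
#'
#' @param fit_a,fit_b `rnm_fit` objects with standard errors.
#' @return list with `estimate_a`, `estimate_b`, `z`, `p`, `approximation`.
#' @export
residual_variance_contrast <- function(fit_a, fit_b) {
  get_ev <- function(f) {
    if (is.null(f$se)) {
      stop_mrnm("fit lacks standard errors (rerun with se = TRUE)",
                class = "mrnm_config_error")
    }
    c(f$params$K_e[1, 1], unname(f$se["sigma2_t0"]))
  }
  a <- get_ev(fit_a); b <- get_ev(fit_b)
  z <- (a[1] - b[1]) / sqrt(a[2]^2 + b[2]^2)
  list(estimate_a = a[1], estimate_b = b[1], z = z,
       p = 2 * stats::pnorm(-abs(z)),
       approximation = "Wald contrast assuming independent fits")
}
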