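#' Phenotype record filtering
#'
#' Two-stage filter applied once, in order: (1) per trait, values outside
#' `mean +/- sd_bound * sd` are set missing; (2) animals belonging to any
#' contemporary group or farm location with fewer than `min_group` records
#' are removed.
#'
#' @param records data frame with one row per animal, containing the trait
#'   columns and the grouping columns.
#' @param traits character vector of trait column names.
#' @param sd_bound outlier bound in phenotypic standard deviations.
#' @param min_group minimum records per group; groups with fewer are
#'   dropped. With `strict = TRUE` the cutoff is `> min_group` (strictly
#'   more than `min_group` records required).
#' @param group_cols grouping columns checked for minimum size.
#' @param strict see `min_group`.
#' @return list with `records` (filtered) and `report` (counts removed per
#'   filter).
#' @export
filter_phenotypes <- function(records, traits, sd_bound = 3, min_group = 5,
                              group_cols = c("contemporary_group",
                                             "farm_location"),
                              strict = FALSE) {
  stopifnot(all(traits %in% names(records)),
            all(group_cols %in% names(records)))
  n_outlier <- integer(0)
  for (tr in traits) {
    x <- records[[tr]]
    mu <- mean(x, na.rm = TRUE); s <- stats::sd(x, na.rm = TRUE)
    out <- !is.na(x) & abs(x - mu) > sd_bound * s
    n_outlier[tr] <- sum(out)
    records[[tr]][out] <- NA
  }
  keep <- rep(TRUE, nrow(records))
  for (gc in group_cols) {
    counts <- table(records[[gc]])
    min_n <- if (strict) min_group + 1L else min_group
    small <- names(counts)[counts < min_n]
    keep <- keep & !(as.character(records[[gc]]) %in% small)
  }
  n_small <- sum(!keep)
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0) {
    binding <- if (n_small > 0) "minimum group size" else "outlier bound"
    stop_mrnm("no records survive filtering (binding filter: %s)", binding,
              class = "mrnm_empty_filter_error")
  }
  list(records = records,
       report = list(outliers_set_missing = n_outlier,
                     animals_removed_small_groups = n_small,
                     sd_bound = sd_bound, min_group = min_group,
                     strict = strict))
}

#' Candidate fixed-effect models
#'
#' The 2 x 4 grid of candidate pre-adjustment models: with or without the
#' first `n_pcs` genomic principal components, crossed with no THI term, a
#' linear THI term, a quadratic THI term, or both. Every candidate
#' includes intercept, sex, contemporary group, farm location and age.
#'
#' @param n_pcs number of PC columns used by the PC-containing designs.
#' @return list of 8 model descriptors (name, `pcs`, `thi`).
#' @export
candidate_models <- function(n_pcs = 10) {
  grid <- expand.grid(thi = c("none", "linear", "quadratic",
                              "linear+quadratic"),
                      pcs = c(FALSE, TRUE), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    list(name = sprintf("%s%s",
                        ifelse(grid$pcs[i], "pcs+", "base+"),
                        grid$thi[i]),
         pcs = grid$pcs[i], n_pcs = n_pcs, thi = grid$thi[i])
  })
}

# Build a full-rank design matrix for one candidate model from an analysis
# table holding sex, contemporary_group, farm_location, age, thi and PC
# columns. Factors enter via treatment contrasts (reference level dropped).
build_design <- function(data, model) {
  terms <- c("~ 1", "factor(sex)", "factor(contemporary_group)",
             "factor(farm_location)", "age")
  if (model$thi %in% c("linear", "linear+quadratic")) terms <- c(terms, "thi")
  if (model$thi %in% c("quadratic", "linear+quadratic"))
    terms <- c(terms, "I(thi^2)")
  if (isTRUE(model$pcs)) {
    pc_cols <- paste0("PC", seq_len(model$n_pcs))
    stopifnot(all(pc_cols %in% names(data)))
    terms <- c(terms, pc_cols)
  }
  f <- stats::as.formula(paste(terms, collapse = " + "))
  X <- stats::model.matrix(f, data = data)
  if (qr(X)$rank < ncol(X)) {
    stop_mrnm("design '%s' is rank deficient", model$name,
              class = "mrnm_rank_error")
  }
  X
}

#' Fixed-effect model selection by AIC
#'
#' Fits each candidate design by ordinary least squares under a Gaussian
#' likelihood and ranks by `AIC = 2k - 2 logL`, with `k` the coefficient
#' count plus one for the residual variance. Ties are broken toward fewer
#' parameters.
#'
#' @param y response vector.
#' @param data analysis table (see [build_design()]).
#' @param models candidate list from [candidate_models()].
#' @return list with `best` (the winning model descriptor, design matrix
#'   attached as `$X`) and `table` (one row per candidate: name, k, logL,
#'   AIC, selected flag).
#' @export
select_by_aic <- function(y, data, models = candidate_models()) {
  rows <- lapply(models, function(m) {
    X <- tryCatch(build_design(data, m), mrnm_rank_error = function(e) NULL)
    if (is.null(X)) {
      return(data.frame(model = m$name, k = NA, logL = NA, AIC = Inf))
    }
    fit <- stats::lm.fit(X, y)
    n <- length(y)
    rss <- sum(fit$residuals^2)
    logL <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
    k <- ncol(X) + 1
    data.frame(model = m$name, k = k, logL = logL, AIC = 2 * k - 2 * logL)
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$AIC, tab$k)
  best_i <- ord[1]
  tab$selected <- seq_len(nrow(tab)) == best_i
  best <- models[[best_i]]
  best$X <- build_design(data, best)
  list(best = best, table = tab)
}

#' Fixed-effect adjustment
#'
#' Residuals of the least-squares projection of `y` on a design matrix;
#' orthogonal to every design column.
#'
#' @param y response vector.
#' @param X full-rank design matrix.
#' @return residual vector.
#' @export
adjust_phenotype <- function(y, X) {
  if (qr(X)$rank < ncol(X)) {
    stop_mrnm("design is rank deficient", class = "mrnm_rank_error")
  }
  stats::lm.fit(X, y)$residuals
}

#' Rank-based inverse normal transform
#'
#' Maps the value with (average, for ties) rank `r` to the standard-normal
#' quantile of `(r - 0.5) / n` (or Blom's `(r - 3/8) / (n + 1/4)`),
#' producing a monotone, approximately standard-normal version of the
#' input used to protect the reaction norm model's normality assumption.
#'
#' @param x numeric vector without missing values.
#' @param method `"mid"` (default, offset 0.5) or `"blom"`.
#' @return transformed vector.
#' @export
rint <- function(x, method = c("mid", "blom")) {
  method <- match.arg(method)
  if (length(x) == 0) stop_mrnm("empty input", class = "mrnm_domain_error")
  if (anyNA(x)) stop_mrnm("missing values not allowed in rint()",
                          class = "mrnm_domain_error")
  r <- rank(x, ties.method = "average")
  n <- length(x)
  u <- switch(method,
              mid = (r - 0.5) / n,
              blom = (r - 3 / 8) / (n + 1 / 4))
  stats::qnorm(u)
}

#' Fixed-effect-adjusted environmental covariate
#'
#' Residualizes the raw covariate (THI) on a design that must exclude any
#' THI terms (PCs, contemporary group, farm location, sex, age), returning
#' the centered residuals. These carry whatever genetic and residual
#' structure the covariate has net of management and structure effects,
#' and serve as the second-trait phenotype of the multivariate reaction
#' norm model.
#'
#' @param raw_thi raw covariate values.
#' @param X full-rank design matrix without THI columns.
#' @return centered residual vector `c_star`.
#' @export
adjust_covariate <- function(raw_thi, X) {
  r <- adjust_phenotype(raw_thi, X)
  r - mean(r)
}
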