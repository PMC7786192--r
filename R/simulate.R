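#' Simulation configuration
#'
#' Collects every parameter of the generative model: the 2 x 2 coefficient
#' covariances `K_g` (genetic intercept/slope) and `K_e` (residual
#' intercept/slope), the cross-covariances of the coefficients with the
#' covariate's genetic (`K_g_beta`) and residual (`K_e_eps`) components,
#' the covariate variances `sigma_beta2` and `sigma_eps2`, and the
#' genotype/population settings. Validates that the implied joint 3 x 3
#' genetic and residual covariances are symmetric positive semi-definite.
#'
#' @param n_individuals,n_snps problem size.
#' @param maf_range interval in (0, 0.5] for ancestral allele frequencies.
#' @param n_subpops,fst optional Balding-Nichols population structure;
#'   `fst` must be 0 when `n_subpops = 1`.
#' @param K_g,K_e 2 x 2 coefficient covariance matrices.
#' @param K_g_beta,K_e_eps length-2 cross-covariances with the covariate
#'   components.
#' @param sigma_beta2,sigma_eps2 covariate genetic / residual variances.
#' @param location_effects per-subpopulation shifts of the raw covariate.
#' @param grand_mean trait grand mean.
#' @param seed integer seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 1000, n_snps = 2000,
                       maf_range = c(0.05, 0.5), n_subpops = 1, fst = 0,
                       K_g = diag(c(0.4, 0)), K_e = diag(c(0.6, 0)),
                       K_g_beta = c(0, 0), K_e_eps = c(0, 0),
                       sigma_beta2 = 0.5, sigma_eps2 = 0.5,
                       location_effects = rep(0, n_subpops),
                       grand_mean = 3, seed = 1) {
  stopifnot(n_individuals >= 1, n_snps >= 1, length(maf_range) == 2,
            length(K_g_beta) == 2, length(K_e_eps) == 2,
            length(location_effects) == n_subpops)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop_mrnm("maf_range must lie within (0, 0.5]",
              class = "mrnm_config_error")
  }
  if (fst < 0 || fst >= 1) {
    stop_mrnm("fst must lie in [0, 1)", class = "mrnm_config_error")
  }
  if (n_subpops == 1 && fst != 0) {
    stop_mrnm("fst must be 0 with a single subpopulation",
              class = "mrnm_config_error")
  }
  cfg <- structure(list(
    n_individuals = n_individuals, n_snps = n_snps, maf_range = maf_range,
    n_subpops = n_subpops, fst = fst,
    K_g = K_g, K_e = K_e, K_g_beta = K_g_beta, K_e_eps = K_e_eps,
    sigma_beta2 = sigma_beta2, sigma_eps2 = sigma_eps2,
    location_effects = location_effects, grand_mean = grand_mean,
    seed = seed), class = "sim_config")
  check_psd(joint_cov(K_g, K_g_beta, sigma_beta2), "joint genetic covariance")
  check_psd(joint_cov(K_e, K_e_eps, sigma_eps2), "joint residual covariance")
  cfg
}

# 3 x 3 joint covariance [[K, k], [k', s2]] of (intercept, slope, env).
joint_cov <- function(K, k, s2) {
  m <- rbind(cbind(K, k), c(k, s2))
  dimnames(m) <- NULL
  (m + t(m)) / 2
}

#' Simulate additive genotypes
#'
#' Draws ancestral allele frequencies uniformly in `maf_range` and
#' genotypes as binomial(2, p) calls. With more than one subpopulation,
#' per-subpopulation frequencies follow the Balding-Nichols beta
#' distribution `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` at the given
#' `fst`, and individuals are split evenly across subpopulations.
#'
#' @param n,m individuals and SNPs.
#' @param maf_range ancestral frequency interval in (0, 0.5].
#' @param n_subpops,fst population structure (see [sim_config()]).
#' @param seed integer seed.
#' @return list with `genotypes` (n x m matrix, dimnames set), `subpop`
#'   (integer labels), `p_anc` and `p_subpop` (the frequencies used).
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.05, 0.5),
                               n_subpops = 1, fst = 0, seed = 1) {
  stopifnot(n >= 1, m >= 1)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop_mrnm("maf_range must lie within (0, 0.5]",
              class = "mrnm_config_error")
  }
  if (fst < 0) stop_mrnm("fst must be non-negative",
                         class = "mrnm_config_error")
  if (n_subpops == 1 && fst != 0) {
    stop_mrnm("fst must be 0 with a single subpopulation",
              class = "mrnm_config_error")
  }
  set.seed(seed)
  p_anc <- stats::runif(m, maf_range[1], maf_range[2])
  subpop <- rep(seq_len(n_subpops), length.out = n)
  subpop <- sort(subpop)
  if (n_subpops > 1 && fst > 0) {
    ratio <- (1 - fst) / fst
    p_subpop <- matrix(stats::rbeta(n_subpops * m,
                                    rep(p_anc, each = n_subpops) * ratio,
                                    rep(1 - p_anc, each = n_subpops) * ratio),
                       nrow = n_subpops)
  } else {
    p_subpop <- matrix(rep(p_anc, each = n_subpops), nrow = n_subpops)
  }
  g <- matrix(stats::rbinom(n * m, 2, p_subpop[subpop, ]), nrow = n)
  dimnames(g) <- list(paste0("id", seq_len(n)), paste0("snp", seq_len(m)))
  list(genotypes = g, subpop = subpop, p_anc = p_anc, p_subpop = p_subpop)
}

#' Simulate correlated random effects
#'
#' Draws the genetic triple `(alpha0, alpha1, beta)` from a zero-mean
#' normal with covariance `G3 (x) A` (Kronecker of the joint 3 x 3 genetic
#' covariance with the GRM) and the residual triple
#' `(tau0, tau1, epsilon)` with covariance `E3 (x) I`, independently. The
#' draw uses an eigendecomposition square root of `A` (with a small
#' diagonal jitter for rank-deficient GRMs), so the finite-sample
#' covariance structure is exact rather than approximated through
#' per-SNP effects.
#'
#' @param A symmetric PSD relationship matrix.
#' @param config `sim_config`.
#' @param seed integer seed.
#' @param jitter diagonal jitter added to `A` before factorization.
#' @return list with vectors `alpha0`, `alpha1`, `beta`, `tau0`, `tau1`,
#'   `eps`.
#' @export
simulate_random_effects <- function(A, config, seed = config$seed,
                                    jitter = 1e-8) {
  n <- nrow(A)
  G3 <- joint_cov(config$K_g, config$K_g_beta, config$sigma_beta2)
  E3 <- joint_cov(config$K_e, config$K_e_eps, config$sigma_eps2)
  check_psd(G3, "joint genetic covariance")
  check_psd(E3, "joint residual covariance")
  set.seed(seed)
  La <- psd_sqrt(A, jitter = jitter)
  Lg <- psd_sqrt(G3)
  Le <- psd_sqrt(E3)
  Zg <- matrix(stats::rnorm(n * 3), n, 3)
  Ze <- matrix(stats::rnorm(n * 3), n, 3)
  Mg <- La %*% Zg %*% t(Lg)   # cov(vec) = G3 (x) A
  Me <- Ze %*% t(Le)          # cov(vec) = E3 (x) I
  list(alpha0 = Mg[, 1], alpha1 = Mg[, 2], beta = Mg[, 3],
       tau0 = Me[, 1], tau1 = Me[, 2], eps = Me[, 3])
}

#' Simulate the environmental covariate
#'
#' Raw covariate = subpopulation location effect + genetic component
#' `beta` + residual component `epsilon`. The standardized covariate `c`
#' is its population z-score; the fixed-effect-adjusted covariate
#' `c_star = beta + epsilon` (location effects removed) plays the
#' second-trait role.
#'
#' @param subpop integer subpopulation labels.
#' @param location_effects per-subpopulation shift.
#' @param beta,eps covariate components from [simulate_random_effects()].
#' @return list with `raw_thi`, `c`, `c_star`.
#' @export
simulate_thi <- function(subpop, location_effects, beta, eps) {
  stopifnot(length(beta) == length(eps), length(subpop) == length(beta),
            max(subpop) <= length(location_effects))
  raw <- location_effects[subpop] + beta + eps
  list(raw_thi = raw, c = standardize_covariate(raw), c_star = beta + eps)
}

#' Simulate trait phenotypes
#'
#' `y_i = mu + alpha0_i + alpha1_i c_i + tau0_i + tau1_i c_i`, exactly:
#' the zero/first-order random-regression decomposition with
#' heterogeneous residuals.
#'
#' @param config `sim_config` (supplies the grand mean).
#' @param truth component list from [simulate_random_effects()].
#' @param c standardized covariate.
#' @return phenotype vector.
#' @export
simulate_phenotype <- function(config, truth, c) {
  stopifnot(length(truth$alpha0) == length(c))
  config$grand_mean + truth$alpha0 + truth$alpha1 * c +
    truth$tau0 + truth$tau1 * c
}

#' Preset simulation scenarios
#'
#' End-to-end generator for the study designs used in testing:
#' \describe{
#'   \item{null}{no interaction variance, no covariate cross-covariance.}
#'   \item{gxe}{genetic slope variance on (`K_g` full 2 x 2).}
#'   \item{rxe}{residual slope variance on (`K_e` full 2 x 2).}
#'   \item{combined}{both interactions on.}
#'   \item{corr_only}{no interaction variance but a genetic correlation of
#'     0.3 between the trait intercept and the covariate's genetic
#'     component — the confounding design in which unmodeled correlation
#'     produces spurious interaction signals.}
#' }
#' Genotypes are simulated, monomorphic SNPs dropped, the GRM built via
#' [standardize_genotypes()] and [compute_grm()], and effects, covariate
#' and phenotypes drawn under the configured covariances.
#'
#' @param name scenario name.
#' @param n,m individuals and SNPs.
#' @param seed integer seed.
#' @param config optional `sim_config` overriding the preset (advanced).
#' @return object of class `mrnm_sim`: list with `genotypes`, `A`, `subpop`,
#'   `raw_thi`, `c`, `c_star`, `y`, `truth` (realized effect vectors plus
#'   the `sim_config`).
#' @export
scenario <- function(name = c("null", "gxe", "rxe", "combined", "corr_only",
                              "corr_strat"),
                     n = 1000, m = 2000, seed = 1, config = NULL) {
  name <- match.arg(name)
  if (is.null(config)) {
    Kg_int <- diag(c(0.4, 0)); Ke_int <- diag(c(0.6, 0))
    Kg_full <- matrix(c(0.4, 0.1, 0.1, 0.2), 2)
    Ke_full <- matrix(c(0.5, -0.05, -0.05, 0.15), 2)
    config <- switch(name,
      null = sim_config(n, m, seed = seed),
      gxe = sim_config(n, m, K_g = Kg_full, K_e = Ke_int, seed = seed),
      rxe = sim_config(n, m, K_g = Kg_int, K_e = Ke_full, seed = seed),
      combined = sim_config(n, m, K_g = Kg_full, K_e = Ke_full, seed = seed),
      corr_only = sim_config(n, m,
                             K_g_beta = c(0.3 * sqrt(0.4 * 0.5), 0),
                             seed = seed),
      corr_strat = sim_config(n, m,
                              K_g_beta = c(0.3 * sqrt(0.4 * 0.5), 0),
                              n_subpops = 2, fst = 0.1,
                              location_effects = c(1, -1), seed = seed))
  }
  gsim <- simulate_genotypes(config$n_individuals, config$n_snps,
                             config$maf_range, config$n_subpops,
                             config$fst, seed = config$seed)
  g <- gsim$genotypes
  poly <- apply(g, 2, function(x) length(unique(x)) > 1)
  g <- g[, poly, drop = FALSE]
  A <- compute_grm(standardize_genotypes(g))
  truth <- simulate_random_effects(A, config, seed = config$seed + 1L)
  thi <- simulate_thi(gsim$subpop, config$location_effects,
                      truth$beta, truth$eps)
  y <- simulate_phenotype(config, truth, thi$c)
  truth$config <- config
  structure(list(genotypes = g, A = A, subpop = gsim$subpop,
                 raw_thi = thi$raw_thi, c = thi$c, c_star = thi$c_star,
                 y = y, truth = truth, scenario = name),
            class = "mrnm_sim")
}

#' @export
print.mrnm_sim <- function(x, ...) {
  cat(sprintf("Synthetic dataset: scenario '%s', n = %d, m = %d SNPs\n",
              x$scenario, length(x$y), ncol(x$genotypes)))
  invisible(x)
}

#' Write a synthetic dataset as plain-text tables
#'
#' Genotypes in the additive-export dialect, phenotype/covariate and truth
#' components as named-column TSV.
#'
#' @param sim `mrnm_sim` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genotypes = file.path(dir, "genotypes.tsv"),
    phen = file.path(dir, "phenotypes.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_plink_additive(sim$genotypes, paths[["genotypes"]])
  utils::write.table(
    data.frame(animal_id = rownames(sim$genotypes), y = sim$y,
               raw_thi = sim$raw_thi, c = sim$c, c_star = sim$c_star,
               subpop = sim$subpop),
    paths[["phen"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(animal_id = rownames(sim$genotypes),
               alpha0 = sim$truth$alpha0, alpha1 = sim$truth$alpha1,
               beta = sim$truth$beta, tau0 = sim$truth$tau0,
               tau1 = sim$truth$tau1, eps = sim$truth$eps),
    paths[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
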