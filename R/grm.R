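#' SNP and sample quality control
#'
#' Filters a genotype matrix the way a standard GWAS pipeline does before
#' building a genomic relationship matrix: animals with excessive
#' missingness are removed first, then SNPs failing missingness, minor
#' allele frequency or Hardy-Weinberg equilibrium thresholds, in a single
#' pass. Optionally removes sex-chromosome SNPs when an annotation is
#' supplied.
#'
#' @param geno n x m matrix of additive genotype calls in `{0, 1, 2, NA}`
#'   with animal ids as rownames and SNP ids as colnames.
#' @param maf_min SNPs with minor allele frequency below this are removed.
#' @param snp_missing_max SNPs with missingness above this are removed.
#' @param hwe_p_min SNPs with a Hardy-Weinberg test p-value below this are
#'   removed (1-df chi-square on observed vs expected genotype counts by
#'   default; `hwe_test = "exact"` uses the exact conditional test).
#' @param indiv_missing_max animals with missingness above this are removed.
#' @param hwe_test `"chisq"` (default) or `"exact"`.
#' @param snp_chr optional character vector (length m) of chromosome labels.
#' @param exclude_chr chromosome labels to drop when `snp_chr` is given.
#' @return list with `genotypes` (the filtered matrix) and `report`, a
#'   `qc_report` recording thresholds and per-filter removal counts.
#' @export
qc_genotypes <- function(geno, maf_min = 0.01, snp_missing_max = 0.10,
                         hwe_p_min = 1e-4, indiv_missing_max = 0.10,
                         hwe_test = c("chisq", "exact"),
                         snp_chr = NULL, exclude_chr = c("X", "Y")) {
  hwe_test <- match.arg(hwe_test)
  stopifnot(is.matrix(geno),
            all(c(maf_min, snp_missing_max, hwe_p_min, indiv_missing_max) >= 0),
            all(c(maf_min, snp_missing_max, hwe_p_min, indiv_missing_max) <= 1))
  n0 <- nrow(geno); m0 <- ncol(geno)

  n_sex <- 0L
  if (!is.null(snp_chr)) {
    stopifnot(length(snp_chr) == ncol(geno))
    keep <- !(snp_chr %in% exclude_chr)
    n_sex <- sum(!keep)
    geno <- geno[, keep, drop = FALSE]
  }

  indiv_miss <- rowMeans(is.na(geno))
  keep_ind <- indiv_miss <= indiv_missing_max
  geno <- geno[keep_ind, , drop = FALSE]

  snp_miss <- colMeans(is.na(geno))
  p <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  hwe_p <- apply(geno, 2, hwe_pvalue, test = hwe_test)
  drop_miss <- snp_miss > snp_missing_max
  drop_maf <- !is.finite(maf) | maf < maf_min
  drop_hwe <- is.finite(hwe_p) & hwe_p < hwe_p_min
  keep_snp <- !(drop_miss | drop_maf | drop_hwe)
  geno <- geno[, keep_snp, drop = FALSE]

  if (ncol(geno) == 0) {
    stop_mrnm("all SNPs removed by quality control", class = "mrnm_empty_panel_error")
  }

  report <- structure(list(
    thresholds = list(maf_min = maf_min, snp_missing_max = snp_missing_max,
                      hwe_p_min = hwe_p_min,
                      indiv_missing_max = indiv_missing_max,
                      hwe_test = hwe_test),
    n_animals_in = n0, n_snps_in = m0,
    removed = list(sex_chromosome = n_sex,
                   animal_missingness = sum(!keep_ind),
                   snp_missingness = sum(drop_miss & !drop_maf),
                   snp_maf = sum(drop_maf),
                   snp_hwe = sum(drop_hwe & !drop_maf & !drop_miss)),
    n_animals_out = nrow(geno), n_snps_out = ncol(geno)
  ), class = "qc_report")
  list(genotypes = geno, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Genotype QC report\n")
  cat(sprintf("  animals: %d -> %d   SNPs: %d -> %d\n",
              x$n_animals_in, x$n_animals_out, x$n_snps_in, x$n_snps_out))
  for (nm in names(x$removed))
    cat(sprintf("  removed by %s: %d\n", gsub("_", " ", nm), x$removed[[nm]]))
  invisible(x)
}

# Hardy-Weinberg equilibrium p-value for one SNP.
# chisq: 1-df goodness of fit of observed genotype counts against
# expectations at the observed allele frequency. exact: conditional
# (Levene-Haldane) test summing probabilities of tables as or less
# probable than the observed heterozygote count.
hwe_pvalue <- function(calls, test = "chisq") {
  calls <- calls[!is.na(calls)]
  n <- length(calls)
  if (n == 0) return(NA_real_)
  n2 <- sum(calls == 2); n1 <- sum(calls == 1); n0 <- n - n1 - n2
  p <- (2 * n2 + n1) / (2 * n)
  if (p == 0 || p == 1) return(1)
  if (test == "chisq") {
    expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    stat <- sum((c(n0, n1, n2) - expd)^2 / expd)
    return(stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }
  # exact test on heterozygote count given allele counts
  nA <- 2 * n2 + n1  # minor or major, symmetric
  nB <- 2 * n - nA
  n_rare <- min(nA, nB)
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  logp <- vapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(h + 1) - lgamma(hom_c + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
  obs <- match(n1, hets)
  sum(pr[pr <= pr[obs] + 1e-12])
}

#' Column-standardize a genotype matrix
#'
#' Imputes missing calls with the SNP mean, then centers each column and
#' divides by its population (divide-by-n) standard deviation. Under this
#' convention the GRM `W W' / m` has mean diagonal exactly 1.
#'
#' @param geno QC-passing genotype matrix in `{0, 1, 2, NA}`.
#' @return standardized n x m numeric matrix `W`.
#' @export
standardize_genotypes <- function(geno) {
  W <- geno
  if (anyNA(W)) {
    mu <- colMeans(W, na.rm = TRUE)
    idx <- which(is.na(W), arr.ind = TRUE)
    W[idx] <- mu[idx[, 2]]
  }
  mu <- colMeans(W)
  sd_pop <- sqrt(colMeans(W^2) - mu^2)
  if (any(sd_pop == 0)) {
    stop_mrnm("zero-variance SNP column(s) present; monomorphic SNPs must be removed by QC before standardization",
              class = "mrnm_internal_invariant_error")
  }
  sweep(sweep(W, 2, mu, "-"), 2, sd_pop, "/")
}

#' Genomic relationship matrix
#'
#' `A = W W' / m` from a column-standardized genotype matrix `W` with `m`
#' SNPs. With population-sd standardization the mean diagonal equals 1
#' exactly.
#'
#' @param W standardized genotype matrix from [standardize_genotypes()].
#' @return symmetric n x n matrix with animal ids as dimnames and the SNP
#'   count in attribute `n_snps`.
#' @export
compute_grm <- function(W) {
  A <- tcrossprod(W) / ncol(W)
  A <- (A + t(A)) / 2
  attr(A, "n_snps") <- ncol(W)
  A
}

#' Principal components of a GRM
#'
#' Eigenvectors of `A` for the `k` largest eigenvalues, scaled by the
#' square root of the eigenvalue, with a deterministic sign convention
#' (largest-magnitude loading positive). Zero-eigenvalue components are
#' dropped with a warning when `k` exceeds the numerical rank.
#'
#' @param A GRM from [compute_grm()].
#' @param k number of components (default 10).
#' @param tol eigenvalues below `tol * max(eigenvalue)` count as zero.
#' @return n x k (or fewer) matrix of PC scores.
#' @export
grm_pcs <- function(A, k = 10, tol = 1e-10) {
  stopifnot(k >= 1, k <= nrow(A))
  ed <- eigen(A, symmetric = TRUE)
  pos <- ed$values > tol * max(ed$values, 0)
  if (sum(pos) < k) {
    warning(sprintf("requested %d PCs but GRM rank is %d; dropping zero-eigenvalue PCs",
                    k, sum(pos)))
    k <- sum(pos)
  }
  scores <- ed$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  scores <- sweep(scores, 2, sqrt(ed$values[seq_len(k)]), "*")
  rownames(scores) <- rownames(A)
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

#' Read / write genotypes in the additive-export text dialect
#'
#' Tab-separated text with a header row naming the SNPs; each subsequent
#' row is an animal id followed by its `{0, 1, 2, NA}` calls.
#'
#' @param geno genotype matrix with dimnames.
#' @param path file path.
#' @return `read_plink_additive` returns the genotype matrix.
#' @export
write_plink_additive <- function(geno, path) {
  df <- data.frame(animal_id = rownames(geno), geno, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plink_additive
#' @export
read_plink_additive <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(animal_id = "character"))
  g <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(g) <- "double"
  rownames(g) <- df$animal_id
  g
}

#' Read / write a GRM in the GCTA text dialect
#'
#' `<prefix>.grm` holds one row per lower-triangle element: 1-based
#' indices `i`, `j <= i`, the SNP count, and `A[i, j]` to six decimals;
#' `<prefix>.grm.id` holds family and individual ids (family id written as
#' the individual id).
#'
#' @param A GRM matrix with animal ids as dimnames.
#' @param prefix path prefix for the two files.
#' @param n_snps SNP count recorded per element; defaults to the
#'   `n_snps` attribute of `A` (or `NA`).
#' @return `read_grm` returns the GRM matrix with attribute `n_snps`.
#' @export
write_grm <- function(A, prefix, n_snps = NULL) {
  n_snps <- n_snps %||% attr(A, "n_snps") %||% NA_integer_
  n <- nrow(A)
  ij <- which(lower.tri(A, diag = TRUE), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  tab <- data.frame(i = ij[, 1], j = ij[, 2], n_snps = n_snps,
                    a = sprintf("%.6f", A[ij]))
  utils::write.table(tab, paste0(prefix, ".grm"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ids <- rownames(A) %||% as.character(seq_len(n))
  utils::write.table(data.frame(fid = ids, iid = ids),
                     paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_grm
#' @export
read_grm <- function(prefix) {
  tab <- utils::read.table(paste0(prefix, ".grm"),
                           col.names = c("i", "j", "n_snps", "a"))
  ids <- utils::read.table(paste0(prefix, ".grm.id"),
                           colClasses = "character")[[2]]
  n <- max(tab$i)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  A[cbind(tab$i, tab$j)] <- tab$a
  A[cbind(tab$j, tab$i)] <- tab$a
  attr(A, "n_snps") <- tab$n_snps[1]
  A
}
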