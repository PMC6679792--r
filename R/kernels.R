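#' Subject-similarity kernels for trajectory coupling
#'
#' These functions build the n x n positive (semi-)definite matrices used to
#' couple subjects' trajectory parameters through the covariance prior. All
#' return an object of class `coupling_kernel`: a list with `matrix`,
#' `family`, and `width_required` (whether the family carries a tunable
#' width sigma that is optimized as a covariance hyperparameter).
#'
#' @name coupling-kernels
NULL

new_kernel <- function(K, family, width_required) {
  K <- (K + t(K)) / 2   # exact symmetry against floating-point drift
  structure(list(matrix = K, family = family,
                 width_required = width_required),
            class = "coupling_kernel")
}

#' @export
print.coupling_kernel <- function(x, ...) {
  cat("Coupling kernel (", x$family, "), ", nrow(x$matrix), " x ",
      ncol(x$matrix),
      if (x$width_required) ", tunable width" else "", "\n", sep = "")
  invisible(x)
}

#' @describeIn coupling-kernels Rank-one linear kernel, the outer product
#'   `b %o% b` of a biomarker vector with itself.
#' @param b Numeric biomarker vector, one value per subject in subject order.
#' @export
linear_kernel <- function(b) {
  b <- as.numeric(b)
  if (anyNA(b)) stop("biomarker vector contains missing values; subjects lacking the covariate must be handled explicitly")
  new_kernel(tcrossprod(b), "linear", width_required = FALSE)
}

#' @describeIn coupling-kernels Squared-exponential (Gaussian RBF) kernel
#'   with entries `exp(-sigma * (b_i - b_j)^2)`; unit diagonal.
#' @param sigma Positive kernel width multiplier on the squared distance.
#' @export
se_kernel <- function(b, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    stop("sigma must be a positive scalar")
  }
  b <- as.numeric(b)
  if (anyNA(b)) stop("biomarker vector contains missing values; subjects lacking the covariate must be handled explicitly")
  D <- outer(b, b, `-`)^2
  new_kernel(exp(-sigma * D), "se", width_required = TRUE)
}

#' @describeIn coupling-kernels Binary group-membership kernel: 1 when two
#'   subjects share a label, 0 otherwise.
#' @param labels Vector of categorical group labels, one per subject.
#' @export
binary_group_kernel <- function(labels) {
  labels <- as.character(labels)
  if (anyNA(labels)) stop("labels contain missing values")
  new_kernel(outer(labels, labels, `==`) * 1, "binary",
             width_required = FALSE)
}

#' Genotype table for identity-by-state kernels
#'
#' @param n_e2,n_e4 Integer allele counts (0, 1 or 2) of the APOE
#'   epsilon-2 and epsilon-4 alleles, one per subject.
#' @param maf_e2,maf_e4 Minor allele frequencies in (0, 0.5] used for the
#'   inverse-MAF weights. By default computed from the supplied cohort with
#'   a floor of 0.01.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(n_e2, n_e4, maf_e2 = NULL, maf_e4 = NULL) {
  n_e2 <- as.integer(n_e2); n_e4 <- as.integer(n_e4)
  if (length(n_e2) != length(n_e4)) stop("allele-count vectors differ in length")
  if (anyNA(n_e2) || anyNA(n_e4) || any(!(n_e2 %in% 0:2)) ||
      any(!(n_e4 %in% 0:2))) {
    stop("allele counts must be integers in {0, 1, 2} with no missing values")
  }
  cohort_maf <- function(g) max(0.01, min(mean(g) / 2, 1 - mean(g) / 2))
  if (is.null(maf_e2)) maf_e2 <- cohort_maf(n_e2)
  if (is.null(maf_e4)) maf_e4 <- cohort_maf(n_e4)
  if (maf_e2 <= 0 || maf_e4 <= 0) stop("minor allele frequencies must be positive")
  structure(list(n_e2 = n_e2, n_e4 = n_e4,
                 maf_e2 = maf_e2, maf_e4 = maf_e4),
            class = "genotype_table")
}

## IBS count between allele counts at one biallelic locus: 2 - |g_i - g_j|
ibs_counts <- function(g) 2 - abs(outer(g, g, `-`))

#' @describeIn coupling-kernels Weighted identity-by-state kernel over the two
#'   APOE loci, `(w_e2 IBS_e2 + w_e4 IBS_e4) / (w_e2 + w_e4)` with inverse-MAF
#'   weights; entries in `[0, 2]`, equal to 2 for identical genotypes.
#' @param g A [genotype_table].
#' @export
ibs_kernel <- function(g) {
  stopifnot(inherits(g, "genotype_table"))
  w2 <- 1 / g$maf_e2
  w4 <- 1 / g$maf_e4
  K <- (w2 * ibs_counts(g$n_e2) + w4 * ibs_counts(g$n_e4)) / (w2 + w4)
  new_kernel(K, "ibs", width_required = FALSE)
}

#' @describeIn coupling-kernels Exponentiated IBS kernel,
#'   `exp(-sigma * (2 - k_IBS))`; entries in `(0, 1]`, exactly 1 for
#'   identical genotypes, directly comparable to the squared-exponential
#'   kernels.
#' @export
exp_ibs_kernel <- function(g, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    stop("sigma must be a positive scalar")
  }
  K0 <- ibs_kernel(g)$matrix
  new_kernel(exp(-sigma * (2 - K0)), "exp_ibs", width_required = TRUE)
}

#' @describeIn coupling-kernels Random-information control kernel: draws an
#'   n-vector of standard normals and returns its squared-exponential kernel
#'   together with the drawn vector. Reproducible under a fixed seed.
#' @param n Number of subjects.
#' @param seed Integer RNG seed.
#' @export
random_kernel <- function(n, sigma, seed) {
  stopifnot(n >= 1)
  r <- withr_seed(seed, stats::rnorm(n))
  K <- se_kernel(r, sigma)
  K$family <- "random_se"
  list(kernel = K, vector = r)
}

## Evaluate an expression under a temporary RNG seed, restoring state after.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Validate positive semi-definiteness of a kernel
#'
#' Symmetrizes the matrix and checks that the minimum eigenvalue is at least
#' `-jitter`; errors naming the offending eigenvalue otherwise. Coupling
#' matrices enter the covariance prior additively, so anything indefinite
#' would break the Cholesky factorizations downstream.
#'
#' @param K A `coupling_kernel` or plain symmetric matrix.
#' @param jitter Tolerated negative eigenvalue magnitude (default `1e-8`
#'   times the mean diagonal).
#' @return The validated (symmetrized) kernel, invisibly classed as before.
#' @export
validate_psd <- function(K, jitter = NULL) {
  is_kernel <- inherits(K, "coupling_kernel")
  M <- if (is_kernel) K$matrix else as.matrix(K)
  if (max(abs(M - t(M))) > 1e-8) stop("kernel matrix is not symmetric")
  M <- (M + t(M)) / 2
  if (is.null(jitter)) jitter <- 1e-8 * max(mean(diag(M)), 1)
  ev_min <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -jitter) {
    stop("kernel is not positive semi-definite: minimum eigenvalue ",
         format(ev_min), " below tolerance ", format(-jitter))
  }
  if (is_kernel) { K$matrix <- M; K } else M
}

#' Write / read a labeled kernel matrix as TSV
#'
#' Plain-text round trip for inspection and debugging.
#'
#' @param K A `coupling_kernel`.
#' @param path Output TSV path.
#' @param subject_ids Row/column labels.
#' @export
write_kernel_tsv <- function(K, path, subject_ids = NULL) {
  M <- if (inherits(K, "coupling_kernel")) K$matrix else as.matrix(K)
  if (is.null(subject_ids)) subject_ids <- paste0("s", seq_len(nrow(M)))
  dimnames(M) <- list(subject_ids, subject_ids)
  utils::write.table(M, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
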