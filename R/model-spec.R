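#' Declarative model specification
#'
#' A `model_spec` names which coupling terms each parameter block of the
#' covariance prior receives. For a polynomial of order p there are
#' d = p + 1 blocks (intercepts, slopes, ...); each block can carry an
#' independent (ridge) term, a fully-shared (all-ones) term, and any number
#' of named subject-similarity kernels. A global ridge term is always
#' present except in the uncoupled OLS baseline.
#'
#' @param name Model label.
#' @param order Polynomial order (default 1: linear trajectories).
#' @param blocks List of length `order + 1`; each element a list with logical
#'   `independent`, logical `shared`, and character `kernels` (possibly
#'   empty) naming entries of `kernels`.
#' @param kernels Named list; each element a list with `family` (one of
#'   `"linear"`, `"se"`, `"binary"`, `"ibs"`, `"exp_ibs"`, `"random_se"`) and
#'   `covariate`, the name of the covariate vector (or genotype table) the
#'   kernel is built from.
#' @param ols Logical; `TRUE` marks the uncoupled per-subject least-squares
#'   baseline (the infinite-ridge limit of the prior), which carries no
#'   covariance hyperparameters.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name, order = 1, blocks = NULL, kernels = list(),
                       ols = FALSE) {
  d <- as.integer(order) + 1L
  if (ols) {
    return(structure(list(name = name, order = as.integer(order),
                          d = d, blocks = list(), kernels = list(),
                          ols = TRUE),
                     class = "model_spec"))
  }
  if (is.null(blocks)) {
    blocks <- replicate(d, list(independent = TRUE, shared = TRUE,
                                kernels = character(0)),
                        simplify = FALSE)
  }
  if (length(blocks) != d) stop("need one block specification per parameter (", d, ")")
  blocks <- lapply(blocks, function(b) {
    b$kernels <- as.character(b$kernels %||% character(0))
    unknown <- setdiff(b$kernels, names(kernels))
    if (length(unknown) > 0) {
      stop("block references unregistered kernel(s): ",
           paste(unknown, collapse = ", "))
    }
    list(independent = isTRUE(b$independent), shared = isTRUE(b$shared),
         kernels = b$kernels)
  })
  families <- c("linear", "se", "binary", "ibs", "exp_ibs", "random_se")
  for (k in names(kernels)) {
    if (!kernels[[k]]$family %in% families) {
      stop("unknown kernel family '", kernels[[k]]$family, "'")
    }
  }
  structure(list(name = name, order = as.integer(order), d = d,
                 blocks = blocks, kernels = kernels, ols = FALSE),
            class = "model_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

width_bearing <- function(family) family %in% c("se", "exp_ibs", "random_se")

#' @export
print.model_spec <- function(x, ...) {
  cat("Model spec '", x$name, "' (order ", x$order, ")\n", sep = "")
  if (x$ols) {
    cat("  uncoupled OLS baseline (no covariance hyperparameters)\n")
    return(invisible(x))
  }
  for (i in seq_along(x$blocks)) {
    b <- x$blocks[[i]]
    cat("  block ", i, ": ",
        paste(c(if (b$independent) "independent", if (b$shared) "shared",
                b$kernels), collapse = " + "), "\n", sep = "")
  }
  cat("  covariance hyperparameters:", count_hyperparameters(x), "\n")
  invisible(x)
}

#' Hyperparameter layout of a model specification
#'
#' Returns the ordered names of the flat log-domain hyperparameter vector:
#' the global ridge weight, per-block coupling weights (independent, shared,
#' one per kernel), per (block, width-bearing kernel) widths, and finally
#' the noise precision `log_beta`.
#'
#' @param spec A [model_spec].
#' @return Character vector of parameter names.
#' @export
hyper_layout <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$ols) return("log_beta")
  nm <- "log_alpha1"
  for (i in seq_along(spec$blocks)) {
    b <- spec$blocks[[i]]
    if (b$independent) nm <- c(nm, sprintf("log_alpha_%d_indep", i))
    if (b$shared) nm <- c(nm, sprintf("log_alpha_%d_shared", i))
    for (k in b$kernels) nm <- c(nm, sprintf("log_alpha_%d_%s", i, k))
  }
  for (i in seq_along(spec$blocks)) {
    for (k in spec$blocks[[i]]$kernels) {
      if (width_bearing(spec$kernels[[k]]$family)) {
        nm <- c(nm, sprintf("log_sigma_%d_%s", i, k))
      }
    }
  }
  c(nm, "log_beta")
}

#' Number of covariance-prior hyperparameters
#'
#' Counts the global ridge weight plus every per-block coupling weight and
#' kernel width; the noise precision beta is a likelihood hyperparameter and
#' is excluded. The uncoupled OLS baseline has none.
#'
#' @param spec A [model_spec].
#' @return Integer count.
#' @examples
#' count_hyperparameters(model_registry()[["plain"]])  # 5
#' @export
count_hyperparameters <- function(spec) {
  length(hyper_layout(spec)) - 1L
}

#' Pack / unpack hyperparameter vectors
#'
#' Hyperparameters live in the log domain so that exponentiation yields
#' strictly positive coupling weights, kernel widths and noise precision.
#' `pack_hyper` strips a named hyperparameter vector to a flat numeric
#' vector; `unpack_hyper` restores the names from the spec's layout. The two
#' are a bijection for a given spec.
#'
#' @param h Named numeric log-domain hyperparameter vector.
#' @param x Flat numeric vector of length `count_hyperparameters(spec) + 1`.
#' @param spec A [model_spec].
#' @return `pack_hyper`: unnamed numeric vector. `unpack_hyper`: named
#'   numeric vector following [hyper_layout].
#' @export
pack_hyper <- function(h, spec) {
  layout <- hyper_layout(spec)
  if (!identical(names(h), layout)) h <- h[layout]
  if (anyNA(h)) stop("hyperparameter vector does not match the spec layout")
  unname(as.numeric(h))
}

#' @rdname pack_hyper
#' @export
unpack_hyper <- function(x, spec) {
  layout <- hyper_layout(spec)
  if (length(x) != length(layout)) {
    stop("expected ", length(layout), " hyperparameters, got ", length(x))
  }
  stats::setNames(as.numeric(x), layout)
}

#' Default (log-domain zero) hyperparameter vector
#'
#' All multiplicative hyperparameters equal 1.
#'
#' @param spec A [model_spec].
#' @export
hyper_init <- function(spec) {
  unpack_hyper(rep(0, length(hyper_layout(spec))), spec)
}

#' Intra-subject indicator matrix
#'
#' The d x d matrix with a single 1 at diagonal position `i`, used in the
#' Kronecker construction of the prior so that inter-subject coupling is
#' learned separately for each parameter type (no sharing between, e.g.,
#' intercepts and slopes).
#'
#' @param i Parameter index in `1..d`.
#' @param d Number of trajectory parameters per subject.
#' @return A d x d numeric matrix.
#' @export
indicator_matrix <- function(i, d) {
  i <- as.integer(i); d <- as.integer(d)
  if (i < 1 || i > d) stop("parameter index out of range 1..", d)
  M <- matrix(0, d, d)
  M[i, i] <- 1
  M
}

## Realize one kernel definition as an n x n matrix given covariates and,
## for width-bearing families, the current width sigma.
realize_kernel <- function(kdef, covariates, sigma = NULL) {
  cov_name <- kdef$covariate
  if (!cov_name %in% names(covariates)) {
    stop("covariate '", cov_name, "' required by a kernel is missing")
  }
  cv <- covariates[[cov_name]]
  switch(kdef$family,
    linear = linear_kernel(cv),
    se = se_kernel(cv, sigma),
    random_se = { k <- se_kernel(cv, sigma); k$family <- "random_se"; k },
    binary = binary_group_kernel(cv),
    ibs = ibs_kernel(cv),
    exp_ibs = exp_ibs_kernel(cv, sigma),
    stop("unknown kernel family '", kdef$family, "'"))
}

#' Assemble the structured parameter-covariance prior
#'
#' Builds the nd x nd prior covariance
#' \deqn{\Sigma_{prior} = \alpha_1 I_{nd} + \sum_{i=1}^{d} \Sigma_{ci} \otimes M_{ii},
#'   \quad \Sigma_{ci} = \alpha_{i1} I_n + \alpha_{i2} 1_n + \sum_j \alpha_{ij+2} K_j}
#' in subject-major parameter ordering (subject i's d coefficients are
#' contiguous, matching the block-diagonal design). Width-bearing kernels
#' are (re)built from the widths stored in `h`.
#'
#' @param h Named log-domain hyperparameter vector (see [hyper_layout]).
#' @param spec A [model_spec].
#' @param covariates Named list of coupling covariates (numeric vectors of
#'   length n, label vectors, or [genotype_table]s) referenced by the spec's
#'   kernels.
#' @param n Number of subjects.
#' @return Symmetric nd x nd numeric matrix, positive definite for positive
#'   hyperparameters.
#' @export
assemble_prior <- function(h, spec, covariates = list(), n) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$ols) stop("the OLS baseline has no covariance prior (alpha1 -> infinity limit)")
  d <- spec$d
  a <- exp(h)
  Sigma <- diag(a[["log_alpha1"]], n * d)
  ones <- matrix(1, n, n)
  for (i in seq_len(d)) {
    b <- spec$blocks[[i]]
    Sci <- matrix(0, n, n)
    if (b$independent) {
      Sci <- Sci + diag(a[[sprintf("log_alpha_%d_indep", i)]], n)
    }
    if (b$shared) Sci <- Sci + a[[sprintf("log_alpha_%d_shared", i)]] * ones
    for (k in b$kernels) {
      kdef <- spec$kernels[[k]]
      sigma <- if (width_bearing(kdef$family)) {
        a[[sprintf("log_sigma_%d_%s", i, k)]]
      }
      K <- realize_kernel(kdef, covariates, sigma)$matrix
      if (nrow(K) != n) stop("kernel '", k, "' has dimension ", nrow(K),
                             ", expected ", n)
      Sci <- Sci + a[[sprintf("log_alpha_%d_%s", i, k)]] * K
    }
    Sigma <- Sigma + kronecker(Sci, indicator_matrix(i, d))
  }
  (Sigma + t(Sigma)) / 2
}

#' Registry of model configurations
#'
#' Returns the named set of linear-trajectory model specifications used in
#' the simulation study and the multi-biomarker application: kernel-coupled
#' variants over both or single parameter blocks, the `plain` mixed
#' independent/shared model, the `random`-information control, the
#' four-kernel `multiple` model, single-biomarker squared-exponential models,
#' the genotype-similarity `apoe` model, and the uncoupled `ols` baseline.
#'
#' Simulation models reference a biomarker covariate `b` (and `r` for the
#' random control); the application-style models reference `suvr`,
#' `log_tau_abeta`, `ptau`, `genotype` and `r`.
#'
#' @return Named list of [model_spec] objects.
#' @export
model_registry <- function() {
  blk <- function(kernels = character(0)) {
    list(independent = TRUE, shared = TRUE, kernels = kernels)
  }
  kern <- function(family, covariate) list(family = family, covariate = covariate)
  b_se <- list(b = kern("se", "b"))
  b_lin <- list(b = kern("linear", "b"))
  r_se <- list(r = kern("random_se", "r"))
  adni_kernels <- list(suvr = kern("se", "suvr"),
                       tau_abeta = kern("se", "log_tau_abeta"),
                       ptau = kern("se", "ptau"),
                       apoe = kern("exp_ibs", "genotype"))
  list(
    random = model_spec("random", blocks = list(blk("r"), blk("r")),
                        kernels = r_se),
    linear_both = model_spec("linear_both", blocks = list(blk("b"), blk("b")),
                             kernels = b_lin),
    gaussian_both = model_spec("gaussian_both",
                               blocks = list(blk("b"), blk("b")),
                               kernels = b_se),
    linear_int = model_spec("linear_int", blocks = list(blk("b"), blk()),
                            kernels = b_lin),
    gaussian_int = model_spec("gaussian_int", blocks = list(blk("b"), blk()),
                              kernels = b_se),
    linear_slope = model_spec("linear_slope", blocks = list(blk(), blk("b")),
                              kernels = b_lin),
    gaussian_slope = model_spec("gaussian_slope",
                                blocks = list(blk(), blk("b")),
                                kernels = b_se),
    plain = model_spec("plain", blocks = list(blk(), blk())),
    ols = model_spec("ols", ols = TRUE),
    multiple = model_spec("multiple",
                          blocks = list(blk(names(adni_kernels)),
                                        blk(names(adni_kernels))),
                          kernels = adni_kernels),
    pet_amyloid = model_spec("pet_amyloid",
                             blocks = list(blk("suvr"), blk("suvr")),
                             kernels = adni_kernels["suvr"]),
    csf_tau_abeta = model_spec("csf_tau_abeta",
                               blocks = list(blk("tau_abeta"), blk("tau_abeta")),
                               kernels = adni_kernels["tau_abeta"]),
    csf_ptau = model_spec("csf_ptau",
                          blocks = list(blk("ptau"), blk("ptau")),
                          kernels = adni_kernels["ptau"]),
    apoe = model_spec("apoe", blocks = list(blk("apoe"), blk("apoe")),
                      kernels = adni_kernels["apoe"])
  )
}
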