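#' Multi-subject longitudinal trajectory data
#'
#' Bundles long-format longitudinal observations (one biomarker value per
#' subject per visit) into the object all model fitting consumes. Subject
#' order is fixed at construction and shared by every derived matrix and
#' kernel.
#'
#' @param data A data.frame with columns `subject_id`, `time` and `value`
#'   (further columns are ignored). Times are in the study's units, e.g.
#'   years of age.
#' @return An object of class `trajectory_data` with elements
#'   `subject_ids` (character, unique, in order of first appearance),
#'   `times` / `values` (named lists of per-subject numeric vectors, times
#'   strictly increasing within subject), `n` (number of subjects) and
#'   `m` (total number of observations).
#' @examples
#' d <- data.frame(subject_id = c("a", "a", "b"), time = c(0, 1, 2),
#'                 value = c(5, 4, 3))
#' td <- trajectory_data(d)
#' td$n
#' @export
trajectory_data <- function(data) {
  stopifnot(is.data.frame(data))
  required <- c("subject_id", "time", "value")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("data is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  ids <- as.character(data$subject_id)
  if (anyNA(ids) || anyNA(data$time) || anyNA(data$value)) {
    stop("subject_id, time and value must not contain missing values")
  }
  subject_ids <- unique(ids)
  times <- vector("list", length(subject_ids))
  values <- vector("list", length(subject_ids))
  names(times) <- names(values) <- subject_ids
  for (s in subject_ids) {
    sel <- ids == s
    ord <- order(data$time[sel])
    ti <- as.numeric(data$time[sel][ord])
    if (any(diff(ti) <= 0)) {
      stop("times within subject '", s, "' must be strictly increasing ",
           "(duplicated visit times found)")
    }
    times[[s]] <- ti
    values[[s]] <- as.numeric(data$value[sel][ord])
  }
  structure(
    list(subject_ids = subject_ids, times = times, values = values,
         n = length(subject_ids), m = sum(lengths(times))),
    class = "trajectory_data")
}

#' @export
print.trajectory_data <- function(x, ...) {
  mi <- lengths(x$times)
  cat("Longitudinal trajectory data:", x$n, "subjects,", x$m,
      "observations\n")
  cat("  observations per subject:", paste(range(mi), collapse = "-"),
      "(median", stats::median(mi), ")\n")
  invisible(x)
}

#' Read long-format trajectory observations from CSV
#'
#' Canonical interchange format: a UTF-8 CSV with header
#' `subject_id,time,value`.
#'
#' @param path Path to the CSV file.
#' @return A [trajectory_data] object.
#' @export
read_trajectory_csv <- function(path) {
  trajectory_data(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Stacked observation vector
#'
#' @param ds A [trajectory_data] object.
#' @return The m-vector stacking all subjects' observations in subject order.
#' @export
stacked_values <- function(ds) {
  unlist(ds$values, use.names = FALSE)
}

#' Polynomial design matrix for one subject
#'
#' Column `j` (0-based) holds the observation times raised elementwise to the
#' power `j`; the first column is the intercept column of ones.
#'
#' @param times Nonempty numeric vector of observation times.
#' @param order Polynomial order p (nonnegative integer); the design has
#'   d = p + 1 columns.
#' @return A `length(times)` by `order + 1` numeric matrix.
#' @examples
#' build_subject_design(c(1, 3), order = 1)
#' @export
build_subject_design <- function(times, order) {
  if (length(times) == 0) stop("degenerate subject: no observation times")
  order <- as.integer(order)
  if (order < 0) stop("polynomial order must be nonnegative")
  outer(as.numeric(times), 0:order, `^`)
}

#' Block-diagonal design matrix across subjects
#'
#' Stacks the per-subject polynomial designs into the overall block-diagonal
#' design: m rows, n(order+1) columns, with subject i's block on the diagonal
#' and exact zeros elsewhere. Subjects with fewer observations than
#' `order + 1` free parameters are retained with a warning - the coupled
#' prior can still identify their parameters.
#'
#' @param ds A [trajectory_data] object.
#' @param order Polynomial order (nonnegative integer).
#' @return An object of class `block_design`: a list with the dense `matrix`,
#'   `order`, `d = order + 1`, and per-subject `row_slices` / `col_slices`
#'   (lists of integer index vectors).
#' @export
build_block_design <- function(ds, order) {
  stopifnot(inherits(ds, "trajectory_data"))
  order <- as.integer(order)
  d <- order + 1L
  mi <- lengths(ds$times)
  if (any(mi < d)) {
    warning(sum(mi < d), " subject(s) have fewer than ", d,
            " observations; their parameters are identified only through ",
            "the coupled prior")
  }
  n <- ds$n
  X <- matrix(0, nrow = ds$m, ncol = n * d)
  row_slices <- col_slices <- vector("list", n)
  names(row_slices) <- names(col_slices) <- ds$subject_ids
  r0 <- 0L
  for (i in seq_len(n)) {
    s <- ds$subject_ids[i]
    rows <- r0 + seq_len(mi[i])
    cols <- (i - 1L) * d + seq_len(d)
    X[rows, cols] <- build_subject_design(ds$times[[s]], order)
    row_slices[[i]] <- rows
    col_slices[[i]] <- cols
    r0 <- r0 + mi[i]
  }
  structure(list(matrix = X, order = order, d = d,
                 row_slices = row_slices, col_slices = col_slices,
                 n = n, m = ds$m),
            class = "block_design")
}

#' @export
print.block_design <- function(x, ...) {
  cat("Block-diagonal polynomial design: ", x$m, " x ", ncol(x$matrix),
      " (", x$n, " subjects, order ", x$order, ")\n", sep = "")
  invisible(x)
}

## Column means/SDs of the pooled per-subject design columns (the zeros
## outside a subject's block are structural, not data, so moments are taken
## over the m stacked design rows).
design_column_moments <- function(ds, order) {
  d <- order + 1L
  rows <- do.call(rbind, lapply(ds$subject_ids, function(s)
    build_subject_design(ds$times[[s]], order)))
  means <- colMeans(rows)
  sds <- apply(rows, 2, stats::sd)
  means[1] <- 0; sds[1] <- 1   # intercept column is never standardized
  list(means = means, sds = sds)
}

#' Standardize training data
#'
#' Z-scores the stacked observations and each nonconstant design column
#' across all subjects, recording the moments so parameters and predictions
#' can be rescaled back afterwards. Intercept columns are left untouched.
#'
#' @param ds A [trajectory_data] object.
#' @param X A [build_block_design] result on `ds` (rebuilt internally from the
#'   standardized columns).
#' @return A list with `y` (standardized m-vector), `X` (standardized
#'   `block_design`), and `params`, an object of class `standardization`
#'   holding `y_mean`, `y_sd`, `column_means`, `column_sds` (per design
#'   column, intercept entries 0/1).
#' @export
standardize_training <- function(ds, X) {
  stopifnot(inherits(ds, "trajectory_data"), inherits(X, "block_design"))
  y <- stacked_values(ds)
  if (length(y) < 2) stop("need at least two observations to standardize")
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd <= 0) {
    stop("cannot standardize: observations have zero variance")
  }
  mom <- design_column_moments(ds, X$order)
  if (any(!is.finite(mom$sds)) || any(mom$sds <= 0)) {
    stop("cannot standardize: a nonconstant design column has zero variance ",
         "(all observation times equal?)")
  }
  params <- structure(
    list(y_mean = mean(y), y_sd = y_sd,
         column_means = mom$means, column_sds = mom$sds, d = X$d),
    class = "standardization")
  Xs <- X
  for (i in seq_len(X$n)) {
    blk <- X$matrix[X$row_slices[[i]], X$col_slices[[i]], drop = FALSE]
    Xs$matrix[X$row_slices[[i]], X$col_slices[[i]]] <-
      sweep(sweep(blk, 2, mom$means, `-`), 2, mom$sds, `/`)
  }
  list(y = (y - params$y_mean) / params$y_sd, X = Xs, params = params)
}

#' Standardize an out-of-sample prediction design
#'
#' Applies the affine map fitted on the training design - no refitting of
#' means or SDs - to new design rows, as required for out-of-sample
#' prediction.
#'
#' @param X_star A numeric matrix whose rows are per-subject polynomial design
#'   rows (d columns), or a full n_star x nd matrix in block layout.
#' @param params A `standardization` object from [standardize_training].
#' @param full Logical; if `TRUE`, `X_star` is in the full block layout and
#'   every subject block is standardized column-wise.
#' @return The standardized matrix, same shape as the input.
#' @export
standardize_prediction_design <- function(X_star, params, full = FALSE) {
  stopifnot(inherits(params, "standardization"))
  d <- params$d
  X_star <- as.matrix(X_star)
  if (!full) {
    if (ncol(X_star) != d) stop("X_star must have ", d, " columns")
    return(sweep(sweep(X_star, 2, params$column_means, `-`),
                 2, params$column_sds, `/`))
  }
  if (ncol(X_star) %% d != 0) stop("full X_star column count must be a multiple of d")
  n <- ncol(X_star) %/% d
  out <- X_star
  for (i in seq_len(n)) {
    cols <- (i - 1L) * d + seq_len(d)
    blk <- X_star[, cols, drop = FALSE]
    nz <- rowSums(blk != 0) > 0      # only standardize structurally nonzero rows
    if (any(nz)) {
      out[nz, cols] <- sweep(sweep(blk[nz, , drop = FALSE], 2,
                                   params$column_means, `-`),
                             2, params$column_sds, `/`)
    }
  }
  out
}

## Per-subject linear map L, c such that w = L w_tilde + c rescales
## standardized-space polynomial coefficients to the original units:
##   y = mu_y + s_y * [ w0~ + sum_a w_a~ (t^a - mu_a)/s_a ]
destandardization_map <- function(params) {
  d <- params$d
  L <- matrix(0, d, d)
  L[1, 1] <- params$y_sd
  if (d > 1) {
    for (a in 2:d) {
      L[a, a] <- params$y_sd / params$column_sds[a]
      L[1, a] <- -params$y_sd * params$column_means[a] / params$column_sds[a]
    }
  }
  cvec <- c(params$y_mean, rep(0, d - 1))
  list(L = L, c = cvec)
}

#' Rescale posterior parameters back to original units
#'
#' Inverts the z-scoring of [standardize_training] on the stacked parameter
#' vector and its covariance: each subject's coefficient block is mapped by
#' the same affine transform, and the covariance by the corresponding linear
#' map \eqn{L \Sigma L^T}.
#'
#' @param w_tilde Standardized nd parameter vector (subject-major).
#' @param Sigma_tilde Standardized nd x nd parameter covariance (or `NULL`).
#' @param params A `standardization` object.
#' @return A list with `w` (rescaled vector) and `Sigma` (rescaled covariance
#'   or `NULL`).
#' @export
destandardize_parameters <- function(w_tilde, Sigma_tilde = NULL, params) {
  stopifnot(inherits(params, "standardization"))
  d <- params$d
  if (length(w_tilde) %% d != 0) stop("parameter vector length must be a multiple of d")
  n <- length(w_tilde) %/% d
  map <- destandardization_map(params)
  W <- matrix(w_tilde, nrow = d)           # d x n, one column per subject
  w <- as.vector(map$L %*% W + map$c)
  Sigma <- NULL
  if (!is.null(Sigma_tilde)) {
    Lbig <- kronecker(diag(n), map$L)
    Sigma <- Lbig %*% Sigma_tilde %*% t(Lbig)
  }
  list(w = w, Sigma = Sigma)
}

#' Rescale predictions back to original units
#'
#' @param mean_tilde Standardized predictive means.
#' @param cov_tilde Standardized predictive covariance (or `NULL`).
#' @param params A `standardization` object.
#' @return List with `mean` and `cov` in the original observation units.
#' @export
destandardize_predictions <- function(mean_tilde, cov_tilde = NULL, params) {
  stopifnot(inherits(params, "standardization"))
  list(mean = params$y_mean + params$y_sd * mean_tilde,
       cov = if (!is.null(cov_tilde)) params$y_sd^2 * cov_tilde)
}
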