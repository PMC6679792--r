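#' Fit a coupled Bayesian trajectory model
#'
#' Fits the multi-task trajectory model to multi-subject longitudinal data:
#' standardizes the observations and design, tunes the coupling and noise
#' hyperparameters by empirical Bayes (marginal-likelihood maximization),
#' computes the closed-form Gaussian posterior over all subjects' polynomial
#' coefficients, and rescales everything back to the original units.
#'
#' @param data A [trajectory_data] object or a long-format data.frame with
#'   columns `subject_id,time,value`.
#' @param model A [model_spec], or the name of a registry model (see
#'   [model_registry]). The `"ols"` entry dispatches to [ols_fit].
#' @param covariates Named list of coupling covariates referenced by the
#'   spec's kernels: numeric vectors (one value per subject, in subject
#'   order), label vectors, or [genotype_table]s. A `random_se` kernel whose
#'   covariate is absent gets a fresh standard-normal vector drawn under
#'   `seed`.
#' @param order Polynomial order of the trajectories (default 1, linear).
#' @param n_restarts,seed,max_iter Passed to [optimize_hyperparameters].
#' @return An object of class `mtl_fit` with, in original units, the
#'   posterior mean `w_bar` and covariance `Sigma_post` of the stacked
#'   parameters, a per-subject `parameters` data.frame (estimates and
#'   posterior SDs), the optimized log-domain `hyper` vector, the
#'   `log_evidence`, and the standardization parameters used.
#' @examples
#' cohort <- simulate_cohort(scenario_config(n_subjects = 25, sigma_m = 1,
#'                                           seed = 7))
#' fit <- mtl_fit(cohort$train, model = "plain", n_restarts = 0)
#' head(fit$parameters)
#' @export
mtl_fit <- function(data, model = "plain", covariates = list(), order = 1,
                    n_restarts = 3, seed = 1, max_iter = 200) {
  ds <- if (inherits(data, "trajectory_data")) data else trajectory_data(data)
  spec <- if (inherits(model, "model_spec")) model else {
    reg <- model_registry()
    if (!model %in% names(reg)) {
      stop("unknown model '", model, "'; registry models are: ",
           paste(names(reg), collapse = ", "))
    }
    reg[[model]]
  }
  if (spec$ols) return(ols_fit(ds, order = order))
  if (spec$order != order) {
    stop("registry models are linear (order 1); supply a custom model_spec ",
         "for other polynomial orders")
  }

  ## draw the random-information vector if a random_se kernel needs one
  for (k in names(spec$kernels)) {
    kdef <- spec$kernels[[k]]
    if (kdef$family == "random_se" && is.null(covariates[[kdef$covariate]])) {
      covariates[[kdef$covariate]] <- withr_seed(seed, stats::rnorm(ds$n))
    }
    if (is.null(covariates[[kdef$covariate]])) {
      stop("model '", spec$name, "' requires covariate '", kdef$covariate,
           "' which was not supplied")
    }
    cv <- covariates[[kdef$covariate]]
    len <- if (inherits(cv, "genotype_table")) length(cv$n_e2) else length(cv)
    if (len != ds$n) {
      stop("covariate '", kdef$covariate, "' has length ", len,
           " but there are ", ds$n, " subjects")
    }
  }

  X_raw <- build_block_design(ds, spec$order)
  std <- standardize_training(ds, X_raw)
  hyper <- optimize_hyperparameters(spec, std$X, std$y, covariates,
                                    n_restarts = n_restarts, seed = seed,
                                    max_iter = max_iter)
  log_evidence <- log_marginal_likelihood(hyper, std$X, std$y, spec,
                                          covariates)
  post <- compute_posterior(hyper, std$X, std$y, spec, covariates)
  destd <- destandardize_parameters(post$w_bar, post$Sigma_post, std$params)

  d <- spec$d
  est <- matrix(destd$w, nrow = d)
  sds <- matrix(sqrt(pmax(diag(destd$Sigma), 0)), nrow = d)
  pnames <- if (d == 2) c("intercept", "slope") else paste0("coef_", 0:(d - 1))
  parameters <- data.frame(subject_id = ds$subject_ids,
                           stringsAsFactors = FALSE)
  for (a in seq_len(d)) {
    parameters[[pnames[a]]] <- est[a, ]
    parameters[[paste0(pnames[a], "_sd")]] <- sds[a, ]
  }

  structure(list(dataset = ds, spec = spec, covariates = covariates,
                 standardization = std$params, X_std = std$X, y_std = std$y,
                 hyper = hyper, hyper_natural = exp(hyper),
                 log_evidence = log_evidence,
                 w_bar = destd$w, Sigma_post = destd$Sigma,
                 w_bar_std = post$w_bar, Sigma_post_std = post$Sigma_post,
                 parameters = parameters),
            class = "mtl_fit")
}

#' @export
print.mtl_fit <- function(x, ...) {
  cat("Coupled Bayesian trajectory fit: model '", x$spec$name, "', ",
      x$dataset$n, " subjects, ", x$dataset$m, " observations\n", sep = "")
  cat("  log evidence: ", format(x$log_evidence, digits = 6),
      "   noise precision beta: ",
      format(x$hyper_natural[["log_beta"]], digits = 4), "\n", sep = "")
  cat("  covariance hyperparameters:", count_hyperparameters(x$spec), "\n")
  invisible(x)
}

## Build the (standardized) prediction design for rows of (subject_id, time):
## each row has subject i's standardized polynomial design row in that
## subject's block and structural zeros elsewhere.
prediction_design <- function(fit, newdata) {
  ds <- fit$dataset
  idx <- match(as.character(newdata$subject_id), ds$subject_ids)
  if (anyNA(idx)) {
    stop("newdata contains subject(s) not in the fitted dataset: ",
         paste(unique(newdata$subject_id[is.na(idx)]), collapse = ", "))
  }
  d <- fit$spec$d
  rows_raw <- build_subject_design(as.numeric(newdata$time), fit$spec$order)
  rows_std <- standardize_prediction_design(rows_raw, fit$standardization)
  Xs <- matrix(0, nrow(newdata), ds$n * d)
  for (r in seq_len(nrow(newdata))) {
    Xs[r, (idx[r] - 1L) * d + seq_len(d)] <- rows_std[r, ]
  }
  Xs
}

#' Probabilistic trajectory predictions
#'
#' Predicts biomarker values at requested subject/time pairs from the
#' posterior predictive distribution: mean \eqn{X_* \bar w} and covariance
#' \eqn{\beta^{-1} I + X_* A^{-1} X_*^T} with
#' \eqn{A = \Sigma_{prior}^{-1} + \beta X^T X}, evaluated on the
#' standardized scale and rescaled to original units. The predictive SD is
#' never below the observation-noise floor \eqn{1/\sqrt\beta}.
#'
#' @param object An `mtl_fit`.
#' @param newdata data.frame with columns `subject_id` and `time`.
#' @param ... Unused.
#' @return `newdata` with columns `mean` and `sd` appended; the full
#'   predictive covariance (original units) is attached as attribute
#'   `"covariance"`.
#' @export
predict.mtl_fit <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata),
            all(c("subject_id", "time") %in% names(newdata)))
  Xs <- prediction_design(object, newdata)
  beta <- object$hyper_natural[["log_beta"]]
  mean_std <- as.numeric(Xs %*% object$w_bar_std)
  cov_std <- diag(1 / beta, nrow(Xs)) +
    Xs %*% object$Sigma_post_std %*% t(Xs)
  out_scale <- destandardize_predictions(mean_std, cov_std,
                                         object$standardization)
  res <- newdata[, c("subject_id", "time")]
  res$mean <- out_scale$mean
  res$sd <- sqrt(pmax(diag(out_scale$cov), 0))
  attr(res, "covariance") <- out_scale$cov
  res
}

#' Uncoupled per-subject least-squares baseline
#'
#' Fits an independent polynomial by ordinary least squares to each
#' subject - the infinite-ridge limit of the coupled model. Subjects with
#' exactly `order + 1` observations are interpolated exactly; subjects with
#' fewer observations are under-determined and raise an error.
#'
#' @param ds A [trajectory_data] object (or long-format data.frame).
#' @param order Polynomial order.
#' @return An object of class `ols_fit` with a `parameters` data.frame
#'   (per-subject coefficients, no posterior SDs), per-subject residual
#'   variances (`NA` when there are no residual degrees of freedom), and a
#'   `predict` method returning point predictions.
#' @export
ols_fit <- function(ds, order = 1) {
  if (!inherits(ds, "trajectory_data")) ds <- trajectory_data(ds)
  d <- as.integer(order) + 1L
  mi <- lengths(ds$times)
  if (any(mi < d)) {
    stop("OLS baseline is under-determined for ", sum(mi < d),
         " subject(s) with fewer than ", d, " observations")
  }
  coefs <- matrix(NA_real_, d, ds$n)
  resid_var <- rep(NA_real_, ds$n)
  for (i in seq_len(ds$n)) {
    s <- ds$subject_ids[i]
    Xi <- build_subject_design(ds$times[[s]], order)
    f <- stats::lm.fit(Xi, ds$values[[s]])
    coefs[, i] <- f$coefficients
    if (mi[i] > d) resid_var[i] <- sum(f$residuals^2) / (mi[i] - d)
  }
  pnames <- if (d == 2) c("intercept", "slope") else paste0("coef_", 0:(d - 1))
  parameters <- data.frame(subject_id = ds$subject_ids,
                           stringsAsFactors = FALSE)
  for (a in seq_len(d)) parameters[[pnames[a]]] <- coefs[a, ]
  structure(list(dataset = ds, order = as.integer(order), d = d,
                 coefficients = coefs, resid_var = resid_var,
                 parameters = parameters,
                 spec = model_registry()[["ols"]]),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat("Per-subject OLS baseline: order ", x$order, ", ", x$dataset$n,
      " subjects\n", sep = "")
  invisible(x)
}

#' @export
predict.ols_fit <- function(object, newdata, ...) {
  idx <- match(as.character(newdata$subject_id), object$dataset$subject_ids)
  if (anyNA(idx)) stop("newdata contains unknown subject(s)")
  rows <- build_subject_design(as.numeric(newdata$time), object$order)
  res <- newdata[, c("subject_id", "time")]
  res$mean <- rowSums(rows * t(object$coefficients[, idx, drop = FALSE]))
  res$sd <- sqrt(object$resid_var[idx])
  res
}

#' Log Bayes factor between two fitted models
#'
#' The difference of log model evidences, `log_evidence(a) - log_evidence(b)`;
#' positive values favor the first model. Both fits must be on identical
#' observations.
#'
#' @param fit_a,fit_b `mtl_fit` objects fitted to the same data.
#' @return Scalar log Bayes factor.
#' @export
log_bayes_factor <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "mtl_fit"), inherits(fit_b, "mtl_fit"))
  ya <- stacked_values(fit_a$dataset)
  yb <- stacked_values(fit_b$dataset)
  ta <- unlist(fit_a$dataset$times, use.names = FALSE)
  tb <- unlist(fit_b$dataset$times, use.names = FALSE)
  if (length(ya) != length(yb) || max(abs(ya - yb)) > 1e-12 ||
      max(abs(ta - tb)) > 1e-12) {
    stop("fits were made on different datasets; Bayes factors are only ",
         "meaningful for identical observations")
  }
  fit_a$log_evidence - fit_b$log_evidence
}

#' Serialize a fit to JSON
#'
#' Writes hyperparameters (log and natural domain), log evidence and the
#' per-subject parameter table to a JSON file; a light-weight record for the
#' command-line workflow.
#'
#' @param fit An `mtl_fit`.
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("write_fit_json requires the jsonlite package")
  }
  obj <- list(model = fit$spec$name,
              log_evidence = fit$log_evidence,
              hyper_log = as.list(fit$hyper),
              hyper_natural = as.list(fit$hyper_natural),
              parameters = fit$parameters,
              data_checksum = round(sum(stacked_values(fit$dataset)^2), 10))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
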