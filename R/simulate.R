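#' Simulation scenario configuration
#'
#' Describes one synthetic-cohort condition: linear trajectories with group
#' differences in either intercept or slope, balanced three-visit sampling
#' with short fixed intervals, and one of several measurement-noise
#' mechanisms (independent Gaussian by default; optionally within-subject
#' correlated or skewed).
#'
#' Defaults are the study conditions: 200 subjects per run, intercepts drawn
#' from \{-10, -8, -6, -4, -2\} with fixed slope -1 (intercept variation) or
#' slopes from \{-1.0, -1.5, -2.0, -2.5, -3.0\} with fixed intercept 0
#' (slope variation); baseline time uniform on [0, 10] with follow-ups at
#' +0.05 and +0.10; the first two samples train, the third is held out.
#'
#' @param scenario `"intercept_variation"` or `"slope_variation"`.
#' @param n_subjects Cohort size per run.
#' @param sigma_m Measurement-noise SD (study levels: 1, 2, 4, 8).
#' @param n_runs Number of simulation runs.
#' @param seed Master seed; each run derives its own reproducible substream.
#' @param rho Within-subject noise correlation in [0, 1] (0 = independent).
#'   When positive, the noise covariance has `sigma_m^2` on the diagonal and
#'   `rho * sigma_m^2` off it.
#' @param skewness Noise skewness (0 = Gaussian; study levels 0.6, 0.9),
#'   with variance `sigma_m^2`.
#' @param train_samples Number of leading samples used for training.
#' @param eval_sample Index of the held-out evaluation sample.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("intercept_variation",
                                         "slope_variation"),
                            n_subjects = 200, sigma_m = 1, n_runs = 30,
                            seed = 1, rho = 0, skewness = 0,
                            train_samples = 2, eval_sample = 3) {
  scenario <- match.arg(scenario)
  stopifnot(n_subjects >= 1, sigma_m >= 0, n_runs >= 1,
            rho >= 0, rho <= 1, skewness >= 0,
            train_samples >= 1, eval_sample > train_samples)
  structure(list(scenario = scenario, n_subjects = as.integer(n_subjects),
                 sigma_m = sigma_m, n_runs = as.integer(n_runs),
                 seed = as.integer(seed), rho = rho, skewness = skewness,
                 train_samples = as.integer(train_samples),
                 eval_sample = as.integer(eval_sample)),
            class = "scenario_config")
}

## Independent reproducible substream seed per (master seed, run); kept
## within 32-bit integer range.
run_seed <- function(seed, run_index) {
  as.integer((abs(as.numeric(seed)) %% 1e6) * 1009 + 97 * run_index) %% 2147483647L
}

#' Within-subject correlated Gaussian noise
#'
#' Draws a zero-mean Gaussian vector with covariance `sigma2` on the
#' diagonal and `rho * sigma2` off-diagonal (compound symmetry): `rho = 0`
#' gives independent errors, `rho = 1` an identical error for all of a
#' subject's samples.
#'
#' @param m_i Number of samples for the subject.
#' @param sigma2 Noise variance.
#' @param rho Correlation in [0, 1].
#' @param seed Optional seed for a reproducible draw.
#' @return Numeric noise vector of length `m_i`.
#' @export
correlated_noise <- function(m_i, sigma2, rho, seed = NULL) {
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  draw <- function() {
    shared <- stats::rnorm(1)
    sqrt(rho * sigma2) * shared + sqrt((1 - rho) * sigma2) * stats::rnorm(m_i)
  }
  if (is.null(seed)) draw() else withr_seed(seed, draw())
}

#' Zero-mean skewed noise
#'
#' Generates measurement error with a target variance and sample skewness
#' from a mean-centered gamma distribution (shape `(2/skewness)^2`, scale
#' chosen for the variance); `skewness = 0` returns exact Gaussian draws.
#'
#' @param m Number of draws.
#' @param variance Target variance.
#' @param skewness Target (moment) skewness, nonnegative.
#' @param seed Optional seed.
#' @return Numeric vector of length `m`.
#' @export
skewed_noise <- function(m, variance, skewness, seed = NULL) {
  if (skewness < 0) stop("skewness must be nonnegative")
  draw <- function() {
    if (skewness == 0) return(stats::rnorm(m, 0, sqrt(variance)))
    shape <- (2 / skewness)^2
    scale <- sqrt(variance / shape)
    stats::rgamma(m, shape = shape, scale = scale) - shape * scale
  }
  if (is.null(seed)) draw() else withr_seed(seed, draw())
}

#' Simulate one synthetic cohort
#'
#' Generates one run of the configured scenario: per-subject true linear
#' parameters drawn from the scenario's five-value set, three samples at
#' `t1, t1 + 0.05, t1 + 0.10` with the configured noise mechanism, a noisy
#' coupling biomarker `b_i = true parameter + N(0, 1)`, and an uninformative
#' standard-normal random vector for control kernels. Fully reproducible
#' from `(cfg$seed, run_index)`.
#'
#' @param cfg A [scenario_config].
#' @param run_index Run number (1-based).
#' @return An object of class `simulated_cohort`: list with `dataset` (all
#'   samples as [trajectory_data]), `train` (first `train_samples` per
#'   subject), `heldout` (data.frame of the evaluation sample),
#'   `true_intercepts`, `true_slopes`, `biomarker`, `random_vector`,
#'   `truth` (per-subject data.frame), `config`, `run_index`.
#' @export
simulate_cohort <- function(cfg, run_index = 1) {
  stopifnot(inherits(cfg, "scenario_config"))
  n <- cfg$n_subjects
  withr_seed(run_seed(cfg$seed, run_index), {
    if (cfg$scenario == "intercept_variation") {
      intercepts <- sample(c(-10, -8, -6, -4, -2), n, replace = TRUE)
      slopes <- rep(-1, n)
    } else {
      slopes <- sample(c(-1.0, -1.5, -2.0, -2.5, -3.0), n, replace = TRUE)
      intercepts <- rep(0, n)
    }
    t1 <- stats::runif(n, 0, 10)
    offsets <- c(0, 0.05, 0.10)
    n_samp <- length(offsets)
    noise <- if (cfg$rho > 0) {
      t(vapply(seq_len(n), function(i)
        correlated_noise(n_samp, cfg$sigma_m^2, cfg$rho), numeric(n_samp)))
    } else if (cfg$skewness > 0) {
      matrix(skewed_noise(n * n_samp, cfg$sigma_m^2, cfg$skewness),
             nrow = n, byrow = TRUE)
    } else {
      matrix(stats::rnorm(n * n_samp, 0, cfg$sigma_m), nrow = n)
    }
    truth_param <- if (cfg$scenario == "intercept_variation") intercepts else slopes
    biomarker <- truth_param + stats::rnorm(n)
    random_vector <- stats::rnorm(n)

    ids <- sprintf("s%03d", seq_len(n))
    sample_times <- outer(t1, offsets, `+`)        # n x 3, row per subject
    long <- data.frame(
      subject_id = rep(ids, each = n_samp),
      time = as.vector(t(sample_times)),
      value = rep(intercepts, each = n_samp) +
        rep(slopes, each = n_samp) * as.vector(t(sample_times)) +
        as.vector(t(noise)))

    train_sel <- rep(seq_len(n_samp), n) <= cfg$train_samples
    eval_sel <- rep(seq_len(n_samp), n) == cfg$eval_sample
    structure(list(dataset = trajectory_data(long),
                   train = trajectory_data(long[train_sel, ]),
                   heldout = long[eval_sel, c("subject_id", "time", "value")],
                   true_intercepts = intercepts, true_slopes = slopes,
                   biomarker = biomarker, random_vector = random_vector,
                   truth = data.frame(subject_id = ids,
                                      true_intercept = intercepts,
                                      true_slope = slopes,
                                      biomarker = biomarker),
                   config = cfg, run_index = run_index),
              class = "simulated_cohort")
  })
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("Simulated cohort (", x$config$scenario, "), run ", x$run_index,
      ": ", x$config$n_subjects, " subjects, sigma_m = ", x$config$sigma_m,
      "\n", sep = "")
  invisible(x)
}

## Score one fitted model on a cohort; returns a named numeric vector.
score_model_on_cohort <- function(fit, cohort) {
  heldout <- cohort$heldout
  pred <- predict(fit, heldout[, c("subject_id", "time")])
  pars <- fit$parameters
  has_sd <- "intercept_sd" %in% names(pars)
  c(pred_mae = mae(pred$mean, heldout$value),
    pred_coverage = if (all(is.finite(pred$sd))) {
      coverage(pred$mean, pred$sd, heldout$value)$covered
    } else NA_real_,
    intercept_mae = mae(pars$intercept, cohort$true_intercepts),
    slope_mae = mae(pars$slope, cohort$true_slopes),
    intercept_coverage = if (has_sd) {
      coverage(pars$intercept, pars$intercept_sd,
               cohort$true_intercepts)$covered
    } else NA_real_,
    slope_coverage = if (has_sd) {
      coverage(pars$slope, pars$slope_sd, cohort$true_slopes)$covered
    } else NA_real_,
    intercept_est_var = stats::var(pars$intercept),
    slope_est_var = stats::var(pars$slope),
    log_evidence = if (inherits(fit, "mtl_fit")) fit$log_evidence else NA_real_)
}

#' Run the train/predict/evaluate simulation study
#'
#' For each run: simulate a cohort, fit every requested model on the first
#' training samples, predict the held-out sample, and score predictions and
#' parameter estimates. Fit failures are recorded as `NA` metric values for
#' that (model, run) cell rather than aborting the study.
#'
#' @param cfg A [scenario_config].
#' @param model_names Character vector of registry model names (see
#'   [model_registry]); the simulation models use the cohort's biomarker
#'   (`b`) and random vector (`r`) as coupling covariates.
#' @param n_restarts,max_iter Optimizer settings passed to [mtl_fit].
#' @return A tidy data.frame with columns
#'   `scenario, sigma_m, run, model, metric, value`.
#' @export
run_study <- function(cfg, model_names = c("plain", "gaussian_both", "ols"),
                      n_restarts = 2, max_iter = 200) {
  stopifnot(inherits(cfg, "scenario_config"))
  reg <- model_registry()
  unknown <- setdiff(model_names, names(reg))
  if (length(unknown) > 0) {
    stop("unknown model(s): ", paste(unknown, collapse = ", "),
         "; registry models are: ", paste(names(reg), collapse = ", "))
  }
  rows <- list()
  for (run in seq_len(cfg$n_runs)) {
    cohort <- simulate_cohort(cfg, run)
    covs <- list(b = cohort$biomarker, r = cohort$random_vector)
    for (mn in model_names) {
      scores <- tryCatch({
        fit <- if (reg[[mn]]$ols) {
          ols_fit(cohort$train)
        } else {
          mtl_fit(cohort$train, model = mn, covariates = covs,
                  n_restarts = n_restarts, max_iter = max_iter,
                  seed = run_seed(cfg$seed, run))
        }
        score_model_on_cohort(fit, cohort)
      }, error = function(e) {
        warning("fit of '", mn, "' failed in run ", run, ": ",
                conditionMessage(e))
        stats::setNames(rep(NA_real_, 9),
                        c("pred_mae", "pred_coverage", "intercept_mae",
                          "slope_mae", "intercept_coverage", "slope_coverage",
                          "intercept_est_var", "slope_est_var",
                          "log_evidence"))
      })
      rows[[length(rows) + 1]] <- data.frame(
        scenario = cfg$scenario, sigma_m = cfg$sigma_m, run = run,
        model = mn, metric = names(scores), value = unname(scores),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
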