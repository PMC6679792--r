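test_that("evidence reduces to the scalar closed form for one observation", {
  # single subject, single observation, constant model: marginal variance is
  # prior variance + noise variance
  ds <- trajectory_data(data.frame(subject_id = "a", time = 2, value = 0.7))
  X <- build_block_design(ds, 0)
  spec <- model_spec("scalar", order = 0,
                     blocks = list(list(independent = TRUE, shared = FALSE,
                                        kernels = character(0))))
  h <- hyper_init(spec)
  h[["log_alpha1"]] <- log(0.5)
  h[["log_alpha_1_indep"]] <- log(1.5)   # s = 0.5 + 1.5 = 2
  h[["log_beta"]] <- log(4)              # noise variance 0.25
  s_tot <- 2 + 0.25
  y0 <- 0.7
  expect_equal(log_marginal_likelihood(h, X, y0, spec, list()),
               -0.5 * log(2 * pi * s_tot) - y0^2 / (2 * s_tot),
               tolerance = 1e-12)
})

test_that("weight-space evidence equals the function-space Gaussian density", {
  # the module's central correctness oracle, on 20 random small instances
  for (k in 1:20) {
    inst <- random_instance(2 + (k %% 5), "gaussian_both", seed = 100 + k)
    h <- random_hyper(inst$spec, seed = 200 + k)
    lw <- log_marginal_likelihood(h, inst$std$X, inst$std$y, inst$spec,
                                  inst$covs)
    lf <- oracle_evidence(h, inst$std, inst$spec, inst$covs, inst$n)
    expect_equal(lw, lf, tolerance = 1e-8)
  }
})

test_that("analytic evidence gradient matches central finite differences", {
  for (k in 1:5) {
    inst <- random_instance(5, "gaussian_both", seed = 300 + k)
    h <- random_hyper(inst$spec, sd = 0.3, seed = 400 + k)
    g <- evidence_gradient(h, inst$std$X, inst$std$y, inst$spec, inst$covs)
    fd <- vapply(seq_along(h), function(j) {
      hp <- h; hm <- h
      hp[j] <- hp[j] + 1e-5; hm[j] <- hm[j] - 1e-5
      (log_marginal_likelihood(hp, inst$std$X, inst$std$y, inst$spec, inst$covs) -
         log_marginal_likelihood(hm, inst$std$X, inst$std$y, inst$spec, inst$covs)) / 2e-5
    }, numeric(1))
    expect_equal(unname(g), fd, tolerance = 1e-4)
  }
  # the noise-precision component has the right sign at random points
  inst <- random_instance(4, "plain", seed = 17)
  for (k in 1:10) {
    h <- random_hyper(inst$spec, seed = 500 + k)
    g <- evidence_gradient(h, inst$std$X, inst$std$y, inst$spec, inst$covs)
    eps <- 1e-5
    hp <- h; hp[["log_beta"]] <- hp[["log_beta"]] + eps
    hm <- h; hm[["log_beta"]] <- hm[["log_beta"]] - eps
    fd_beta <- (log_marginal_likelihood(hp, inst$std$X, inst$std$y, inst$spec, inst$covs) -
                  log_marginal_likelihood(hm, inst$std$X, inst$std$y, inst$spec, inst$covs)) / (2 * eps)
    expect_equal(sign(g[["log_beta"]]), sign(fd_beta))
  }
})

test_that("evidence is invariant under consistent subject relabeling", {
  set.seed(77)
  n <- 5
  long <- data.frame(subject_id = rep(sprintf("s%d", 1:n), each = 3),
                     time = as.vector(replicate(n, sort(runif(3, 0, 10)))),
                     value = rnorm(3 * n))
  b <- rnorm(n)
  spec <- model_registry()[["gaussian_both"]]
  h <- random_hyper(spec, seed = 3)
  ev <- function(d, bb) {
    ds <- trajectory_data(d)
    std <- standardize_training(ds, build_block_design(ds, 1))
    log_marginal_likelihood(h, std$X, std$y, spec, list(b = bb))
  }
  perm <- c(3, 1, 5, 2, 4)
  long2 <- do.call(rbind, lapply(perm, function(i)
    long[long$subject_id == sprintf("s%d", i), ]))
  expect_equal(ev(long, b), ev(long2, b[perm]), tolerance = 1e-9)
})

test_that("hyperparameter optimization satisfies its ascent and determinism contracts", {
  inst <- random_instance(6, "gaussian_both", seed = 55)
  h_opt <- optimize_hyperparameters(inst$spec, inst$std$X, inst$std$y,
                                    inst$covs, n_restarts = 1, seed = 2)
  ev_opt <- attr(h_opt, "log_evidence")
  ev_init <- log_marginal_likelihood(hyper_init(inst$spec), inst$std$X,
                                     inst$std$y, inst$spec, inst$covs)
  expect_gte(ev_opt, ev_init)
  expect_equal(ev_opt,
               log_marginal_likelihood(h_opt, inst$std$X, inst$std$y,
                                       inst$spec, inst$covs),
               tolerance = 1e-6)
  # beats pure random search
  set.seed(8)
  ev_random <- max(vapply(1:10, function(k) {
    h <- random_hyper(inst$spec)
    log_marginal_likelihood(h, inst$std$X, inst$std$y, inst$spec, inst$covs)
  }, numeric(1)))
  expect_gte(ev_opt, ev_random)
  # fixed seed gives bit-identical results
  h2 <- optimize_hyperparameters(inst$spec, inst$std$X, inst$std$y,
                                 inst$covs, n_restarts = 1, seed = 2)
  expect_identical(unname(h_opt), unname(h2))
})

test_that("posterior follows the closed form and shrinks the prior", {
  # zero data -> zero posterior mean
  inst <- random_instance(4, "plain", seed = 9)
  h <- random_hyper(inst$spec, seed = 10)
  post0 <- compute_posterior(h, inst$std$X, rep(0, length(inst$std$y)),
                             inst$spec, list())
  expect_equal(post0$w_bar, rep(0, 8))
  # posterior covariance never exceeds the prior (Loewner order)
  post <- compute_posterior(h, inst$std$X, inst$std$y, inst$spec, list())
  Sigma_prior <- assemble_prior(h, inst$spec, list(), inst$n)
  ev_min <- min(eigen(Sigma_prior - post$Sigma_post, symmetric = TRUE,
                      only.values = TRUE)$values)
  expect_gte(ev_min, -1e-8)
})

test_that("a flat prior recovers the per-subject least-squares solution", {
  # one subject, two points, huge diagonal prior, beta = 1
  ds <- trajectory_data(data.frame(subject_id = "a", time = c(0, 1),
                                   value = c(0, 1)))
  X <- build_block_design(ds, 1)
  spec <- model_registry()[["plain"]]
  h <- hyper_init(spec)
  h[grep("alpha", names(h))] <- -40
  h[["log_alpha1"]] <- log(1e8)
  post <- compute_posterior(h, X, c(0, 1), spec, list())
  expect_equal(post$w_bar, c(0, 1), tolerance = 1e-4)
  # multi-subject: flat-prior posterior equals OLS after destandardization
  set.seed(23)
  long <- data.frame(subject_id = rep(sprintf("s%d", 1:5), each = 4),
                     time = as.vector(replicate(5, sort(runif(4, 0, 10)))),
                     value = rnorm(20, -5, 3))
  ds2 <- trajectory_data(long)
  std <- standardize_training(ds2, build_block_design(ds2, 1))
  h2 <- hyper_init(spec)
  h2[grep("alpha", names(h2))] <- -40
  h2[["log_alpha1"]] <- log(1e8)
  post2 <- compute_posterior(h2, std$X, std$y, spec, list())
  w_back <- destandardize_parameters(post2$w_bar, NULL, std$params)$w
  expect_equal(w_back, as.vector(ols_fit(ds2, 1)$coefficients),
               tolerance = 1e-4)
})

test_that("predictions match the Gaussian-conditioning oracle", {
  for (k in 1:5) {
    inst <- random_instance(4, "gaussian_both", seed = 600 + k)
    h <- random_hyper(inst$spec, sd = 0.4, seed = 700 + k)
    beta <- exp(h[["log_beta"]])
    post <- compute_posterior(h, inst$std$X, inst$std$y, inst$spec, inst$covs)
    Xstar <- inst$std$X$matrix[c(2, 7), , drop = FALSE]
    mean_w <- as.numeric(Xstar %*% post$w_bar)
    cov_w <- diag(1 / beta, 2) + Xstar %*% post$Sigma_post %*% t(Xstar)
    # independent oracle: condition the joint Gaussian over (y, y*)
    Sp <- assemble_prior(h, inst$spec, inst$covs, inst$n)
    Xm <- inst$std$X$matrix
    C <- Xm %*% Sp %*% t(Xm) + diag(1 / beta, length(inst$std$y))
    Kxs <- Xstar %*% Sp %*% t(Xm)
    mean_f <- as.numeric(Kxs %*% solve(C, inst$std$y))
    cov_f <- diag(1 / beta, 2) + Xstar %*% Sp %*% t(Xstar) -
      Kxs %*% solve(C, t(Kxs))
    expect_equal(mean_w, mean_f, tolerance = 1e-8)
    expect_equal(cov_w, cov_f, tolerance = 1e-8)
    # predictive variance never drops below the observation-noise floor
    expect_true(all(diag(cov_w) >= 1 / beta - 1e-12))
  }
})

test_that("fitted model reproduces training rows and honors the noise floor", {
  cohort <- simulate_cohort(scenario_config(n_subjects = 20, sigma_m = 1,
                                            seed = 12))
  fit <- mtl_fit(cohort$train, "plain", n_restarts = 0)
  train_rows <- data.frame(subject_id = rep(cohort$train$subject_ids, each = 1),
                           time = vapply(cohort$train$times, `[`, numeric(1), 1))
  pred <- predict(fit, train_rows)
  # predictive mean at a training input equals the fitted value there
  fitted_vals <- vapply(seq_len(nrow(train_rows)), function(r) {
    w <- fit$w_bar[(r - 1) * 2 + 1:2]
    w[1] + w[2] * train_rows$time[r]
  }, numeric(1))
  expect_equal(pred$mean, fitted_vals, tolerance = 1e-8)
  beta <- fit$hyper_natural[["log_beta"]]
  noise_floor_raw <- fit$standardization$y_sd / sqrt(beta)
  expect_true(all(pred$sd >= noise_floor_raw - 1e-10))
})

test_that("per-subject OLS interpolates exact data and flags under-determined subjects", {
  ds <- trajectory_data(data.frame(subject_id = c("a", "a"), time = c(0, 1),
                                   value = c(0, 1)))
  fit <- ols_fit(ds, 1)
  expect_equal(as.vector(fit$coefficients), c(0, 1))
  expect_true(is.na(fit$resid_var[1]))   # no residual degrees of freedom
  pred <- predict(fit, data.frame(subject_id = "a", time = 2))
  expect_equal(pred$mean, 2)
  short <- trajectory_data(data.frame(subject_id = "a", time = 1, value = 1))
  expect_error(ols_fit(short, 1), "under-determined")
})

test_that("log Bayes factors are antisymmetric and refuse mismatched data", {
  cohort <- simulate_cohort(scenario_config(n_subjects = 15, sigma_m = 2,
                                            seed = 31))
  covs <- list(b = cohort$biomarker, r = cohort$random_vector)
  fa <- mtl_fit(cohort$train, "plain", covariates = covs, n_restarts = 0)
  fb <- mtl_fit(cohort$train, "gaussian_both", covariates = covs,
                n_restarts = 0)
  expect_equal(log_bayes_factor(fa, fa), 0)
  expect_equal(log_bayes_factor(fa, fb), -log_bayes_factor(fb, fa))
  other <- simulate_cohort(scenario_config(n_subjects = 15, sigma_m = 2,
                                           seed = 32))
  fc <- mtl_fit(other$train, "plain", n_restarts = 0)
  expect_error(log_bayes_factor(fa, fc), "different datasets")
})
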