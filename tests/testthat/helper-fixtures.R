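# Fixtures are generated in code; everything is seeded for reproducibility.

# Small long-format dataset with irregular per-subject visit counts.
tiny_long <- function() {
  data.frame(
    subject_id = c("a", "a", "b", "b", "b", "c", "c"),
    time = c(0, 1, 0.5, 1.5, 2.5, 2, 3),
    value = c(5, 4, 6, 5, 4, 7, 6.5),
    stringsAsFactors = FALSE)
}

# Random standardized instance for evidence/posterior oracles: n subjects
# with 3 visits each, pure-noise values, plus coupling covariates.
random_instance <- function(n, spec_name = "gaussian_both", seed = 1) {
  set.seed(seed)
  long <- data.frame(
    subject_id = rep(sprintf("s%02d", seq_len(n)), each = 3),
    time = as.vector(replicate(n, sort(stats::runif(3, 0, 10)))),
    value = stats::rnorm(3 * n, 0, 2))
  ds <- trajectory_data(long)
  std <- standardize_training(ds, build_block_design(ds, 1))
  list(ds = ds, std = std,
       covs = list(b = stats::rnorm(n), r = stats::rnorm(n)),
       spec = model_registry()[[spec_name]], n = n)
}

# Random draw of a log-domain hyperparameter vector for a spec.
random_hyper <- function(spec, sd = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  unpack_hyper(stats::rnorm(length(hyper_layout(spec)), 0, sd), spec)
}

# Independent function-space evidence oracle: plain Gaussian log-density of
# y under covariance X Sigma_prior X' + beta^{-1} I, computed directly with
# determinant() and solve() (no shared code with the package's engine).
oracle_evidence <- function(h, std, spec, covs, n) {
  Sp <- assemble_prior(h, spec, covs, n)
  Xm <- std$X$matrix
  y <- std$y
  C <- Xm %*% Sp %*% t(Xm) + diag(1 / exp(h[["log_beta"]]), length(y))
  as.numeric(-0.5 * (length(y) * log(2 * pi) +
                       determinant(C, logarithm = TRUE)$modulus +
                       t(y) %*% solve(C, y)))
}
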