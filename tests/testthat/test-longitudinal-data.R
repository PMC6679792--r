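test_that("per-subject polynomial designs follow the Vandermonde layout", {
  expect_equal(build_subject_design(0, 2), matrix(c(1, 0, 0), 1))
  expect_equal(build_subject_design(3.7, 0), matrix(1, 1, 1))
  expect_equal(build_subject_design(c(1, 3), 1),
               matrix(c(1, 1, 1, 3), 2))
  expect_error(build_subject_design(numeric(0), 1), "degenerate")
})

test_that("block design stacks subject blocks with exact zeros elsewhere", {
  ds <- trajectory_data(tiny_long())
  X <- build_block_design(ds, 1)
  expect_equal(dim(X$matrix), c(7, 6))
  # block i equals that subject's design
  for (i in 1:3) {
    s <- ds$subject_ids[i]
    expect_equal(X$matrix[X$row_slices[[i]], X$col_slices[[i]]],
                 build_subject_design(ds$times[[s]], 1))
  }
  # everything outside the diagonal blocks is exactly zero
  M <- X$matrix
  for (i in 1:3) M[X$row_slices[[i]], X$col_slices[[i]]] <- 0
  expect_true(all(M == 0))
  # one subject: block design is that subject's design
  one <- trajectory_data(tiny_long()[1:2, ])
  expect_equal(build_block_design(one, 1)$matrix,
               build_subject_design(c(0, 1), 1))
  # under-sampled subjects warn but are retained
  short <- trajectory_data(data.frame(subject_id = c("a", "b", "b", "b"),
                                      time = c(1, 1, 2, 3),
                                      value = c(1, 2, 3, 4)))
  expect_warning(Xs <- build_block_design(short, 2), "fewer than")
  expect_equal(dim(Xs$matrix), c(4, 6))
})

test_that("times within a subject must be strictly increasing", {
  bad <- data.frame(subject_id = c("a", "a"), time = c(1, 1), value = c(1, 2))
  expect_error(trajectory_data(bad), "strictly increasing")
})

test_that("standardization z-scores observations and nonconstant columns", {
  ds <- trajectory_data(tiny_long())
  std <- standardize_training(ds, build_block_design(ds, 1))
  expect_equal(mean(std$y), 0)
  expect_equal(sd(std$y), 1)
  # pooled time column has mean 0, sd 1; intercept column untouched
  tcol <- unlist(lapply(seq_len(ds$n), function(i)
    std$X$matrix[std$X$row_slices[[i]], std$X$col_slices[[i]][2]]))
  icol <- unlist(lapply(seq_len(ds$n), function(i)
    std$X$matrix[std$X$row_slices[[i]], std$X$col_slices[[i]][1]]))
  expect_equal(mean(tcol), 0, tolerance = 1e-12)
  expect_equal(sd(tcol), 1)
  expect_true(all(icol == 1))
  # degenerate inputs are refused
  flat <- data.frame(subject_id = c("a", "a"), time = 0:1, value = c(2, 2))
  dsf <- trajectory_data(flat)
  expect_error(standardize_training(dsf, build_block_design(dsf, 1)),
               "zero variance")
})

test_that("prediction design reuses training moments without refitting", {
  ds <- trajectory_data(tiny_long())
  std <- standardize_training(ds, build_block_design(ds, 1))
  # a row at a training time standardizes identically to the training row
  row <- standardize_prediction_design(build_subject_design(1.5, 1),
                                       std$params)
  i <- 2  # subject b, second visit is t = 1.5
  expect_equal(as.numeric(row),
               std$X$matrix[std$X$row_slices[[i]][2], std$X$col_slices[[i]]])
  # the mean training time maps to standardized zero
  t_all <- unlist(ds$times)
  row_mu <- standardize_prediction_design(
    build_subject_design(mean(t_all), 1), std$params)
  expect_equal(row_mu[1, 2], 0, tolerance = 1e-12)
  expect_error(standardize_prediction_design(matrix(1, 1, 3), std$params),
               "columns")
})

test_that("destandardization applies the stated affine map to w and Sigma", {
  params <- structure(list(y_mean = 0, y_sd = 2,
                           column_means = c(0, 0), column_sds = c(1, 1),
                           d = 2L), class = "standardization")
  out <- destandardize_parameters(c(1, 1), diag(2), params)
  expect_equal(out$w, c(2, 2))
  # slope variance scales by (y_sd/t_sd)^2
  expect_equal(out$Sigma[2, 2], 4)
  # identity standardization changes nothing
  id <- structure(list(y_mean = 0, y_sd = 1, column_means = c(0, 0),
                       column_sds = c(1, 1), d = 2L),
                  class = "standardization")
  expect_equal(destandardize_parameters(c(0.3, -0.7), NULL, id)$w,
               c(0.3, -0.7))
})

test_that("standardize -> destandardize is the identity round trip", {
  ds <- trajectory_data(tiny_long())
  std <- standardize_training(ds, build_block_design(ds, 1))
  # observations round-trip
  y_back <- destandardize_predictions(std$y, NULL, std$params)$mean
  expect_equal(y_back, stacked_values(ds), tolerance = 1e-10)
  # raw-space parameters -> standardized space -> back
  map <- trajmtl:::destandardization_map(std$params)
  w_raw <- c(2, -1, 0.5, 0.3, -4, 1.2)
  W <- matrix(w_raw, nrow = 2)
  w_tilde <- as.vector(solve(map$L) %*% (W - map$c))
  expect_equal(destandardize_parameters(w_tilde, NULL, std$params)$w,
               w_raw, tolerance = 1e-10)
})

test_that("OLS after standardization matches OLS on raw data per subject", {
  set.seed(21)
  long <- data.frame(subject_id = rep(sprintf("s%d", 1:6), each = 4),
                     time = as.vector(replicate(6, sort(runif(4, 0, 10)))),
                     value = rnorm(24, -3, 2))
  ds <- trajectory_data(long)
  std <- standardize_training(ds, build_block_design(ds, 1))
  raw <- ols_fit(ds, 1)
  w_std <- numeric(0)
  for (i in seq_len(ds$n)) {
    Xi <- std$X$matrix[std$X$row_slices[[i]], std$X$col_slices[[i]]]
    w_std <- c(w_std, stats::lm.fit(Xi, std$y[std$X$row_slices[[i]]])$coefficients)
  }
  w_back <- destandardize_parameters(w_std, NULL, std$params)$w
  expect_equal(w_back, as.vector(raw$coefficients), tolerance = 1e-8)
})

test_that("CSV round trip preserves the dataset", {
  path <- tempfile(fileext = ".csv")
  write.csv(tiny_long(), path, row.names = FALSE)
  ds <- read_trajectory_csv(path)
  expect_equal(ds$n, 3)
  expect_equal(ds$m, 7)
  expect_equal(ds$values[["b"]], c(6, 5, 4))
  unlink(path)
})
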