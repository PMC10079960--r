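test_that("FVE matches hand arithmetic and flags degenerate input", {
  y <- c(1, 2, 3, 4, 5)
  expect_equal(compute_fve(y, y), 1)
  expect_equal(compute_fve(rep(mean(y), 5), y), 0)
  pred <- c(1.5, 1.5, 3.5, 3.5, 5)
  expect_equal(compute_fve(pred, y),
               1 - stats::var(y - pred) / stats::var(y))
  expect_warning(f <- compute_fve(y, rep(2, 5)), "zero variance")
  expect_true(is.na(f))
  expect_error(compute_fve(y, y[-1]), "equal length")
})

test_that("folds are balanced, chunk-aligned and trial-stratified", {
  fx <- make_encoding_fixture(n_trials = 40, seed = 29, noise_sigma = 0.1)
  fold <- assign_cv_folds(fx$design, n_folds = 50, seed = 1)
  ## chunks are never split across folds
  expect_true(all(tapply(fold, fx$design$chunk_id,
                         function(f) length(unique(f))) == 1))
  ## fold frame counts within +/- 20% of the mean
  counts <- table(fold)
  expect_length(counts, 50)
  expect_true(all(abs(counts - mean(counts)) <= 0.2 * mean(counts)))
  ## each trial's chunks are spread over many distinct folds
  per_trial <- tapply(fold, fx$design$trial_id,
                      function(f) length(unique(f)))
  expect_gt(min(per_trial), 10)
  ## deterministic under the seed
  expect_identical(fold, assign_cv_folds(fx$design, n_folds = 50, seed = 1))
  expect_error(assign_cv_folds(fx$design, n_folds = 1e6), "chunks")
})

test_that("lambda selection obeys the one-standard-error rule", {
  fx <- make_encoding_fixture(n_trials = 40, seed = 37, noise_sigma = 0.15)
  fit <- fit_encoding(fx$design, fx$trace, seed = 2)
  i_max <- which.max(fit$cv_fve_mean)
  expect_gte(fit$lambda_selected, fit$lambda_path[i_max])
  expect_gte(fit$cv_fve_mean[fit$lambda_index],
             max(fit$cv_fve_mean) - fit$cv_fve_sd[i_max])
  ## no larger lambda on the path also satisfies the rule
  if (fit$lambda_index > 1) {
    expect_true(all(fit$cv_fve_mean[seq_len(fit$lambda_index - 1)] <
                      max(fit$cv_fve_mean) - fit$cv_fve_sd[i_max]))
  }
})

test_that("a noiseless trace is recovered nearly perfectly", {
  fx <- make_encoding_fixture(
    n_trials = 50, seed = 43,
    tuned = list(o_plus = list(shape = "brief", amplitude = 1)),
    noise_sigma = 0
  )
  fit <- fit_encoding(fx$design, fx$trace, seed = 3)
  expect_gte(fit$fve, 0.95)
  k_hat <- extract_kernel(fit, "o_plus")
  k_true <- true_kernel(fx$truth, "o_plus")
  expect_lte(max(abs(k_hat$value - k_true$value)),
             0.05 * max(abs(k_true$value)))
})

test_that("pure noise yields chance-level cross-validated FVE", {
  fx <- make_encoding_fixture(n_trials = 40, seed = 47, tuned = list(),
                              noise_sigma = 0.2)
  fit <- fit_encoding(fx$design, fx$trace, seed = 4)
  expect_lte(fit$fve_cv, 0.01)
})

test_that("the intercept-only limit predicts the mean and explains nothing", {
  fx <- make_encoding_fixture(n_trials = 40, seed = 53, noise_sigma = 0.2)
  empty <- drop_predictors(fx$design,
                           groups = c("pre_outcome", "outcome",
                                      "internal_value", "movement"))
  expect_equal(ncol(empty$X), 0L)
  fit0 <- fit_encoding(empty, fx$trace, fold_id = assign_cv_folds(fx$design,
                                                                  50, 1))
  expect_length(fit0$coefficients, 0)
  expect_equal(fit0$intercept, mean(fx$trace$values))
  expect_lte(fit0$fve_cv, 0.01)
})

test_that("tuning indices separate true from null predictors", {
  fx <- make_encoding_fixture(
    n_trials = 50, seed = 59,
    tuned = list(o_plus = list(shape = "brief", amplitude = 0.9)),
    noise_sigma = 0.3  # effect peak is 3x the noise SD
  )
  fit <- fit_encoding(fx$design, fx$trace, seed = 5)
  ## dropping nothing is a no-op
  t0 <- tuning_index(fit, fx$design, fx$trace)
  expect_equal(t0$index, 0)
  ## a null predictor contributes nothing
  t_null <- tuning_index(fit, fx$design, fx$trace, predictors = "init")
  expect_lt(t_null$index, 0.01)
  ## the reward-tethered effect carries at least the 5% threshold at the
  ## group level (with a fixed choice-to-outcome delay, a single outcome
  ## kernel is spanned by the choice kernel plus the complementary outcome
  ## kernel, so grouped indices are the identifiable quantity)
  t_true <- tuning_index(fit, fx$design, fx$trace, groups = "outcome",
                         predictors = c("rpe_plus", "rpe_minus"))
  expect_gte(t_true$index, 0.05)
  expect_true(t_true$tuned)
  expect_true(t_true$task_tuned)
})

test_that("kernel extraction is the basis-weighted sum of coefficients", {
  fx <- make_encoding_fixture(n_trials = 40, seed = 61, noise_sigma = 0.1)
  fit <- fit_encoding(fx$design, fx$trace, seed = 6)
  ## zero coefficients give a zero kernel
  fit0 <- fit
  fit0$coefficients[fit0$col_meta$predictor == "choice"] <- 0
  expect_true(all(extract_kernel(fit0, "choice")$value == 0))
  ## continuous predictors have no kernel
  expect_error(extract_kernel(fit, "dQ"), "continuous")
  expect_error(extract_kernel(fit, "nonexistent"), "unknown")
  ## manual reconstruction at a few lags
  k <- extract_kernel(fit, "o_plus", n_points = 5)
  sp <- fit$specs$o_plus$basis
  gam <- fit$coefficients[fit$col_meta$predictor == "o_plus"]
  expect_equal(k$value,
               as.numeric(build_spline_basis(sp, k$lag) %*% gam))
})

test_that("kernel recovery improves monotonically with SNR", {
  sigmas <- c(0.6, 0.2, 0.05)  # decreasing noise = increasing SNR
  med_rmse <- vapply(sigmas, function(sg) {
    errs <- vapply(1:4, function(i) {
      fx <- make_encoding_fixture(
        n_trials = 30, seed = 100 * i, noise_sigma = sg,
        tuned = list(o_plus = list(shape = "brief", amplitude = 0.8))
      )
      fit <- fit_encoding(fx$design, fx$trace, seed = i, n_lambda = 30)
      k_hat <- extract_kernel(fit, "o_plus")
      k_true <- true_kernel(fx$truth, "o_plus")
      sqrt(mean((k_hat$value - k_true$value)^2)) / max(abs(k_true$value))
    }, numeric(1))
    stats::median(errs)
  }, numeric(1))
  expect_true(all(diff(med_rmse) < 0))
})

test_that("overlapping event types are separated by the model", {
  ## outcome follows choice by 0.5 s on every trial: their kernels overlap
  fx <- make_encoding_fixture(
    n_trials = 50, seed = 67,
    tuned = list(choice = list(shape = "brief", amplitude = 0.8),
                 o_plus = list(shape = "persistent", amplitude = 0.5)),
    noise_sigma = 0.05
  )
  fit <- fit_encoding(fx$design, fx$trace, seed = 7)
  for (p in c("choice", "o_plus")) {
    k_hat <- extract_kernel(fit, p)
    k_true <- true_kernel(fx$truth, p)
    expect_lt(max(abs(k_hat$value - k_true$value)),
              0.25 * max(abs(k_true$value)))
  }
})
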