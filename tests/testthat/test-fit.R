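test_that("a noiseless linear signal is recovered with high r2", {
  tab <- make_toy_table(n_patients = 100, seed = 42,
                        outcome_fun = function(x) 80 - 40 * x[, 1])
  fit <- fit_structfunc(tab, n_replicates = 20, seed = 3, num_trees = 100)
  expect_gte(fit$summary$r2, 0.9)
  # the signal-bearing predictor dominates importance
  expect_equal(names(which.max(fit$importance)), "RPE_LOSS_r01_c01")
})

test_that("permuted outcomes score near zero and MAE matches the null scale", {
  set.seed(8)
  tab <- make_toy_table(n_patients = 150, seed = 9,
                        outcome_fun = function(x) 80 - 40 * x[, 1])
  tab$outcome <- sample(tab$outcome)        # destroy the signal
  fit <- fit_structfunc(tab, n_replicates = 100, seed = 4, num_trees = 100)
  expect_lte(fit$summary$r2, 0.1)
  mad0 <- mean(abs(tab$outcome - mean(tab$outcome)))
  expect_lt(abs(fit$summary$mae - mad0) / mad0, 0.1)
})

test_that("patient-level splits never leak a patient across sides", {
  tab <- make_toy_table(n_patients = 40, seed = 5)
  fit <- fit_structfunc(tab, n_replicates = 100, seed = 6, num_trees = 5)
  for (s in fit$splits)
    expect_length(intersect(s$train_units, s$test_units), 0)
})

test_that("results are reproducible under a fixed seed", {
  tab <- make_toy_table(n_patients = 30, seed = 7)
  f1 <- fit_structfunc(tab, n_replicates = 5, seed = 11, num_trees = 20)
  f2 <- fit_structfunc(tab, n_replicates = 5, seed = 11, num_trees = 20)
  expect_identical(f1$replicates, f2$replicates)
  expect_identical(f1$importance, f2$importance)
  f3 <- fit_structfunc(tab, n_replicates = 5, seed = 12, num_trees = 20)
  expect_false(identical(f1$replicates$r2, f3$replicates$r2))
})

test_that("summary quartiles bracket the median and MAE stays in letters", {
  tab <- make_toy_table(n_patients = 30, seed = 13, noise_sd = 10)
  fit <- fit_structfunc(tab, n_replicates = 10, seed = 1, num_trees = 20)
  s <- fit$summary
  expect_lte(s$mae_q25, s$mae)
  expect_lte(s$mae, s$mae_q75)
  expect_gte(s$mae, 0)
  expect_lte(s$mae, 100)
  expect_equal(s$n_replicates, 10)
})

test_that("eye-level splitting and the split-only scheme are available", {
  tab <- make_toy_table(n_patients = 25, seed = 14)
  fe <- fit_structfunc(tab, n_replicates = 5, seed = 2, num_trees = 10,
                       split_unit = "eye", scheme = "split_only")
  expect_equal(fe$hyperparameters$scheme, "split_only")
  for (s in fe$splits) {
    expect_length(intersect(s$train_units, s$test_units), 0)
    # split_only partitions: every eye is on exactly one side
    expect_equal(length(s$train_units) + length(s$test_units), nrow(tab))
  }
})

test_that("one-eye-per-patient sensitivity keeps one row per patient", {
  # unilateral cohort: selection is a no-op, result matches the plain fit
  uni <- make_toy_table(n_patients = 30, eyes_per_patient = 1, seed = 15)
  f_plain <- fit_structfunc(uni, n_replicates = 5, seed = 3, num_trees = 10)
  f_sens <- sensitivity_one_eye(uni, rule = "first", seed = 3,
                                n_replicates = 5, num_trees = 10)
  expect_identical(f_plain$replicates, f_sens$replicates)

  # 476 eyes / 325 patients: 151 bilateral + 174 unilateral
  set.seed(16)
  mixed <- make_toy_table(n_patients = 325, eyes_per_patient = 1, seed = 16)
  extra <- mixed[1:151, ]
  extra$eye_id <- sprintf("E2%03d", 1:151)
  both <- rbind(mixed, extra)
  attributes(both)[c("column_info", "block_dim", "outcome_name", "extent_mm")] <-
    attributes(mixed)[c("column_info", "block_dim", "outcome_name", "extent_mm")]
  class(both) <- class(mixed)
  expect_equal(nrow(both), 476)
  f <- sensitivity_one_eye(both, rule = "random", seed = 4,
                           n_replicates = 2, num_trees = 5)
  expect_equal(f$n_eyes, 325)
  expect_equal(f$n_patients, 325)
})

test_that("prediction and residuals run against the final forest", {
  tab <- make_toy_table(n_patients = 30, seed = 17,
                        outcome_fun = function(x) 60 - 30 * x[, 2])
  fit <- fit_structfunc(tab, n_replicates = 3, seed = 5, num_trees = 50)
  p <- predict(fit, tab)
  expect_length(p, nrow(tab))
  expect_gt(cor(p, tab$outcome), 0.9)
  expect_equal(residuals(fit, tab), tab$outcome - p)
})
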