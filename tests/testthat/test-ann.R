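# Levenberg-Marquardt training of the linear feed-forward network.

test_that("noiseless linear data is learned to machine-level MSE", {
  data <- make_study_data(noise_sd = 0)
  m <- train_ann(data$cal_spec, data$cal$nominal, ann_config(seed = 3))
  expect_lt(tail(m$history[, "train"], 1), 1e-8)
  pv <- predict(m, data$val_spec)
  expect_lt(max(abs(100 * pv / data$val$nominal - 100)), 0.01)
})

test_that("the purelin-purelin network is exactly an affine map", {
  data <- make_study_data(noise_sd = 0.002, seed = 2)
  m <- train_ann(data$cal_spec, data$cal$nominal, ann_config(seed = 2))
  aff <- ann_as_affine(m)
  direct <- sweep(data$val_spec$absorbance %*% aff$A, 2, aff$c, `+`)
  expect_equal(unname(predict(m, data$val_spec)), unname(direct),
               tolerance = 1e-10)
})

test_that("on full-rank data the converged network equals the OLS fit", {
  fr <- make_full_rank_data(n = 40, p = 6, q = 3, noise_sd = 0.05, seed = 7)
  newd <- make_full_rank_data(n = 15, p = 6, q = 3, seed = 11)
  m <- train_ann(fr$spectra, fr$Y,
                 ann_config(n_hidden = 6, max_epochs = 400, max_fail = 400,
                            seed = 5, split_fractions = c(1, 0, 0)))
  oracle <- ols_oracle_predict(fr$X, fr$Y, newd$X)
  expect_lt(max(abs(predict(m, newd$spectra) - oracle)), 1e-4)
})

test_that("training MSE decreases across accepted LM steps", {
  data <- make_study_data(noise_sd = 0.002, seed = 5)
  m <- train_ann(data$cal_spec, data$cal$nominal, ann_config(seed = 5))
  expect_true(all(diff(m$history[, "train"]) <= 1e-12))
})

test_that("weight initialization and splits are seed-reproducible", {
  data <- make_study_data(noise_sd = 0.002, seed = 8)
  m1 <- train_ann(data$cal_spec, data$cal$nominal, ann_config(seed = 9))
  m2 <- train_ann(data$cal_spec, data$cal$nominal, ann_config(seed = 9))
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$idx_train, m2$idx_train)
  m3 <- train_ann(data$cal_spec, data$cal$nominal, ann_config(seed = 10))
  expect_false(identical(m1$idx_train, m3$idx_train))
})

test_that("the learned map approximates the Beer-Lambert pseudo-inverse", {
  data <- make_study_data(noise_sd = 0)
  m <- train_ann(data$cal_spec, data$cal$nominal, ann_config(seed = 3))
  aff <- ann_as_affine(m)
  win <- colnames(data$cal_spec$absorbance)
  S_true <- t(data$pure$unit_absorptivity[, win])
  pinv_map <- S_true %*% solve(crossprod(S_true))
  for (j in 1:4) expect_gt(cor(aff$A[, j], pinv_map[, j]), 0.99)
})

test_that("training diagnostics describe the splits and the best epoch", {
  data <- make_study_data(noise_sd = 0)
  m <- train_ann(data$cal_spec, data$cal$nominal, ann_config(seed = 4))
  td <- training_diagnostics(m)
  expect_setequal(td$split, c("train", "validation", "test"))
  expect_true(all(abs(td$slope - 1) < 1e-6))
  expect_true(all(abs(td$intercept) < 1e-4))
  expect_true(all(td$r > 1 - 1e-9))
  # best epoch minimizes the recorded validation curve
  expect_equal(m$best_epoch,
               unname(which.min(m$history[, "validation"])))
})

test_that("noisy recoveries are on the order of the published ANN column", {
  sds <- sapply(1:4, function(seed) {
    data <- make_study_data(noise_sd = 0.002, seed = seed)
    m <- train_ann(data$cal_spec, data$cal$nominal, ann_config(seed = seed))
    recovery_stats(predict(m, data$val_spec), data$val$nominal)$sd
  })
  expect_true(all(rowMeans(sds) < 2))
  means <- sapply(1:4, function(seed) {
    data <- make_study_data(noise_sd = 0.002, seed = seed)
    m <- train_ann(data$cal_spec, data$cal$nominal, ann_config(seed = seed))
    recovery_stats(predict(m, data$val_spec), data$val$nominal)$mean
  })
  expect_true(all(rowMeans(means) > 98 & rowMeans(means) < 102))
})

test_that("split sizing is validated", {
  data <- make_study_data(noise_sd = 0)
  tiny <- quatspec:::new_spectra_set(
    data$cal_spec$wavelengths_nm,
    data$cal_spec$absorbance[1:8, , drop = FALSE],
    data$cal_spec$sample_ids[1:8])
  expect_error(train_ann(tiny, data$cal$nominal[1:8, ], ann_config(seed = 1)),
               "fewer than 3")
  expect_error(ann_config(split_fractions = c(0.5, 0.3, 0.3)), "sum to 1")
})
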