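# MCR-ALS: constrained alternating least squares and its figures of merit.

test_that("in-package NNLS agrees with an independent solver", {
  skip_if_not_installed("pracma")
  set.seed(10)
  for (rep in 1:20) {
    A <- matrix(runif(12 * 4), 12, 4)
    b <- as.numeric(A %*% runif(4, -0.5, 1.5) + rnorm(12, 0, 0.05))
    ours <- quatspec:::nnls_solve(A, b)
    ref <- pracma::lsqnonneg(A, b)$x
    expect_equal(ours, ref, tolerance = 1e-8)
    expect_true(all(ours >= 0))
  }
})

test_that("lack of fit and explained variance obey their definitions", {
  set.seed(2)
  C <- matrix(runif(20), 5, 4); S <- matrix(runif(32), 8, 4)
  D <- tcrossprod(C, S)
  expect_equal(lack_of_fit(D, C, S), 0)
  expect_equal(explained_variance(D, C, S), 100)
  expect_equal(lack_of_fit(D, 0 * C, S), 100)
  # algebraic identity R2 = 100 - LOF^2/100 for arbitrary mismatched inputs
  C2 <- C + matrix(rnorm(20, 0, 0.2), 5, 4)
  lof <- lack_of_fit(D, C2, S)
  expect_equal(explained_variance(D, C2, S), 100 - lof^2 / 100,
               tolerance = 1e-12)
  expect_error(lack_of_fit(0 * D, C, S), "all-zero")
})

test_that("true-spectra initialization is a fixed point on noiseless data", {
  data <- make_study_data(noise_sd = 0)
  win <- colnames(data$cal_spec$absorbance)
  S_true <- t(data$pure$unit_absorptivity[, win])
  m <- fit_mcr_als(data$cal_spec, data$cal$nominal,
                   mcr_config(init = "provided-spectra"), S_init = S_true)
  expect_lte(m$n_iter, 2)
  expect_lt(m$lof, 1e-6)
})

test_that("purest-variable start resolves the true profiles on clean data", {
  data <- make_study_data(noise_sd = 0)
  m <- fit_mcr_als(data$cal_spec, data$cal$nominal)
  expect_true(all(m$S >= 0))
  expect_true(min(m$C_als) >= -1e-10)
  expect_gt(m$r2, 99.999)
  win <- colnames(data$cal_spec$absorbance)
  S_true <- t(data$pure$unit_absorptivity[, win])
  perm <- match_components(m$S, S_true)
  expect_true(all(diag(cor(S_true, m$S[, perm])) > 0.999))
  # correlation constraint anchors concentrations in real units
  expect_lt(max(abs(m$C - data$cal$nominal)), 1e-3)
})

test_that("noisy fit converges with unit-slope concentration anchoring", {
  data <- make_study_data(noise_sd = 0.002, seed = 3)
  m <- fit_mcr_als(data$cal_spec, data$cal$nominal)
  expect_lt(m$n_iter, m$config$max_iter)
  expect_lt(m$lof, 1)
  expect_equal(m$r2, 100 - m$lof^2 / 100, tolerance = 1e-10)
  for (a in analytes()) {
    sl <- coef(lm(m$C[, a] ~ data$cal$nominal[, a]))[2]
    expect_lt(abs(sl - 1), 0.02)
  }
  # resolved spectra remain close to truth under noise, after matching
  win <- colnames(data$cal_spec$absorbance)
  S_true <- t(data$pure$unit_absorptivity[, win])
  perm <- match_components(m$S, S_true)
  expect_true(all(diag(cor(S_true, m$S[, perm])) > 0.999))
})

test_that("one-by-one augmented prediction recovers test concentrations", {
  data <- make_study_data(noise_sd = 0)
  m <- fit_mcr_als(data$cal_spec, data$cal$nominal)
  # duplicating a calibration row must reproduce its nominal values
  dup <- quatspec:::new_spectra_set(
    data$cal_spec$wavelengths_nm,
    data$cal_spec$absorbance[7, , drop = FALSE], "dup")
  p <- predict_mcr(m, dup, data$cal_spec, data$cal$nominal)
  expect_lt(max(abs(p - data$cal$nominal[7, ])), 1e-4)
  # noiseless validation mixtures: recovery 100 +/- 0.1%
  pv <- predict_mcr(m, data$val_spec, data$cal_spec, data$cal$nominal)
  expect_lt(max(abs(100 * pv / data$val$nominal - 100)), 0.1)
})

test_that("noisy validation recoveries sit on the published scale", {
  recs <- sapply(1:3, function(seed) {
    data <- make_study_data(noise_sd = 0.002, seed = seed)
    m <- fit_mcr_als(data$cal_spec, data$cal$nominal)
    pv <- predict_mcr(m, data$val_spec, data$cal_spec, data$cal$nominal)
    colMeans(100 * pv / data$val$nominal)
  })
  expect_true(all(rowMeans(recs) > 98 & rowMeans(recs) < 102))
})

test_that("constraint configuration is validated", {
  expect_error(mcr_config(constraints = "unimodality"), "unknown constraint")
  expect_error(mcr_config(convergence_tol = 0), "positive")
  data <- make_study_data(noise_sd = 0)
  expect_error(fit_mcr_als(data$cal_spec, data$cal$nominal,
                           mcr_config(init = "provided-spectra")),
               "S_init")
})
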