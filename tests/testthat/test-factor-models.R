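# PCR / PLS calibration engines and cross-validation.

test_that("noiseless rank-4 data is fit exactly with four latent variables", {
  data <- make_study_data(noise_sd = 0)
  for (fit_fun in list(fit_pcr, fit_pls)) {
    m <- fit_fun(data$cal_spec, data$cal$nominal, 4)
    fitted <- predict(m, data$cal_spec)
    expect_lt(max(abs(fitted - data$cal$nominal)), 1e-6)
    expect_lt(unname(rmse(fitted, data$cal$nominal, "RMSEC")), 1e-6)
    # validation recoveries 100 +/- 0.01%
    pv <- predict(m, data$val_spec)
    expect_lt(max(abs(100 * pv / data$val$nominal - 100)), 0.01)
  }
})

test_that("at full rank PCR, PLS and the OLS oracle coincide", {
  fr <- make_full_rank_data(n = 40, p = 6, q = 3, noise_sd = 0.05)
  newd <- make_full_rank_data(n = 15, p = 6, q = 3, noise_sd = 0, seed = 11)
  oracle <- ols_oracle_predict(fr$X, fr$Y, newd$X)
  for (fit_fun in list(fit_pcr, fit_pls)) {
    m <- fit_fun(fr$spectra, fr$Y, n_lv = 6)
    expect_lt(max(abs(predict(m, newd$spectra) - oracle)), 1e-6)
  }
})

test_that("single-response PLS matches an independent PLS1 implementation", {
  fr <- make_full_rank_data(n = 30, p = 8, q = 1, noise_sd = 0.1, seed = 3)
  newd <- make_full_rank_data(n = 12, p = 8, q = 1, seed = 13)
  for (k in c(2, 4)) {
    m <- fit_pls(fr$spectra, fr$Y, n_lv = k, algorithm = "pls1")
    oracle <- pls1_oracle(fr$X, fr$Y[, 1], k)
    expect_lt(max(abs(predict(m, newd$spectra) -
                        oracle$predict(newd$X))), 1e-8)
  }
  expect_error(fit_pls(fr$spectra, cbind(fr$Y, fr$Y), 2, algorithm = "pls1"),
               "single-column")
})

test_that("model structure invariants hold", {
  data <- make_study_data(noise_sd = 0.002, seed = 2)
  m_pcr <- fit_pcr(data$cal_spec, data$cal$nominal, 4)
  # orthonormal PCA loadings, orthogonal scores
  expect_equal(crossprod(m_pcr$x_loadings), diag(4), tolerance = 1e-10)
  TT <- crossprod(m_pcr$x_scores)
  expect_lt(max(abs(TT - diag(diag(TT)))), 1e-8)
  # explained X-variance non-increasing by component
  expect_true(all(diff(diag(TT)) <= 1e-8))
  m_pls <- fit_pls(data$cal_spec, data$cal$nominal, 4)
  expect_equal(crossprod(m_pls$pls_weights), diag(4), tolerance = 1e-10)
  # predictions from scores/loadings equal predictions from B
  Xc <- sweep(data$cal_spec$absorbance, 2, m_pls$x_means)
  via_b <- Xc %*% m_pls$coefficients
  via_t <- m_pls$x_scores %*% t(m_pls$y_loadings)
  expect_lt(max(abs(via_b - via_t)), 1e-8)
  # RMSEC non-increasing with more latent variables
  rmsec <- vapply(1:6, function(k) {
    m <- fit_pcr(data$cal_spec, data$cal$nominal, k)
    unname(rmse(predict(m, data$cal_spec), data$cal$nominal, "RMSEC"))
  }, 0)
  expect_true(all(diff(rmsec) <= 1e-10))
})

test_that("leave-one-out cross-validation recovers the true rank", {
  data <- make_study_data(noise_sd = 0)
  Y <- data$cal$nominal
  for (method in c("pcr", "pls")) {
    cv <- loo_cross_validate(data$cal_spec, Y, max_lv = 6, method = method)
    expect_equal(cv$selected_lv, 4)
    expect_true(all(cv$rmsecv >= 0, na.rm = TRUE))
  }
  # 0-LV model: closed form sqrt(n/(n-1)) * sample SD (fold recentering)
  cv <- loo_cross_validate(data$cal_spec, Y, max_lv = 2, method = "pcr")
  n <- nrow(Y)
  expect_equal(unname(cv$rmsecv["0", ]),
               unname(apply(Y, 2, sd) * sqrt(n / (n - 1))),
               tolerance = 1e-10)
})

test_that("extra latent variables do not improve true prediction error", {
  clean <- make_study_data(noise_sd = 0)
  err <- rowMeans(sapply(4:8, function(seed) {
    data <- make_study_data(noise_sd = 0.002, seed = seed)
    vapply(4:8, function(k) {
      m <- fit_pcr(data$cal_spec, data$cal$nominal, k)
      unname(rmse(predict(m, clean$val_spec), data$val$nominal))
    }, 0)
  }))
  # averaged over noise draws, components past the true rank only add noise
  expect_lt(err[1], min(err[-1]) + 0.1 * err[1])
})

test_that("noisy validation recoveries sit on the published scale", {
  recs <- sapply(1:4, function(seed) {
    data <- make_study_data(noise_sd = 0.002, seed = seed)
    m <- fit_pls(data$cal_spec, data$cal$nominal, 4)
    colMeans(100 * predict(m, data$val_spec) / data$val$nominal)
  })
  expect_true(all(rowMeans(recs) > 98 & rowMeans(recs) < 102))
})

test_that("factor models serialize to JSON and back", {
  data <- make_study_data(noise_sd = 0.002, seed = 6)
  m <- fit_pls(data$cal_spec, data$cal$nominal, 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_factor_model(m, path)
  m2 <- read_factor_model(path)
  expect_equal(predict(m2, data$val_spec), predict(m, data$val_spec),
               tolerance = 1e-12)
})
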