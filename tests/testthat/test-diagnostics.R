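# Figures of merit, Durbin-Watson, EJCR and method comparison.

test_that("recovery statistics match a streaming oracle and exact cases", {
  set.seed(1)
  found <- matrix(runif(20, 3, 12), 5, 4, dimnames = list(NULL, analytes()))
  nominal <- matrix(runif(20, 3, 12), 5, 4)
  rs <- recovery_stats(found, nominal)
  for (j in 1:4) {
    w <- welford_stats(100 * found[, j] / nominal[, j])
    expect_equal(unname(rs$mean[j]), w$mean, tolerance = 1e-10)
    expect_equal(unname(rs$sd[j]), w$sd, tolerance = 1e-10)
  }
  exact <- recovery_stats(nominal, nominal)
  expect_true(all(exact$recovery == 100))
  expect_true(all(exact$sd == 0))
  expect_error(recovery_stats(found, 0 * nominal), "positive")
})

test_that("rmse has its closed forms and matches a loop oracle", {
  set.seed(2)
  found <- matrix(rnorm(20, 10), 5, 4)
  expect_equal(unname(rmse(found, found)), 0)
  expect_equal(unname(rmse(found + 0.37, found)), 0.37)
  ref <- found + matrix(rnorm(20, 0, 0.5), 5, 4)
  acc <- 0
  for (i in 1:5) for (j in 1:4) acc <- acc + (found[i, j] - ref[i, j])^2
  expect_equal(unname(rmse(found, ref)), sqrt(acc / 20), tolerance = 1e-12)
})

test_that("Durbin-Watson statistic matches hand-computed cases", {
  a <- 0.7
  alt <- a * rep(c(1, -1), 5)                   # perfectly alternating, n = 10
  expect_equal(durbin_watson(alt, n_perm = 50)$dw, 3.6)
  expect_equal(durbin_watson(rep(a, 8), n_perm = 50)$dw, 0)
  expect_error(durbin_watson(rep(0, 5)), "all-zero")
  expect_error(durbin_watson(c(1, 2)), "at least 3")
})

test_that("strong residual autocorrelation yields a small permutation p", {
  set.seed(3)
  trending <- cumsum(rnorm(25))                  # heavily autocorrelated
  res <- durbin_watson(trending, n_perm = 999, seed = 4)
  expect_lt(res$dw, 1)
  expect_lt(res$p, 0.05)
})

test_that("permutation p-values are uniform under the i.i.d. null", {
  set.seed(11)
  pvals <- vapply(1:400, function(s) {
    durbin_watson(rnorm(25), n_perm = 199, seed = s)$p
  }, 0)
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("t and F from raw values equal those from their own summaries", {
  set.seed(4)
  g1 <- rnorm(5, 100, 1.2); g2 <- rnorm(5, 99.4, 0.8)
  raw <- compare_methods(g1, g2)
  summ <- compare_methods(list(mean = mean(g1), sd = sd(g1), n = 5),
                          list(mean = mean(g2), sd = sd(g2), n = 5))
  expect_equal(raw$t, summ$t, tolerance = 1e-12)
  expect_equal(raw$F, summ$F, tolerance = 1e-12)
  expect_gte(raw$F, 1)
  # criticals at 95%, two five-sample groups
  expect_equal(raw$t_critical, qt(0.975, 8), tolerance = 1e-12)
  expect_equal(raw$F_critical, qf(0.95, 4, 4), tolerance = 1e-12)
  expect_equal(round(raw$F_critical, 2), 6.39)
  same <- compare_methods(g1, g1)
  expect_equal(same$t, 0)
  expect_equal(same$F, 1)
  expect_error(compare_methods(rep(1, 4), rep(1, 4)), "zero variance")
})

test_that("EJCR contains the ideal point exactly when it should", {
  nominal <- c(4, 8, 12, 16, 20)
  expect_true(ejcr(nominal, nominal)$contains_ideal)      # exact fit
  set.seed(5)
  noisy_ok <- nominal + rnorm(5, 0, 0.15)
  expect_true(ejcr(noisy_ok, nominal)$contains_ideal)     # unbiased
  biased <- 2 * nominal + rnorm(5, 0, 0.01)
  expect_false(ejcr(biased, nominal)$contains_ideal)      # gross slope bias
  expect_error(ejcr(c(1, 2, 3), rep(5, 3)), "all equal")
})

test_that("EJCR membership equals a brute-force quadratic-form oracle", {
  set.seed(6)
  nominal <- seq(2, 20, length.out = 8)
  predicted <- 0.97 * nominal + 0.3 + rnorm(8, 0, 0.2)
  res <- ejcr(predicted, nominal)
  # independent route: lm for the estimate, explicit form for the bound
  fit <- lm(predicted ~ nominal)
  X <- cbind(1, nominal)
  s2 <- sum(residuals(fit)^2) / (8 - 2)
  bound <- 2 * s2 * qf(0.95, 2, 6)
  grid <- expand.grid(int = seq(-2, 2, length.out = 41),
                      slope = seq(0, 2, length.out = 41))
  member_oracle <- apply(grid, 1, function(g) {
    d <- coef(fit) - c(g[["int"]], g[["slope"]])
    as.numeric(t(d) %*% crossprod(X) %*% d) <= bound
  })
  member_pkg <- apply(grid, 1, function(g) {
    d <- c(res$intercept, res$slope) - c(g[["int"]], g[["slope"]])
    as.numeric(t(d) %*% res$XtX %*% d) <= res$rhs
  })
  expect_identical(member_pkg, member_oracle)
  expect_equal(res$contains_ideal,
               member_oracle[grid$int == 0 & grid$slope == 1])
})

test_that("EJCR area shrinks with residual variance on a fixed design", {
  set.seed(7)
  nominal <- seq(2, 20, length.out = 10)
  z <- rnorm(10)
  areas <- vapply(c(1, 0.5, 0.2, 0.05), function(eps)
    ejcr(nominal + eps * z, nominal)$area, 0)
  expect_true(all(diff(areas) < 0))
})

test_that("regression figures of merit are coherent on near-perfect data", {
  set.seed(8)
  nominal <- c(4, 8, 12, 16, 20)
  predicted <- nominal + rnorm(5, 0, 0.05)
  fom <- regression_fom(predicted, nominal, n_perm = 199)
  expect_lt(abs(fom$slope - 1), 0.05)
  expect_gt(fom$r, 0.999)
  expect_true(fom$dw >= 0 && fom$dw <= 4)
})
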