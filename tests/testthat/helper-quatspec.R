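# Shared fixtures and independent oracles for the test suite.

# Canonical synthetic study data: published design, packaged band table.
make_study_data <- function(noise_sd = 0, seed = 1, val_seed = seed + 100) {
  design <- generate_design()
  pure <- default_pure_spectra()
  cal <- design_subset(design, "calibration")
  val <- design_subset(design, "validation")
  list(design = design, pure = pure, cal = cal, val = val,
       cal_spec = select_window(simulate_spectra(cal, pure, noise_sd, seed)),
       val_spec = select_window(simulate_spectra(val, pure, noise_sd,
                                                 val_seed)))
}

# Small full-column-rank instance (more samples than wavelengths) where the
# ordinary least-squares fit is unique, for PCR/PLS/ANN oracle equivalence.
make_full_rank_data <- function(n = 40, p = 6, q = 3, noise_sd = 0, seed = 7) {
  set.seed(seed)
  wl <- seq(240, 240 + p - 1)
  X <- matrix(stats::runif(n * p, 0.05, 1.2), n, p)
  B <- matrix(stats::rnorm(p * q), p, q)
  Y <- X %*% B + matrix(5, n, q)
  if (noise_sd > 0) Y <- Y + matrix(stats::rnorm(n * q, 0, noise_sd), n, q)
  colnames(Y) <- paste0("Y", seq_len(q))
  spec <- quatspec:::new_spectra_set(wl, X, sprintf("s%02d", seq_len(n)))
  list(spectra = spec, X = X, Y = Y)
}

# OLS oracle: per-response lm() of Y on all X columns; returns prediction fn.
ols_oracle_predict <- function(X, Y, X_new) {
  sapply(seq_len(ncol(Y)), function(j) {
    fit <- stats::lm(Y[, j] ~ X)
    cbind(1, X_new) %*% stats::coef(fit)
  })
}

# Independent single-response NIPALS PLS1 (textbook form, coded separately
# from the package's PLS2 path).
pls1_oracle <- function(X, y, n_lv) {
  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2, xm); f <- y - ym
  W <- NULL; P <- NULL; Q <- NULL
  for (a in seq_len(n_lv)) {
    w <- crossprod(E, f); w <- w / sqrt(sum(w^2))
    t <- E %*% w
    p <- crossprod(E, t) / sum(t^2)
    q <- sum(f * t) / sum(t^2)
    E <- E - t %*% t(p); f <- f - q * t
    W <- cbind(W, w); P <- cbind(P, p); Q <- c(Q, q)
  }
  b <- W %*% solve(crossprod(P, W), Q)
  list(predict = function(X_new) sweep(X_new, 2, xm) %*% b + ym)
}

# Streaming (Welford) mean and sample SD, an independent route to the
# recovery summary statistics.
welford_stats <- function(x) {
  m <- 0; s <- 0; n <- 0
  for (v in x) {
    n <- n + 1
    d <- v - m
    m <- m + d / n
    s <- s + d * (v - m)
  }
  list(mean = m, sd = sqrt(s / (n - 1)))
}

# Published validation-set recovery columns used as worked examples
# (paracetamol, PCR and ANN engines).
table2_pcr_para <- c(98.88, 102.54, 99.91, 99.40, 99.81)
table2_ann_para <- c(99.83, 100.00, 100.00, 101.16, 100.00)
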