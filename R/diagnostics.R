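# Validation figures of merit and between-method statistics.

#' Recovery statistics
#'
#' Elementwise recovery % = 100 found / nominal, with per-analyte mean,
#' sample SD (n - 1 denominator) and RSD. The SD column is the one comparable
#' with published recovery tables for this mixture.
#'
#' @param found predicted concentrations (vector or samples x analytes).
#' @param nominal reference concentrations, same shape, strictly positive.
#' @return A `recovery_table`: `recovery` (per-sample %), `mean`, `sd`, `rsd`.
#' @export
recovery_stats <- function(found, nominal) {
  found <- as.matrix(found); nominal <- as.matrix(nominal)
  qs_check(all(dim(found) == dim(nominal)),
           "found and nominal must have the same shape")
  qs_check(all(nominal > 0), "nominal concentrations must be positive")
  rec <- 100 * found / nominal
  m <- colMeans(rec)
  s <- apply(rec, 2, stats::sd)
  structure(list(recovery = rec, mean = m, sd = s, rsd = 100 * s / m),
            class = "recovery_table")
}

#' @export
print.recovery_table <- function(x, ...) {
  cat("<recovery_table> ", nrow(x$recovery), " samples\n", sep = "")
  print(round(rbind(mean = x$mean, sd = x$sd), 2))
  invisible(x)
}

#' Root mean squared error
#'
#' RMSEC over the calibration set or RMSEP over the prediction (validation)
#' set: sqrt(sum((found - reference)^2) / n), n the number of entries.
#'
#' @param found,reference equal-shape numeric data (ug/mL).
#' @param which label only, `"RMSEC"` or `"RMSEP"`.
#' @return Named numeric scalar.
#' @export
rmse <- function(found, reference, which = c("RMSEP", "RMSEC")) {
  which <- match.arg(which)
  qs_check(length(found) == length(reference),
           "found and reference must have the same length")
  stats::setNames(sqrt(mean((as.numeric(found) - as.numeric(reference))^2)),
                  which)
}

#' Durbin-Watson statistic with a permutation p-value
#'
#' DW = sum_{i>=2} (e_i - e_{i-1})^2 / sum e_i^2 on residuals ordered by
#' ascending nominal concentration (the natural ordering for
#' predicted-versus-nominal residuals). Values near 2 indicate no first-order
#' autocorrelation. The p-value is a seeded permutation test: residual order
#' is shuffled and the two-sided departure |DW - 2| compared with the
#' observed one.
#'
#' @param residuals numeric vector, length >= 3, not all zero.
#' @param n_perm number of permutations (default 2000).
#' @param seed integer seed for the shuffles.
#' @return List with `dw` and `p`.
#' @export
durbin_watson <- function(residuals, n_perm = 2000, seed = 1) {
  e <- as.numeric(residuals)
  qs_check(length(e) >= 3, "need at least 3 residuals")
  qs_check(sum(e^2) > 0, "Durbin-Watson undefined for all-zero residuals")
  dw_stat <- function(x) sum(diff(x)^2) / sum(x^2)
  obs <- dw_stat(e)
  set.seed(as.integer(seed))
  exceed <- 0L
  for (b in seq_len(n_perm))
    if (abs(dw_stat(sample(e)) - 2) >= abs(obs - 2)) exceed <- exceed + 1L
  list(dw = obs, p = (1 + exceed) / (n_perm + 1))
}

summarize_group <- function(g) {
  if (is.list(g)) {
    qs_check(all(c("mean", "sd", "n") %in% names(g)),
             "summary group needs mean, sd and n")
    g
  } else {
    qs_check(length(g) >= 2, "raw group needs at least 2 values")
    list(mean = mean(g), sd = stats::sd(g), n = length(g))
  }
}

#' Pooled t and variance-ratio F comparison of two methods
#'
#' Accepts raw recovery values or `(mean, sd, n)` summaries per group.
#' The t statistic uses the pooled variance with df = n1 + n2 - 2; the F
#' statistic is the larger variance over the smaller (so F >= 1), with the
#' one-tailed 95% critical value at the corresponding df.
#'
#' @param group1,group2 numeric vectors or lists with `mean`, `sd`, `n`.
#' @param conf_level confidence level for the criticals (default 0.95).
#' @return A `comparison_result` with statistics, criticals and
#'   significance flags.
#' @export
compare_methods <- function(group1, group2, conf_level = 0.95) {
  g1 <- summarize_group(group1); g2 <- summarize_group(group2)
  qs_check(g1$sd > 0 || g2$sd > 0, "both groups have zero variance")
  df_t <- g1$n + g2$n - 2
  sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / df_t
  t_stat <- abs(g1$mean - g2$mean) / sqrt(sp2 * (1 / g1$n + 1 / g2$n))
  t_crit <- stats::qt(1 - (1 - conf_level) / 2, df_t)
  if (g1$sd^2 >= g2$sd^2) {
    f_stat <- g1$sd^2 / max(g2$sd^2, .Machine$double.xmin)
    df_f <- c(g1$n - 1, g2$n - 1)
  } else {
    f_stat <- g2$sd^2 / g1$sd^2
    df_f <- c(g2$n - 1, g1$n - 1)
  }
  f_crit <- stats::qf(conf_level, df_f[1], df_f[2])
  structure(list(t = t_stat, t_critical = t_crit, t_df = df_t,
                 F = f_stat, F_critical = f_crit, F_df = df_f,
                 group1 = g1, group2 = g2,
                 t_significant = t_stat > t_crit,
                 F_significant = f_stat > f_crit),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result> t = ", format(x$t, digits = 4), " (crit ",
      format(x$t_critical, digits = 4), "), F = ", format(x$F, digits = 4),
      " (crit ", format(x$F_critical, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Elliptical joint confidence region test for trueness
#'
#' Regresses predicted on nominal concentrations and builds the joint
#' (intercept, slope) confidence region
#' \{b : (bhat - b)' X'X (bhat - b) <= 2 s^2 F(2, n-2, 1-alpha)\} with
#' X = \[1, nominal\]. The method is accurate at level alpha when the ideal
#' point (intercept 0, slope 1) lies inside.
#'
#' @param predicted,nominal numeric vectors, length >= 3.
#' @param alpha significance level (default 0.05).
#' @return An `ejcr_result`: `intercept`, `slope`, shape matrix `XtX`,
#'   residual variance `s2`, `f_critical`, `rhs` (region bound), ellipse
#'   `area`, and `contains_ideal`.
#' @export
ejcr <- function(predicted, nominal, alpha = 0.05) {
  x <- as.numeric(nominal); y <- as.numeric(predicted)
  n <- length(x)
  qs_check(n >= 3, "EJCR needs at least 3 points")
  qs_check(stats::sd(x) > 0, "nominal values must not be all equal")
  X <- cbind(1, x)
  bhat <- solve(crossprod(X), crossprod(X, y))
  s2 <- sum((y - X %*% bhat)^2) / (n - 2)
  f_crit <- stats::qf(1 - alpha, 2, n - 2)
  rhs <- 2 * s2 * f_crit
  d <- bhat - c(0, 1)
  q_ideal <- as.numeric(t(d) %*% crossprod(X) %*% d)
  # numerical slack so an exact fit (s2 = 0, bhat = ideal to rounding) counts
  slack <- 1e-10 * sum(diag(crossprod(X)))
  structure(list(intercept = bhat[1], slope = bhat[2], XtX = crossprod(X),
                 s2 = s2, f_critical = f_crit, rhs = rhs,
                 area = pi * rhs / sqrt(det(crossprod(X))),
                 q_ideal = q_ideal,
                 contains_ideal = q_ideal <= rhs + slack),
            class = "ejcr_result")
}

#' @export
print.ejcr_result <- function(x, ...) {
  cat("<ejcr_result> slope ", format(x$slope, digits = 5), ", intercept ",
      format(x$intercept, digits = 5), "; ideal point ",
      if (x$contains_ideal) "inside" else "OUTSIDE", " the region\n", sep = "")
  invisible(x)
}

#' Regression figures of merit for one analyte
#'
#' Slope, intercept and correlation of predicted versus nominal, RMSE over
#' the same set, and the Durbin-Watson statistic of the residuals ordered by
#' ascending nominal concentration.
#'
#' @param predicted,nominal numeric vectors.
#' @param n_perm,seed controls for the Durbin-Watson permutation p-value.
#' @return A one-row data frame.
#' @export
regression_fom <- function(predicted, nominal, n_perm = 2000, seed = 1) {
  fit <- stats::lm(predicted ~ nominal)
  ord <- order(nominal)
  res <- (predicted - nominal)[ord]
  dw <- durbin_watson(res, n_perm = n_perm, seed = seed)
  data.frame(slope = unname(stats::coef(fit)[2]),
             intercept = unname(stats::coef(fit)[1]),
             r = stats::cor(predicted, nominal),
             rmse = unname(rmse(predicted, nominal)),
             dw = dw$dw, dw_p = dw$p)
}
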