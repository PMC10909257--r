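# PCR and NIPALS PLS calibration with leave-one-out cross-validation.
#
# Both engines consume the raw windowed absorbance block; X and Y are
# mean-centered internally and the centering means are stored in the model, so
# prediction on new spectra uses the calibration means.

new_factor_model <- function(kind, n_lv, P, T, W, Q, B, x_means, y_means,
                             wavelengths_nm, analyte_names) {
  structure(list(kind = kind, n_lv = n_lv, x_loadings = P, x_scores = T,
                 pls_weights = W, y_loadings = Q, coefficients = B,
                 x_means = x_means, y_means = y_means,
                 wavelengths_nm = wavelengths_nm,
                 analyte_names = analyte_names),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat("<factor_model> ", x$kind, " with ", x$n_lv, " latent variables, ",
      length(x$wavelengths_nm), " wavelengths -> ",
      length(x$analyte_names), " analytes\n", sep = "")
  invisible(x)
}

as_y_matrix <- function(Y) {
  Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- analytes()[seq_len(ncol(Y))]
  Y
}

#' Principal component regression
#'
#' PCA of the mean-centered spectra by SVD, then least-squares regression of
#' the (centered) concentrations on the first `n_lv` component scores. PCA
#' extracts directions of maximal spectral variance without reference to the
#' concentrations.
#'
#' @param spectra windowed `spectra_set` (calibration X-block).
#' @param Y calibration concentrations, samples x analytes (ug/mL).
#' @param n_lv number of latent variables (components) to keep.
#' @return A `factor_model` with orthonormal loadings `x_loadings`, scores,
#'   regression coefficients `coefficients` (wavelengths x analytes) and the
#'   centering means.
#' @export
fit_pcr <- function(spectra, Y, n_lv) {
  Y <- as_y_matrix(Y)
  X <- spectra$absorbance
  qs_check(nrow(X) == nrow(Y), "X and Y must have the same number of samples")
  qs_check(n_lv >= 1 && n_lv <= min(nrow(X) - 1, ncol(X)),
           "n_lv must be between 1 and min(n_samples - 1, n_wavelengths)")
  x_means <- colMeans(X); y_means <- colMeans(Y)
  Xc <- sweep(X, 2, x_means); Yc <- sweep(Y, 2, y_means)
  sv <- svd(Xc, nu = n_lv, nv = n_lv)
  qs_check(sv$d[n_lv] > 1e-12 * sv$d[1],
           "score matrix is rank deficient at the requested n_lv")
  P <- sv$v                                   # orthonormal loadings
  T <- sv$u %*% diag(sv$d[seq_len(n_lv)], n_lv)
  G <- solve(crossprod(T), crossprod(T, Yc))  # n_lv x n_analytes
  B <- P %*% G
  dimnames(B) <- list(colnames(X), colnames(Y))
  # y_loadings stored analytes x n_lv so fitted values are T %*% t(Q)
  new_factor_model("PCR", n_lv, P, T, NULL, t(G), B, x_means, y_means,
                   spectra$wavelengths_nm, colnames(Y))
}

#' Partial least squares (NIPALS)
#'
#' NIPALS PLS with deflation of X and Y after each component. The default is
#' PLS2 (all analytes modelled jointly, as in toolbox-era multivariate
#' calibration); `algorithm = "pls1"` fits the single supplied response.
#' Coefficients are assembled as B = W (P'W)^-1 Q'.
#'
#' @inheritParams fit_pcr
#' @param algorithm `"pls2"` (default) or `"pls1"` (Y must be one column).
#' @param max_iter,tol inner-loop NIPALS controls.
#' @return A `factor_model` with orthonormal `pls_weights`.
#' @export
fit_pls <- function(spectra, Y, n_lv, algorithm = c("pls2", "pls1"),
                    max_iter = 500, tol = 1e-10) {
  algorithm <- match.arg(algorithm)
  Y <- as_y_matrix(Y)
  if (algorithm == "pls1")
    qs_check(ncol(Y) == 1, "pls1 requires a single-column Y")
  X <- spectra$absorbance
  qs_check(nrow(X) == nrow(Y), "X and Y must have the same number of samples")
  qs_check(n_lv >= 1 && n_lv <= min(nrow(X) - 1, ncol(X)),
           "n_lv must be between 1 and min(n_samples - 1, n_wavelengths)")
  x_means <- colMeans(X); y_means <- colMeans(Y)
  E <- sweep(X, 2, x_means); F <- sweep(Y, 2, y_means)
  nw <- ncol(X); na <- ncol(Y)
  W <- matrix(0, nw, n_lv); P <- matrix(0, nw, n_lv)
  T <- matrix(0, nrow(X), n_lv); Q <- matrix(0, na, n_lv)
  ss_x0 <- sum(E^2)
  for (a in seq_len(n_lv)) {
    qs_check(sum(E^2) > 1e-20 * ss_x0,
             "X block exhausted: rank deficient at the requested n_lv")
    u <- F[, which.max(apply(F, 2, stats::var))]
    if (sum(u^2) < 1e-30) u <- F[, 1]
    t_old <- rep(Inf, nrow(X))
    for (it in seq_len(max_iter)) {
      w <- crossprod(E, u); w <- w / sqrt(sum(w^2))
      t <- E %*% w
      q <- crossprod(F, t) / sum(t^2)
      u <- F %*% q / sum(q^2)
      if (sqrt(sum((t - t_old)^2)) < tol * sqrt(sum(t^2))) break
      t_old <- t
      if (it == max_iter) stop("NIPALS inner loop failed to converge")
    }
    p <- crossprod(E, t) / sum(t^2)
    E <- E - t %*% t(p)
    F <- F - t %*% t(q)
    W[, a] <- w; P[, a] <- p; T[, a] <- t; Q[, a] <- q
  }
  B <- W %*% solve(crossprod(P, W), t(Q))
  dimnames(B) <- list(colnames(X), colnames(Y))
  new_factor_model("PLS", n_lv, P, T, W, Q, B, x_means, y_means,
                   spectra$wavelengths_nm, colnames(Y))
}

#' Predict concentrations from a fitted factor model
#'
#' Centers the new spectra with the stored calibration means, applies the
#' coefficient matrix and adds back the concentration means.
#'
#' @param object a `factor_model`.
#' @param spectra a `spectra_set` on the training wavelength window.
#' @param ... unused.
#' @return Matrix of predicted concentrations (ug/mL), samples x analytes.
#' @export
predict.factor_model <- function(object, spectra, ...) {
  qs_check(isTRUE(all.equal(spectra$wavelengths_nm, object$wavelengths_nm)),
           "wavelength grid does not match the training window")
  Xc <- sweep(spectra$absorbance, 2, object$x_means)
  Yhat <- sweep(Xc %*% object$coefficients, 2, object$y_means, `+`)
  rownames(Yhat) <- spectra$sample_ids
  Yhat
}

#' Leave-one-out cross-validation over latent-variable counts
#'
#' For every left-out calibration sample the model is refit on the remainder
#' (recentring each fold) and the held-out sample predicted. RMSECV is
#' reported per analyte and per LV count, including the 0-LV mean-only model;
#' the selected count minimizes the analyte-averaged RMSECV, ties broken
#' toward fewer LVs.
#'
#' @inheritParams fit_pcr
#' @param max_lv largest LV count to test (at most n_samples - 2).
#' @param method `"pcr"` or `"pls"`.
#' @return A `cv_curve`: `lv_counts`, `rmsecv` (LV x analyte), `mean_rmsecv`,
#'   `selected_lv`.
#' @export
loo_cross_validate <- function(spectra, Y, max_lv, method = c("pcr", "pls")) {
  method <- match.arg(method)
  Y <- as_y_matrix(Y)
  X <- spectra$absorbance
  n <- nrow(X)
  qs_check(max_lv <= n - 2, "max_lv must be at most n_samples - 2")
  fit_fun <- if (method == "pcr") fit_pcr else fit_pls
  lv_counts <- 0:max_lv
  sse <- matrix(0, length(lv_counts), ncol(Y),
                dimnames = list(lv_counts, colnames(Y)))
  for (i in seq_len(n)) {
    train <- new_spectra_set(spectra$wavelengths_nm,
                             X[-i, , drop = FALSE], spectra$sample_ids[-i])
    test <- new_spectra_set(spectra$wavelengths_nm,
                            X[i, , drop = FALSE], spectra$sample_ids[i])
    y_bar <- colMeans(Y[-i, , drop = FALSE])
    sse[1, ] <- sse[1, ] + (Y[i, ] - y_bar)^2
    for (k in seq_len(max_lv)) {
      # LV counts beyond the rank of a fold are infeasible; mark NA
      m <- tryCatch(fit_fun(train, Y[-i, , drop = FALSE], k),
                    error = function(e) NULL)
      sse[k + 1, ] <- if (is.null(m)) NA else
        sse[k + 1, ] + (Y[i, ] - predict(m, test))^2
    }
  }
  rmsecv <- sqrt(sse / n)
  mean_rmsecv <- rowMeans(rmsecv)
  selected <- lv_counts[which.min(mean_rmsecv)]  # first tie/NA-safe minimum
  structure(list(lv_counts = lv_counts, rmsecv = rmsecv,
                 mean_rmsecv = mean_rmsecv, selected_lv = selected,
                 method = method),
            class = "cv_curve")
}

#' @export
print.cv_curve <- function(x, ...) {
  cat("<cv_curve> ", toupper(x$method), " leave-one-out RMSECV, LVs ",
      min(x$lv_counts), "-", max(x$lv_counts), "; selected ",
      x$selected_lv, "\n", sep = "")
  invisible(x)
}

#' Serialize / restore a factor model as JSON
#'
#' @param model a `factor_model`.
#' @param path file path.
#' @return `read_factor_model` returns the restored `factor_model`.
#' @export
write_factor_model <- function(model, path) {
  payload <- list(schema = "quatspec/factor_model/1",
                  kind = model$kind, n_lv = model$n_lv,
                  coefficients = model$coefficients,
                  x_means = model$x_means, y_means = model$y_means,
                  wavelengths_nm = model$wavelengths_nm,
                  analyte_names = model$analyte_names)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_factor_model
#' @export
read_factor_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  qs_check(identical(p$schema, "quatspec/factor_model/1"),
           "unrecognized model file schema")
  B <- as.matrix(p$coefficients)
  colnames(B) <- p$analyte_names
  new_factor_model(p$kind, p$n_lv, NULL, NULL, NULL, NULL, B,
                   p$x_means, stats::setNames(p$y_means, p$analyte_names),
                   p$wavelengths_nm, p$analyte_names)
}
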