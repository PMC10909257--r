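# Multivariate curve resolution by alternating least squares (MCR-ALS) with
# non-negativity and correlation constraints.
#
# The bilinear model is D ~ C S' (samples x wavelengths = samples x K times
# K x wavelengths transposed). Non-negativity is enforced by active-set NNLS
# per row/column; the correlation constraint regresses each resolved
# concentration column on the known reference column over the calibration
# rows and replaces those entries by the fitted values, anchoring the
# component ordering and the concentration scale to real units.

#' MCR-ALS configuration
#'
#' @param n_components number of resolved components (default 4).
#' @param constraints subset of `"non-negativity-C"`, `"non-negativity-S"`,
#'   `"correlation"`; all three by default.
#' @param convergence_tol relative change in %LOF between consecutive
#'   iterations, in percent (default 0.1, the toolbox convention).
#' @param max_iter iteration cap (default 100).
#' @param init `"purest-variables"` (determinant-based purest-sample spectra)
#'   or `"provided-spectra"` (pass `S_init` to [fit_mcr_als()]).
#' @param nonneg_solver `"nnls"` (active-set, default) or `"clip"` (fast
#'   clipped least squares).
#' @return A list of class `mcr_config`.
#' @export
mcr_config <- function(n_components = 4,
                       constraints = c("non-negativity-C",
                                       "non-negativity-S", "correlation"),
                       convergence_tol = 0.1, max_iter = 100,
                       init = c("purest-variables", "provided-spectra"),
                       nonneg_solver = c("nnls", "clip")) {
  qs_check(convergence_tol > 0, "convergence_tol must be positive")
  qs_check(n_components >= 1, "n_components must be at least 1")
  allowed <- c("non-negativity-C", "non-negativity-S", "correlation")
  qs_check(all(constraints %in% allowed), "unknown constraint name")
  structure(list(n_components = n_components, constraints = constraints,
                 convergence_tol = convergence_tol, max_iter = max_iter,
                 init = match.arg(init),
                 nonneg_solver = match.arg(nonneg_solver)),
            class = "mcr_config")
}

# Lawson-Hanson active-set non-negative least squares: min ||Ax - b||, x >= 0.
nnls_solve <- function(A, b, tol = 1e-12) {
  p <- ncol(A)
  x <- numeric(p)
  passive <- rep(FALSE, p)
  w <- crossprod(A, b - A %*% x)
  iter <- 0
  while (any(!passive & w > tol * max(1, max(abs(w)))) && iter < 30 * p) {
    iter <- iter + 1
    j <- which.max(replace(w, passive, -Inf))
    passive[j] <- TRUE
    repeat {
      s <- numeric(p)
      Ap <- A[, passive, drop = FALSE]
      s[passive] <- qr.solve(Ap, b)
      if (all(s[passive] > tol)) { x <- s; break }
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive <- passive & x > tol
      x[!passive] <- 0
    }
    w <- crossprod(A, b - A %*% x)
  }
  x
}

# least-squares step with optional non-negativity: solve B from  M ~ Z B'
# row-wise; returns matrix with one solution per row of M.
ls_rows <- function(M, Z, nonneg, solver) {
  G <- crossprod(Z)
  qs_check(rcond(G) > 1e-14, "singular normal equations in ALS step")
  if (!nonneg) return(t(solve(G, crossprod(Z, t(M)))))
  if (solver == "clip") {
    out <- t(solve(G, crossprod(Z, t(M))))
    return(pmax(out, 0))
  }
  res <- apply(M, 1, function(row) nnls_solve(Z, row))
  if (is.null(dim(res))) matrix(res, ncol = 1) else t(res)
}

# purest-sample initial spectra: greedy determinant (volume) criterion on
# unit-normalized rows of D.
purest_rows_init <- function(D, K) {
  norms <- sqrt(rowSums(D^2))
  Dn <- D / pmax(norms, 1e-30)
  sel <- which.max(norms)
  for (k in seq_len(K - 1)) {
    cand <- setdiff(seq_len(nrow(D)), sel)
    vol <- vapply(cand, function(i) det(tcrossprod(Dn[c(sel, i), ])), 0)
    sel <- c(sel, cand[which.max(vol)])
  }
  S <- t(D[sel, , drop = FALSE])
  sweep(S, 2, sqrt(colSums(S^2)), `/`)
}

#' Match resolved components to reference profiles
#'
#' Finds the column permutation of `est` maximizing the total correlation with
#' the columns of `ref` (exhaustive assignment; K is small).
#'
#' @param est,ref matrices with the same number of columns.
#' @return Integer vector `perm` such that `est[, perm]` aligns with `ref`.
#' @export
match_components <- function(est, ref) {
  K <- ncol(ref)
  cors <- stats::cor(ref, est)          # K x K: ref rows, est cols
  perms <- all_perms(K)
  scores <- apply(perms, 1, function(p) sum(cors[cbind(seq_len(K), p)]))
  perms[which.max(scores), ]
}

#' Percent lack of fit of a bilinear model
#'
#' LOF = 100 sqrt(sum(E^2) / sum(D^2)) with E = D - C S'.
#'
#' @param D data matrix (samples x wavelengths).
#' @param C concentration profiles (samples x K).
#' @param S spectral profiles (wavelengths x K).
#' @return Percent lack of fit.
#' @export
lack_of_fit <- function(D, C, S) {
  ss_d <- sum(D^2)
  qs_check(ss_d > 0, "lack of fit undefined for an all-zero data matrix")
  E <- D - tcrossprod(C, S)
  100 * sqrt(sum(E^2) / ss_d)
}

#' Percent explained variance of a bilinear model
#'
#' R2 = 100 (1 - sum(E^2) / sum(D^2)); algebraically R2 = 100 - LOF^2/100.
#'
#' @inheritParams lack_of_fit
#' @return Percent explained variance.
#' @export
explained_variance <- function(D, C, S) {
  ss_d <- sum(D^2)
  qs_check(ss_d > 0, "explained variance undefined for an all-zero matrix")
  E <- D - tcrossprod(C, S)
  100 * (1 - sum(E^2) / ss_d)
}

# one full ALS pass over D given current S; cal_rows indexes the rows where
# the correlation constraint anchors C to C_ref. Returns updated C, S, fit.
als_iteration <- function(D, S, C_ref, cal_rows, cfg) {
  nnC <- "non-negativity-C" %in% cfg$constraints
  nnS <- "non-negativity-S" %in% cfg$constraints
  corr <- "correlation" %in% cfg$constraints
  C <- ls_rows(D, S, nnC, cfg$nonneg_solver)
  fit <- NULL
  if (corr) {
    fit <- matrix(0, 2, ncol(C), dimnames = list(c("intercept", "slope"),
                                                 colnames(C_ref)))
    for (k in seq_len(ncol(C))) {
      b <- stats::coef(stats::lm(C[cal_rows, k] ~ C_ref[, k]))
      fit[, k] <- b
      C[cal_rows, k] <- b[1] + b[2] * C_ref[, k]
    }
  }
  S <- ls_rows(t(D), C, nnS, cfg$nonneg_solver)
  if (!corr) S <- sweep(S, 2, pmax(sqrt(colSums(S^2)), 1e-30), `/`)
  list(C = C, S = S, fit = fit)
}

run_als <- function(D, S, C_ref, cal_rows, cfg) {
  lof_trace <- numeric(0)
  lof_prev <- Inf
  bad <- 0
  fit <- NULL
  for (it in seq_len(cfg$max_iter)) {
    step <- als_iteration(D, S, C_ref, cal_rows, cfg)
    C <- step$C; S <- step$S; fit <- step$fit
    lof <- lack_of_fit(D, C, S)
    lof_trace <- c(lof_trace, lof)
    if (lof < 1e-8) break
    if (is.finite(lof_prev)) {
      if (lof > lof_prev + cfg$convergence_tol) {
        bad <- bad + 1
        if (bad >= 3) stop("MCR-ALS diverged: lack of fit increased for 3 ",
                           "consecutive iterations")
      } else bad <- 0
      if (100 * abs(lof_prev - lof) / lof_prev < cfg$convergence_tol) break
    }
    lof_prev <- lof
  }
  list(C = C, S = S, fit = fit, lof_trace = lof_trace, n_iter = length(lof_trace))
}

#' Fit MCR-ALS on a calibration block
#'
#' Alternates least-squares estimates of concentration and spectral profiles
#' under the configured constraints until the relative change in %LOF drops
#' below `convergence_tol`. With the correlation constraint active the
#' resolved concentrations are returned in real units (ug/mL), components
#' ordered as the reference analytes.
#'
#' @param spectra windowed calibration `spectra_set` (raw absorbances).
#' @param C_ref calibration reference concentrations, samples x K (ug/mL).
#' @param config an [mcr_config()].
#' @param S_init optional wavelengths x K initial spectra
#'   (`init = "provided-spectra"`).
#' @return An `mcr_model`: resolved `S` (wavelengths x K), `C` (ug/mL),
#'   `C_als` (internal ALS units), `correlation_fit` (intercept/slope per
#'   component mapping ug/mL to ALS units), `lof_trace`, `r2`, `n_iter`.
#' @export
fit_mcr_als <- function(spectra, C_ref, config = mcr_config(),
                        S_init = NULL) {
  D <- spectra$absorbance
  C_ref <- as_y_matrix(C_ref)
  qs_check(nrow(D) == nrow(C_ref), "spectra and C_ref must be row-aligned")
  K <- config$n_components
  if (config$init == "provided-spectra") {
    qs_check(!is.null(S_init), "S_init required for provided-spectra init")
    S <- as.matrix(S_init)
  } else {
    S <- purest_rows_init(D, K)
  }
  qs_check(ncol(S) == K && nrow(S) == ncol(D), "S_init has wrong shape")
  # align components with reference analytes before constraining
  C0 <- ls_rows(D, S, FALSE, config$nonneg_solver)
  S <- S[, match_components(C0, C_ref), drop = FALSE]
  res <- run_als(D, S, C_ref, seq_len(nrow(D)), config)
  C_real <- res$C
  if (!is.null(res$fit))
    C_real <- sweep(sweep(res$C, 2, res$fit["intercept", ]), 2,
                    res$fit["slope", ], `/`)
  colnames(C_real) <- colnames(C_ref)
  structure(list(S = res$S, C = C_real, C_als = res$C,
                 correlation_fit = res$fit, lof_trace = res$lof_trace,
                 lof = utils::tail(res$lof_trace, 1),
                 r2 = explained_variance(D, res$C, res$S),
                 n_iter = res$n_iter, config = config,
                 wavelengths_nm = spectra$wavelengths_nm,
                 analyte_names = colnames(C_ref)),
            class = "mcr_model")
}

#' @export
print.mcr_model <- function(x, ...) {
  cat("<mcr_model> ", ncol(x$S), " components, ", x$n_iter,
      " iterations; %LOF = ", format(x$lof, digits = 6),
      ", R2 = ", format(x$r2, digits = 6), "%\n", sep = "")
  invisible(x)
}

#' Predict test samples by one-by-one augmented MCR-ALS
#'
#' Each test spectrum is appended to the calibration data matrix and the ALS
#' optimization re-run from the fitted spectral profiles, with the
#' correlation constraint applied to the calibration rows only; the resolved
#' test-row concentrations are mapped back to ug/mL through the stored
#' reference regression.
#'
#' @param model a fitted `mcr_model`.
#' @param test_spectra `spectra_set` of one or more test samples (each is
#'   processed in its own augmented run).
#' @param cal_spectra the calibration `spectra_set` used for the fit.
#' @param C_ref the calibration reference concentrations.
#' @return Matrix of predicted concentrations (ug/mL), test samples x K.
#' @export
predict_mcr <- function(model, test_spectra, cal_spectra, C_ref) {
  C_ref <- as_y_matrix(C_ref)
  D_cal <- cal_spectra$absorbance
  n_cal <- nrow(D_cal)
  cfg <- model$config
  out <- matrix(NA_real_, nrow(test_spectra$absorbance), ncol(model$S),
                dimnames = list(test_spectra$sample_ids, model$analyte_names))
  for (i in seq_len(nrow(out))) {
    D_aug <- rbind(D_cal, test_spectra$absorbance[i, , drop = FALSE])
    res <- run_als(D_aug, model$S, C_ref, seq_len(n_cal), cfg)
    c_test <- res$C[n_cal + 1, ]
    if (!is.null(res$fit))
      c_test <- (c_test - res$fit["intercept", ]) / res$fit["slope", ]
    out[i, ] <- c_test
  }
  out
}
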