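# Linear (purelin-purelin) feed-forward network trained by
# Levenberg-Marquardt with early-stopping splits.
#
# With identity transfer functions in both layers the network composes to a
# single affine map, so the training objective is a (possibly underdetermined)
# linear least-squares problem; LM solves it through damped Gauss-Newton
# steps on the full weight vector, which doubles as an exact correctness
# oracle (the converged network must match the least-squares affine fit).

#' ANN configuration
#'
#' @param n_hidden hidden-layer size (default 5; 4 is the alternative
#'   architecture supported for this mixture).
#' @param max_epochs training epoch cap (default 100).
#' @param mu_init,mu_inc,mu_dec,mu_max Levenberg-Marquardt damping schedule:
#'   initial mu, multiplier on a rejected step, multiplier on an accepted
#'   step, and the ceiling that aborts training.
#' @param split_fractions train/validation/test fractions over the
#'   calibration samples (default 0.70/0.15/0.15); must sum to 1.
#' @param max_fail consecutive validation-MSE increases tolerated before
#'   early stopping (default 6).
#' @param seed integer seed for weight init and split assignment.
#' @return A list of class `ann_config`.
#' @export
ann_config <- function(n_hidden = 5, max_epochs = 100, mu_init = 0.1,
                       mu_inc = 10, mu_dec = 0.1, mu_max = 1e10,
                       split_fractions = c(0.70, 0.15, 0.15),
                       max_fail = 6, seed = 1) {
  qs_check(abs(sum(split_fractions) - 1) < 1e-9,
           "split_fractions must sum to 1")
  qs_check(max_epochs >= 1, "max_epochs must be at least 1")
  structure(list(n_hidden = n_hidden, max_epochs = max_epochs,
                 mu_init = mu_init, mu_inc = mu_inc, mu_dec = mu_dec,
                 mu_max = mu_max, split_fractions = split_fractions,
                 max_fail = max_fail, seed = seed),
            class = "ann_config")
}

# Affine scalers: forward (x - center) / halfwidth per column.
#
# Outputs use per-feature mapminmax to [-1, 1] so all four analytes carry
# equal training weight. Inputs share one global halfwidth (half the largest
# column range) with per-wavelength centering: absorbances are commensurable
# (one physical unit), and per-wavelength normalization would inflate the
# noise at weakly absorbing wavelengths, degrading the converged network.
make_scaler <- function(M, global = FALSE) {
  lo <- apply(M, 2, min); hi <- apply(M, 2, max)
  if (global) {
    hw <- rep(max(c(hi - lo, 1e-30)) / 2, ncol(M))
    list(center = colMeans(M), halfwidth = hw)
  } else {
    hw <- pmax((hi - lo) / 2, 1e-30)
    list(center = (lo + hi) / 2, halfwidth = hw)
  }
}
scale_fwd <- function(M, s) sweep(sweep(M, 2, s$center), 2, s$halfwidth, `/`)
scale_bwd <- function(M, s) sweep(sweep(M, 2, s$halfwidth, `*`), 2, s$center, `+`)

ann_forward <- function(W1, b1, W2, b2, X) {
  H <- X %*% t(W1) + matrix(b1, nrow(X), length(b1), byrow = TRUE)
  H %*% t(W2) + matrix(b2, nrow(X), length(b2), byrow = TRUE)
}

# per-split MSE in scaled ([-1, 1]) target space, the space the network is
# trained and early-stopped in, so every analyte carries equal weight
split_mse <- function(W1, b1, W2, b2, Xs, Ys, idx) {
  if (length(idx) == 0) return(NA_real_)
  pred <- ann_forward(W1, b1, W2, b2, Xs[idx, , drop = FALSE])
  mean((pred - Ys[idx, , drop = FALSE])^2)
}

#' Train the linear feed-forward network
#'
#' Inputs are the windowed absorbances (81 wavelengths by default), outputs
#' the four concentrations; both are scaled to [-1, 1] per feature. Each
#' epoch attempts one Levenberg-Marquardt update of the full weight vector on
#' the training split (damping mu is raised on rejected steps and lowered on
#' accepted ones), so the training MSE decreases monotonically across
#' accepted steps. Training stops at `max_epochs`, when the validation MSE
#' has risen for `max_fail` consecutive epochs, or when mu hits its ceiling;
#' the returned weights are those of the epoch with the lowest validation
#' MSE (or lowest training MSE when there is no validation split).
#'
#' @param spectra windowed calibration `spectra_set`.
#' @param Y calibration concentrations, samples x analytes (ug/mL).
#' @param config an [ann_config()].
#' @return An `ann_model`: weights `W1`, `b1`, `W2`, `b2`, scalers, per-epoch
#'   MSE `history` for each split, `best_epoch`, and the split indices.
#' @export
train_ann <- function(spectra, Y, config = ann_config()) {
  Y <- as_y_matrix(Y)
  X <- spectra$absorbance
  n <- nrow(X)
  fr <- config$split_fractions
  set.seed(as.integer(config$seed))
  perm <- sample.int(n)
  n_val <- floor(fr[2] * n); n_test <- floor(fr[3] * n)
  if (fr[2] > 0) qs_check(n_val >= 3, "validation split has fewer than 3 samples")
  if (fr[3] > 0) qs_check(n_test >= 3, "test split has fewer than 3 samples")
  idx_val <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
  idx_test <- if (n_test > 0) perm[n_val + seq_len(n_test)] else integer(0)
  idx_train <- if (n_val + n_test > 0) perm[-seq_len(n_val + n_test)] else perm
  qs_check(length(idx_train) >= 3, "training split has fewer than 3 samples")

  x_scaler <- make_scaler(X, global = TRUE); y_scaler <- make_scaler(Y)
  Xs <- scale_fwd(X, x_scaler); Ys <- scale_fwd(Y, y_scaler)
  Xtr <- Xs[idx_train, , drop = FALSE]; Ytr <- Ys[idx_train, , drop = FALSE]

  # small fan-in-scaled uniform init; the 0.1 factor keeps the converged
  # affine map nearly free of the random components left untouched along
  # directions outside the span of the training data
  p_in <- ncol(X); h <- config$n_hidden; p_out <- ncol(Y)
  W1 <- matrix(stats::runif(h * p_in, -0.05, 0.05) / sqrt(p_in), h, p_in)
  b1 <- stats::runif(h, -0.05, 0.05)
  W2 <- matrix(stats::runif(p_out * h, -0.05, 0.05) / sqrt(h), p_out, h)
  b2 <- stats::runif(p_out, -0.05, 0.05)

  unpack <- function(theta) {
    i <- 0
    W1 <- matrix(theta[i + seq_len(h * p_in)], h, p_in); i <- i + h * p_in
    b1 <- theta[i + seq_len(h)]; i <- i + h
    W2 <- matrix(theta[i + seq_len(p_out * h)], p_out, h); i <- i + p_out * h
    b2 <- theta[i + seq_len(p_out)]
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  }
  pack <- function(W1, b1, W2, b2) c(W1, b1, W2, b2)

  resid_vec <- function(w)
    as.numeric(ann_forward(w$W1, w$b1, w$W2, w$b2, Xtr) - Ytr)

  # Jacobian of the stacked residual vector (training samples x outputs,
  # column-major over outputs) with respect to the packed weights.
  jacobian <- function(w) {
    ntr <- nrow(Xtr)
    Hid <- Xtr %*% t(w$W1) + matrix(w$b1, ntr, h, byrow = TRUE)
    J <- matrix(0, ntr * p_out, h * p_in + h + p_out * h + p_out)
    for (o in seq_len(p_out)) {
      rows <- (o - 1) * ntr + seq_len(ntr)
      # dW1[hh, j] -> W2[o, hh] * x_j ; db1[hh] -> W2[o, hh]
      for (hh in seq_len(h)) {
        J[rows, (hh - 1) + h * (seq_len(p_in) - 1) + 1] <-
          w$W2[o, hh] * Xtr
        J[rows, h * p_in + hh] <- w$W2[o, hh]
      }
      # dW2[o, hh] -> Hid[, hh] ; db2[o] -> 1
      for (hh in seq_len(h))
        J[rows, h * p_in + h + (hh - 1) * p_out + o] <- Hid[, hh]
      J[rows, h * p_in + h + p_out * h + o] <- 1
    }
    J
  }

  theta <- pack(W1, b1, W2, b2)
  w <- unpack(theta)
  r <- resid_vec(w)
  sse <- sum(r^2)
  mu <- config$mu_init
  hist <- matrix(NA_real_, 0, 3, dimnames = list(NULL,
                 c("train", "validation", "test")))
  best <- list(val = Inf, w = w, epoch = 0)
  fails <- 0

  record <- function(w, epoch) {
    m <- c(split_mse(w$W1, w$b1, w$W2, w$b2, Xs, Ys, idx_train),
           split_mse(w$W1, w$b1, w$W2, w$b2, Xs, Ys, idx_val),
           split_mse(w$W1, w$b1, w$W2, w$b2, Xs, Ys, idx_test))
    hist <<- rbind(hist, m)
    crit <- if (length(idx_val) > 0) m[2] else m[1]
    if (crit < best$val) { best <<- list(val = crit, w = w, epoch = epoch) }
    if (length(idx_val) > 0) {
      if (nrow(hist) > 1 && m[2] > hist[nrow(hist) - 1, 2]) fails <<- fails + 1
      else fails <<- 0
    }
  }

  for (epoch in seq_len(config$max_epochs)) {
    J <- jacobian(w)
    accepted <- FALSE
    while (!accepted && mu <= config$mu_max) {
      # (J'J + mu I)^-1 J' r, via the dual form when weights outnumber rows
      if (ncol(J) <= nrow(J)) {
        delta <- solve(crossprod(J) + diag(mu, ncol(J)), crossprod(J, r))
      } else {
        delta <- crossprod(J, solve(tcrossprod(J) + diag(mu, nrow(J)), r))
      }
      w_new <- unpack(theta - as.numeric(delta))
      r_new <- resid_vec(w_new)
      sse_new <- sum(r_new^2)
      if (sse_new < sse) {
        theta <- theta - as.numeric(delta)
        w <- w_new; r <- r_new; sse <- sse_new
        mu <- mu * config$mu_dec
        accepted <- TRUE
      } else {
        mu <- mu * config$mu_inc
      }
    }
    record(w, epoch)
    if (!accepted) break                       # mu ceiling: converged
    if (fails >= config$max_fail) break        # early stopping
    if (sse < 1e-24) break
  }

  structure(list(W1 = best$w$W1, b1 = best$w$b1, W2 = best$w$W2,
                 b2 = best$w$b2, history = hist, best_epoch = best$epoch,
                 x_scaler = x_scaler, y_scaler = y_scaler,
                 idx_train = idx_train, idx_val = idx_val,
                 idx_test = idx_test, config = config,
                 wavelengths_nm = spectra$wavelengths_nm,
                 analyte_names = colnames(Y),
                 X = X, Y = Y),
            class = "ann_model")
}

#' @export
print.ann_model <- function(x, ...) {
  cat("<ann_model> ", ncol(x$W1), " inputs -> ", nrow(x$W1),
      " hidden (purelin) -> ", nrow(x$W2), " outputs; ",
      nrow(x$history), " epochs, best at ", x$best_epoch, "\n", sep = "")
  invisible(x)
}

#' Predict concentrations with a trained network
#'
#' @param object an `ann_model`.
#' @param spectra `spectra_set` on the training window.
#' @param ... unused.
#' @return Matrix of predicted concentrations (ug/mL).
#' @export
predict.ann_model <- function(object, spectra, ...) {
  X <- spectra$absorbance
  qs_check(ncol(X) == ncol(object$W1),
           "input wavelength count does not match the trained network")
  Xs <- scale_fwd(X, object$x_scaler)
  out <- scale_bwd(ann_forward(object$W1, object$b1, object$W2, object$b2, Xs),
                   object$y_scaler)
  dimnames(out) <- list(spectra$sample_ids, object$analyte_names)
  out
}

#' Collapse the purelin-purelin network to its affine map
#'
#' A linear-transfer network is exactly an affine transform of the raw
#' absorbances; this returns its coefficient matrix and intercept in
#' original (AU -> ug/mL) units.
#'
#' @param model an `ann_model`.
#' @return List with `A` (wavelengths x analytes) and `c` (length-4
#'   intercept) such that predictions = X A + c (rows of X raw AU).
#' @export
ann_as_affine <- function(model) {
  xs <- model$x_scaler; ys <- model$y_scaler
  M <- model$W2 %*% model$W1                       # scaled-space map
  v <- as.numeric(model$W2 %*% model$b1 + model$b2)
  # x_s = (x - cx)/hx ; y = y_s hy + cy
  A <- t(M / rep(xs$halfwidth, each = nrow(M))) *
    rep(ys$halfwidth, each = ncol(M))
  cvec <- (v - as.numeric(M %*% (xs$center / xs$halfwidth))) *
    ys$halfwidth + ys$center
  list(A = A, c = cvec)
}

#' Per-split training diagnostics
#'
#' Predicted-versus-target regression (slope, intercept, correlation) and MSE
#' for the train, validation and test splits of a fitted network.
#'
#' @param model an `ann_model`.
#' @return Data frame with one row per non-empty split.
#' @export
training_diagnostics <- function(model) {
  sets <- list(train = model$idx_train, validation = model$idx_val,
               test = model$idx_test)
  spectra <- new_spectra_set(model$wavelengths_nm, model$X,
                             rownames(model$X) %||% paste0("s", seq_len(nrow(model$X))))
  pred <- predict(model, spectra)
  out <- do.call(rbind, lapply(names(sets), function(nm) {
    idx <- sets[[nm]]
    if (length(idx) == 0) return(NULL)
    p <- as.numeric(pred[idx, ]); y <- as.numeric(model$Y[idx, ])
    fit <- stats::lm(p ~ y)
    data.frame(split = nm, n = length(idx),
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r = stats::cor(p, y), mse = mean((p - y)^2))
  }))
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
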