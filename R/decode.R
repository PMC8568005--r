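# Time-resolved pairwise ridge decoding, temporal generalization matrices
# (TGMs), and TGM component-attribution analyses.

#' Per-trial standardization
#'
#' Standardizes each trial/channel time series to mean 0, sd 1 (the
#' convention for the decoders here, which carry no information in the
#' per-trial offset/scale).  Zero-variance series become all zeros.
#'
#' @param epochs an [epoch_set()].
#' @return standardized `epoch_set`.
#' @export
standardize_trial <- function(epochs) {
  stop_if(!inherits(epochs, "epoch_set"), "epochs must be an epoch_set")
  d <- epochs$data
  dm <- dim(d)
  stop_if(dm[3] < 2, "need at least 2 samples per trial")
  for (n in seq_len(dm[1])) {
    for (c in seq_len(dm[2])) {
      x <- d[n, c, ]
      s <- stats::sd(x)
      d[n, c, ] <- if (s > 0) (x - mean(x)) / s else 0 * x
    }
  }
  epochs$data <- d
  epochs
}

#' Cross-validation scheme for decoding
#'
#' Stratified outer folds assess accuracy; inner folds on each outer
#' training set select the ridge penalty by mean squared error over a
#' log-spaced grid (by default 10 points in `[1e-3, 1e3] * n_features`).
#'
#' @param n_outer outer fold count.
#' @param n_inner inner fold count (0 disables inner selection; the first
#'   grid value is then used as a fixed penalty).
#' @param lambda_grid penalty grid; `NULL` for the scaled default.
#' @param seed fold-assignment seed, recorded in outputs.
#' @return object of class `cv_scheme`.
#' @export
cv_scheme <- function(n_outer = 10, n_inner = 5, lambda_grid = NULL, seed = 1) {
  stop_if(n_outer < 2, "need at least 2 outer folds")
  structure(list(n_outer = as.integer(n_outer), n_inner = as.integer(n_inner),
                 lambda_grid = lambda_grid, seed = as.integer(seed)),
            class = "cv_scheme")
}

# Stratified fold assignment: shuffles within class, deals fold ids
# round-robin so every fold holds both classes whenever counts allow.
make_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

default_lambda_grid <- function(p) 10^seq(-3, 3, length.out = 10) * p

# Ridge solutions over a penalty grid via one SVD of the centered design.
# Returns P x L coefficients and per-lambda intercepts (unpenalized).
ridge_path <- function(X, y, lambdas) {
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  sv <- svd(Xc)
  uy <- as.numeric(crossprod(sv$u, y - ym))
  B <- vapply(lambdas,
              function(l) as.numeric(sv$v %*% (sv$d * uy / (sv$d^2 + l))),
              numeric(ncol(X)))
  B <- matrix(B, ncol(X), length(lambdas))
  list(beta = B, intercept = ym - as.numeric(xm %*% B), d = sv$d)
}

#' Fit a ridge decoder at one time point
#'
#' Solves `argmin ||y - X b||^2 + lambda ||b||^2` in closed form with an
#' unpenalized intercept; labels are encoded -1/+1 and predictions are
#' classified by sign.
#'
#' @param X trials x features matrix.
#' @param y labels, -1/+1 (any two-valued coding is recoded).
#' @param lambda ridge penalty >= 0.
#' @return object of class `ridge_decoder` with `beta`, `intercept`,
#'   `lambda`.
#' @export
fit_ridge <- function(X, y, lambda) {
  stop_if(lambda < 0, "lambda must be >= 0")
  y <- recode_pm1(y)
  stop_if(length(unique(y)) < 2, "both classes must be present")
  rp <- ridge_path(X, y, lambda)
  if (lambda == 0) {
    d <- rp$d
    stop_if(length(d) == 0 || min(d) <= max(d) * 1e-10 || ncol(X) > nrow(X) - 1,
            "singular system with lambda = 0; use lambda > 0")
  }
  structure(list(beta = rp$beta[, 1], intercept = rp$intercept[1],
                 lambda = lambda),
            class = "ridge_decoder")
}

#' @export
predict.ridge_decoder <- function(object, newdata, ...) {
  as.numeric(newdata %*% object$beta) + object$intercept
}

# Recode any two-level label vector as -1/+1 (sorted order).
recode_pm1 <- function(y) {
  u <- sort(unique(y))
  stop_if(length(u) != 2, "expected exactly two classes, got ", length(u))
  ifelse(y == u[1], -1, 1)
}

# Inner-CV lambda selection (by MSE) and final fit on the full training set.
ridge_cv_train <- function(Xtr, ytr, cv, grid) {
  if (cv$n_inner >= 2 && length(grid) > 1) {
    inner <- make_folds(ytr, cv$n_inner, cv$seed + 1L)
    mse <- numeric(length(grid))
    for (f in sort(unique(inner))) {
      tr <- inner != f
      if (length(unique(ytr[tr])) < 2) next
      rp <- ridge_path(Xtr[tr, , drop = FALSE], ytr[tr], grid)
      pred <- Xtr[!tr, , drop = FALSE] %*% rp$beta
      pred <- sweep(pred, 2, rp$intercept, "+")
      mse <- mse + colMeans((pred - ytr[!tr])^2)
    }
    lam <- grid[which.min(mse)]
  } else {
    lam <- grid[1]
  }
  rp <- ridge_path(Xtr, ytr, lam)
  list(beta = rp$beta[, 1], intercept = rp$intercept[1], lambda = lam)
}

#' Cross-validated decoding accuracy at one time point
#'
#' Outer-fold accuracy of the ridge decoder trained and tested at sample
#' `t`; the inner loop selects the penalty per outer fold.  Predictions
#' are classified by sign; exact ties count half.
#'
#' @param epochs an [epoch_set()] (standardize first if desired).
#' @param labels two-class labels (default: `epochs$labels`).
#' @param t sample index.
#' @param cv a [cv_scheme()].
#' @return accuracy in `[0, 1]`.
#' @export
decode_timepoint <- function(epochs, labels = epochs$labels, t,
                             cv = cv_scheme()) {
  y <- recode_pm1(labels)
  d <- epochs$data
  grid <- cv$lambda_grid %||% default_lambda_grid(dim(d)[2])
  fold <- make_folds(y, cv$n_outer, cv$seed)
  correct <- 0
  for (f in sort(unique(fold))) {
    tr <- fold != f
    stop_if(length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2,
            "a fold is missing one class; use fewer folds")
    Xtr <- matrix(d[tr, , t], ncol = dim(d)[2])
    fit <- ridge_cv_train(Xtr, y[tr], cv, grid)
    yhat <- matrix(d[!tr, , t], ncol = dim(d)[2]) %*% fit$beta + fit$intercept
    s <- sign(yhat)
    correct <- correct + sum(ifelse(s == 0, 0.5, (s == y[!tr]) * 1))
  }
  correct / length(y)
}

#' Temporal generalization matrix
#'
#' Entry `(t, t')` is the cross-validated accuracy of the ridge decoder
#' trained at time `t` and applied to held-out trials at time `t'`; the
#' diagonal equals [decode_timepoint()] under the same fold seed, exactly.
#'
#' @inheritParams decode_timepoint
#' @param contrast optional identifier stored with the matrix.
#' @return object of class `tgm` with the `T x T` `accuracy` matrix,
#'   `contrast`, the `cv` scheme and the sampling rate `fs`.
#' @export
compute_tgm <- function(epochs, labels = epochs$labels, cv = cv_scheme(),
                        contrast = NULL) {
  y <- recode_pm1(labels)
  d <- epochs$data
  dm <- dim(d)
  T <- dm[3]
  grid <- cv$lambda_grid %||% default_lambda_grid(dm[2])
  fold <- make_folds(y, cv$n_outer, cv$seed)
  correct <- matrix(0, T, T)
  for (f in sort(unique(fold))) {
    tr <- fold != f
    stop_if(length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2,
            "a fold is missing one class; use fewer folds")
    dte <- d[!tr, , , drop = FALSE]
    nte <- sum(!tr)
    Xte <- matrix(aperm(dte, c(1, 3, 2)), nte * T, dm[2])  # (trial,time) x chan
    yte <- y[!tr]
    for (t in seq_len(T)) {
      fit <- ridge_cv_train(matrix(d[tr, , t], ncol = dm[2]), y[tr], cv, grid)
      yhat <- matrix(Xte %*% fit$beta + fit$intercept, nte, T)  # trial x t'
      s <- sign(yhat)
      sc <- ifelse(s == 0, 0.5, (s == yte) * 1)
      correct[t, ] <- correct[t, ] + colSums(sc)
    }
  }
  structure(list(accuracy = correct / length(y), contrast = contrast,
                 cv = cv, fs = epochs$fs),
            class = "tgm")
}

#' @export
print.tgm <- function(x, ...) {
  cat(sprintf("tgm: %d x %d, diagonal mean %.3f, off-diagonal mean %.3f\n",
              nrow(x$accuracy), ncol(x$accuracy),
              mean(diag(x$accuracy)),
              mean(x$accuracy[row(x$accuracy) != col(x$accuracy)])))
  invisible(x)
}

#' TGMs for the signal and its components
#'
#' Computes four TGMs under identical fold assignments: the original
#' (recombined) signal, the non-oscillatory trend, the oscillatory
#' residual, and the power envelope of the oscillatory component (its
#' analytic-signal magnitude, i.e. phase removed).  Each input is
#' standardized per trial before decoding.
#'
#' @param components a [split_components()] result.
#' @param labels two-class labels (default: component labels).
#' @param cv a [cv_scheme()]; its seed fixes the shared folds.
#' @return named list of [compute_tgm()] results:
#'   `original`, `trend`, `oscillatory`, `power`.
#' @export
tgm_for_components <- function(components, labels = components$labels,
                               cv = cv_scheme()) {
  stop_if(!inherits(components, "signal_components"),
          "components must come from split_components()")
  dm <- dim(components$trend)
  stop_if(length(labels) != dm[1], "labels must match the trial count")
  env <- components$oscillatory
  for (n in seq_len(dm[1])) {
    for (c in seq_len(dm[2])) {
      env[n, c, ] <- Mod(analytic_signal(components$oscillatory[n, c, ]))
    }
  }
  mk <- function(arr) standardize_trial(
    epoch_set(arr, components$fs, components$labels, components$attributes))
  inputs <- list(original = components$trend + components$oscillatory,
                 trend = components$trend,
                 oscillatory = components$oscillatory,
                 power = env)
  out <- lapply(names(inputs), function(nm)
    compute_tgm(mk(inputs[[nm]]), labels, cv, contrast = nm))
  names(out) <- names(inputs)
  out
}

#' Explained variance of one TGM from others
#'
#' Vectorizes the TGM entries and fits ordinary least squares with an
#' intercept, reporting the coefficient of determination.  Used to ask how
#' much of the original signal's TGM the component TGMs account for, and
#' for nested-model comparisons (fit twice with different predictor sets).
#'
#' @param target a `tgm` (or accuracy matrix).
#' @param predictors named list of `tgm`s (or matrices) of the same shape.
#' @return list with `r_squared`, `coefficients`, `n` (entries used).
#' @export
tgm_attribution <- function(target, predictors) {
  as_mat <- function(x) if (inherits(x, "tgm")) x$accuracy else as.matrix(x)
  ty <- as_mat(target)
  Xs <- lapply(predictors, as_mat)
  for (m in Xs) stop_if(!all(dim(m) == dim(ty)), "all TGMs must share a shape")
  yv <- as.vector(ty)
  X <- do.call(cbind, lapply(Xs, as.vector))
  colnames(X) <- names(predictors) %||% paste0("p", seq_along(Xs))
  stop_if(length(yv) < ncol(X) + 1, "fewer TGM entries than predictors + 1")
  fit <- stats::lm(yv ~ X)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((yv - mean(yv))^2)
  list(r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       coefficients = stats::coef(fit),
       n = length(yv))
}

#' Diagonal, off-diagonal and orthogonal-section summaries of a TGM
#'
#' The orthogonal section runs along the anti-diagonal through `(t, t)`:
#' point `d` is the accuracy of the decoder trained at `t + d` tested at
#' `t - d`, reported against the train-test separation `2 d / fs` in ms
#' (so a theta half-cycle shows up near 71 ms for a 7-Hz carrier).  The
#' off-diagonal mean excludes a band `|t - t'| <= exclude_ms` around the
#' diagonal.
#'
#' @param tgm a `tgm`.
#' @param t center sample of the section.
#' @param half_window section half-length in samples.
#' @param exclude_ms half-width in ms of the diagonal band excluded from
#'   the off-diagonal mean (default 100 ms, beyond a theta half-cycle).
#' @return list with `diagonal_mean`, `offdiag_mean`, and `section`
#'   (offsets in ms, values, and the realized length after truncation at
#'   the matrix bounds).
#' @export
tgm_sections <- function(tgm, t, half_window, exclude_ms = 100) {
  stop_if(!inherits(tgm, "tgm"), "tgm must come from compute_tgm()")
  A <- tgm$accuracy
  T <- nrow(A)
  stop_if(t < 1 || t > T, "t outside the trial")
  band <- round(exclude_ms / 1000 * tgm$fs)
  off <- abs(row(A) - col(A)) > band
  ds <- (-half_window):half_window
  keep <- t + ds >= 1 & t + ds <= T & t - ds >= 1 & t - ds <= T
  ds <- ds[keep]
  vals <- A[cbind(t + ds, t - ds)]
  list(diagonal_mean = mean(diag(A)),
       offdiag_mean = if (any(off)) mean(A[off]) else NA_real_,
       section = list(offset_ms = 2 * ds / tgm$fs * 1000, values = vals,
                      length = length(ds)))
}

#' Offset of the below-baseline rebound trough of a TGM section
#'
#' Locates the worse-than-chance rebound on the anti-diagonal section
#' through `(t, t)`: the value-weighted mean train-test separation of the
#' below-baseline region within `max_offset_ms` (weights `0.5 - accuracy`,
#' clipped at 0).  For an oscillatory phase effect the trough sits at half
#' the carrier period (about 71 ms at 7 Hz).
#'
#' @param tgm a `tgm`.
#' @param t center sample (default: diagonal maximum).
#' @param max_offset_ms largest separation considered, ms (default 120,
#'   below a full theta cycle so only the first rebound lobe enters).
#' @param baseline chance level (0.5 for balanced two-class decoding).
#' @return list with `offset_ms` (trough location), `depth` (baseline
#'   minus minimum accuracy), `min_value`.
#' @export
tgm_rebound_trough <- function(tgm, t = NULL, max_offset_ms = 120,
                               baseline = 0.5) {
  stop_if(!inherits(tgm, "tgm"), "tgm must come from compute_tgm()")
  A <- tgm$accuracy
  if (is.null(t)) t <- which.max(diag(A))
  hw <- ceiling(max_offset_ms / 1000 * tgm$fs / 2)
  sec <- tgm_sections(tgm, t, hw)
  o <- abs(sec$section$offset_ms)
  v <- sec$section$values
  keep <- o > 0 & o <= max_offset_ms
  o <- o[keep]; v <- v[keep]
  w <- pmax(0, baseline - v)
  if (sum(w) == 0) {
    return(list(offset_ms = NA_real_, depth = 0, min_value = min(v)))
  }
  list(offset_ms = sum(w * o) / sum(w),
       depth = baseline - min(v),
       min_value = min(v))
}
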