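# Temporally unconstrained decoding: K regression decoders with per-trial
# activation time courses gamma, a left-to-right transition matrix, and
# three constraints against degenerate solutions:
#   1. decoders activate in sequence: every trial starts in state 1 and
#      ends in state K (no skips);
#   2. a window mask keeps each decoder near its mean activation point;
#   3. all decoders' regression coefficients sum to the same value, so no
#      decoder can specialize on a class via an overall offset.
#
# Inference is penalized (MAP) expectation-maximization on a single
# objective: Gaussian prior on the coefficients, inverse-gamma on the
# noise variances, Dirichlet(1) on transition rows.  The E-step is an
# exact forward-backward pass over monotone state paths; the M-step
# maximizes the penalized expected complete-data log-likelihood within
# the sum-constraint subspace, so the recorded free energy (negative
# penalized log-evidence) never increases.

#' PCA reduction of an epoch set
#'
#' PCA over the pooled (trial x time) x channel matrix; the retained
#' components reach the requested explained-variance threshold (or an
#' explicit count).
#'
#' @param epochs an [epoch_set()].
#' @param var_threshold cumulative explained-variance target in (0, 1].
#' @param n_pc explicit component count (overrides the threshold).
#' @return list with `epochs` (reduced `epoch_set`, channels replaced by
#'   components) and `basis` (class `pca_basis`: orthonormal `components`
#'   channels x n_pc, `explained` variance fractions, `n_pc`, `center`).
#' @export
pca_reduce <- function(epochs, var_threshold = 0.98, n_pc = NULL) {
  stop_if(!inherits(epochs, "epoch_set"), "epochs must be an epoch_set")
  d <- epochs$data
  dm <- dim(d)
  stop_if(!is.null(n_pc) && n_pc > dm[2],
          sprintf("n_pc (%d) exceeds channel count (%d)", n_pc, dm[2]))
  stop_if(is.null(n_pc) && (var_threshold <= 0 || var_threshold > 1),
          "var_threshold must be in (0, 1]")
  X <- matrix(aperm(d, c(1, 3, 2)), dm[1] * dm[3], dm[2])
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  fr <- pc$sdev^2 / sum(pc$sdev^2)
  if (is.null(n_pc)) {
    n_pc <- which(cumsum(fr) >= var_threshold - 1e-12)[1]
    if (is.na(n_pc)) n_pc <- length(fr)
  }
  scores <- sweep(X, 2, pc$center) %*% pc$rotation[, seq_len(n_pc), drop = FALSE]
  red <- aperm(array(scores, c(dm[1], dm[3], n_pc)), c(1, 3, 2))
  basis <- structure(list(components = pc$rotation[, seq_len(n_pc), drop = FALSE],
                          explained = fr, n_pc = as.integer(n_pc),
                          center = pc$center),
                     class = "pca_basis")
  list(epochs = epoch_set(red, epochs$fs, epochs$labels, epochs$attributes,
                          channels = paste0("pc", seq_len(n_pc))),
       basis = basis)
}

#' Window mask restricting when each decoder may be active
#'
#' State `k` is allowed at samples `t` with
#' `(k - 1 - slack) * T / K < t <= (k + slack) * T / K`, clipped to
#' `[1, T]`: each decoder stays within `slack` state-widths of its mean
#' activation point `k/K * T`.
#'
#' @param T samples per trial.
#' @param K decoder count (K <= T).
#' @param slack band half-width in state-widths (>= 1).
#' @return object of class `state_window_mask` with the `T x K` logical
#'   `allowed` matrix.
#' @export
build_window_mask <- function(T, K, slack = 1) {
  stop_if(K > T, "K must not exceed T")
  stop_if(slack < 1, "slack must be >= 1")
  allowed <- matrix(FALSE, T, K)
  for (k in seq_len(K)) {
    lb <- (k - 1 - slack) * T / K
    ub <- (k + slack) * T / K
    lo <- max(1L, as.integer(floor(lb)) + 1L)
    hi <- min(T, as.integer(floor(ub + 1e-9)))
    if (lo <= hi) allowed[lo:hi, k] <- TRUE
  }
  stop_if(any(rowSums(allowed) == 0), "mask leaves a time point with no state")
  structure(list(allowed = allowed, T = as.integer(T), K = as.integer(K),
                 slack = slack),
            class = "state_window_mask")
}

# Batched forward-backward over monotone (stay-or-advance) state paths
# that start in state 1 and end in state K, with zero probability
# off-mask.  logE: N x T x K log-emissions; M: K x K upper-bidiagonal.
# Returns gamma (T x N x K), per-trial log-evidence, expected transition
# counts (K x K).
fb_batch <- function(logE, M, mask = NULL) {
  dm <- dim(logE)
  N <- dm[1]; T <- dm[2]; K <- dm[3]
  if (!is.null(mask)) {
    al <- if (inherits(mask, "state_window_mask")) mask$allowed else mask
    stop_if(!all(dim(al) == c(T, K)), "mask shape must be T x K")
    for (k in seq_len(K)) logE[, !al[, k], k] <- -Inf
  }
  # per-(n,t) max for scaling
  mx <- apply(logE, c(1, 2), max)
  stop_if(any(!is.finite(mx)), "no admissible state at some time point")
  E <- exp(logE - array(mx, c(N, T, K)))   # scaled emissions in [0, 1]

  A <- array(0, c(T, N, K))
  A[1, , 1] <- E[, 1, 1]
  stop_if(any(E[, 1, 1] == 0), "state 1 not admissible at t = 1")
  logZ <- mx[, 1]
  stay <- diag(M)
  adv <- if (K > 1) M[cbind(seq_len(K - 1), 2:K)] else numeric(0)
  for (t in 2:T) {
    prev <- matrix(A[t - 1, , ], N, K)
    cur <- sweep(prev, 2, stay, "*")
    if (K > 1) cur[, 2:K] <- cur[, 2:K] +
        sweep(prev[, 1:(K - 1), drop = FALSE], 2, adv, "*")
    cur <- cur * matrix(E[, t, ], N, K)
    cn <- rowSums(cur)
    stop_if(any(cn == 0), "no admissible monotone path (mask too tight?)")
    logZ <- logZ + log(cn) + mx[, t]
    A[t, , ] <- cur / cn
  }
  endw <- A[T, , K]
  stop_if(any(endw == 0), "no path reaches state K at t = T")
  logZ <- logZ + log(endw)

  B <- array(0, c(T, N, K))
  B[T, , K] <- 1
  for (t in (T - 1):1) {
    nxt <- matrix(B[t + 1, , ], N, K)
    en <- matrix(E[, t + 1, ], N, K)
    cur <- sweep(nxt * en, 2, stay, "*")
    if (K > 1) cur[, 1:(K - 1)] <- cur[, 1:(K - 1)] +
        sweep((nxt * en)[, 2:K, drop = FALSE], 2, adv, "*")
    cn <- rowSums(cur)
    cn[cn == 0] <- 1
    B[t, , ] <- cur / cn
  }

  gamma <- A * B
  gs <- apply(gamma, c(1, 2), sum)
  gamma <- gamma / array(gs, c(T, N, K))

  counts <- matrix(0, K, K)
  for (t in seq_len(T - 1)) {
    At <- matrix(A[t, , ], N, K)
    Bn <- matrix(B[t + 1, , ], N, K) * matrix(E[, t + 1, ], N, K)
    Ws <- sweep(At * Bn, 2, stay, "*")
    Wa <- if (K > 1)
      sweep(At[, 1:(K - 1), drop = FALSE] * Bn[, 2:K, drop = FALSE], 2, adv, "*")
    else matrix(0, N, 0)
    den <- rowSums(Ws) + if (K > 1) rowSums(Wa) else 0
    den[den == 0] <- 1
    counts[cbind(1:K, 1:K)] <- counts[cbind(1:K, 1:K)] + colSums(Ws / den)
    if (K > 1) counts[cbind(1:(K - 1), 2:K)] <-
        counts[cbind(1:(K - 1), 2:K)] + colSums(Wa / den)
  }
  list(gamma = gamma, log_evidence = logZ, counts = counts)
}

#' Exact posterior over monotone decoder sequences for one trial
#'
#' Forward-backward pass over all state paths that are non-decreasing,
#' start in state 1 at `t = 1`, end in state K at `t = T`, advance at most
#' one state per step, and respect the window mask.
#'
#' @param logem `T x K` matrix of log-emission values.
#' @param M `K x K` row-stochastic upper-bidiagonal transition matrix.
#' @param mask optional [build_window_mask()] result (or `T x K` logical).
#' @return list with `gamma` (`T x K` posterior state probabilities),
#'   `log_evidence`, and expected transition `counts`.
#' @export
constrained_forward_backward <- function(logem, M, mask = NULL) {
  stop_if(!is.matrix(logem), "logem must be a T x K matrix")
  T <- nrow(logem); K <- ncol(logem)
  stop_if(!all(dim(M) == c(K, K)), "M must be K x K")
  logE <- array(0, c(1, T, K))
  logE[1, , ] <- logem
  r <- fb_batch(logE, M, mask)
  list(gamma = matrix(r$gamma[, 1, ], T, K),
       log_evidence = r$log_evidence[1],
       counts = r$counts)
}

# Flatten [N, P, T] regressors into an (N*T) x P matrix whose row order
# matches as.vector(t(gamma[, , k])) (trial fastest, then time).
flatten_x <- function(X) {
  dm <- dim(X)
  matrix(aperm(X, c(1, 3, 2)), dm[1] * dm[3], dm[2])
}

#' M-step: decoder coefficients and noise variances
#'
#' Each decoder solves a responsibility-weighted ridge regression of the
#' label on the reduced data; the sum-to-equal-value constraint is then
#' enforced exactly, as the constrained maximizer of the penalized
#' objective (projection in the precision metric, with the common value
#' chosen optimally).  Noise variances get their inverse-gamma MAP update.
#'
#' @param X reduced data, `[N, P, T]` array.
#' @param y numeric label per trial (e.g. -1/+1).
#' @param gamma responsibilities, `T x N x K`.
#' @param alpha Gaussian prior precision on the coefficients.
#' @param sigma2 current noise variance per state (default 1s).
#' @param sum_constraint enforce equal coefficient sums across decoders.
#' @param a0,b0 inverse-gamma prior for the noise variances.
#' @param share_noise tie the noise variance across states (default).  A
#'   free per-state variance lets decoders specialize on the class they
#'   fit best through their noise term alone, the same degeneracy the
#'   coefficient-sum constraint guards against.
#' @return list with `betas` (`K x P`), `sigma2` (length K), and the
#'   per-state effective sample sizes `weights`.
#' @export
m_step_decoders <- function(X, y, gamma, alpha = 0.01, sigma2 = NULL,
                            sum_constraint = TRUE, a0 = 1, b0 = 0.01,
                            share_noise = TRUE) {
  dm <- dim(X)
  N <- dm[1]; P <- dm[2]; T <- dm[3]
  K <- dim(gamma)[3]
  stop_if(dim(gamma)[1] != T || dim(gamma)[2] != N,
          "gamma must be T x N x K congruent with X")
  if (is.null(sigma2)) sigma2 <- rep(1, K)
  Xf <- flatten_x(X)
  yrep <- rep(y, T)
  betas <- matrix(0, K, P)
  us <- matrix(0, K, P)
  Wk <- numeric(K)
  low_resp <- logical(K)
  for (k in seq_len(K)) {
    w <- as.vector(t(matrix(gamma[, , k], T, N)))
    Wk[k] <- sum(w)
    if (Wk[k] < 1) {
      low_resp[k] <- TRUE
      us[k, ] <- rep(1 / alpha, P) * NA
      next
    }
    Xw <- Xf * w
    Sxx <- crossprod(Xf, Xw)
    Sxy <- crossprod(Xw, yrep)
    Ak <- Sxx / sigma2[k] + diag(alpha, P)
    betas[k, ] <- solve(Ak, Sxy / sigma2[k])
    us[k, ] <- solve(Ak, rep(1, P))
  }
  if (any(low_resp)) {
    warning(sum(low_resp), " state(s) with responsibility < 1 sample; ",
            "coefficients shrunk to the prior mean")
  }
  ok <- !low_resp
  if (sum_constraint && sum(ok) > 1) {
    s <- rowSums(us)[ok]                 # 1' A^-1 1 per state
    bs <- rowSums(betas)[ok]             # current coefficient sums
    cc <- sum(bs / s) / sum(1 / s)       # optimal common sum
    ks <- which(ok)
    for (i in seq_along(ks)) {
      k <- ks[i]
      betas[k, ] <- betas[k, ] - us[k, ] * (bs[i] - cc) / s[i]
    }
  }
  ssr <- numeric(K)
  for (k in seq_len(K)) {
    w <- as.vector(t(matrix(gamma[, , k], T, N)))
    ssr[k] <- sum(w * (yrep - Xf %*% betas[k, ])^2)
  }
  if (share_noise) {
    # constrained maximizer with sigma tied across states
    s2 <- max((2 * K * b0 + sum(ssr)) / (2 * K * (a0 + 1) + sum(Wk)), 1e-10)
    sigma2 <- rep(s2, K)
  } else {
    sigma2 <- pmax((2 * b0 + ssr) / (2 * (a0 + 1) + Wk), 1e-10)
  }
  list(betas = betas, sigma2 = sigma2, weights = Wk)
}

# log prior density terms entering the penalized objective
log_priors <- function(betas, sigma2, alpha, a0, b0) {
  P <- ncol(betas)
  lp_beta <- sum(P / 2 * log(alpha / (2 * pi)) - alpha / 2 * rowSums(betas^2))
  lp_sig <- sum(a0 * log(b0) - lgamma(a0) - (a0 + 1) * log(sigma2) - b0 / sigma2)
  lp_beta + lp_sig
}

tuda_emissions <- function(Xf, y, betas, sigma2, N, T) {
  K <- nrow(betas)
  logE <- array(0, c(N, T, K))
  yrep <- rep(y, T)
  for (k in seq_len(K)) {
    r2 <- (yrep - Xf %*% betas[k, ])^2
    logE[, , k] <- matrix(-0.5 * log(2 * pi * sigma2[k]) - r2 / (2 * sigma2[k]),
                          N, T)
  }
  logE
}

# Label-marginal emissions: the likelihood of the decoder output under a
# mixture over the observed label values (empirical weights).  Paths
# inferred from these cannot encode any individual trial's label.
tuda_marginal_emissions <- function(Xf, y, betas, sigma2, N, T) {
  vals <- sort(unique(y))
  w <- as.numeric(table(factor(y, levels = vals))) / length(y)
  K <- nrow(betas)
  logE <- array(0, c(N, T, K))
  for (k in seq_len(K)) {
    pred <- as.numeric(Xf %*% betas[k, ])
    mix <- 0
    for (v in seq_along(vals)) {
      mix <- mix + w[v] * exp(-(vals[v] - pred)^2 / (2 * sigma2[k]))
    }
    logE[, , k] <- matrix(-0.5 * log(2 * pi * sigma2[k]) + log(mix), N, T)
  }
  logE
}

ramp_gamma <- function(T, K, jitter = 0) {
  centers <- (seq_len(K) - 0.5) * T / K
  width <- T / K
  g <- outer(seq_len(T), centers, function(t, c) exp(-(t - c)^2 / (2 * width^2)))
  if (jitter > 0) g <- g * matrix(stats::rexp(T * K, 1)^jitter, T, K)
  g / rowSums(g)
}

#' Fit the constrained decoder-sequence model
#'
#' Alternates an exact E-step (constrained forward-backward over monotone
#' state paths under the window mask) with a constrained M-step
#' ([m_step_decoders()] plus transition-count updates) until the free
#' energy (negative penalized log-evidence) changes by less than `tol`
#' relative, or `max_iter` iterations.  The free-energy trace is
#' non-increasing by construction.  Multiple restarts jitter the initial
#' responsibilities; the best (lowest) free energy is kept.
#'
#' @param epochs reduced [epoch_set()] (see [pca_reduce()]) or an
#'   `[N, P, T]` array.
#' @param labels numeric label per trial (-1/+1 for binary contrasts, or a
#'   centered numeric attribute).
#' @param K decoder count (study default 8).
#' @param slack window-mask slack in state-widths.
#' @param alpha Gaussian prior precision on the decoder coefficients.
#' @param max_iter,tol EM iteration cap and relative free-energy tolerance.
#' @param restarts random restarts (first is the deterministic ramp).
#' @param share_noise tie the noise variance across states (see
#'   [m_step_decoders()]).
#' @param seed seed for restart jitter.
#' @param sum_constraint enforce the equal-coefficient-sum constraint.
#' @param a0,b0 inverse-gamma prior on the noise variances.
#' @return object of class `tuda_fit`: `betas` (K x P), `gamma`
#'   (T x N x K), `gamma_marginal` (same shape; responsibilities
#'   re-inferred with the label marginalized out, for realignment-based
#'   tests), transition matrix `M`, `sigma2`, `free_energy` trace,
#'   `mask`, `log_evidence`, `K`, `labels`, `converged`.
#' @export
fit_tuda <- function(epochs, labels = NULL, K = 8, slack = 1, alpha = 0.01,
                     max_iter = 100, tol = 1e-6, restarts = 3, seed = 1,
                     sum_constraint = TRUE, a0 = 1, b0 = 0.01,
                     share_noise = TRUE) {
  X <- if (inherits(epochs, "epoch_set")) epochs$data else epochs
  stop_if(length(dim(X)) != 3, "epochs must be a 3-D [N, P, T] array")
  if (is.null(labels)) labels <- if (inherits(epochs, "epoch_set"))
    recode_pm1(epochs$labels) else stop("labels required")
  dm <- dim(X)
  N <- dm[1]; P <- dm[2]; T <- dm[3]
  stop_if(K < 1, "K must be >= 1")
  y <- as.numeric(labels)
  stop_if(length(y) != N, "labels must match trial count")
  mask <- build_window_mask(T, K, slack)
  Xf <- flatten_x(X)

  best <- NULL
  for (r in seq_len(restarts)) {
    if (r > 1) set.seed(derive_seed(seed, r))
    g0 <- ramp_gamma(T, K, jitter = if (r > 1) 0.5 else 0)
    gamma <- array(0, c(T, N, K))
    for (k in seq_len(K)) gamma[, , k] <- matrix(g0[, k], T, N)

    M <- diag(1 - min(0.5, K / T), K)
    if (K > 1) {
      M[cbind(1:(K - 1), 2:K)] <- min(0.5, K / T)
      M[K, K] <- 1
    } else M[1, 1] <- 1

    ms <- m_step_decoders(X, y, gamma, alpha, NULL, sum_constraint, a0, b0,
                          share_noise)
    fe <- numeric(0)
    converged <- FALSE
    eres <- NULL
    for (it in seq_len(max_iter)) {
      logE <- tuda_emissions(Xf, y, ms$betas, ms$sigma2, N, T)
      eres <- fb_batch(logE, M, mask)
      obj <- sum(eres$log_evidence) +
        log_priors(ms$betas, ms$sigma2, alpha, a0, b0)
      stop_if(!is.finite(obj), "non-finite free energy at iteration ", it)
      fe <- c(fe, -obj)
      if (it > 1 && abs(fe[it - 1] - fe[it]) < tol * (1 + abs(fe[it]))) {
        converged <- TRUE
        break
      }
      gamma <- eres$gamma
      ms <- m_step_decoders(X, y, gamma, alpha, ms$sigma2, sum_constraint,
                            a0, b0, share_noise)
      cnt <- eres$counts
      for (k in seq_len(K)) {
        rs <- sum(cnt[k, ])
        M[k, ] <- if (rs > 0) cnt[k, ] / rs else as.numeric(seq_len(K) == k)
      }
      if (K > 1) M[K, ] <- as.numeric(seq_len(K) == K)
    }
    cand <- list(betas = ms$betas, sigma2 = ms$sigma2, M = M,
                 gamma = eres$gamma, log_evidence = eres$log_evidence,
                 free_energy = fe, converged = converged)
    if (is.null(best) || utils::tail(fe, 1) < utils::tail(best$free_energy, 1))
      best <- cand
  }

  # label-free responsibilities for realignment-based tests: paths from
  # emissions with the label marginalized out, so per-trial timing cannot
  # be bent to fit the label it is later tested against
  logEm <- tuda_marginal_emissions(Xf, y, best$betas, best$sigma2, N, T)
  gm <- fb_batch(logEm, best$M, mask)$gamma

  structure(list(K = as.integer(K), betas = best$betas, gamma = best$gamma,
                 gamma_marginal = gm, M = best$M, sigma2 = best$sigma2,
                 free_energy = best$free_energy,
                 log_evidence = best$log_evidence, mask = mask,
                 labels = y, alpha = alpha, converged = best$converged),
            class = "tuda_fit")
}

#' @export
print.tuda_fit <- function(x, ...) {
  cat(sprintf("tuda_fit: K = %d decoders, %d trials, %d samples; free energy %.2f (%s)\n",
              x$K, dim(x$gamma)[2], dim(x$gamma)[1],
              utils::tail(x$free_energy, 1),
              if (x$converged) "converged" else "iteration cap"))
  invisible(x)
}

# Hard state path per trial: argmax responsibilities, ties to the lowest k.
state_path <- function(gamma) {
  T <- dim(gamma)[1]; N <- dim(gamma)[2]; K <- dim(gamma)[3]
  path <- matrix(0L, T, N)
  for (n in seq_len(N)) {
    path[, n] <- max.col(matrix(gamma[, n, ], T, K), ties.method = "first")
  }
  path
}

#' Per-trial state onset times
#'
#' The onset of state `k` in a trial is the first sample where `k` is the
#' most responsible decoder.  State 1 is excluded (it always starts at the
#' first sample); states never active in a trial yield `NA` and are
#' excluded from downstream tests (counts are attached as an attribute).
#'
#' @param fit a [fit_tuda()] result (or a `T x N x K` gamma array).
#' @param marginal use the label-marginal responsibilities (default when
#'   available): onsets then cannot carry label information by
#'   construction, which keeps the downstream latency permutation test
#'   honest.
#' @return `N x (K - 1)` matrix of onset samples, columns named
#'   `state2` ... `stateK`; attribute `n_missing` holds per-state counts.
#' @export
state_onsets <- function(fit, marginal = TRUE) {
  gamma <- if (inherits(fit, "tuda_fit")) {
    if (marginal && !is.null(fit$gamma_marginal)) fit$gamma_marginal
    else fit$gamma
  } else fit
  K <- dim(gamma)[3]
  stop_if(K < 2, "onsets need at least 2 states")
  path <- state_path(gamma)
  N <- ncol(path)
  on <- matrix(NA_real_, N, K - 1)
  colnames(on) <- paste0("state", 2:K)
  for (n in seq_len(N)) {
    for (k in 2:K) {
      w <- which(path[, n] == k)
      if (length(w)) on[n, k - 1] <- w[1]
    }
  }
  attr(on, "n_missing") <- colSums(is.na(on))
  on
}

#' Cross-validated accuracy curve of the decoder-sequence model
#'
#' For each outer fold the model is fit on the training trials; held-out
#' trials are predicted per time point with the decoders weighted by the
#' training-set mean responsibility time course (held-out responsibilities
#' cannot be inferred without the label).  The permutation envelope refits
#' the model on label-permuted training data and records the per-time
#' maximum accuracy across permutations.
#'
#' @param epochs reduced [epoch_set()] or `[N, P, T]` array.
#' @param labels -1/+1 labels.
#' @param K decoder count.
#' @param cv a [cv_scheme()] (outer folds only are used).
#' @param n_perm permutation count for the envelope (0 to skip).
#' @param seed permutation seed.
#' @param ... passed to [fit_tuda()].
#' @return list with `accuracy` (length T), `envelope` (length T or NULL),
#'   `n_perm`, `seed`.
#' @export
tuda_accuracy_curve <- function(epochs, labels = NULL, K = 8,
                                cv = cv_scheme(n_outer = 5), n_perm = 100,
                                seed = 1, ...) {
  X <- if (inherits(epochs, "epoch_set")) epochs$data else epochs
  if (is.null(labels)) labels <- recode_pm1(epochs$labels)
  y <- as.numeric(labels)
  dm <- dim(X)
  T <- dm[3]
  fold <- make_folds(y, cv$n_outer, cv$seed)
  predict_fold <- function(ytr, f) {
    tr <- fold != f
    fit <- fit_tuda(X[tr, , , drop = FALSE], ytr[tr], K = K, seed = seed, ...)
    gbar <- apply(fit$gamma, c(1, 3), mean)            # T x K
    te <- which(!tr)
    yh <- matrix(0, length(te), T)
    for (t in seq_len(T)) {
      xt <- matrix(X[te, , t], ncol = dm[2])
      yh[, t] <- (xt %*% t(fit$betas)) %*% gbar[t, ]
    }
    yh
  }
  curve_for <- function(ylab) {
    correct <- numeric(T)
    for (f in sort(unique(fold))) {
      yh <- predict_fold(ylab, f)
      yte <- ylab[fold == f]
      s <- sign(yh)
      correct <- correct + colSums(ifelse(s == 0, 0.5, (s == yte) * 1))
    }
    correct / length(y)
  }
  acc <- curve_for(y)
  env <- NULL
  if (n_perm > 0) {
    env <- rep(-Inf, T)
    for (r in seq_len(n_perm)) {
      set.seed(derive_seed(seed, r))
      env <- pmax(env, curve_for(sample(y)))
    }
  }
  list(accuracy = acc, envelope = env, n_perm = n_perm, seed = seed)
}
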