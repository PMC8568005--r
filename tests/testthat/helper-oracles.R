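# Independent oracle implementations used to validate the package's
# numerics by a second route.  These deliberately share no code with R/.

# Direct tricube-weighted local linear smoother (the classic lowess
# definition, no robustness iterations), fit point by point.
oracle_tricube_local_linear <- function(x, f = 0.1) {
  T <- length(x)
  tt <- seq_len(T)
  r <- max(2, floor(f * T))
  out <- numeric(T)
  for (i in tt) {
    dist <- abs(tt - i)
    h <- sort(dist)[r]
    w <- (1 - pmin(1, dist / max(h, 1e-12))^3)^3
    use <- w > 0
    W <- w[use]
    xx <- tt[use]
    yy <- x[use]
    sw <- sum(W)
    mx <- sum(W * xx) / sw
    my <- sum(W * yy) / sw
    denom <- sum(W * (xx - mx)^2)
    b <- if (denom > 0) sum(W * (xx - mx) * (yy - my)) / denom else 0
    out[i] <- my + b * (i - mx)
  }
  out
}

# Exhaustive enumeration of monotone stay-or-advance state paths from
# state 1 at t = 1 to state K at t = T, with posterior marginals and
# evidence computed path by path.
oracle_enumerate_paths <- function(logem, M, mask = NULL) {
  T <- nrow(logem)
  K <- ncol(logem)
  if (!is.null(mask)) {
    al <- if (inherits(mask, "state_window_mask")) mask$allowed else mask
    for (k in seq_len(K)) logem[!al[, k], k] <- -Inf
  }
  paths <- list()
  recurse <- function(path) {
    t <- length(path)
    k <- path[t]
    if (t == T) {
      if (k == K) paths[[length(paths) + 1]] <<- path
      return(invisible(NULL))
    }
    for (nk in c(k, k + 1)) if (nk <= K) recurse(c(path, nk))
  }
  recurse(1L)
  logw <- vapply(paths, function(p) {
    sum(logem[cbind(seq_len(T), p)]) + sum(log(M[cbind(p[-T], p[-1])]))
  }, numeric(1))
  mw <- max(logw)
  w <- exp(logw - mw)
  Z <- sum(w)
  gamma <- matrix(0, T, K)
  for (i in seq_along(paths)) {
    idx <- cbind(seq_len(T), paths[[i]])
    gamma[idx] <- gamma[idx] + w[i]
  }
  list(gamma = gamma / Z, log_evidence = log(Z) + mw,
       viterbi = paths[[which.max(logw)]], n_paths = length(paths))
}

# von Mises sampler (Best & Fisher 1979 rejection scheme); kappa = 0
# falls back to uniform.
oracle_rvonmises <- function(n, mu = 0, kappa = 0) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  out <- numeric(n)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  i <- 1
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- ((if (u[3] > 0.5) 1 else -1) * acos(f) + mu + pi) %% (2 * pi) - pi
      i <- i + 1
    }
  }
  out
}

# Switching regression data with a known decoder sequence: K states with
# distinct coefficient vectors in channel space, state boundaries jittered
# per trial around their nominal positions.  Used for recovery tests.
make_switching_data <- function(N, C, T, K, seed, noise = 0.4,
                                signal_dims = NULL) {
  set.seed(seed)
  if (is.null(signal_dims)) signal_dims <- min(C, 2 * K)
  y <- rep(c(-1, 1), length.out = N)
  betas <- matrix(0, K, C)
  for (k in seq_len(K)) {
    b <- numeric(C)
    pick <- ((k - 1) * 2) %% signal_dims + c(1, 2)
    b[pick] <- c(1, -0.7)
    betas[k, ] <- b
  }
  # per-trial ordered switch points around k/K positions
  bounds <- matrix(0, N, K - 1)
  for (n in seq_len(N)) {
    nominal <- (seq_len(K - 1) / K + stats::rnorm(K - 1, 0, 0.06)) * T
    bounds[n, ] <- sort(pmin(pmax(round(nominal), 2), T - 1))
  }
  X <- array(stats::rnorm(N * C * T, 0, noise), c(N, C, T))
  state_of <- function(n, t) sum(t > bounds[n, ]) + 1
  for (n in seq_len(N)) {
    for (t in seq_len(T)) {
      X[n, , t] <- X[n, , t] + y[n] * betas[state_of(n, t), ]
    }
  }
  list(X = X, y = y, betas = betas, bounds = bounds)
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Small random epoch set for structural tests.
random_epochs <- function(N = 8, C = 3, T = 50, fs = 100, seed = 1) {
  set.seed(seed)
  epoch_set(array(stats::rnorm(N * C * T), c(N, C, T)), fs,
            labels = rep_len(1:2, N),
            attributes = data.frame(animacy = rep_len(0:1, N),
                                    size = rep_len(1:3, N)))
}
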