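# Decoder-sequence model: PCA, window mask, exact E-step against path
# enumeration, constrained M-step against hand-solved systems, recovery.

test_that("pca_reduce respects rank, thresholds and known covariance structure", {
  # exact rank 3
  set.seed(1)
  L <- matrix(rnorm(8 * 3), 8, 3)
  Z <- matrix(rnorm(300 * 3), 300, 3)
  X <- Z %*% t(L)
  ep <- epoch_set(aperm(array(X, c(30, 10, 8)), c(1, 3, 2)), 100,
                  rep_len(1:2, 30))
  red <- pca_reduce(ep, var_threshold = 0.98)
  expect_equal(red$basis$n_pc, 3)
  expect_equal(unname(crossprod(red$basis$components)), diag(3),
               tolerance = 1e-10)
  # identity covariance, threshold 1 keeps all channels
  ep2 <- random_epochs(N = 40, C = 5, T = 30, seed = 2)
  expect_equal(pca_reduce(ep2, var_threshold = 1)$basis$n_pc, 5)
  expect_error(pca_reduce(ep2, n_pc = 9), "exceeds")
  # known 5-factor covariance: explained fractions match eigenvalue ratios
  set.seed(3)
  ev <- c(5, 4, 3, 2, 1)
  Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  Sg <- Q %*% diag(ev) %*% t(Q)
  Xs <- matrix(rnorm(20000 * 5), 20000, 5) %*% chol(Sg)
  ep3 <- epoch_set(aperm(array(Xs, c(200, 100, 5)), c(1, 3, 2)), 100,
                   rep_len(1:2, 200))
  fr <- pca_reduce(ep3, var_threshold = 1)$basis$explained
  expect_lt(max(abs(fr - ev / sum(ev))), 0.02)
})

test_that("window mask bands follow the band formula and degenerate safely", {
  m <- build_window_mask(12, 3, 1)$allowed
  expect_equal(range(which(m[, 1])), c(1, 8))
  expect_equal(range(which(m[, 2])), c(1, 12))
  expect_equal(range(which(m[, 3])), c(5, 12))
  expect_true(all(build_window_mask(10, 2, 1)$allowed))
  expect_true(all(build_window_mask(20, 4, 4)$allowed))  # slack >= K
  expect_error(build_window_mask(5, 8, 1), "exceed")
})

test_that("forward-backward equals brute-force path enumeration exactly", {
  for (cfg in list(c(T = 6, K = 3), c(T = 8, K = 2), c(T = 12, K = 3))) {
    T <- cfg[["T"]]; K <- cfg[["K"]]
    M <- diag(0.6, K)
    if (K > 1) {
      M[cbind(1:(K - 1), 2:K)] <- 0.4
      M[K, K] <- 1
    } else M[1, 1] <- 1
    # uniform emissions: gamma equals path-counting frequencies
    fb_u <- constrained_forward_backward(matrix(0, T, K), M)
    or_u <- oracle_enumerate_paths(matrix(0, T, K), M)
    expect_equal(fb_u$gamma, or_u$gamma, tolerance = 1e-12)
    expect_equal(fb_u$log_evidence, or_u$log_evidence, tolerance = 1e-12)
    # random emissions, with the window mask applied
    set.seed(T * 10 + K)
    le <- matrix(rnorm(T * K, 0, 2), T, K)
    mask <- build_window_mask(T, K, 1)
    fb_r <- constrained_forward_backward(le, M, mask)
    or_r <- oracle_enumerate_paths(le, M, mask)
    expect_equal(fb_r$gamma, or_r$gamma, tolerance = 1e-12)
    expect_equal(fb_r$log_evidence, or_r$log_evidence, tolerance = 1e-12)
  }
})

test_that("K = 1 reduces to a single always-on decoder", {
  le <- matrix(rnorm(10), 10, 1)
  r <- constrained_forward_backward(le, matrix(1, 1, 1))
  expect_equal(r$gamma, matrix(1, 10, 1))
  expect_equal(r$log_evidence, sum(le))
})

test_that("overwhelming emissions pin the switch at the favoured time", {
  T <- 10; K <- 2
  M <- matrix(c(0.5, 0, 0.5, 1), 2, 2)
  for (tstar in c(3, 6, 9)) {
    le <- matrix(0, T, K)
    le[seq_len(tstar - 1), 2] <- -50
    le[tstar:T, 1] <- -50
    fb <- constrained_forward_backward(le, M)
    path <- max.col(fb$gamma, ties.method = "first")
    orc <- oracle_enumerate_paths(le, M)
    expect_equal(path, orc$viterbi)
    expect_equal(which(path == 2)[1], tstar)
  }
})

test_that("the M-step matches hand-solved weighted normal equations", {
  set.seed(5)
  N <- 6; P <- 2; T <- 4; K <- 2
  X <- array(rnorm(N * P * T), c(N, P, T))
  y <- rep(c(-1, 1), 3)
  gamma <- array(0, c(T, N, K))
  gamma[, , 1] <- matrix(c(0.9, 0.7, 0.4, 0.2), T, N)
  gamma[, , 2] <- 1 - gamma[, , 1]
  alpha <- 0.5
  ms <- m_step_decoders(X, y, gamma, alpha = alpha, sigma2 = c(1, 1),
                        sum_constraint = FALSE, share_noise = FALSE)
  # oracle: explicit accumulation of the weighted system per state
  for (k in 1:K) {
    Sxx <- matrix(0, P, P); Sxy <- numeric(P)
    for (n in 1:N) for (t in 1:T) {
      x <- X[n, , t]
      Sxx <- Sxx + gamma[t, n, k] * tcrossprod(x)
      Sxy <- Sxy + gamma[t, n, k] * x * y[n]
    }
    bk <- solve(Sxx + alpha * diag(P), Sxy)
    expect_equal(unname(ms$betas[k, ]), unname(bk), tolerance = 1e-8)
  }
  # symmetric responsibilities and shared data give identical decoders
  gamma_sym <- array(0.5, c(T, N, K))
  ms_sym <- m_step_decoders(X, y, gamma_sym, alpha = alpha)
  expect_equal(ms_sym$betas[1, ], ms_sym$betas[2, ], tolerance = 1e-12)
  # the sum constraint equalizes coefficient sums exactly
  ms_con <- m_step_decoders(X, y, gamma, alpha = alpha, sigma2 = c(1, 1),
                            sum_constraint = TRUE)
  expect_lt(diff(range(rowSums(ms_con$betas))), 1e-8)
})

test_that("fit_tuda recovers switch times and decoders with a monotone free energy", {
  sw <- make_switching_data(N = 60, C = 8, T = 60, K = 2, seed = 13)
  fit <- fit_tuda(sw$X, sw$y, K = 2, restarts = 1, max_iter = 60)
  fe <- fit$free_energy
  expect_true(all(diff(fe) <= 1e-6 * (1 + abs(fe[-1]))))
  on <- state_onsets(fit)
  expect_gt(cor(on[, 1], sw$bounds[, 1], use = "complete.obs"), 0.8)
  for (k in 1:2) {
    expect_gt(cosine_sim(fit$betas[k, ], sw$betas[k, ]), 0.9)
  }
  # structural invariants
  expect_equal(apply(fit$gamma, c(1, 2), sum),
               matrix(1, 60, 60), tolerance = 1e-9)
  expect_equal(rowSums(fit$M), c(1, 1), tolerance = 1e-12)
  expect_equal(fit$M[2, 1], 0)
  expect_lt(diff(range(rowSums(fit$betas))), 1e-8)
  expect_equal(unname(apply(fit$gamma[1, , , drop = FALSE], 2, which.max)),
               rep(1, 60))
})

test_that("K = 1 nests pooled regression decoding", {
  sw <- make_switching_data(N = 40, C = 6, T = 30, K = 2, seed = 3)
  cv <- cv_scheme(n_outer = 4, n_inner = 0, lambda_grid = 1, seed = 9)
  res <- tuda_accuracy_curve(sw$X, sw$y, K = 1, cv = cv, n_perm = 0,
                             restarts = 1, max_iter = 30)
  # oracle: pooled ridge over all time points, same folds, same prediction rule
  fold <- oscdecode:::make_folds(sw$y, 4, 9L)
  T <- dim(sw$X)[3]
  correct <- numeric(T)
  for (f in sort(unique(fold))) {
    tr <- fold != f
    Xf <- oscdecode:::flatten_x(sw$X[tr, , , drop = FALSE])
    yf <- rep(sw$y[tr], T)
    alpha <- 0.01
    # the K = 1 model's MAP decoder: ridge with the model's own prior scale
    s2 <- 1
    for (it in 1:30) {
      b <- solve(crossprod(Xf) / s2 + alpha * diag(ncol(Xf)),
                 crossprod(Xf, yf) / s2)
      s2n <- (2 * 0.01 + sum((yf - Xf %*% b)^2)) / (2 * 2 + length(yf))
      if (abs(s2n - s2) < 1e-10) break
      s2 <- s2n
    }
    te <- which(!tr)
    for (t in seq_len(T)) {
      yh <- matrix(sw$X[te, , t], ncol = dim(sw$X)[2]) %*% b
      s <- sign(yh)
      correct[t] <- correct[t] + sum(ifelse(s == 0, 0.5, (s == sw$y[te]) * 1))
    }
  }
  oracle_acc <- correct / length(sw$y)
  expect_lt(mean(abs(res$accuracy - oracle_acc)), 0.02)
})

test_that("the coefficient-sum constraint blocks class-offset specialization", {
  set.seed(5)
  N <- 80; P <- 6; T <- 60
  y <- rep(c(-1, 1), N / 2)
  X <- array(rnorm(N * P * T, 0, 0.5), c(N, P, T))
  for (n in seq_len(N)) X[n, , ] <- X[n, , ] + (2 + y[n]) / sqrt(P)
  respdiff <- function(f) {
    g <- apply(f$gamma, c(2, 3), mean)
    max(abs(colMeans(g[y == 1, , drop = FALSE]) -
              colMeans(g[y == -1, , drop = FALSE])))
  }
  f_on <- fit_tuda(X, y, K = 2, restarts = 1, max_iter = 60,
                   sum_constraint = TRUE)
  f_off <- fit_tuda(X, y, K = 2, restarts = 1, max_iter = 60,
                    sum_constraint = FALSE)
  expect_lt(respdiff(f_on), 0.2)
  expect_gt(respdiff(f_off), 0.2)
})

test_that("state onsets follow the argmax rule with ties to the lowest state", {
  gamma <- array(0, c(120, 3, 2))
  gamma[, , 1] <- 1
  gamma[100:120, 2, 1] <- 0
  gamma[100:120, 2, 2] <- 1
  gamma[50:120, 3, 1] <- 0
  gamma[50:120, 3, 2] <- 1
  on <- state_onsets(gamma)
  expect_true(is.na(on[1, 1]))        # state 2 never wins in trial 1
  expect_equal(unname(on[2, 1]), 100)
  expect_equal(unname(on[3, 1]), 50)
  expect_equal(attr(on, "n_missing")[["state2"]], 1)
  # uniform responsibilities: ties resolve to state 1, others never activate
  gu <- array(1 / 2, c(20, 2, 2))
  on_u <- state_onsets(gu)
  expect_true(all(is.na(on_u)))
})

test_that("accuracy curves exceed their permutation envelope only under real effects", {
  sw <- make_switching_data(N = 40, C = 6, T = 30, K = 2, seed = 21,
                            noise = 0.5)
  cv <- cv_scheme(n_outer = 4, n_inner = 0, lambda_grid = 1, seed = 5)
  res <- tuda_accuracy_curve(sw$X, sw$y, K = 2, cv = cv, n_perm = 8,
                             seed = 3, restarts = 1, max_iter = 25)
  expect_gt(mean(res$accuracy > res$envelope), 0.5)
  res2 <- tuda_accuracy_curve(sw$X, sw$y, K = 2, cv = cv, n_perm = 8,
                              seed = 3, restarts = 1, max_iter = 25)
  expect_identical(res2$envelope, res$envelope)
  # null data: the curve stays inside its envelope almost everywhere
  set.seed(4)
  Xn <- array(rnorm(40 * 6 * 30), c(40, 6, 30))
  resn <- tuda_accuracy_curve(Xn, sw$y, K = 2, cv = cv, n_perm = 19,
                              seed = 6, restarts = 1, max_iter = 25)
  expect_gte(mean(resn$accuracy <= resn$envelope), 0.85)
})
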