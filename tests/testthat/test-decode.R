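# Ridge decoding, TGMs, attribution and sections.

test_that("standardize_trial normalizes each trial/channel and zeroes constants", {
  ep <- random_epochs(N = 5, C = 2, T = 40, seed = 2)
  ep$data[3, 1, ] <- 7   # constant channel
  st <- standardize_trial(ep)
  expect_lt(max(abs(apply(st$data[-3, , , drop = FALSE], c(1, 2), mean))), 1e-12)
  expect_lt(max(abs(apply(st$data[-3, , , drop = FALSE], c(1, 2), sd) - 1)), 1e-12)
  expect_equal(st$data[3, 1, ], rep(0, 40))
  expect_identical(standardize_trial(st)$data[1, 1, ], st$data[1, 1, ],
                   tolerance = 1e-12)
})

test_that("fit_ridge matches hand solutions and limiting cases", {
  # hand-solved system: (X'X + lambda) b = X'y -> 2 / (2 + 1)
  fr <- fit_ridge(matrix(c(1, -1), 2, 1), c(1, -1), 1)
  expect_equal(fr$beta, 2 / 3, tolerance = 1e-12)
  # lambda = 0 on a full-rank system equals OLS
  set.seed(1)
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(c(-1, 1), 10)
  f0 <- fit_ridge(X, y, 0)
  ols <- coef(lm(y ~ X))
  expect_equal(unname(f0$beta), unname(ols[-1]), tolerance = 1e-8)
  expect_equal(unname(f0$intercept), unname(ols[1]), tolerance = 1e-8)
  # huge penalty drives the coefficients (not the intercept) to zero
  Xs <- scale(X)
  fb <- fit_ridge(Xs, y, 1e9)
  expect_lt(sqrt(sum(fb$beta^2)), 1e-6)
  # singular system at lambda = 0 is refused with advice
  expect_error(fit_ridge(matrix(1, 4, 6), rep(c(-1, 1), 2), 0), "lambda > 0")
})

test_that("decode_timepoint is calibrated under permuted labels and strong under separation", {
  set.seed(3)
  cv <- cv_scheme(n_outer = 5, n_inner = 0, lambda_grid = 5, seed = 1)
  accs <- numeric(25)
  for (r in seq_len(25)) {
    ep <- random_epochs(N = 40, C = 4, T = 10, seed = 100 + r)
    y <- sample(rep(c(-1, 1), 20))
    accs[r] <- decode_timepoint(ep, y, 5, cv)
  }
  expect_lt(abs(mean(accs) - 0.5), 0.05)
  # separable classes: margin much larger than noise
  ep <- random_epochs(N = 40, C = 4, T = 10, seed = 7)
  y <- rep(c(-1, 1), 20)
  for (n in 1:40) ep$data[n, , 5] <- ep$data[n, , 5] * 0.1 + y[n]
  expect_gt(decode_timepoint(ep, y, 5, cv), 0.95)
  # scaling all features leaves accuracy unchanged after standardization
  ep2 <- ep
  ep2$data <- ep$data * 2
  expect_equal(decode_timepoint(ep2, y, 5, cv), decode_timepoint(ep, y, 5, cv))
})

test_that("the TGM diagonal equals per-timepoint decoding under the same folds", {
  cf <- sim_config(n_trials = 30, n_channels = 4, n_categories = 2, fs = 25,
                   trial_dur = 1, additive_shift = c(animacy = 0.5),
                   noise_sd = 0.8, seed = 12)
  g <- generate_trials(cf)
  ep <- standardize_trial(g$epochs)
  y <- ifelse(g$epochs$attributes$animacy == 1, 1, -1)
  cv <- cv_scheme(n_outer = 5, n_inner = 3,
                  lambda_grid = c(1, 10, 100), seed = 4)
  tg <- compute_tgm(ep, y, cv)
  for (t in c(3, 11, 20)) {
    expect_identical(tg$accuracy[t, t], decode_timepoint(ep, y, t, cv))
  }
  # determinism under the fold seed
  tg2 <- compute_tgm(ep, y, cv)
  expect_identical(tg$accuracy, tg2$accuracy)
})

test_that("a stationary additive effect generalizes broadly; no effect stays at chance", {
  cv <- cv_scheme(n_outer = 5, n_inner = 0, lambda_grid = 10, seed = 2)
  cf <- sim_config(n_trials = 40, n_channels = 4, n_categories = 2, fs = 25,
                   additive_shift = c(animacy = 2), osc_amp = 0,
                   trend_onset = 0, trend_rise = 0.04,
                   noise_sd = 0.5, seed = 31)
  g <- generate_trials(cf)
  y <- ifelse(g$epochs$attributes$animacy == 1, 1, -1)
  # decoded unstandardized: the effect IS the per-trial offset
  tg <- compute_tgm(g$epochs, y, cv)
  # restrict to the post-onset plateau where the effect lives
  win <- 5:25
  A <- tg$accuracy[win, win]
  dg <- mean(diag(A))
  offd <- mean(A[row(A) != col(A)])
  expect_lt(abs(dg - offd), 0.05)
  expect_gt(dg, 0.8)
  # null data: everything near chance
  cf0 <- sim_config(n_trials = 40, n_channels = 4, n_categories = 2, fs = 25,
                    noise_sd = 1, seed = 32)
  g0 <- generate_trials(cf0)
  y0 <- ifelse(g0$epochs$attributes$animacy == 1, 1, -1)
  tg0 <- compute_tgm(standardize_trial(g0$epochs), y0, cv)
  expect_lt(abs(mean(tg0$accuracy) - 0.5), 0.05)
})

test_that("phase opposition produces below-chance lobes at half-cycle separations", {
  cf <- sim_config(n_trials = 60, n_channels = 8, n_categories = 2, fs = 100,
                   global_shift = c(animacy = 1 / 14),  # half of a 7 Hz cycle
                   latency_jitter_sd = 0.005, trend_amp = 0,
                   noise_sd = 0.5, seed = 7)
  g <- generate_trials(cf)
  y <- ifelse(g$epochs$attributes$animacy == 1, 1, -1)
  ep <- standardize_trial(lowpass_filter(g$epochs, 10))
  cv <- cv_scheme(n_outer = 5, n_inner = 0, lambda_grid = 8, seed = 2)
  tg <- compute_tgm(ep, y, cv)
  tr <- tgm_rebound_trough(tg)
  expect_lt(tr$min_value, 0.5)
  expect_gte(tr$offset_ms, 25)
  expect_lte(tr$offset_ms, 110)
})

test_that("component TGMs dissociate trend-borne and phase-borne information", {
  cv <- cv_scheme(n_outer = 5, n_inner = 0, lambda_grid = 8, seed = 6)
  # trend-only effect
  cf_tr <- sim_config(n_trials = 40, n_channels = 4, n_categories = 2,
                      fs = 50, additive_shift = c(animacy = 1.2),
                      osc_amp = 0.3, noise_sd = 0.5, seed = 41)
  g <- generate_trials(cf_tr)
  y <- ifelse(g$epochs$attributes$animacy == 1, 1, -1)
  comps <- split_components(lowpass_filter(g$epochs, 10))
  tgs <- tgm_for_components(comps, y, cv)
  expect_named(tgs, c("original", "trend", "oscillatory", "power"))
  expect_gt(mean(diag(tgs$trend$accuracy)), mean(diag(tgs$oscillatory$accuracy)))
  expect_lt(abs(mean(tgs$oscillatory$accuracy) - 0.5), 0.08)
  # phase-only effect: power envelope is class-invariant
  cf_ph <- sim_config(n_trials = 40, n_channels = 4, n_categories = 2,
                      fs = 50, global_shift = c(animacy = 1 / 14),
                      latency_jitter_sd = 0.005, trend_amp = 0,
                      noise_sd = 0.4, seed = 43)
  g2 <- generate_trials(cf_ph)
  y2 <- ifelse(g2$epochs$attributes$animacy == 1, 1, -1)
  comps2 <- split_components(lowpass_filter(g2$epochs, 10))
  tgs2 <- tgm_for_components(comps2, y2, cv)
  expect_gt(mean(diag(tgs2$oscillatory$accuracy)), 0.7)
  expect_lt(abs(mean(diag(tgs2$power$accuracy)) - 0.5), 0.12)
  # identical fold seed: bit-identical output
  tgs2b <- tgm_for_components(comps2, y2, cv)
  expect_identical(tgs2$oscillatory$accuracy, tgs2b$oscillatory$accuracy)
})

test_that("TGM attribution recovers exact and noisy mixtures", {
  set.seed(10)
  T <- 50
  A <- matrix(runif(T * T, 0.4, 0.9), T, T)
  B <- matrix(runif(T * T, 0.4, 0.9), T, T)
  target <- 0.2 + 0.5 * A + 0.3 * B
  fit <- tgm_attribution(target, list(a = A, b = B))
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # independent-noise target
  noise_t <- matrix(runif(T * T), T, T)
  expect_lt(tgm_attribution(noise_t, list(a = A, b = B))$r_squared, 0.05)
  # mixture with noise tuned to R^2 = 0.8 (analytic variance partition)
  r2s <- numeric(60)
  for (r in seq_len(60)) {
    set.seed(r)
    A <- matrix(rnorm(T * T), T, T)
    B <- matrix(rnorm(T * T), T, T)
    sig <- 0.7 * A + 0.3 * B
    noise_sd <- sd(sig) * sqrt(1 / 0.8 - 1)
    tgt <- sig + matrix(rnorm(T * T, 0, noise_sd), T, T)
    r2s[r] <- tgm_attribution(tgt, list(A, B))$r_squared
  }
  expect_lt(abs(mean(r2s) - 0.80), 0.03)
  expect_error(tgm_attribution(matrix(1, 2, 1), list(matrix(1, 2, 1),
                                                     matrix(2, 2, 1),
                                                     matrix(3, 2, 1))),
               "fewer")
})

test_that("tgm_sections reports symmetric sections and truncates at the bounds", {
  T <- 30
  S <- matrix(0.5, T, T)
  S <- (S + t(S)) / 2
  tg <- structure(list(accuracy = S, contrast = NULL,
                       cv = cv_scheme(seed = 1), fs = 100),
                  class = "tgm")
  sec <- tgm_sections(tg, 15, 5)
  expect_equal(sec$section$values, rev(sec$section$values))
  expect_equal(sec$diagonal_mean, 0.5)
  expect_equal(sec$offdiag_mean, 0.5)
  # truncation near the edge, with the realized length reported
  sec_edge <- tgm_sections(tg, 2, 10)
  expect_lt(sec_edge$section$length, 21)
  expect_equal(sec_edge$section$length, length(sec_edge$section$values))
})
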