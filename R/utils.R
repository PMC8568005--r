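#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

#' Analytic signal of a real time series
#'
#' FFT-based analytic signal: negative frequencies are zeroed, positive
#' frequencies doubled, DC (and Nyquist, for even length) kept.  The
#' imaginary part is the Hilbert transform of the input.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  stop_if(any(!is.finite(x)), "analytic_signal: input must be finite")
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Tukey (cosine-tapered) window supported on sample indices [i0, i1] of a
# length-n vector; zero outside, flat in the middle, raised-cosine ramps of
# fractional length `taper/2` at each end of the support.
tukey_support <- function(n, i0, i1, taper = 0.5) {
  w <- numeric(n)
  m <- i1 - i0 + 1
  if (m <= 0) return(w)
  r <- min(max(taper, 0), 1)
  wt <- rep(1, m)
  edge <- floor(r * (m - 1) / 2)
  if (edge > 0) {
    k <- 0:(edge - 1)
    ramp <- 0.5 * (1 + cos(pi * (k / edge - 1)))
    wt[1:edge] <- ramp
    wt[m:(m - edge + 1)] <- ramp
  }
  w[i0:i1] <- wt
  w
}

#' Ordered-pair count for pairwise decoding
#'
#' Number of ordered pairs of distinct categories, the bookkeeping count
#' used when every unordered category pair is decoded in both directions
#' (118 categories give 13806).
#'
#' @param n_categories number of stimulus categories.
#' @return integer count `n * (n - 1)`.
#' @export
ordered_pair_count <- function(n_categories) {
  stop_if(n_categories < 2, "need at least two categories")
  as.integer(n_categories) * (as.integer(n_categories) - 1L)
}

#' Number of decoders used by standard time-resolved decoding
#'
#' Standard decoding trains one decoder per sample, so a trial of
#' `trial_dur` seconds at `fs` Hz uses `round(fs * trial_dur)` decoders
#' (250 for a 1-s trial at 250 Hz).
#'
#' @param fs sampling rate in Hz.
#' @param trial_dur trial duration in seconds.
#' @return integer decoder count.
#' @export
n_standard_decoders <- function(fs = 250, trial_dur = 1.0) {
  stop_if(fs <= 0 || trial_dur <= 0, "fs and trial_dur must be positive")
  as.integer(round(fs * trial_dur))
}

# Deterministic per-unit seed derived from a master seed, kept within the
# 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(index)) %% 2147483647)
}

# Classification accuracy for sign-decoded predictions of +/-1 labels;
# exact zeros count as half right.
sign_accuracy <- function(yhat, y) {
  s <- sign(yhat)
  mean(ifelse(s == 0, 0.5, (s == sign(y)) * 1))
}

# Zero-phase IIR filtering of many series at once (rows of X), forward
# and backward passes in direct-form-II-transposed with steady-state
# initial conditions (the lfilter_zi construction), vectorized over rows.
# Callers are expected to pad the series; transients then decay in the
# padding.
zero_phase_filter <- function(b, a, X) {
  b <- b / a[1]
  a <- a / a[1]
  n <- length(a) - 1
  stopifnot(length(b) == n + 1, n >= 1)
  # steady-state state vector for a unit-step input
  comp <- rbind(-a[-1], cbind(diag(1, n - 1), matrix(0, n - 1, 1)))
  zi <- solve(diag(n) - t(comp), b[-1] - a[-1] * b[1])
  one_pass <- function(M) {
    S <- nrow(M)
    T <- ncol(M)
    Y <- matrix(0, S, T)
    Z <- outer(M[, 1], zi)
    for (t in seq_len(T)) {
      xt <- M[, t]
      yt <- b[1] * xt + Z[, 1]
      if (n > 1) {
        Z[, 1:(n - 1)] <- Z[, 2:n, drop = FALSE] +
          outer(xt, b[2:n]) - outer(yt, a[2:n])
      }
      Z[, n] <- xt * b[n + 1] - yt * a[n + 1]
      Y[, t] <- yt
    }
    Y
  }
  Y <- one_pass(X)
  one_pass(Y[, ncol(Y):1, drop = FALSE])[, ncol(Y):1, drop = FALSE]
}
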