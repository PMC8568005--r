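# Instantaneous phase/amplitude of the oscillatory component, the
# phase-locking factor (PLF), and decoder-aligned phase windows.

#' Instantaneous phase and amplitude envelope
#'
#' Analytic-signal estimate per trial and channel of the (already
#' band-limited) oscillatory component.  The first and last 5% of each
#' trial are flagged unreliable (analytic-signal edge effects) and are
#' excluded from PLF summaries by default.
#'
#' @param oscillatory `[N, C, T]` array (e.g. the `oscillatory` element of
#'   [split_components()]) or a `signal_components` object.
#' @param fs sampling rate, Hz (taken from the components object if given).
#' @param edge_frac fraction of samples flagged unreliable at each end.
#' @return object of class `phase_tensor`: `phase` (radians in (-pi, pi],
#'   `[N, C, T]`), `envelope` (same shape, >= 0), `fs`, and the logical
#'   `reliable` time index.  All-zero series give `NA` phase and a warning.
#' @export
analytic_phase <- function(oscillatory, fs = NULL, edge_frac = 0.05) {
  if (inherits(oscillatory, "signal_components")) {
    fs <- oscillatory$fs
    oscillatory <- oscillatory$oscillatory
  }
  stop_if(is.null(fs), "fs is required when passing a bare array")
  dm <- dim(oscillatory)
  stop_if(length(dm) != 3, "expected an [N, C, T] array")
  ph <- array(NA_real_, dm)
  env <- array(0, dm)
  degenerate <- 0L
  for (n in seq_len(dm[1])) {
    for (c in seq_len(dm[2])) {
      x <- oscillatory[n, c, ]
      if (all(x == 0)) {
        degenerate <- degenerate + 1L
        next
      }
      z <- analytic_signal(x)
      ph[n, c, ] <- Arg(z)
      env[n, c, ] <- Mod(z)
    }
  }
  if (degenerate > 0)
    warning(degenerate, " all-zero series: phase undefined (NA)")
  T <- dm[3]
  edge <- max(1L, ceiling(edge_frac * T))
  reliable <- rep(TRUE, T)
  reliable[c(seq_len(edge), (T - edge + 1L):T)] <- FALSE
  structure(list(phase = ph, envelope = env, fs = fs, reliable = reliable),
            class = "phase_tensor")
}

#' Phase-locking factor
#'
#' Modulus of the across-trial mean unit phasor,
#' `PLF = |mean(exp(i phi))|`: 1 for perfectly aligned phases, near 0 for
#' uniformly scattered ones (expectation `sqrt(pi)/(2 sqrt(N))` under a
#' uniform phase distribution).
#'
#' @param phases numeric vector of phases (radians) across trials.
#' @return PLF value in `[0, 1]`.
#' @export
plf <- function(phases) {
  stop_if(length(phases) < 1, "need at least one phase")
  Mod(mean(exp(1i * phases)))
}

#' PLF matrix over time and channels
#'
#' @param pt a [analytic_phase()] result.
#' @param reliable_only mask unreliable edge samples to `NA`.
#' @return `T x C` matrix of PLF values across trials.
#' @export
plf_matrix <- function(pt, reliable_only = TRUE) {
  stop_if(!inherits(pt, "phase_tensor"), "pt must be a phase_tensor")
  dm <- dim(pt$phase)
  Z <- exp(1i * pt$phase)
  out <- t(apply(Z, c(2, 3), function(v) Mod(mean(v))))  # T x C
  if (reliable_only) out[!pt$reliable, ] <- NA_real_
  out
}

#' Decoder-aligned phase windows
#'
#' Extracts, per trial, the phases of the samples assigned to decoder `k`
#' (argmax responsibility) and resamples them to a common length by
#' nearest-index picking (no interpolation of wrapped angles across the
#' branch cut).  Trials where the state never activates are excluded and
#' counted.
#'
#' @param pt a [analytic_phase()] result.
#' @param gamma responsibilities `T x N x K` (or a `tuda_fit`).
#' @param k state index.
#' @param L common resampled window length (>= 1).
#' @return array `[n_kept, L, C]` of phases; attributes `kept` (trial
#'   indices) and `n_excluded`.
#' @export
decoder_aligned_phases <- function(pt, gamma, k, L) {
  stop_if(!inherits(pt, "phase_tensor"), "pt must be a phase_tensor")
  stop_if(L < 1, "L must be >= 1")
  if (inherits(gamma, "tuda_fit")) gamma <- gamma$gamma
  dm <- dim(pt$phase)
  stop_if(dim(gamma)[1] != dm[3] || dim(gamma)[2] != dm[1],
          "gamma must be T x N x K congruent with the phase tensor")
  path <- state_path(gamma)
  kept <- integer(0)
  rows <- list()
  for (n in seq_len(dm[1])) {
    idx <- which(path[, n] == k)
    if (!length(idx)) next
    pos <- idx[pmin(length(idx), pmax(1, round(seq(1, length(idx),
                                                   length.out = L))))]
    kept <- c(kept, n)
    rows[[length(rows) + 1]] <- pt$phase[n, , pos, drop = FALSE]
  }
  stop_if(!length(kept), "state ", k, " never activates in any trial")
  out <- array(NA_real_, c(length(kept), L, dm[2]))
  for (i in seq_along(rows)) {
    out[i, , ] <- t(matrix(rows[[i]][1, , ], dm[2], L))
  }
  attr(out, "kept") <- kept
  attr(out, "n_excluded") <- dm[1] - length(kept)
  out
}

#' Per-trial global phase latency within a time window
#'
#' Estimates each trial's global (channel-common) oscillatory latency as
#' the arithmetic mean over channels of the trial's per-channel phase
#' offset from the across-trial reference, converted to seconds by the
#' carrier frequency.  Averaging offsets across channels makes the
#' estimate exactly insensitive to relative phase configurations that sum
#' to zero over channels, and exactly sensitive to a common shift --
#' the construction that dissociates the two effects.  Label-free, so
#' latency statistics built on it cannot encode class labels through the
#' realignment itself.
#'
#' @param pt a [analytic_phase()] result.
#' @param window integer sample indices defining the (decoder) window.
#' @param carrier_freq oscillation frequency in Hz used to convert phase
#'   to time.
#' @return numeric vector of per-trial latencies in seconds (positive =
#'   later than the reference); attribute `offsets` holds the `[N, C]`
#'   per-channel phase offsets in radians.
#' @export
global_phase_latency <- function(pt, window, carrier_freq) {
  stop_if(!inherits(pt, "phase_tensor"), "pt must be a phase_tensor")
  dm <- dim(pt$phase)
  stop_if(any(window < 1 | window > dm[3]), "window outside the trial")
  Z <- exp(1i * pt$phase[, , window, drop = FALSE])
  ref <- apply(Z, c(2, 3), mean)                       # C x W across trials
  u <- matrix(0, dm[1], dm[2])
  for (n in seq_len(dm[1])) {
    zn <- matrix(Z[n, , ], dm[2], length(window))
    u[n, ] <- Arg(rowSums(zn * Conj(ref)))
  }
  tau <- rowMeans(u) / (2 * pi * carrier_freq)
  attr(tau, "offsets") <- u
  tau
}

#' Remove each trial's global phase offset
#'
#' Subtracts the per-trial mean (over channels) phase offset from a phase
#' window, so that only the cross-channel relative configuration remains.
#'
#' @param phases `[N, L, C]` array (e.g. [decoder_aligned_phases()]).
#' @param offsets per-trial global offsets in radians (e.g. mean of the
#'   `offsets` attribute of [global_phase_latency()]).
#' @return array of the same shape, wrapped to (-pi, pi].
#' @export
remove_global_phase <- function(phases, offsets) {
  stop_if(dim(phases)[1] != length(offsets),
          "offsets must have one entry per trial")
  out <- sweep(phases, 1, offsets, "-")
  Arg(exp(1i * out))
}
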