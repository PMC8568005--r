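# Separation of each trial/channel signal into an uncorrelated slow
# (non-oscillatory) trend and an oscillatory residual, plus spectral and
# peak-count characterization of the two components.

#' Zero-phase low-pass filter
#'
#' Forward-backward (zero-phase) Butterworth low-pass of order 5, applied
#' per trial and channel.  Zero-phase filtering is used so that phase
#' analyses downstream are not biased by filter delay.
#'
#' @param epochs an [epoch_set()].
#' @param cutoff cutoff frequency, Hz; must be below Nyquist.
#' @param order filter order (per pass).
#' @return filtered `epoch_set` of the same shape.
#' @export
lowpass_filter <- function(epochs, cutoff = 10, order = 5) {
  stop_if(!inherits(epochs, "epoch_set"), "epochs must be an epoch_set")
  nyq <- epochs$fs / 2
  stop_if(cutoff >= nyq,
          sprintf("cutoff (%g Hz) must be below Nyquist (%g Hz)", cutoff, nyq))
  bt <- signal::butter(order, cutoff / nyq, type = "low")
  d <- epochs$data
  dm <- dim(d)
  T <- dm[3]
  pad <- min(T - 1, max(3 * order, ceiling(3 * epochs$fs / cutoff)))
  X <- matrix(d, dm[1] * dm[2], T)
  ext <- cbind(2 * X[, 1] - X[, (pad + 1):2, drop = FALSE],
               X,
               2 * X[, T] - X[, (T - 1):(T - pad), drop = FALSE])
  Y <- zero_phase_filter(bt$b, bt$a, ext)
  epochs$data <- array(Y[, (pad + 1):(pad + T), drop = FALSE], dm)
  epochs
}

#' Anti-aliased integer decimation
#'
#' Low-passes at 80% of the new Nyquist frequency, then keeps every
#' `factor`-th sample.  Intended for imported data recorded above the
#' working rate; synthetic data generated at the working rate needs none.
#'
#' @param epochs an [epoch_set()].
#' @param factor integer decimation factor >= 1.
#' @return decimated `epoch_set` with updated sampling rate.
#' @export
decimate_epochs <- function(epochs, factor) {
  stop_if(factor < 1 || factor != round(factor), "factor must be a positive integer")
  if (factor == 1) return(epochs)
  new_fs <- epochs$fs / factor
  ep <- lowpass_filter(epochs, cutoff = 0.8 * new_fs / 2)
  keep <- seq(1, dim(ep$data)[3], by = factor)
  ep$data <- ep$data[, , keep, drop = FALSE]
  ep$fs <- new_fs
  ep
}

#' Slow trend by tricube-weighted local linear regression
#'
#' Local regression with weighted linear least squares and a first-degree
#' polynomial (classic lowess with no robustness iterations), evaluated at
#' every sample.  The default span uses 100 points for a 1-s trial at the
#' 250 Hz working rate: the window covers almost three theta cycles, so
#' the oscillation averages out of the trend while slower structure stays.
#' Narrower spans let theta leak into the trend and defeat the
#' decomposition.
#'
#' @param x numeric vector, one trial/channel time series.
#' @param span_frac fraction of the series length used per local fit
#'   (0.40 = 100 points at T = 250).
#' @return numeric vector: the slow trend, same length as `x`.
#' @export
loess_trend <- function(x, span_frac = 0.40) {
  stop_if(any(is.na(x)), "loess_trend: NA input rejected")
  T <- length(x)
  stop_if(span_frac <= 0 || span_frac > 1, "span_frac must be in (0, 1]")
  stop_if(T < 2 || max(2, floor(span_frac * T)) > T,
          "series shorter than the local window")
  stats::lowess(seq_len(T), x, f = span_frac, iter = 0, delta = 0)$y
}

#' Split epochs into trend and oscillatory components
#'
#' Per trial and channel: the slow trend is estimated by [loess_trend()],
#' then regressed onto the signal (least squares with intercept); the
#' fitted curve is the non-oscillatory component and the residual is the
#' detrended oscillatory component.  By construction the two components
#' are exactly uncorrelated and sum to the input.
#'
#' @param epochs an [epoch_set()], normally already low-passed.
#' @param span_frac lowess span as a fraction of the trial.
#' @return object of class `signal_components`: arrays `trend` and
#'   `oscillatory` congruent with `epochs$data`, the regression `scale`
#'   `[N, C]`, plus `fs`, `labels`, `attributes`.
#' @export
split_components <- function(epochs, span_frac = 0.40) {
  stop_if(!inherits(epochs, "epoch_set"), "epochs must be an epoch_set")
  d <- epochs$data
  dm <- dim(d)
  trend <- array(0, dm)
  osc <- array(0, dm)
  scale <- matrix(0, dm[1], dm[2])
  for (n in seq_len(dm[1])) {
    for (c in seq_len(dm[2])) {
      x <- d[n, c, ]
      tr <- loess_trend(x, span_frac)
      trc <- tr - mean(tr)
      ss <- sum(trc^2)
      if (ss < .Machine$double.eps * length(x)) {
        b <- 0
      } else {
        b <- sum(trc * (x - mean(x))) / ss
      }
      a <- mean(x) - b * mean(tr)
      fit <- a + b * tr
      trend[n, c, ] <- fit
      osc[n, c, ] <- x - fit
      scale[n, c] <- b
    }
  }
  structure(list(trend = trend, oscillatory = osc, scale = scale,
                 fs = epochs$fs, labels = epochs$labels,
                 attributes = epochs$attributes, channels = epochs$channels),
            class = "signal_components")
}

#' @export
print.signal_components <- function(x, ...) {
  d <- dim(x$trend)
  cat(sprintf("signal_components: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  invisible(x)
}

#' Average power spectra of the two components
#'
#' Raw periodograms per trial and channel, averaged over trials, reported
#' per channel and component.  On generator defaults the oscillatory
#' component's power peaks in the theta band (6-8 Hz) and the trend shows
#' no peak above the lowest frequencies.
#'
#' @param components a [split_components()] result.
#' @return object of class `spectral_profile`: `freq` (Hz, increasing) and
#'   `power`, a list with `trend` and `oscillatory` matrices
#'   `[n_freq, n_channels]` of trial-averaged power.
#' @export
component_spectra <- function(components) {
  stop_if(!inherits(components, "signal_components"),
          "components must come from split_components()")
  dm <- dim(components$trend)
  stop_if(dm[1] < 1, "need at least one trial")
  T <- dm[3]
  stop_if(T < 4, "trial shorter than one spectral window")
  one <- function(x) {
    sp <- stats::spec.pgram(stats::ts(x, frequency = components$fs),
                            taper = 0, detrend = FALSE, fast = FALSE,
                            plot = FALSE)
    sp$spec
  }
  freq <- stats::spec.pgram(stats::ts(components$trend[1, 1, ],
                                      frequency = components$fs),
                            taper = 0, detrend = FALSE, fast = FALSE,
                            plot = FALSE)$freq
  acc <- function(arr) {
    pw <- matrix(0, length(freq), dm[2])
    for (c in seq_len(dm[2])) {
      for (n in seq_len(dm[1])) pw[, c] <- pw[, c] + one(arr[n, c, ])
      pw[, c] <- pw[, c] / dm[1]
    }
    pw
  }
  structure(list(freq = freq,
                 power = list(trend = acc(components$trend),
                              oscillatory = acc(components$oscillatory))),
            class = "spectral_profile")
}

#' Count strict interior local maxima
#'
#' Number of interior samples that strictly exceed both neighbours;
#' plateaus (runs of equal values strictly above their flanks) are counted
#' once, at their left edge.  Endpoints are never peaks.
#'
#' @param x numeric vector, length >= 3.
#' @return integer peak count.
#' @export
count_peaks <- function(x) {
  stop_if(length(x) < 3, "need at least 3 samples")
  # collapse plateaus: one value per run of equal consecutive samples
  v <- rle(x)$values
  m <- length(v)
  if (m < 3) return(0L)
  inner <- 2:(m - 1)
  sum(v[inner] > v[inner - 1] & v[inner] > v[inner + 1])
}
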