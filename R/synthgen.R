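# Synthetic epoched-data generator with recorded ground truth.
#
# Emulates the structure the downstream analyses assume: each trial is a
# slow stimulus-locked trend plus a transient theta-band oscillation plus
# noise, with four kinds of class effects that can be injected separately:
#   * a global latency (phase) shift of the oscillation, common to channels;
#   * relative per-channel phase offsets (zero-sum across channels);
#   * a multiplicative oscillatory power change;
#   * an additive shift carried by the slow trend.

#' Simulation configuration
#'
#' Builds and validates the configuration consumed by [generate_trials()].
#' Class effects are parameterized per category attribute ("animacy", two
#' levels, effect-coded -1/2, +1/2; "size", three levels, effect-coded
#' -1, 0, +1), so e.g. `global_shift = c(animacy = 0.04)` makes the two
#' animacy classes differ by 40 ms in oscillation latency.
#'
#' @param n_trials number of trials.
#' @param n_channels number of channels.
#' @param n_categories number of stimulus categories; categories are mapped
#'   to animacy/size cells round-robin unless `attribute_map` is given.
#' @param fs sampling rate, Hz.
#' @param trial_dur trial duration, seconds; `n_time = round(fs * trial_dur)`.
#' @param carrier_freq oscillation frequency, Hz (theta-band default 7).
#' @param attribute_map data.frame with columns `category`, `animacy`
#'   (0/1) and `size` (1/2/3), one row per category.
#' @param global_shift named numeric, seconds: between-class latency
#'   difference per contrast (`animacy` and/or `size`).
#' @param relative_phase named list of per-channel phase-offset vectors
#'   (radians, length `n_channels`) per contrast; centered to sum to zero
#'   across channels unless `center_relative_phase = FALSE`.
#' @param power_ratio named numeric > 0: multiplicative oscillatory power
#'   ratio between classes per contrast (1 = no effect).
#' @param additive_shift named numeric, signal units: additive trend
#'   amplitude difference between classes per contrast.
#' @param trend_onset,trend_rise onset and rise time of the slow trend
#'   (half-Gaussian ramp to a plateau), seconds.
#' @param trend_amp baseline trend amplitude, signal units.
#' @param osc_amp baseline oscillation amplitude, signal units.
#' @param osc_window two-element vector, seconds: support of the Tukey
#'   taper confining the evoked oscillation (default onset to 0.7 s).
#' @param base_phase class-independent per-channel phase profile of the
#'   oscillation (radians, length `n_channels`, or a single spread value
#'   `s` for an evenly spaced profile in `[-s/2, s/2]`).  Gives channels
#'   distinct carrier phases, as sensors at different positions see; the
#'   default 0 makes all channels cophasal.
#' @param latency_jitter_sd per-trial zero-mean Gaussian latency jitter sd,
#'   seconds, truncated at +/-100 ms.
#' @param noise_sd additive Gaussian noise sd, signal units.
#' @param ar1 optional AR(1) coefficient for temporally correlated channel
#'   noise (0 = white).
#' @param center_relative_phase center relative-phase vectors to zero sum.
#' @param seed integer seed; the generator is deterministic given the config.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_trials, n_channels, n_categories = 2,
                       fs = 250, trial_dur = 1.0, carrier_freq = 7,
                       attribute_map = NULL,
                       global_shift = c(animacy = 0, size = 0),
                       relative_phase = NULL,
                       power_ratio = c(animacy = 1, size = 1),
                       additive_shift = c(animacy = 0, size = 0),
                       trend_onset = 0.05, trend_rise = 0.25,
                       trend_amp = 1, osc_amp = 1,
                       osc_window = c(NA, 0.7),
                       base_phase = 0,
                       latency_jitter_sd = 0.02,
                       noise_sd = 1, ar1 = 0,
                       center_relative_phase = TRUE,
                       seed = 1) {
  stop_if(n_trials < 1 || n_channels < 1 || n_categories < 1,
          "n_trials, n_channels and n_categories must be positive")
  stop_if(fs <= 0 || trial_dur <= 0, "fs and trial_dur must be positive")
  n_time <- as.integer(round(fs * trial_dur))
  stop_if(n_time < 2, "trial too short: round(fs * trial_dur) < 2")

  fill2 <- function(x, default = 0) {
    out <- c(animacy = default, size = default)
    if (length(x)) {
      stop_if(is.null(names(x)) || !all(names(x) %in% names(out)),
              "effect vectors must be named with 'animacy' and/or 'size'")
      out[names(x)] <- x
    }
    stop_if(any(!is.finite(out)), "effect amplitudes must be finite")
    out
  }
  global_shift   <- fill2(global_shift)
  additive_shift <- fill2(additive_shift)
  power_ratio    <- fill2(power_ratio, default = 1)
  stop_if(any(power_ratio <= 0), "power_ratio must be > 0")

  rp <- list(animacy = numeric(n_channels), size = numeric(n_channels))
  if (!is.null(relative_phase)) {
    stop_if(!is.list(relative_phase) ||
              !all(names(relative_phase) %in% c("animacy", "size")),
            "relative_phase must be a named list over 'animacy'/'size'")
    for (nm in names(relative_phase)) {
      v <- relative_phase[[nm]]
      stop_if(length(v) != n_channels,
              sprintf("relative_phase$%s has length %d, expected n_channels = %d",
                      nm, length(v), n_channels))
      stop_if(any(!is.finite(v)), "relative_phase must be finite")
      if (center_relative_phase) v <- v - mean(v)
      rp[[nm]] <- v
    }
  }

  if (is.null(attribute_map)) {
    attribute_map <- data.frame(
      category = seq_len(n_categories),
      animacy = rep_len(c(0L, 1L), n_categories),
      size = rep_len(rep(1:3, each = 2), n_categories)
    )
  }
  stop_if(!all(c("category", "animacy", "size") %in% names(attribute_map)),
          "attribute_map needs columns category, animacy, size")
  stop_if(!setequal(attribute_map$category, seq_len(n_categories)) ||
            anyDuplicated(attribute_map$category) > 0,
          "attribute_map must cover every category exactly once")

  if (is.na(osc_window[1])) osc_window[1] <- trend_onset
  if (length(base_phase) == 1 && n_channels > 1) {
    base_phase <- seq(-base_phase / 2, base_phase / 2, length.out = n_channels)
  }
  stop_if(length(base_phase) != n_channels && !(n_channels == 1 && length(base_phase) == 1),
          "base_phase must have length n_channels (or be a single spread)")

  cfg <- list(
    n_trials = as.integer(n_trials), n_channels = as.integer(n_channels),
    n_categories = as.integer(n_categories), n_time = n_time,
    fs = fs, trial_dur = trial_dur, carrier_freq = carrier_freq,
    attribute_map = attribute_map,
    global_shift = global_shift, relative_phase = rp,
    power_ratio = power_ratio, additive_shift = additive_shift,
    trend_onset = trend_onset, trend_rise = trend_rise,
    trend_amp = trend_amp, osc_amp = osc_amp, osc_window = osc_window,
    base_phase = base_phase,
    latency_jitter_sd = latency_jitter_sd,
    noise_sd = noise_sd, ar1 = ar1, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Construct an epoched data set
#'
#' Container for trials x channels x time data with labels and category
#' attributes; the object every analysis stage consumes.
#'
#' @param data numeric array `[N, C, T]`, finite.
#' @param fs sampling rate, Hz.
#' @param labels integer category id per trial.
#' @param attributes data.frame with per-trial `animacy` and `size`.
#' @param channels optional channel ids.
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, labels, attributes = NULL, channels = NULL) {
  stop_if(!is.array(data) || length(dim(data)) != 3,
          "data must be a 3-D array [trials x channels x time]")
  d <- dim(data)
  stop_if(any(d < 1), "all dimensions must be >= 1")
  stop_if(any(!is.finite(data)), "data contains NaN/Inf")
  stop_if(length(labels) != d[1], "labels length must equal the trial count")
  if (is.null(channels)) channels <- paste0("ch", seq_len(d[2]))
  if (is.null(attributes)) {
    attributes <- data.frame(animacy = rep(NA_integer_, d[1]),
                             size = rep(NA_integer_, d[1]))
  }
  structure(list(data = data, fs = fs, labels = labels,
                 attributes = attributes, channels = channels),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("epoch_set: %d trials x %d channels x %d samples @ %g Hz, %d categories\n",
              d[1], d[2], d[3], x$fs, length(unique(x$labels))))
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d trials, %d channels, %d samples @ %g Hz, carrier %g Hz, seed %d\n",
              x$n_trials, x$n_channels, x$n_time, x$fs, x$carrier_freq, x$seed))
  invisible(x)
}

# Effect code per trial for a contrast: animacy in {-1/2, +1/2},
# size in {-1, 0, +1}.
effect_code <- function(attr, contrast) {
  switch(contrast,
         animacy = attr$animacy - 0.5,
         size = attr$size - 2,
         stop("unknown contrast: ", contrast))
}

#' Generate one subject's epoched trials with ground truth
#'
#' Emits `data[n, c, t] = trend(n, c, t) + amp(n, c) *
#' cos(2 pi f (t - shift(n)) + phi(c, class(n))) * window(t) + noise`,
#' where the Tukey `window` confines the evoked oscillation to a post-onset
#' interval, `shift` carries the class latency effect plus truncated
#' per-trial jitter, `phi` carries zero-sum relative per-channel phase
#' offsets, `amp` carries the multiplicative power effect, and the
#' half-Gaussian trend carries the additive effect.  Everything injected is
#' recorded in the returned ground truth; the emitted data is reproducible
#' bit for bit from the config seed.
#'
#' @param config a [sim_config()].
#' @return list with elements `epochs` (an [epoch_set()]) and `truth`
#'   (class `ground_truth`: arrays `trend`, `oscillation`, `noise`
#'   congruent with the data; per-trial `latency_shift` in seconds;
#'   `phase_offsets` `[N, C]` radians; `labels`, `attributes`).
#' @export
generate_trials <- function(config) {
  stop_if(!inherits(config, "sim_config"), "config must be a sim_config")
  cf <- config
  N <- cf$n_trials; C <- cf$n_channels; T <- cf$n_time
  set.seed(cf$seed)

  labels <- rep_len(seq_len(cf$n_categories), N)
  attr_tr <- cf$attribute_map[match(labels, cf$attribute_map$category),
                              c("animacy", "size"), drop = FALSE]
  rownames(attr_tr) <- NULL
  ca <- effect_code(attr_tr, "animacy")
  cs <- effect_code(attr_tr, "size")

  tsec <- (seq_len(T) - 1) / cf$fs

  # slow trend: half-Gaussian ramp to a plateau, class-dependent amplitude
  ramp <- numeric(T)
  sig <- cf$trend_rise / 2
  pk <- cf$trend_onset + cf$trend_rise
  rising <- tsec >= cf$trend_onset & tsec < pk
  ramp[rising] <- exp(-((tsec[rising] - pk)^2) / (2 * sig^2))
  ramp[tsec >= pk] <- 1
  trend_amp_tr <- cf$trend_amp +
    cf$additive_shift["animacy"] * ca + cf$additive_shift["size"] * cs

  # latency: class shift plus truncated per-trial jitter
  jitter <- stats::rnorm(N, 0, cf$latency_jitter_sd)
  jitter <- pmin(pmax(jitter, -0.1), 0.1)
  if (cf$latency_jitter_sd == 0) jitter <- numeric(N)
  shift <- cf$global_shift["animacy"] * ca + cf$global_shift["size"] * cs + jitter

  # per-trial/channel oscillation amplitude (multiplicative power effect)
  amp_tr <- cf$osc_amp * cf$power_ratio["animacy"]^ca * cf$power_ratio["size"]^cs

  # zero-sum relative phase offsets per channel, scaled by the class code,
  # on top of the class-independent per-channel base profile
  phi <- outer(ca, cf$relative_phase$animacy) + outer(cs, cf$relative_phase$size)
  phi <- phi + matrix(cf$base_phase, nrow(phi), ncol(phi), byrow = TRUE)

  i0 <- max(1L, as.integer(round(cf$osc_window[1] * cf$fs)) + 1L)
  i1 <- min(T, as.integer(round(cf$osc_window[2] * cf$fs)))
  win <- tukey_support(T, i0, i1, taper = 0.5)

  trend <- array(0, dim = c(N, C, T))
  osc <- array(0, dim = c(N, C, T))
  for (n in seq_len(N)) {
    tr_n <- trend_amp_tr[n] * ramp
    arg <- 2 * pi * cf$carrier_freq * (tsec - shift[n])
    for (c in seq_len(C)) {
      trend[n, c, ] <- tr_n
      osc[n, c, ] <- amp_tr[n] * cos(arg + phi[n, c]) * win
    }
  }

  noise <- array(stats::rnorm(N * C * T, 0, cf$noise_sd), dim = c(N, C, T))
  if (cf$ar1 != 0) {
    a <- cf$ar1
    stop_if(abs(a) >= 1, "ar1 coefficient must be in (-1, 1)")
    innov_sd <- cf$noise_sd * sqrt(1 - a^2)
    noise <- noise / cf$noise_sd * innov_sd
    for (t in 2:T) noise[, , t] <- a * noise[, , t - 1] + noise[, , t]
  }
  if (cf$noise_sd == 0) noise[] <- 0

  data <- trend + osc + noise
  ep <- epoch_set(data, cf$fs, labels, attr_tr)
  truth <- structure(list(trend = trend, oscillation = osc, noise = noise,
                          latency_shift = as.numeric(shift),
                          phase_offsets = phi, labels = labels,
                          attributes = attr_tr, config = cf),
                     class = "ground_truth")
  list(epochs = ep, truth = truth)
}

#' Generate a multi-subject cohort
#'
#' Subject-level seeds are derived deterministically from the master seed;
#' optional between-subject jitter multiplies the effect amplitudes
#' (`global_shift`, `additive_shift`, log `power_ratio`, `relative_phase`)
#' by `1 + rnorm(0, spread)` per subject, truncated at 0.1.
#'
#' @param config a [sim_config()] shared across subjects.
#' @param n_subjects number of subjects (>= 1).
#' @param seed master seed; defaults to the config seed.
#' @param spread sd of the multiplicative between-subject effect jitter.
#' @return list of `n_subjects` results of [generate_trials()].
#' @export
generate_cohort <- function(config, n_subjects, seed = config$seed, spread = 0) {
  stop_if(!inherits(config, "sim_config"), "config must be a sim_config")
  stop_if(n_subjects < 1, "n_subjects must be >= 1")
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    cf <- config
    cf$seed <- derive_seed(seed, s)
    if (spread > 0) {
      set.seed(derive_seed(seed, 100000 + s))
      g <- function() max(0.1, 1 + stats::rnorm(1, 0, spread))
      cf$global_shift <- cf$global_shift * c(g(), g())
      cf$additive_shift <- cf$additive_shift * c(g(), g())
      cf$power_ratio <- exp(log(cf$power_ratio) * c(g(), g()))
      cf$relative_phase <- lapply(cf$relative_phase, function(v) v * g())
    }
    out[[s]] <- generate_trials(cf)
  }
  out
}

#' Switching-regression data with a known decoder sequence
#'
#' Generates trials in which the mapping from channels to the label
#' switches through K successive coefficient vectors at per-trial jittered
#' boundary times: the ground-truth scenario for decoder-sequence
#' recovery studies.  Each state's coefficients load two channels; the
#' label enters as `y * beta_state` plus white noise.
#'
#' @param n_trials,n_channels,n_time,K dimensions.
#' @param seed integer seed.
#' @param noise white-noise sd.
#' @param boundary_jitter sd of the boundary jitter as a fraction of the
#'   trial length.
#' @return list with `X` (`[N, C, T]`), `y` (-1/+1), `betas` (`K x C`
#'   true coefficients), `bounds` (`N x (K-1)` true switch samples).
#' @export
generate_switching_regression <- function(n_trials, n_channels, n_time, K,
                                          seed = 1, noise = 0.4,
                                          boundary_jitter = 0.06) {
  stop_if(K < 2, "need at least 2 states")
  stop_if(n_channels < 2 * K %% n_channels + 2, "too few channels")
  set.seed(seed)
  y <- rep(c(-1, 1), length.out = n_trials)
  betas <- matrix(0, K, n_channels)
  for (k in seq_len(K)) {
    pick <- (((k - 1) * 2) %% n_channels) + c(1, 2)
    pick[pick > n_channels] <- pick[pick > n_channels] - n_channels
    betas[k, pick] <- c(1, -0.7)
  }
  bounds <- matrix(0, n_trials, K - 1)
  for (n in seq_len(n_trials)) {
    nominal <- (seq_len(K - 1) / K +
                  stats::rnorm(K - 1, 0, boundary_jitter)) * n_time
    bounds[n, ] <- sort(pmin(pmax(round(nominal), 2), n_time - 1))
  }
  X <- array(stats::rnorm(n_trials * n_channels * n_time, 0, noise),
             c(n_trials, n_channels, n_time))
  for (n in seq_len(n_trials)) {
    st <- vapply(seq_len(n_time), function(t) sum(t > bounds[n, ]) + 1L,
                 integer(1))
    for (t in seq_len(n_time)) {
      X[n, , t] <- X[n, , t] + y[n] * betas[st[t], ]
    }
  }
  list(X = X, y = y, betas = betas, bounds = bounds)
}
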