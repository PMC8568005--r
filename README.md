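# oscdecode

Where does time-resolved decoding accuracy in epoched electrophysiology
(MEG/EEG) actually come from?  `oscdecode` decomposes multichannel
trials into a slow **non-oscillatory trend** and a theta-band
**oscillatory residual**, and dissects the stimulus information each one
carries into three separable parts:

* the stable, non-oscillatory representation (carried by the trend);
* a **global phase/latency shift** of the oscillation — some stimuli are
  processed faster, delaying the oscillation equally at every channel;
* **relative phase differences across channels** — stimulus-specific
  multichannel phase configurations over and above processing speed.

The toolkit implements:

* an analytic trend/oscillation split per trial and channel (zero-phase
  Butterworth low-pass; tricube local linear regression with the trend
  regressed out, leaving exactly uncorrelated components);
* **temporal generalization matrices** (TGMs): cross-validated ridge
  decoders (labels ±1, nested penalty selection) trained at each time
  point and tested at all others, for the signal, each component, and
  the oscillatory power envelope under identical folds, with attribution
  (R² of one TGM from others) and anti-diagonal section/rebound-trough
  summaries;
* a **constrained decoder-sequence model** (temporally unconstrained
  decoding): K ridge decoders with per-trial activation time courses
  `γ[t, n, k]`, a left-to-right transition matrix, a window mask, and an
  equal-coefficient-sum constraint, fitted by penalized EM with an exact
  constrained forward–backward E-step and a provably monotone
  free-energy trace;
* **phase statistics**: analytic-signal phase/envelope, the phase-locking
  factor `PLF = |mean(exp(iφ))|`, decoder-aligned phase windows, and a
  per-trial global phase-latency estimator that is exactly insensitive to
  zero-sum relative phase configurations;
* **permutation tests** for global-latency and relative-phase effects per
  decoder window, combined across subjects with the non-parametric
  combination algorithm (Fisher function, synchronized permutations);
* a **synthetic-data generator** with recorded ground truth for every
  injected effect (latency shifts, relative phase, power, additive
  trend), plus a switching-regression generator for decoder-sequence
  recovery studies.

## Worked example

```r
library(oscdecode)

# two stimulus classes differing in trend amplitude (additive effect) and
# in their cross-channel phase configuration (relative phase effect)
cf <- sim_config(n_trials = 60, n_channels = 8, n_categories = 2, fs = 125,
                 additive_shift = c(animacy = 0.8),
                 relative_phase = list(animacy = 0.9 * rep(c(1, -1), 4)),
                 base_phase = pi / 2, noise_sd = 0.8, seed = 42)
sim <- generate_trials(cf)
sim$epochs
#> epoch_set: 60 trials x 8 channels x 125 samples @ 125 Hz, 2 categories

comps <- split_components(lowpass_filter(sim$epochs, 10))
y <- ifelse(sim$epochs$attributes$animacy == 1, 1, -1)
tgms <- tgm_for_components(comps, y,
          cv_scheme(n_outer = 5, n_inner = 0, lambda_grid = 8, seed = 1))
tgms$trend
#> tgm: 125 x 125, diagonal mean 0.692, off-diagonal mean 0.544
tgms$oscillatory
#> tgm: 125 x 125, diagonal mean 0.690, off-diagonal mean 0.509

att <- tgm_attribution(tgms$original,
                       list(trend = tgms$trend, oscillatory = tgms$oscillatory))
sprintf("attribution R^2: %.3f", att$r_squared)
#> "attribution R^2: 0.543"

tr <- tgm_rebound_trough(tgms$oscillatory)
sprintf("rebound trough: %.1f ms (accuracy %.2f)", tr$offset_ms, tr$min_value)
#> "rebound trough: 73.8 ms (accuracy 0.15)"
```

Both components decode the stimulus (diagonal means ≈ 0.69), but they
generalize differently: the trend's accuracy persists off the diagonal
(0.544 vs 0.509), while the oscillatory component's decoder *inverts*
half a theta cycle away from its training time — the rebound trough at
~74 ms separation dips far below the 0.5 chance level, which is the
signature of phase-borne information.  The component TGMs jointly
explain about half the variance of the recombined signal's TGM for a
single subject of this size; averaged over a 20-subject cohort the
complementarity pattern (oscillation dominates the diagonal, trend the
off-diagonal) is significant by sign-flip tests and the peak-row
attribution R² exceeds 0.9 (see the acceptance script below).

For the full chain — decoder-sequence fitting, decoder-window latency
and relative-phase hypothesis tests (`H_I`–`H_IV`), and group-level NPC
— see `run_hypothesis_battery()` and `run_pipeline()`, and the methods
vignette (`vignettes/methods.Rmd`) for the models, constraints, and
design decisions.

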