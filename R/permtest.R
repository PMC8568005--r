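# Permutation tests dissociating global latency effects (on decoder onset
# times) from relative cross-channel phase effects (on within-class PLF in
# decoder-aligned windows), and group-level non-parametric combination.

perm_outcome <- function(statistic, null, seed, id) {
  p <- (1 + sum(null >= statistic)) / (1 + length(null))
  structure(list(statistic = statistic, null = null, p = p,
                 n_perm = length(null), seed = seed, id = id),
            class = "perm_outcome")
}

#' @export
print.perm_outcome <- function(x, ...) {
  cat(sprintf("perm_outcome [%s]: statistic %.4g, p = %.4g (%d permutations)\n",
              x$id %||% "", x$statistic, x$p, x$n_perm))
  invisible(x)
}

#' Permutation test for a global latency difference
#'
#' Tests whether a decoder's onset time differs between two stimulus
#' classes: the statistic is the (absolute, by default) difference of
#' class-mean onsets, with a null from label permutation.  Missing onsets
#' (state never active in a trial) are dropped listwise.
#'
#' @param onsets numeric onset time per trial (samples or seconds);
#'   `NA` allowed.
#' @param labels two-class labels.
#' @param n_perm permutation count.
#' @param seed permutation seed.
#' @param two_sided if `FALSE`, uses the signed difference
#'   (first class minus second, sorted order).
#' @param id optional identifier stored in the outcome.
#' @return object of class `perm_outcome` with `statistic`, `null`, `p`
#'   (with the +1 correction, so never exactly 0), `n_perm`, `seed`.
#' @export
latency_perm_test <- function(onsets, labels, n_perm = 1000, seed = 1,
                              two_sided = TRUE, id = NULL) {
  keep <- !is.na(onsets)
  onsets <- onsets[keep]
  labels <- labels[keep]
  u <- sort(unique(labels))
  stop_if(length(u) != 2, "need exactly two classes with non-missing onsets")
  stat <- function(lab) {
    d <- mean(onsets[lab == u[1]]) - mean(onsets[lab == u[2]])
    if (two_sided) abs(d) else d
  }
  obs <- stat(labels)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(r) stat(sample(labels)), numeric(1))
  perm_outcome(obs, null, seed, id %||% "latency")
}

# Sum over channels and window positions of per-class PLF values.
# Z may be [N, L, C] or pre-flattened [N, L*C]; only the trial dimension
# is resolved, so the flattened form is exact.
plf_class_statistic <- function(Z, labels, u) {
  if (length(dim(Z)) == 3) Z <- matrix(Z, dim(Z)[1], dim(Z)[2] * dim(Z)[3])
  s <- 0
  for (cl in u) {
    s <- s + sum(Mod(colMeans(Z[labels == cl, , drop = FALSE])))
  }
  s
}

#' Permutation test for relative phase effects (within- vs between-class PLF)
#'
#' Within the decoder-aligned window of one state, tests whether phase is
#' more consistent within stimulus classes than across them.  The base
#' statistic is the sum over channels and window positions of
#' `PLF(class A trials) + PLF(class B trials)`, maximized when
#' within-class phase locking dominates; the null permutes the class
#' labels across trials.
#'
#' @param phases `[N, L, C]` array from [decoder_aligned_phases()].
#' @param labels two-class labels (length N, matching the kept trials).
#' @param n_perm permutation count.
#' @param seed permutation seed.
#' @param min_per_class minimum trials per class (fewer: error).
#' @param id optional identifier.
#' @return object of class `perm_outcome`.
#' @export
plf_class_perm_test <- function(phases, labels, n_perm = 1000, seed = 1,
                                min_per_class = 3, id = NULL) {
  stop_if(length(dim(phases)) != 3, "phases must be an [N, L, C] array")
  stop_if(dim(phases)[1] != length(labels), "labels must match trial count")
  u <- sort(unique(labels))
  stop_if(length(u) != 2, "need exactly two classes")
  stop_if(min(table(labels)) < min_per_class,
          "a class has fewer than ", min_per_class, " trials in this window")
  Z <- exp(1i * phases)
  obs <- plf_class_statistic(Z, labels, u)
  set.seed(seed)
  null <- vapply(seq_len(n_perm),
                 function(r) plf_class_statistic(Z, sample(labels), u),
                 numeric(1))
  perm_outcome(obs, null, seed, id %||% "plf")
}

#' Group-level non-parametric combination (NPC)
#'
#' Combines per-subject permutation tests that share a permutation count:
#' each permutation's statistic is ranked within its own subject's null
#' (observed included) to a p-value, subject p-values are combined with
#' Fisher's function `-2 sum(log p)`, and the group p-value is the
#' proportion of permutations whose combined value reaches the observed
#' one.  With a single subject this reduces exactly to that subject's p.
#'
#' @param observed numeric vector, one statistic per subject.
#' @param nulls matrix `[n_subjects, n_perm]` of null statistics with
#'   synchronized permutation counts.
#' @return object of class `group_result`: per-subject `p`, combined
#'   `group_p`, `combining = "fisher"`, `n_perm`.
#' @export
npc_combine <- function(observed, nulls) {
  stop_if(!is.matrix(nulls) || nrow(nulls) != length(observed),
          "nulls must be a subjects x n_perm matrix matching observed")
  S <- length(observed)
  R <- ncol(nulls)
  all_t <- cbind(observed, nulls)            # column 1 = observed
  P <- matrix(0, S, R + 1)
  for (s in seq_len(S)) {
    P[s, ] <- vapply(seq_len(R + 1),
                     function(r) sum(all_t[s, ] >= all_t[s, r]) / (R + 1),
                     numeric(1))
  }
  comb <- -2 * colSums(log(P))
  group_p <- sum(comb >= comb[1]) / (R + 1)
  structure(list(p = P[, 1], group_p = group_p, combining = "fisher",
                 n_perm = R),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("group_result: %d subjects, group p = %.4g (%s, %d permutations)\n",
              length(x$p), x$group_p, x$combining, x$n_perm))
  invisible(x)
}

# Per-subject null sample for the latency test, synchronized seeds.
latency_subject_stats <- function(onsets, labels, n_perm, seed) {
  keep <- !is.na(onsets)
  onsets <- onsets[keep]; labels <- labels[keep]
  u <- sort(unique(labels))
  stat <- function(lab) abs(mean(onsets[lab == u[1]]) - mean(onsets[lab == u[2]]))
  obs <- stat(labels)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(r) stat(sample(labels)), numeric(1))
  list(obs = obs, null = null)
}

plf_subject_stats <- function(phases, labels, n_perm, seed) {
  u <- sort(unique(labels))
  Z <- exp(1i * phases)
  obs <- plf_class_statistic(Z, labels, u)
  set.seed(seed)
  null <- vapply(seq_len(n_perm),
                 function(r) plf_class_statistic(Z, sample(labels), u),
                 numeric(1))
  list(obs = obs, null = null)
}

# Phases at the given samples with each trial's global (channel-common)
# phase removed per position: the channel deviations from the per-trial
# channel resultant, referenced to the across-trial mean phasor.  A
# common latency shift cancels exactly at every sample; zero-sum relative
# configurations survive.  Returns [N, L, C].
dealign_window_phases <- function(pt, pos) {
  Z <- exp(1i * pt$phase[, , pos, drop = FALSE])     # N x C x L
  dmn <- dim(Z)
  ref <- apply(Z, c(2, 3), mean)                     # C x L
  refu <- ref / pmax(Mod(ref), 1e-12)
  D <- Z * array(rep(Conj(refu), each = dmn[1]), dmn)
  Dp <- aperm(D, c(1, 3, 2))                         # N x L x C
  m <- apply(Dp, c(1, 2), sum)                       # channel resultant, N x L
  mu <- m / pmax(Mod(m), 1e-12)
  Arg(Dp * array(Conj(mu), dim(Dp)))
}

# Level pairs of an attribute column (animacy: one pair; size: three).
attribute_pairs <- function(values) {
  lv <- sort(unique(values))
  if (length(lv) < 2) return(list())
  idx <- utils::combn(length(lv), 2, simplify = FALSE)
  lapply(idx, function(ij) lv[ij])
}

#' Full hypothesis battery over a cohort
#'
#' For each subject: decompose the signal, reduce with PCA, fit the
#' decoder-sequence model per contrast, then test, per decoder window and
#' pair of attribute levels:
#' * global latency (`H_I` for size, `H_II` for animacy, states 2..K):
#'   a label permutation test on each trial's global phase latency
#'   ([global_phase_latency()]) within the decoder's window -- the mean
#'   over channels of the trial's phase offsets, which tracks a common
#'   shift and ignores zero-sum relative configurations;
#' * relative phase (`H_III` size, `H_IV` animacy, all states): the
#'   within- vs between-class PLF test on the window's phases after each
#'   trial's global offset is removed ([remove_global_phase()]), so a
#'   latency difference cannot masquerade as a relative effect.
#'
#' Decoder windows are the contiguous segments where each decoder's mean
#' label-marginal responsibility dominates; all realignment quantities
#' are label-free, so the permutation tests stay valid under the null.
#' Subject statistics (summed over level pairs) are combined per state
#' with NPC.
#'
#' @param cohort list of [generate_trials()] results (or `epoch_set`s).
#' @param contrasts character subset of `c("size", "animacy")`.
#' @param K decoder count.
#' @param n_perm permutation count (synchronized across subjects).
#' @param seed master seed.
#' @param span_frac lowess span for the decomposition.
#' @param lowpass low-pass cutoff in Hz applied before decomposition.
#' @param pca_var PCA explained-variance threshold.
#' @param window_len resampled decoder-window length for the PLF test.
#' @param ... passed to [fit_tuda()].
#' @return list with `table` (data.frame: subject, hypothesis, contrast,
#'   state, pair, statistic, p, n_perm) and `group` (data.frame:
#'   hypothesis, contrast, state, group_p), plus `quantiles` of the
#'   subject-level p-values (50/75/87.5/95% bands per hypothesis).
#' @export
run_hypothesis_battery <- function(cohort, contrasts = c("size", "animacy"),
                                   K = 8, n_perm = 200, seed = 1,
                                   span_frac = 0.40, lowpass = 10,
                                   pca_var = 0.98, window_len = 5, ...) {
  hyp_name <- function(test, contrast) {
    if (test == "latency") c(size = "H_I", animacy = "H_II")[[contrast]]
    else c(size = "H_III", animacy = "H_IV")[[contrast]]
  }
  rows <- list()
  gstats <- list()   # key: hyp|state -> list(obs = S-vector, null = S x R)
  S <- length(cohort)
  for (s in seq_len(S)) {
    ep <- cohort[[s]]
    if (!inherits(ep, "epoch_set")) ep <- ep$epochs
    comps <- split_components(lowpass_filter(ep, lowpass), span_frac)
    osc_ep <- standardize_trial(epoch_set(comps$oscillatory, ep$fs, ep$labels,
                                          ep$attributes))
    red <- pca_reduce(osc_ep, var_threshold = pca_var)
    pt <- analytic_phase(comps$oscillatory, ep$fs)
    # carrier frequency from the oscillatory component's spectral peak
    spp <- component_spectra(comps)
    inband <- spp$freq >= 3 & spp$freq <= 12
    f_carrier <- spp$freq[inband][which.max(rowMeans(spp$power$oscillatory)[inband])]
    for (contrast in contrasts) {
      vals <- ep$attributes[[contrast]]
      y <- as.numeric(scale(vals, scale = FALSE))
      fit <- fit_tuda(red$epochs, y, K = K, seed = derive_seed(seed, s), ...)
      # decoder windows: where each decoder's mean responsibility dominates
      gbar <- apply(fit$gamma_marginal, c(1, 3), mean)
      win_state <- max.col(gbar, ties.method = "first")
      pairs <- attribute_pairs(vals)
      for (k in seq_len(K)) {
        Wk <- which(win_state == k)
        if (!length(Wk)) next
        tau_k <- global_phase_latency(pt, Wk, f_carrier)
        pos <- Wk[pmax(1, round(seq(1, length(Wk),
                                    length.out = min(window_len, length(Wk)))))]
        ph_k <- dealign_window_phases(pt, pos)
        for (test in c("latency", "plf")) {
          if (test == "latency" && k == 1) next
          hyp <- hyp_name(test, contrast)
          key <- paste(hyp, k, sep = "|")
          obs_sum <- 0
          null_sum <- numeric(n_perm)
          ok <- FALSE
          for (pi in seq_along(pairs)) {
            pr <- pairs[[pi]]
            in_pair <- vals %in% pr
            sd_seed <- derive_seed(seed, s * 1000 + k * 37 + pi)
            if (test == "latency") {
              if (sum(in_pair) < 4) next
              st <- latency_subject_stats(tau_k[in_pair], vals[in_pair],
                                          n_perm, sd_seed)
            } else {
              sel <- which(in_pair)
              if (length(sel) < 6 || min(table(vals[sel])) < 3) next
              st <- plf_subject_stats(ph_k[sel, , , drop = FALSE],
                                      vals[sel], n_perm, sd_seed)
            }
            ok <- TRUE
            obs_sum <- obs_sum + st$obs
            null_sum <- null_sum + st$null
            rows[[length(rows) + 1]] <- data.frame(
              subject = s, hypothesis = hyp, contrast = contrast, state = k,
              pair = paste(pr, collapse = "v"), statistic = st$obs,
              p = (1 + sum(st$null >= st$obs)) / (1 + n_perm),
              n_perm = n_perm)
          }
          if (ok) {
            if (is.null(gstats[[key]]))
              gstats[[key]] <- list(obs = rep(NA_real_, S),
                                    null = matrix(NA_real_, S, n_perm),
                                    contrast = contrast, hyp = hyp, state = k)
            gstats[[key]]$obs[s] <- obs_sum
            gstats[[key]]$null[s, ] <- null_sum
          }
        }
      }
    }
  }
  table <- do.call(rbind, rows)
  group <- do.call(rbind, lapply(gstats, function(g) {
    keep <- !is.na(g$obs)
    if (!any(keep)) return(NULL)
    gr <- npc_combine(g$obs[keep], g$null[keep, , drop = FALSE])
    data.frame(hypothesis = g$hyp, contrast = g$contrast, state = g$state,
               n_subjects = sum(keep), group_p = gr$group_p)
  }))
  rownames(group) <- NULL
  qs <- NULL
  if (!is.null(table) && nrow(table)) {
    qs <- do.call(rbind, lapply(split(table$p, table$hypothesis), function(p)
      data.frame(q50 = stats::quantile(p, 0.50), q75 = stats::quantile(p, 0.75),
                 q87.5 = stats::quantile(p, 0.875),
                 q95 = stats::quantile(p, 0.95), row.names = NULL)))
    qs$hypothesis <- names(split(table$p, table$hypothesis))
  }
  list(table = table, group = group, quantiles = qs)
}

#' One-sample sign-flip permutation test
#'
#' Tests whether paired differences are positive on average by randomly
#' flipping their signs: the statistic is the mean, the p-value the
#' proportion of flip patterns (plus one) whose mean reaches the observed
#' one.
#'
#' @param x numeric vector of per-unit differences.
#' @param n_perm number of sign-flip draws.
#' @param seed seed.
#' @return object of class `perm_outcome`.
#' @export
sign_flip_test <- function(x, n_perm = 1000, seed = 1) {
  stop_if(length(x) < 2, "need at least 2 observations")
  obs <- mean(x)
  set.seed(seed)
  null <- vapply(seq_len(n_perm),
                 function(r) mean(x * sample(c(-1, 1), length(x),
                                             replace = TRUE)),
                 numeric(1))
  perm_outcome(obs, null, seed, "sign_flip")
}
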