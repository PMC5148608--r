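# From raw multichannel recordings to per-trial band-power features:
# bipolar derivation, epoching, baseline-normalised band traces, channel
# selection, modulation significance, force onset/normalisation and yank.

#' Bipolar derivation of the four monopolar contacts
#'
#' Neighbouring contacts are subtracted (pair k = contact k - contact k+1),
#' yielding pairs 01, 12 and 23; any signal common to all contacts (shared
#' artifact, reference) cancels exactly.
#'
#' @param monopolar 4 x n matrix, contacts 0-3 in rows (caudal to cranial).
#' @return 3 x n matrix with rownames "01", "12", "23".
#' @export
derive_bipolar <- function(monopolar) {
  if (!is.matrix(monopolar) || nrow(monopolar) != 4L)
    stopf("expected a 4 x n matrix of monopolar contacts, got %s rows",
          if (is.matrix(monopolar)) nrow(monopolar) else "non-matrix")
  out <- monopolar[1:3, , drop = FALSE] - monopolar[2:4, , drop = FALSE]
  rownames(out) <- c("01", "12", "23")
  out
}

# average x into time bins of width 1/fs_out over [window[1], window[2]);
# t gives sample times; returns exactly round(diff(window)*fs_out) values
bin_average <- function(x, t, fs_out, window) {
  n_bins <- round(diff(window) * fs_out)
  bin <- floor((t - window[1]) * fs_out) + 1L
  keep <- bin >= 1L & bin <= n_bins
  sums <- rowsum(x[keep], bin[keep])
  cnts <- rowsum(rep(1, sum(keep)), bin[keep])
  out <- rep(NA_real_, n_bins)
  out[as.integer(rownames(sums))] <- sums / cnts
  out
}

#' Detect force onset within a trial
#'
#' The onset is the first time after the cue at which force exceeds the
#' pre-cue baseline mean by `max(5%` of the trial peak, `3 x` baseline s.d.)
#' and stays above that threshold for at least 100 ms. Returns `NA` when the
#' rule never fires (a valid outcome, e.g. a no-grip trial).
#'
#' @param force numeric force over the decode window.
#' @param times sample times in seconds relative to the cue.
#' @param min_hold minimum supra-threshold duration in seconds (default 0.1).
#' @return onset time in seconds relative to the cue, or `NA_real_`.
#' @export
detect_onset <- function(force, times, min_hold = 0.1) {
  stopifnot(length(force) == length(times))
  base <- force[times < 0]
  if (!length(base)) stopf("no pre-cue baseline samples for onset detection")
  thr <- mean(base) + max(0.05 * max(force), 3 * sd(base))
  dt <- median(diff(times))
  need <- max(1L, round(min_hold / dt))
  above <- force > thr & times >= 0
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= need)
  if (!length(hit)) return(NA_real_)
  times[starts[hit[1L]]]
}

#' Force yank (time derivative) and its initialisation-phase peak
#'
#' Central-difference derivative of force against time (one-sided at the
#' ends). The peak yank is taken over the force-initialisation phase, the
#' first second after the cue, and indexes movement vigour.
#'
#' @param force numeric force trace (>= 2 samples).
#' @param fs sampling rate of the trace in Hz.
#' @param times optional times (s relative to cue); needed for the peak.
#' @param init_window window (s) for the peak yank (default c(0, 1)).
#' @return list with `yank` (numeric vector) and `peak` (max yank in the
#'   initialisation window; `NA` when `times` is missing).
#' @export
force_yank <- function(force, fs, times = NULL, init_window = c(0, 1)) {
  n <- length(force)
  if (n < 2L) stopf("need at least 2 samples to differentiate")
  dt <- 1 / fs
  yank <- numeric(n)
  yank[1] <- (force[2] - force[1]) / dt
  yank[n] <- (force[n] - force[n - 1]) / dt
  if (n > 2L)
    yank[2:(n - 1)] <- (force[3:n] - force[1:(n - 2)]) / (2 * dt)
  peak <- NA_real_
  if (!is.null(times)) {
    sel <- times >= init_window[1] & times < init_window[2]
    if (any(sel)) peak <- max(yank[sel])
  }
  list(yank = yank, peak = peak)
}

#' Epoch a recording into decode-window trials
#'
#' Cuts the force channel into windows of \[-1, 2.8) s around each cue
#' (optionally decimating to a feature rate by bin averaging) and carries the
#' per-trial effort label. Cues whose window (including `pad` s of margin on
#' each side, reserved for wavelet edge effects) does not fit inside the
#' recording are dropped with a warning.
#'
#' @param recording an `stn_recording` (or compatible list with `force`,
#'   `fs`, `cue_times`, `sre`).
#' @param window decode window (s relative to cue), default c(-1, 2.8).
#' @param fs_out optional output rate; when given, force is decimated by bin
#'   averaging to exactly `round(diff(window) * fs_out)` samples.
#' @param pad margin (s) that must also fit in the recording (default 0).
#' @return list of trials, each with `force`, `times`, `fs`, `sre`,
#'   `cue_time`, `index`; attribute `dropped` lists dropped trial indices.
#' @export
epoch_trials <- function(recording, window = c(-1, 2.8), fs_out = NULL,
                         pad = 0) {
  fs <- recording$fs
  n <- length(recording$force)
  trials <- list()
  dropped <- integer()
  for (i in seq_along(recording$cue_times)) {
    cue <- recording$cue_times[i]
    i0 <- floor((cue + window[1]) * fs) + 1L
    len <- round(diff(window) * fs)
    p <- round(pad * fs)
    if (i0 - p < 1L || i0 + len - 1L + p > n) {
      dropped <- c(dropped, i)
      next
    }
    idx <- i0:(i0 + len - 1L)
    t_rel <- (idx - 1) / fs - cue
    f <- recording$force[idx]
    if (!is.null(fs_out)) {
      f <- bin_average(f, t_rel, fs_out, window)
      t_rel <- window[1] + (seq_along(f) - 0.5) / fs_out
      fs_tr <- fs_out
    } else fs_tr <- fs
    trials[[length(trials) + 1L]] <-
      list(force = f, times = t_rel, fs = fs_tr, sre = recording$sre[i],
           cue_time = cue, index = i)
  }
  if (length(dropped))
    warning(sprintf("dropped %d trial(s) too close to the recording edge: %s",
                    length(dropped), paste(dropped, collapse = ", ")),
            call. = FALSE)
  attr(trials, "dropped") <- dropped
  trials
}

#' Normalise trial forces against maximal-effort grips
#'
#' Divides every force sample by the mean of the per-trial peak force over
#' the maximal-effort (SRE = 10) trials, putting force on a 0-1 scale
#' (fraction of maximal voluntary force). When no maximal-effort trial
#' exists, the three largest-peak trials stand in (with a message).
#'
#' @param trials list of trials with `force` and `sre`.
#' @return the trials with normalised `force`; the divisor is attached as
#'   attribute `"divisor"`.
#' @export
normalize_force <- function(trials) {
  peaks <- vapply(trials, function(tr) max(tr$force), numeric(1))
  sre <- vapply(trials, function(tr) as.numeric(tr$sre), numeric(1))
  ref <- which(sre == 10)
  if (!length(ref)) {
    message("no maximal-effort (SRE = 10) trials; using the three largest-peak trials")
    ref <- order(peaks, decreasing = TRUE)[seq_len(min(3L, length(peaks)))]
  }
  divisor <- mean(peaks[ref])
  if (!is.finite(divisor) || divisor <= 0)
    stopf("cannot normalise force: maximal-effort peak force is zero")
  out <- lapply(trials, function(tr) { tr$force <- tr$force / divisor; tr })
  attributes(out) <- attributes(trials)
  attr(out, "divisor") <- divisor
  out
}

#' Select the bipolar pair with the deepest movement-related beta suppression
#'
#' Given the mean beta-band power change (1 s after movement onset, averaged
#' over the maximal-effort trials) of each bipolar pair, returns the pair
#' with the most negative value; ties go to the lowest pair index.
#'
#' @param beta_changes numeric vector of per-pair beta changes (fractional),
#'   optionally named; default names are "01", "12", "23".
#' @return list with `index` and `pair` (label).
#' @export
#' @examples
#' select_channel(c(-0.05, -0.20, -0.01))$pair  # "12"
select_channel <- function(beta_changes) {
  if (!length(beta_changes) || all(is.na(beta_changes)))
    stopf("no beta-change values to select from")
  labs <- names(beta_changes)
  if (is.null(labs)) labs <- c("01", "12", "23")[seq_along(beta_changes)]
  idx <- as.integer(which.min(beta_changes))  # first min = lowest pair on ties
  list(index = idx, pair = labs[idx])
}

#' Assess the significance of movement-related band-power modulation
#'
#' For each band the 5th and 95th percentiles of the trial-averaged baseline
#' samples define the pre-movement power distribution boundaries; modulation
#' is significant when at least 50% (inclusive) of the samples in the second
#' after movement onset fall below the 5% boundary (ERD) or above the 95%
#' boundary (ERS).
#'
#' @param band_traces named list of trial-averaged band traces (fractional
#'   power change or raw power; the rule is invariant to per-band affine
#'   scaling).
#' @param times sample times (s relative to cue).
#' @param onset movement-onset time (s relative to cue); when `NA`/`NULL`
#'   falls back to cue + 0.3 s with a warning (typical LFP-to-force lead is
#'   200-300 ms).
#' @param baseline baseline window (default c(-1, 0)).
#' @return data.frame with one row per band: `band`, `mean_change`,
#'   `frac_below`, `frac_above`, `significant`, `direction` ("ERD"/"ERS"/
#'   "none").
#' @export
assess_modulation <- function(band_traces, times, onset = NULL,
                              baseline = c(-1, 0)) {
  if (is.null(onset) || is.na(onset)) {
    warning("movement onset undefined; falling back to cue + 0.3 s",
            call. = FALSE)
    onset <- 0.3
  }
  bsel <- times >= baseline[1] & times < baseline[2]
  psel <- times >= onset & times < onset + 1
  if (sum(bsel) < 2L) stopf("need at least 1 s of baseline samples")
  if (!any(psel)) stopf("post-onset window lies outside the trace")
  rows <- lapply(names(band_traces), function(b) {
    x <- band_traces[[b]]
    lo <- quantile(x[bsel], 0.05, names = FALSE)
    hi <- quantile(x[bsel], 0.95, names = FALSE)
    fb <- mean(x[psel] < lo)
    fa <- mean(x[psel] > hi)
    sig <- fb >= 0.5 || fa >= 0.5
    dir <- if (!sig) "none" else if (fb >= fa) "ERD" else "ERS"
    data.frame(band = b, mean_change = mean(x[psel]), frac_below = fb,
               frac_above = fa, significant = sig, direction = dir,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# time-frequency power of one bipolar channel for one trial on a padded
# epoch; NULL when the padded window does not fit
trial_power_map <- function(sig, fs, cue, window, pad, freqs, n_cycles) {
  i0 <- floor((cue + window[1] - pad) * fs) + 1L
  len <- round((diff(window) + 2 * pad) * fs)
  if (i0 < 1L || i0 + len - 1L > length(sig)) return(NULL)
  idx <- i0:(i0 + len - 1L)
  t0 <- (i0 - 1) / fs - cue
  morlet_cwt(sig[idx], fs, freqs, n_cycles, t0 = t0)
}

# band traces of one bipolar channel for one trial: padded epoch -> CWT ->
# per-trial baseline-relative change -> crop to the decode window
trial_band_traces <- function(sig, fs, cue, window, pad, freqs, n_cycles) {
  tf <- trial_power_map(sig, fs, cue, window, pad, freqs, n_cycles)
  if (is.null(tf)) return(NULL)
  rp <- relative_power_change(tf)
  keep <- rp$times >= window[1] & rp$times < window[2]
  list(times = rp$times[keep],
       traces = lapply(rp$band_traces, function(x) x[keep]))
}

# band traces of the TRIAL-AVERAGED power over several cues (power averaged
# first, then normalised against its own baseline): the stable estimator
# used for channel selection and the modulation report
averaged_band_traces <- function(sig, fs, cues, window, pad, freqs,
                                 n_cycles) {
  acc <- NULL
  n_used <- 0L
  for (cue in cues) {
    tf <- trial_power_map(sig, fs, cue, window, pad, freqs, n_cycles)
    if (is.null(tf)) next
    if (is.null(acc)) acc <- tf else acc$power <- acc$power + tf$power
    n_used <- n_used + 1L
  }
  if (!n_used) return(NULL)
  acc$power <- acc$power / n_used
  rp <- relative_power_change(acc)
  keep <- rp$times >= window[1] & rp$times < window[2]
  list(times = rp$times[keep],
       traces = lapply(rp$band_traces, function(x) x[keep]),
       n_trials = n_used)
}

#' Extract per-trial band-power features and normalised force
#'
#' The full feature pipeline: bipolar derivation; selection of the pair with
#' the deepest beta suppression on the maximal-effort trials (or a fixed
#' pair); per-trial 7-cycle Morlet CWT on a 2 s-padded epoch (so wavelet
#' edge effects never enter the decode window); normalisation against the
#' 1 s pre-cue baseline; band averaging (alpha 4-12, beta 13-30, gamma
#' 55-90 Hz, inclusive); bin-average decimation of band traces and force to
#' the feature rate; force-onset detection; and force normalisation against
#' maximal-effort grips.
#'
#' @param recording an `stn_recording`.
#' @param pair "auto" (default), or one of "01", "12", "23" / 1-3.
#' @param fs_feature feature rate in Hz (default 100).
#' @param freqs CWT frequency grid (default 1-90 Hz).
#' @param n_cycles Morlet cycles (default 7).
#' @param window decode window (default c(-1, 2.8) s).
#' @param pad CWT padding in seconds (default 2).
#' @return list of class `stn_features`: `trials` (each with `band_trace`,
#'   `force` on the 0-1 scale, `times`, `sre`, `onset_time`, `cue_time`),
#'   `pair`, `pair_index`, `beta_by_pair` (when auto-selected),
#'   `modulation` (data.frame from [assess_modulation()]), `fs_feature`,
#'   `window`, `dropped`.
#' @export
extract_features <- function(recording, pair = "auto", fs_feature = 100,
                             freqs = 1:90, n_cycles = 7,
                             window = c(-1, 2.8), pad = 2) {
  bip <- derive_bipolar(recording$monopolar)
  fs <- recording$fs
  labels <- rownames(bip)
  max_idx <- which(recording$sre == 10)
  beta_by_pair <- NULL

  # force epochs at the feature rate (used for onset detection + modelling)
  force_trials <- epoch_trials(recording, window, fs_out = fs_feature,
                               pad = pad)
  kept <- vapply(force_trials, function(tr) tr$index, integer(1))

  onset_of <- function(tr) detect_onset(tr$force, tr$times)

  if (identical(pair, "auto")) {
    sel_trials <- intersect(max_idx, kept)
    if (!length(sel_trials))
      stopf("channel selection needs at least one maximal-effort (SRE = 10) trial")
    sel_trials <- sel_trials[seq_len(min(3L, length(sel_trials)))]
    onsets <- vapply(sel_trials, function(i) {
      on <- onset_of(force_trials[[match(i, kept)]])
      if (is.na(on)) 0.3 else on
    }, numeric(1))
    mean_on <- mean(onsets)
    beta_by_pair <- vapply(seq_len(nrow(bip)), function(p) {
      bt <- averaged_band_traces(bip[p, ], fs,
                                 recording$cue_times[sel_trials], window,
                                 pad, freqs, n_cycles)
      sel <- bt$times >= mean_on & bt$times < mean_on + 1
      mean(bt$traces$beta[sel])
    }, numeric(1))
    names(beta_by_pair) <- labels
    sel <- select_channel(beta_by_pair)
    pair_index <- sel$index
  } else {
    pair_index <- if (is.numeric(pair)) as.integer(pair) else match(pair, labels)
    if (is.na(pair_index) || pair_index < 1L || pair_index > 3L)
      stopf("pair must be 'auto', '01', '12', '23' or 1..3")
  }

  sig <- bip[pair_index, ]
  trials <- list()
  for (j in seq_along(force_trials)) {
    ftr <- force_trials[[j]]
    bt <- trial_band_traces(sig, fs, ftr$cue_time, window, pad, freqs,
                            n_cycles)
    traces <- lapply(bt$traces, function(x)
      bin_average(x, bt$times, fs_feature, window))
    t_feat <- window[1] + (seq_along(traces$beta) - 0.5) / fs_feature
    trials[[j]] <- list(band_trace = traces, force = ftr$force,
                        times = t_feat, fs = fs_feature, sre = ftr$sre,
                        onset_time = onset_of(ftr), cue_time = ftr$cue_time,
                        index = ftr$index)
  }
  trials <- normalize_force(trials)

  # modulation report on the trial-averaged power of the maximal-effort
  # trials (trial-averaged baseline distribution, per the significance rule)
  rep_idx <- which(vapply(trials, function(tr) tr$sre == 10, logical(1)))
  if (!length(rep_idx)) rep_idx <- seq_along(trials)
  rep_cues <- vapply(trials[rep_idx], function(tr) tr$cue_time, numeric(1))
  avg <- averaged_band_traces(sig, fs, rep_cues, window, pad, freqs,
                              n_cycles)
  onsets <- vapply(trials[rep_idx], function(tr)
    if (is.na(tr$onset_time)) NA_real_ else tr$onset_time, numeric(1))
  mean_onset <- if (all(is.na(onsets))) NA_real_ else mean(onsets, na.rm = TRUE)
  modulation <- assess_modulation(avg$traces, avg$times, mean_onset)

  structure(list(trials = trials, pair = labels[pair_index],
                 pair_index = pair_index, beta_by_pair = beta_by_pair,
                 modulation = modulation, fs_feature = fs_feature,
                 window = window,
                 dropped = attr(force_trials, "dropped")),
            class = "stn_features")
}

#' @export
print.stn_features <- function(x, ...) {
  cat(sprintf("Features: %d trials, pair %s, %g Hz feature rate\n",
              length(x$trials), x$pair, x$fs_feature))
  print(x$modulation)
  invisible(x)
}
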