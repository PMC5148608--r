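# Synthetic session generator.
#
# Emulates the statistical structure the decoding analysis assumes: cue-paced
# grips whose self-rated effort (SRE, 0-10) scales a movement-locked beta
# power suppression and gamma power increase (plus a modest low-frequency
# increase), band-limited oscillatory carriers whose POWER tracks those
# envelopes over a 1/f background with a shared common-mode artifact, and a
# force channel produced by a known first-order transfer function with dead
# time. Ground truth (envelopes, model id, parameters) is carried alongside
# for recovery testing.

# fixed per-contact gain profile per band (contacts 0-3, caudal -> cranial);
# chosen so bipolar pair 12 carries the largest band-signal difference,
# i.e. pair 12 is the most reactive by construction
.CONTACT_GAINS <- cbind(
  alpha = c(1.0, 0.8, 1.2, 1.0),
  beta  = c(1.0, 0.55, 1.55, 1.0),
  gamma = c(1.0, 0.7, 1.3, 0.9)
)

.BAND_LIMITS <- list(alpha = c(4, 12), beta = c(13, 30), gamma = c(55, 90))

# carrier occupancy: inset within each analysis band so that the Morlet
# kernels of one band's rows (sigma_f = f/7) do not integrate the
# neighbouring band's carrier -- contiguous carriers would let the strong
# low-frequency carrier mask the beta ERD at rows 13-16
.CARRIER_BANDS <- list(alpha = c(4, 9.5), beta = c(14, 29.5), gamma = c(56, 89))

#' Configuration of the synthetic-session generator
#'
#' Defaults state the emulated world: ~3 s grips cued every 11-13 s, effort
#' levels spread over the whole 0-10 scale with maximal-effort trials always
#' present, a 30% beta suppression and 30% gamma increase at maximal effort
#' (20% alpha increase), and force generated by model 2 with gamma gain 2,
#' beta gain -1, time constant 0.2 s and dead time 0.2 s.
#'
#' @param n_trials number of grips (>= 2; default 30).
#' @param fs recording sampling rate in Hz (> 180; default 2048).
#' @param trial_spacing range (s) of the uniform inter-cue interval
#'   (default c(11, 13)).
#' @param cue_duration grip/cue duration in seconds (default 3).
#' @param sre_levels optional integer vector (0-10) of per-trial efforts; by
#'   default levels 0..10 are cycled to cover the scale evenly (so both the
#'   low/high effort halves are non-empty and maximal-effort trials exist)
#'   and shuffled.
#' @param true_model_id generating model id 1-8 (default 2).
#' @param true_params generating parameters for `true_model_id`.
#' @param beta_mod_depth fractional beta power change at maximal effort
#'   (default -0.3).
#' @param gamma_mod_depth fractional gamma power change at maximal effort
#'   (default +0.3).
#' @param alpha_mod_depth fractional alpha power change at maximal effort
#'   (default +0.2).
#' @param envelope_rise_tau per-band rise time constants in seconds (named
#'   alpha/beta/gamma). Gamma rises fast (80 ms) while the beta suppression
#'   develops slowly (500 ms); the distinct dynamics are what let the data
#'   distinguish the bands' contributions in multi-band models.
#' @param envelope_latency per-band onset latency (s) after the cue.
#' @param gamma_transient extra fractional gamma power of the brief onset
#'   burst at maximal effort (default 0.25); indexes movement vigour.
#' @param effort_scaling `"banded"` (default) or `"linear"`. Banded scaling
#'   gives each band its own monotone effort curve -- beta saturating over
#'   the low-effort range, gamma supra-linear over the high-effort range,
#'   alpha saturating -- mirroring the band-specific effort coding seen
#'   empirically; it also makes the band mix vary across trials, which is
#'   what renders multi-band model gains identifiable. `"linear"` scales all
#'   bands by `sre/10`.
#' @param noise_sd force measurement noise s.d. as a fraction of the
#'   maximal-effort steady force (default 0.05).
#' @param common_mode_amp amplitude of the artifact shared by all four
#'   contacts (default 0.5, arbitrary units).
#' @param pink_noise_exponent 1/f^x background slope (default 1).
#' @param carrier_snr in-band carrier-to-background power ratio on bipolar
#'   pair 12 (default 30, an electrode well inside the motor STN; the
#'   carrier-background cross-term makes single-sample band power fluctuate
#'   by ~2/sqrt(SNR)).
#' @param carrier_amp_stab amplitude stabilisation of the Gaussian carrier
#'   component in \[0, 1\] (default 0; see `carrier_tone_frac`).
#' @param carrier_tone_frac fraction of each band carrier's power carried by
#'   a fixed-frequency tone (6.75 / 21.75 / 72.5 Hz; default 0.8), the rest
#'   by band-limited Gaussian noise. The wavelet-scale power of any purely
#'   stochastic carrier fades chi-squared-like at the wavelet's
#'   time-bandwidth limit, which makes per-trial baseline ratios noisy and
#'   biased and defeats end-to-end parameter recovery; the tonal component
#'   gives each band deterministic in-band power that tracks the imposed
#'   envelope. See the methods vignette for what this does and does not
#'   emulate.
#' @param contact_gains optional 4 x 3 matrix (columns alpha/beta/gamma) of
#'   per-contact carrier gains, overriding the built-in profile under which
#'   bipolar pair 12 is the most reactive.
#' @param fs_feature rate (Hz) of the ground-truth envelope grid
#'   (default 100).
#' @param seed RNG seed; a fixed seed makes sessions bit-identical.
#' @return list of class `stn_synth_config`.
#' @export
synthetic_config <- function(n_trials = 30L, fs = 2048, trial_spacing = c(11, 13),
                             cue_duration = 3, sre_levels = NULL,
                             true_model_id = 2L,
                             true_params = c(Kp1 = 2, Kp2 = -1, Tp = 0.2, Td = 0.2),
                             beta_mod_depth = -0.3, gamma_mod_depth = 0.3,
                             alpha_mod_depth = 0.2,
                             envelope_rise_tau = c(alpha = 0.5, beta = 0.5, gamma = 0.08),
                             envelope_latency = c(alpha = 0.2, beta = 0.35, gamma = 0.1),
                             gamma_transient = 0.25,
                             effort_scaling = c("banded", "linear"),
                             noise_sd = 0.05, common_mode_amp = 0.5,
                             pink_noise_exponent = 1, carrier_snr = 30,
                             carrier_amp_stab = 0, carrier_tone_frac = 0.9,
                             contact_gains = NULL,
                             fs_feature = 100, seed = 1L) {
  if (n_trials < 2L) stopf("n_trials must be >= 2")
  if (fs <= 2 * 90) stopf("fs must exceed 180 Hz (twice the top gamma frequency)")
  if (is.null(sre_levels)) {
    sre_levels <- rep(0:10, length.out = n_trials)
    if (!any(sre_levels == 10L)) sre_levels[n_trials] <- 10L
  } else {
    sre_levels <- as.integer(sre_levels)
    if (length(sre_levels) != n_trials)
      stopf("sre_levels must have length n_trials")
  }
  if (any(sre_levels < 0L | sre_levels > 10L))
    stopf("sre_levels must lie in [0, 10]")
  if (!any(sre_levels == 10L))
    stopf("at least one maximal-effort (SRE = 10) trial is required for force normalisation")
  if (beta_mod_depth <= -1) stopf("beta_mod_depth must be > -1 (power cannot go negative)")
  sp <- model_spec(true_model_id)
  true_params <- coerce_params(sp, true_params)
  cfg <- list(n_trials = as.integer(n_trials), fs = fs,
              trial_spacing = trial_spacing, cue_duration = cue_duration,
              sre_levels = sre_levels, true_model_id = sp$model_id,
              true_params = true_params,
              beta_mod_depth = beta_mod_depth, gamma_mod_depth = gamma_mod_depth,
              alpha_mod_depth = alpha_mod_depth,
              envelope_rise_tau = envelope_rise_tau,
              envelope_latency = envelope_latency,
              gamma_transient = gamma_transient,
              effort_scaling = match.arg(effort_scaling),
              noise_sd = noise_sd, common_mode_amp = common_mode_amp,
              pink_noise_exponent = pink_noise_exponent,
              carrier_snr = carrier_snr, carrier_amp_stab = carrier_amp_stab,
              carrier_tone_frac = carrier_tone_frac,
              contact_gains = contact_gains,
              fs_feature = fs_feature, seed = as.integer(seed))
  class(cfg) <- "stn_synth_config"
  cfg
}

# canonical decode-window time grid (bin centres) at the feature rate
decode_times <- function(fs_feature = 100, window = c(-1, 2.8)) {
  n <- round(diff(window) * fs_feature)
  window[1] + (seq_len(n) - 0.5) / fs_feature
}

# per-band monotone effort curves, all mapping 0 -> 0 and 10 -> 1: beta
# saturates over the low-effort range (so relative to beta, gamma dominates
# at high efforts), gamma tracks effort linearly, alpha saturates gently
effort_scale <- function(sre, band, scaling) {
  x <- sre / 10
  if (identical(scaling, "linear")) return(x)
  switch(band,
         alpha = sqrt(x),
         beta = (1 - exp(-sre / 4)) / (1 - exp(-10 / 4)),
         gamma = x)
}

# single-band envelope shape at unit depth: smooth rise after the per-band
# latency, hold through the grip, exponential release after cue_duration
envelope_shape <- function(t, latency, tau, cue_duration) {
  r <- ifelse(t >= latency, 1 - exp(-(pmax(t - latency, 0)) / tau), 0)
  rel <- t > cue_duration
  if (any(rel)) {
    r_end <- 1 - exp(-(cue_duration - latency) / tau)
    r[rel] <- r_end * exp(-(t[rel] - cue_duration) / 0.3)
  }
  r
}

#' Ground-truth band-power envelopes for one grip
#'
#' Relative-power (fractional change) envelopes of the alpha, beta and gamma
#' bands over the decode window: zero through the pre-cue baseline second,
#' then a smooth rise (per-band latency and time constant) to a plateau of
#' `depth * s_b(sre)`, where `s_b` is the per-band monotone effort curve
#' (see `effort_scaling` in [synthetic_config()]; `s_b(10) = 1` always, and
#' `s_b(sre) = sre/10` under `"linear"` scaling). The gamma band carries an
#' additional brief onset burst scaling with effort, and the alpha rise is
#' weighted toward the force-onset phase (where the low-frequency increase
#' is empirically strongest); both features also pin the corresponding
#' branch dynamics in multi-band models.
#'
#' @param sre integer effort level 0-10.
#' @param config a [synthetic_config()].
#' @param times time grid in seconds relative to the cue (defaults to the
#'   decode window \[-1, 2.8) s at `config$fs_feature`).
#' @return matrix `length(times)` x 3 with columns alpha/beta/gamma.
#' @export
generate_band_envelopes <- function(sre, config = synthetic_config(),
                                    times = decode_times(config$fs_feature)) {
  if (length(sre) != 1L || is.na(sre) || sre < 0 || sre > 10)
    stopf("sre must be a single value in [0, 10]")
  depth <- c(alpha = config$alpha_mod_depth, beta = config$beta_mod_depth,
             gamma = config$gamma_mod_depth)
  scaling <- if (is.null(config$effort_scaling)) "banded"
             else config$effort_scaling
  env <- vapply(BAND_NAMES, function(b) {
    depth[[b]] * effort_scale(sre, b, scaling) *
      envelope_shape(times, config$envelope_latency[[b]],
                     config$envelope_rise_tau[[b]], config$cue_duration)
  }, numeric(length(times)))
  burst_t0 <- config$envelope_latency[["gamma"]] + 0.15
  env[, "gamma"] <- env[, "gamma"] +
    config$gamma_transient * effort_scale(sre, "gamma", scaling) *
      exp(-(times - burst_t0)^2 / (2 * 0.08^2)) * (times >= 0)
  # low-frequency increase is strongest during the force-onset phase:
  # weight the sustained alpha rise with a sharp onset-locked emphasis burst
  # (its timescale must be short relative to the branch lag for the alpha
  # dynamics to be recoverable -- the generator's own recovery contract)
  a_t0 <- config$envelope_latency[["alpha"]] + 0.45
  env[, "alpha"] <- env[, "alpha"] *
    (1 + 1.0 * exp(-(times - a_t0)^2 / (2 * 0.1^2)))
  env
}

# fraction of total 1/f background power falling in [f1, f2] given the FFT
# spectral shaping actually used by pink_noise()
pink_band_fraction <- function(n, fs, exponent, band) {
  f <- seq(0, fs / 2, by = fs / n)[-1]
  w2 <- f^(-exponent)
  sum(w2[f >= band[1] & f <= band[2]]) / sum(w2)
}

fft_freqs <- function(n, fs) {
  f <- (seq_len(n) - 1) * fs / n
  f[f > fs / 2] <- f[f > fs / 2] - fs
  f
}

# 1/f^x noise via spectral shaping of white noise, unit variance.
# FFTs run at a highly composite length >= n (mixed-radix FFT on awkward
# lengths is pathologically slow) and the result is truncated.
pink_noise <- function(n, fs, exponent) {
  N <- nextn(n)
  X <- fft(rnorm(N))
  f <- abs(fft_freqs(N, fs))
  w <- c(0, f[-1]^(-exponent / 2))     # kill DC
  x <- Re(fft(X * w, inverse = TRUE))[seq_len(n)] / N
  x / sd(x)
}

# band-limited noise carrier, unit variance. stab in [0, 1] regularises the
# instantaneous (Hilbert) amplitude: 0 leaves Gaussian noise, whose band
# power is chi-squared with very few dof at the wavelet's time-bandwidth
# limit; 1 gives a constant-amplitude frequency-wandering carrier whose
# band power tracks the imposed envelope deterministically.
band_noise <- function(n, fs, band, stab = 0) {
  N <- nextn(n)
  X <- fft(rnorm(N))
  f <- fft_freqs(N, fs)
  X[f < band[1] | f > band[2]] <- 0      # one-sided: analytic signal
  a <- fft(X, inverse = TRUE)[seq_len(n)] / N
  y <- Re(a)
  if (stab > 0) {
    A <- Mod(a)
    y <- y * (mean(A) / pmax(A, 1e-12))^stab
  }
  y / sd(y)
}

#' Synthesise four monopolar contact signals from band envelopes
#'
#' Each contact is a gain-weighted sum of three band-limited Gaussian-noise
#' carriers whose amplitude is scaled by `sqrt(1 + envelope)` -- so measured
#' *power* tracks the envelope -- plus independent 1/f background noise and a
#' common-mode artifact identical on all contacts (removed by bipolar
#' derivation). Carrier amplitudes are calibrated so that the in-band
#' carrier-to-background power ratio on bipolar pair 12 equals
#' `config$carrier_snr`.
#'
#' @param envelopes `n_samples` x 3 matrix (columns alpha/beta/gamma) of
#'   fractional power change over the session timeline at `config$fs`.
#' @param config a [synthetic_config()].
#' @return 4 x `n_samples` matrix of monopolar signals (contacts 0-3).
#' @export
synthesize_lfp <- function(envelopes, config = synthetic_config()) {
  fs <- config$fs
  if (fs <= 2 * .BAND_LIMITS$gamma[2])
    stopf("fs too low to synthesise the gamma band")
  n <- nrow(envelopes)
  t <- (seq_len(n) - 1) / fs
  G <- if (is.null(config$contact_gains)) .CONTACT_GAINS
       else as.matrix(config$contact_gains)
  # carrier s.d. per band from the pair-12 SNR calibration
  dgain <- G[2, ] - G[3, ]
  carrier_sd <- vapply(BAND_NAMES, function(b) {
    bg <- 2 * pink_band_fraction(n, fs, config$pink_noise_exponent,
                                 .BAND_LIMITS[[b]])  # bipolar doubles power
    sqrt(config$carrier_snr * bg) / abs(dgain[[b]])
  }, numeric(1))
  stab <- if (is.null(config$carrier_amp_stab)) 0 else config$carrier_amp_stab
  tone_frac <- if (is.null(config$carrier_tone_frac)) 0.9
               else config$carrier_tone_frac
  # tone combs spanning each band: deterministic in-band power at every
  # analysis row, with tone-tone beat ripple at or above the comb spacing
  # (7 Hz beta, 14 Hz gamma) -- above the force band, so the plant lag
  # filters it out of predictions
  tone_freq <- list(alpha = c(4.5, 7.5, 10.5),
                    beta = c(14, 21, 28),
                    gamma = c(58, 72, 86))
  carriers <- vapply(BAND_NAMES, function(b) {
    amp <- sqrt(pmax(1 + envelopes[, b], 0))
    fr <- tone_freq[[b]]
    tones <- rowSums(vapply(fr, function(fk)
      cos(2 * pi * fk * t + runif(1, 0, 2 * pi)), numeric(n)))
    x <- sqrt(1 - tone_frac) * band_noise(n, fs, .CARRIER_BANDS[[b]], stab) +
      sqrt(2 * tone_frac / length(fr)) * tones
    carrier_sd[[b]] * x * amp
  }, numeric(n))
  cm <- config$common_mode_amp *
    (sin(2 * pi * 50 * t) + 0.5 * sin(2 * pi * 1.3 * t + runif(1, 0, 2 * pi)))
  mono <- matrix(0, nrow = 4L, ncol = n)
  for (ct in 1:4) {
    mono[ct, ] <- carriers %*% G[ct, ] +
      pink_noise(n, fs, config$pink_noise_exponent) + cm
  }
  rownames(mono) <- paste0("contact", 0:3)
  mono
}

# steady maximal-effort force used to scale measurement noise
force_reference <- function(config) {
  env <- generate_band_envelopes(10, config)
  f <- simulate_forward(config$true_model_id, config$true_params,
                        envelope_trace(env), config$fs_feature)
  max(f)
}

envelope_trace <- function(env) {
  list(alpha = env[, "alpha"], beta = env[, "beta"], gamma = env[, "gamma"])
}

#' Generate a force trace from band envelopes and the true model
#'
#' Forward-simulates the generating transfer function on the envelopes, adds
#' Gaussian measurement noise (s.d. = `noise_sd` times the maximal-effort
#' steady force) and clamps at zero.
#'
#' @param envelopes matrix (columns alpha/beta/gamma) or band-trace list.
#' @param true_model_id generating model id.
#' @param true_params generating parameters.
#' @param config a [synthetic_config()] (supplies `noise_sd` and the noise
#'   reference scale).
#' @param fs sampling rate of `envelopes` (default `config$fs_feature`).
#' @param noise add measurement noise (default TRUE); the noiseless limit is
#'   obtained with `noise = FALSE` or `noise_sd = 0`.
#' @return numeric force vector (>= 0).
#' @export
generate_force <- function(envelopes, true_model_id = config$true_model_id,
                           true_params = config$true_params,
                           config = synthetic_config(),
                           fs = config$fs_feature, noise = TRUE) {
  trace <- if (is.matrix(envelopes)) envelope_trace(envelopes) else envelopes
  f <- simulate_forward(true_model_id, true_params, trace, fs)
  if (noise && config$noise_sd > 0) {
    f <- f + rnorm(length(f), sd = config$noise_sd * force_reference(config))
  }
  pmax(f, 0)
}

#' Generate a complete synthetic session
#'
#' Builds the cue schedule (uniform 11-13 s spacing by default), per-trial
#' effort labels, the full-timeline band envelopes, four monopolar LFP
#' contacts, and the force channel, plus per-trial ground-truth envelopes on
#' the decode-window grid. All randomness flows from `config$seed`; a fixed
#' seed yields bit-identical sessions.
#'
#' @param config a [synthetic_config()].
#' @return list of class `stn_session` with elements `recording` (class
#'   `stn_recording`: `monopolar` 4 x n, `force`, `fs`, `cue_times`, `sre`,
#'   `meta`), `true_envelopes` (list of per-trial matrices at
#'   `config$fs_feature`), `true_params`, `true_model_id`, `config`.
#' @export
generate_session <- function(config = synthetic_config()) {
  with_seed(config$seed, {
    n_tr <- config$n_trials
    sre <- sample(config$sre_levels)          # shuffled, composition fixed
    gaps <- runif(n_tr - 1L, config$trial_spacing[1], config$trial_spacing[2])
    cue_times <- 5 + cumsum(c(0, gaps))
    dur <- max(cue_times) + 8
    n <- ceiling(dur * config$fs)
    t <- (seq_len(n) - 1) / config$fs

    env_full <- matrix(0, nrow = n, ncol = 3L,
                       dimnames = list(NULL, BAND_NAMES))
    for (i in seq_len(n_tr)) {
      idx <- which(t >= cue_times[i] - 1 & t < cue_times[i] + 6)
      env_full[idx, ] <- env_full[idx, ] +
        generate_band_envelopes(sre[i], config, times = t[idx] - cue_times[i])
    }
    mono <- synthesize_lfp(env_full, config)
    force <- generate_force(env_full, config$true_model_id, config$true_params,
                            config, fs = config$fs)
    true_env <- lapply(seq_len(n_tr), function(i)
      generate_band_envelopes(sre[i], config))
    recording <- structure(
      list(monopolar = mono, force = force, fs = config$fs,
           cue_times = cue_times, sre = sre,
           meta = list(subject = "synthetic", side = "left", hand = "right")),
      class = "stn_recording")
    structure(list(recording = recording, true_envelopes = true_env,
                   true_params = config$true_params,
                   true_model_id = config$true_model_id, config = config),
              class = "stn_session")
  })
}

#' Default generating parameters per model family
#'
#' Plausible truths used by recovery tests and examples: gamma gains
#' positive, beta gains negative (beta suppresses during grip), alpha gains
#' modest and positive, time constants 0.15-0.4 s and dead times 0.15-0.25 s
#' (the empirical dead-time range is 0-277 ms).
#'
#' @param model_id integer 1-8.
#' @return named parameter vector valid for `model_id`.
#' @export
default_true_params <- function(model_id) {
  switch(as.character(model_spec(model_id)$model_id),
    `1` = c(Kp = 1.5, Tp = 0.2, Td = 0.2),
    `2` = c(Kp1 = 2, Kp2 = -1, Tp = 0.2, Td = 0.2),
    `3` = c(Kp1 = 2, Tp1 = 0.15, Td1 = 0.15, Kp2 = -1, Tp2 = 0.3, Td2 = 0.25),
    `4` = c(Kp1 = 2, Kp2 = -1, Kp3 = 0.8, Tp = 0.2, Td = 0.2),
    `5` = c(Kp1 = 2, Tp1 = 0.15, Td1 = 0.15, Kp2 = -1, Tp2 = 0.3, Td2 = 0.25,
            Kp3 = 0.8, Tp3 = 0.4, Td3 = 0.2),
    `6` = c(Kp = 1.2, Tp = 0.25, Td = 0.2),
    `7` = c(Kp = -1.5, Tp = 0.2, Td = 0.2),
    `8` = c(Kp = 2, Tp = 0.2, Td = 0.2))
}

#' Generate ground-truth trials at the feature rate (no raw LFP)
#'
#' The light-weight counterpart of [generate_session()]: per-trial true band
#' envelopes on the decode-window grid and force produced by the generating
#' transfer function (plus measurement noise), without synthesising the raw
#' LFP carriers. This is the canonical fixture for parameter- and
#' model-recovery studies, where wavelet estimation error must not be
#' conflated with optimiser accuracy.
#'
#' @param config a [synthetic_config()].
#' @param noise add force measurement noise (default TRUE).
#' @return list of trials (`band_trace`, `force`, `times`, `fs`, `sre`).
#' @export
generate_trials <- function(config = synthetic_config(), noise = TRUE) {
  times <- decode_times(config$fs_feature)
  with_seed(config$seed, {
    sre <- sample(config$sre_levels)
    lapply(seq_len(config$n_trials), function(i) {
      env <- generate_band_envelopes(sre[i], config)
      list(band_trace = envelope_trace(env),
           force = generate_force(env, config$true_model_id,
                                  config$true_params, config, noise = noise),
           times = times, fs = config$fs_feature, sre = sre[i])
    })
  })
}

#' Ground-truth trials of a synthetic session at the feature rate
#'
#' Returns the session's trials with the *true* band envelopes as features
#' and force regenerated on the decode-window grid (noise drawn from the
#' session seed), the fixture for parameter- and model-recovery testing
#' without conflating wavelet estimation error with optimiser accuracy.
#'
#' @param session an `stn_session`.
#' @param noise include measurement noise (default uses `config$noise_sd`).
#' @return list of trials (each with `band_trace`, `force`, `sre`).
#' @export
session_true_trials <- function(session, noise = TRUE) {
  cfg <- session$config
  with_seed(cfg$seed + 1L, {
    lapply(seq_along(session$true_envelopes), function(i) {
      env <- session$true_envelopes[[i]]
      list(band_trace = envelope_trace(env),
           force = generate_force(env, cfg$true_model_id, cfg$true_params,
                                  cfg, noise = noise),
           sre = session$recording$sre[i])
    })
  })
}

#' @export
print.stn_session <- function(x, ...) {
  r <- x$recording
  cat(sprintf(
    "Synthetic session: %d trials, fs %g Hz, %.1f s, true model %d (seed %d)\n",
    length(r$cue_times), r$fs, length(r$force) / r$fs, x$true_model_id,
    x$config$seed))
  invisible(x)
}

#' @export
print.stn_recording <- function(x, ...) {
  cat(sprintf("Recording: 4 contacts + force, fs %g Hz, %d trials, SRE %s\n",
              x$fs, length(x$cue_times),
              paste(range(x$sre), collapse = "-")))
  invisible(x)
}
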