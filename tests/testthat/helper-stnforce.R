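# shared fixtures: everything is generated in code at test time

# ground-truth trials for a given generating model (no raw-LFP synthesis)
recovery_trials <- function(model_id, seed, n_trials = 12L, noise = FALSE) {
  cfg <- synthetic_config(n_trials = n_trials, true_model_id = model_id,
                          true_params = default_true_params(model_id),
                          seed = seed)
  generate_trials(cfg, noise = noise)
}

# a flat band trace of given length with one band replaced
flat_trace <- function(n = 380, ...) {
  tr <- list(alpha = numeric(n), beta = numeric(n), gamma = numeric(n))
  ov <- list(...)
  for (nm in names(ov)) tr[[nm]] <- ov[[nm]]
  tr
}

# decode-window time grid used throughout (bin centres at 100 Hz)
feat_times <- function(n = 380, fs = 100) -1 + (seq_len(n) - 0.5) / fs

# step input aligned to the cue (t >= 0)
step_input <- function(n = 380, fs = 100, t0 = 0) {
  as.numeric(feat_times(n, fs) >= t0)
}

# random smooth input: low-pass filtered white noise, zero before the cue
smooth_input <- function(n = 380, fs = 100, tau = 0.3) {
  a <- exp(-1 / (fs * tau))
  x <- numeric(n)
  e <- rnorm(n)
  for (i in 2:n) x[i] <- a * x[i - 1] + (1 - a) * e[i]
  x <- x / max(abs(x), 1e-12)
  x[feat_times(n, fs) < 0] <- 0
  x
}

# Ornstein-Uhlenbeck smoothed stationary trace (wavelet-scale correlation)
ou_trace <- function(n, tau_s, sd, fs = 100) {
  a <- exp(-1 / (fs * tau_s))
  x <- numeric(n)
  x[1] <- rnorm(1)
  for (i in 2:n) x[i] <- a * x[i - 1] + sqrt(1 - a^2) * rnorm(1)
  x * sd
}

# a small raw-LFP session; fs reduced to keep CWT cost down (analysis
# frequencies <= 90 Hz are unaffected)
small_session <- function(seed = 1, n_trials = 8L, fs = 512, ...) {
  generate_session(synthetic_config(n_trials = n_trials, fs = fs,
                                    seed = seed, ...))
}

max_rel_err <- function(est, truth) max(abs(est - truth) / abs(truth))
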