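test_that("Morlet CWT localises frequency and scales quadratically", {
  fs <- 512
  t <- seq(0, 6, by = 1 / fs)
  x <- sin(2 * pi * 20 * t)
  tf <- morlet_cwt(x, fs)
  mid <- tf$times > 1 & tf$times < 5          # avoid edges
  avg <- rowMeans(tf$power[, mid])
  expect_equal(tf$freqs[which.max(avg)], 20)
  # amplitude normalisation: |W|^2 at the tone frequency equals A^2
  expect_equal(max(avg), 1, tolerance = 0.02)
  tf2 <- morlet_cwt(2 * x, fs)
  expect_equal(tf2$power, 4 * tf$power, tolerance = 1e-9)
  expect_equal(morlet_cwt(numeric(1000), fs)$power,
               matrix(0, 90, 1000), ignore_attr = TRUE)
  expect_error(morlet_cwt(x, fs = 150), "Nyquist|maximum analysis",
               ignore.case = TRUE)
  # edge flags cover 2 wavelet s.d. at each end
  sig_t <- 7 / (2 * pi * 1)
  expect_true(all(tf$edge[1, tf$times - tf$times[1] < 2 * sig_t]))
  expect_false(tf$edge[90, which(mid)[1]])
})

test_that("relative power change implements the baseline ratio exactly", {
  # hand-built map: baseline power 2, post-cue power 4 -> change +1
  n <- 200
  times <- seq(-1, 1, length.out = n)
  power <- matrix(2, nrow = 90, ncol = n)
  power[, times >= 0] <- 4
  tf <- structure(list(freqs = 1:90, times = times, power = power),
                  class = "stn_tfmap")
  rp <- relative_power_change(tf)
  expect_true(all(rp$relchange[, times >= 0] == 1))
  expect_true(all(rp$relchange[, times < 0] == 0))
  expect_equal(rp$band_traces$beta[n], 1)
  expect_named(rp$band_traces, c("alpha", "beta", "gamma"))
  # stationary map: time-mean of every band trace is ~0
  set.seed(2)
  pw <- matrix(rexp(90 * n), nrow = 90)
  tfs <- structure(list(freqs = 1:90, times = times, power = pw),
                   class = "stn_tfmap")
  rps <- relative_power_change(tfs)
  for (b in names(rps$band_traces))
    expect_lt(abs(mean(rps$band_traces[[b]])), 0.15)
  # zero baseline power is a hard error
  pw0 <- pw; pw0[5, times < 0] <- 0
  tf0 <- structure(list(freqs = 1:90, times = times, power = pw0),
                   class = "stn_tfmap")
  expect_error(relative_power_change(tf0), "baseline")
})

test_that("bipolar derivation and channel selection follow the conventions", {
  m <- matrix(rnorm(4 * 100), nrow = 4)
  b <- derive_bipolar(m)
  expect_identical(rownames(b), c("01", "12", "23"))
  expect_equal(b[1, ], m[1, ] - m[2, ])
  expect_error(derive_bipolar(m[1:3, ]), "4 x n")
  # identical contacts cancel; the (c, c+a, c, c) pattern gives (-a, +a, 0)
  cc <- rnorm(50); a <- rnorm(50)
  m2 <- rbind(cc, cc + a, cc, cc)
  b2 <- derive_bipolar(m2)
  expect_equal(unname(b2), rbind(-a, a, numeric(50)), ignore_attr = TRUE)
  expect_equal(derive_bipolar(rbind(cc, cc, cc, cc)),
               matrix(0, 3, 50), ignore_attr = TRUE)

  expect_identical(select_channel(c(-0.05, -0.20, -0.01))$pair, "12")
  expect_identical(select_channel(c(-0.2, -0.2, 0))$pair, "01")  # tie rule
  expect_identical(select_channel(c(`01` = 0.1, `12` = -0.1, `23` = 0))$index, 2L)
  expect_error(select_channel(numeric(0)), "no beta")
})

test_that("modulation significance uses inclusive 50% percentile boundaries", {
  times <- feat_times()
  base <- times < 0
  post <- times >= 0.3 & times < 1.3
  # construct a trace with exactly 50% of post-onset points below the
  # 5% boundary of the baseline samples
  x <- numeric(380)
  x[base] <- seq(-1, 1, length.out = sum(base))    # 5% boundary = -0.9+
  lo <- quantile(x[base], 0.05)
  ip <- which(post)
  x[ip[seq_len(50)]] <- lo - 1                     # exactly half below
  x[ip[51:100]] <- 0
  rep <- assess_modulation(list(beta = x), times, onset = 0.3)
  expect_true(rep$significant)                      # >= is inclusive
  expect_identical(rep$direction, "ERD")
  expect_equal(rep$frac_below, 0.5)
  # 49/100 below is not significant
  x[ip[50]] <- 0
  expect_false(assess_modulation(list(beta = x), times, 0.3)$significant)
  # sustained +50% ERS through the post-onset second is detected
  set.seed(4)
  g <- ou_trace(380, 0.016, 0.1) + 0.5 * (times >= 0.3)
  repg <- assess_modulation(list(gamma = g), times, 0.3)
  expect_true(repg$significant)
  expect_identical(repg$direction, "ERS")
  # undefined onset falls back to cue + 0.3 s with a warning
  expect_warning(assess_modulation(list(beta = x), times, onset = NA),
                 "0.3")
})

test_that("force onset detection implements the sustained-threshold rule", {
  times <- feat_times()
  expect_true(is.na(detect_onset(numeric(380), times)))
  f <- ifelse(times >= 0.35, 1, 0)
  expect_equal(detect_onset(f, times), 0.355, tolerance = 0.011)
  # noisy ramp: onset within 20 ms of the analytic threshold crossing
  set.seed(8)
  ramp <- pmax(0, (times - 0.3) / 0.5)
  noise <- rnorm(380, sd = 0.003)
  fno <- pmax(ramp + noise, 0)
  thr <- mean(fno[times < 0]) + max(0.05 * max(fno), 3 * sd(fno[times < 0]))
  analytic <- 0.3 + 0.5 * thr                     # ramp crosses thr here
  expect_lt(abs(detect_onset(fno, times) - analytic), 0.02)
  # a 50 ms blip does not count as onset
  blip <- numeric(380); blip[times >= 0.5 & times < 0.55] <- 1
  expect_true(is.na(detect_onset(blip, times)))
})

test_that("epoching keeps the window arithmetic and drops edge trials", {
  rec <- small_session(seed = 3, n_trials = 5)$recording
  tr <- epoch_trials(rec, fs_out = 100)
  expect_length(tr, 5)
  expect_length(tr[[1]]$force, 380)               # round(3.8 * 100)
  expect_equal(tr[[1]]$times[1], -0.995)
  trn <- epoch_trials(rec)
  expect_length(trn[[1]]$force, round(3.8 * rec$fs))
  # a cue too close to the recording start is dropped with a warning
  rec2 <- rec
  rec2$cue_times <- c(0.5, rec$cue_times)
  rec2$sre <- c(5L, rec$sre)
  expect_warning(tr2 <- epoch_trials(rec2, fs_out = 100), "dropped")
  expect_length(tr2, 5)
  expect_identical(attr(tr2, "dropped"), 1L)
})

test_that("force normalisation puts maximal-effort peaks at 1", {
  mk <- function(peak, sre) list(force = c(0, peak, 0), sre = sre,
                                 times = c(-1, 1, 2), fs = 1)
  trials <- list(mk(10, 10), mk(12, 10), mk(8, 10), mk(5, 3))
  out <- normalize_force(trials)
  expect_equal(attr(out, "divisor"), 10)           # mean of (10, 12, 8)
  expect_equal(max(out[[4]]$force), 0.5)
  peaks <- vapply(out[1:3], function(tr) max(tr$force), numeric(1))
  expect_equal(mean(peaks), 1)                     # self-consistency
  # no maximal-effort trials: three largest peaks stand in, with a message
  expect_message(out2 <- normalize_force(list(mk(4, 2), mk(6, 3), mk(8, 4),
                                              mk(2, 1))),
                 "largest-peak")
  expect_equal(attr(out2, "divisor"), 6)
  expect_error(normalize_force(list(mk(0, 10), mk(0, 10))), "zero")
})

test_that("force yank differentiates and peaks in the initialisation phase", {
  times <- feat_times()
  expect_equal(force_yank(rep(0.7, 380), 100)$yank, numeric(380))
  expect_equal(force_yank(3 * times, 100)$yank, rep(3, 380))
  # first-order step response at fine sampling: peak yank ~ Kp / Tp
  fs <- 1000
  tt <- seq(-1, 2.8, by = 1 / fs)
  fstep <- ifelse(tt >= 0, 2 * (1 - exp(-tt / 0.2)), 0)
  fy <- force_yank(fstep, fs, tt)
  expect_equal(fy$peak, 2 / 0.2, tolerance = 0.01)
  expect_error(force_yank(1, 100), "2 samples")
})

test_that("the feature pipeline is invariant to recording-wide rescaling", {
  ses <- small_session(seed = 5, n_trials = 6)
  rec <- ses$recording
  rec2 <- rec
  rec2$monopolar <- 7 * rec$monopolar
  rec2$force <- 3.5 * rec$force
  f1 <- extract_features(rec, pair = "12")
  f2 <- extract_features(rec2, pair = "12")
  for (i in seq_along(f1$trials)) {
    expect_equal(f1$trials[[i]]$band_trace, f2$trials[[i]]$band_trace,
                 tolerance = 1e-9)
    expect_equal(f1$trials[[i]]$force, f2$trials[[i]]$force,
                 tolerance = 1e-9)
  }
  # trial count and SRE pairing preserved, forces normalised
  expect_identical(vapply(f1$trials, `[[`, integer(1), "sre"), rec$sre)
})

test_that("channel selection picks the constructed most-beta-reactive pair", {
  G <- cbind(alpha = c(1, 0.8, 1.2, 1), beta = c(1, 1, 2.2, 2.08),
             gamma = c(1, 0.7, 1.3, 0.9))
  for (seed in c(2, 6)) {
    lv <- c(rep(10L, 3), rep(0:9, length.out = 17))
    ses <- generate_session(synthetic_config(
      n_trials = 20, fs = 512, sre_levels = lv, contact_gains = G,
      beta_mod_depth = -0.5, carrier_snr = 100, seed = seed))
    f <- extract_features(ses$recording, pair = "auto")
    expect_identical(f$pair, "12")
    expect_lt(f$beta_by_pair[["12"]], min(f$beta_by_pair[c("01", "23")]))
  }
})
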