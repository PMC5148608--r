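test_that("config validation enforces the stated world", {
  expect_error(synthetic_config(n_trials = 1), "n_trials")
  expect_error(synthetic_config(fs = 150), "180")
  expect_error(synthetic_config(n_trials = 4, sre_levels = c(2, 3, 11, 10)),
               "0, 10")
  expect_error(synthetic_config(n_trials = 3, sre_levels = c(1, 2, 3)),
               "maximal-effort")
  expect_error(synthetic_config(beta_mod_depth = -1.2), "-1")
  # default effort labels always include a maximal-effort trial
  cfg <- synthetic_config(n_trials = 8)
  expect_true(any(cfg$sre_levels == 10L))
})

test_that("band envelopes scale with effort and respect the baseline", {
  cfg <- synthetic_config()
  t <- feat_times()
  e0 <- generate_band_envelopes(0, cfg)
  expect_equal(unname(e0), matrix(0, 380, 3), ignore_attr = TRUE)
  e10 <- generate_band_envelopes(10, cfg)
  expect_true(all(e10[t < 0, ] == 0))                 # silent baseline
  expect_true(all(e10[t >= 0, "beta"] <= 0))          # ERD
  expect_true(all(e10[t >= 0, "gamma"] >= 0))         # ERS
  # gamma plateau equals the stated modulation depth (fast rise, transient
  # long gone); the slow beta suppression approaches its depth asymptotically
  expect_equal(unname(e10[which(t >= 2.5)[1], "gamma"]), 0.3,
               tolerance = 1e-6)
  expect_equal(unname(e10[380, "beta"]), -0.3, tolerance = 0.01)
  # monotone effort coding at the plateau
  plateaus <- sapply(0:10, function(s)
    generate_band_envelopes(s, cfg)[which(t >= 2.5)[1], "gamma"])
  expect_true(all(diff(plateaus) >= 0))
  # linear option: plateau(5) is half of plateau(10)
  lin <- synthetic_config(effort_scaling = "linear")
  p5 <- generate_band_envelopes(5, lin)[which(t >= 2.5)[1], ]
  p10 <- generate_band_envelopes(10, lin)[which(t >= 2.5)[1], ]
  expect_equal(unname(p5), unname(0.5 * p10), tolerance = 1e-9)
  expect_error(generate_band_envelopes(11, cfg), "sre")
  expect_error(generate_band_envelopes(-1, cfg), "sre")
})

test_that("generate_force is the forward model plus clamped noise", {
  cfg <- synthetic_config(noise_sd = 0)
  env <- generate_band_envelopes(8, cfg)
  f <- generate_force(env, config = cfg)
  expect_equal(f, simulate_forward(2, cfg$true_params, stnforce:::envelope_trace(env)))
  # zero gains give zero force
  z <- generate_force(env, 2, c(Kp1 = 0, Kp2 = 0, Tp = 0.2, Td = 0.2), cfg,
                      noise = FALSE)
  expect_equal(z, numeric(380))
  # step envelope: 63.2% rise one time constant after the dead time
  t <- feat_times()
  env_step <- cbind(alpha = numeric(380), beta = numeric(380),
                    gamma = step_input())
  fs <- generate_force(env_step, 8, c(Kp = 2, Tp = 0.2, Td = 0.2), cfg,
                       noise = FALSE)
  i63 <- which(t >= 0.005 + 0.2 + 0.2)[1]
  expect_equal(fs[i63], 2 * (1 - exp(-1)), tolerance = 1e-9)
  # doubling the envelopes doubles the (unclamped) steady state
  f2 <- generate_force(2 * env_step, 8, c(Kp = 2, Tp = 0.2, Td = 0.2), cfg,
                       noise = FALSE)
  expect_equal(f2[380], 2 * fs[380], tolerance = 1e-9)
})

test_that("sessions are deterministic, complete, and carry aligned truth", {
  s1 <- small_session(seed = 42, n_trials = 6)
  s2 <- small_session(seed = 42, n_trials = 6)
  expect_identical(s1, s2)                            # bit-identical
  s3 <- small_session(seed = 43, n_trials = 6)
  expect_false(identical(s1$recording$monopolar, s3$recording$monopolar))

  rec <- s1$recording
  expect_length(rec$cue_times, 6)
  expect_length(rec$sre, 6)
  expect_true(all(diff(rec$cue_times) >= 11 & diff(rec$cue_times) <= 13))
  expect_identical(dim(rec$monopolar), c(4L, length(rec$force)))
  expect_length(s1$true_envelopes, 6)
  expect_identical(dim(s1$true_envelopes[[1]]), c(380L, 3L))
  tt <- session_true_trials(s1)
  expect_length(tt, 6)
  expect_length(tt[[1]]$force, 380)
  expect_identical(vapply(tt, `[[`, numeric(1), "sre"), as.numeric(rec$sre))
})

test_that("bipolar derivation removes the common-mode artifact entirely", {
  s0 <- small_session(seed = 9, n_trials = 4, common_mode_amp = 0)
  s5 <- small_session(seed = 9, n_trials = 4, common_mode_amp = 5)
  expect_false(isTRUE(all.equal(s0$recording$monopolar,
                                s5$recording$monopolar)))
  b0 <- derive_bipolar(s0$recording$monopolar)
  b5 <- derive_bipolar(s5$recording$monopolar)
  expect_lt(max(abs(b0 - b5)), 1e-9)
})

test_that("stable force and peak yank are monotone in effort (noiseless)", {
  cfg <- synthetic_config(n_trials = 22, noise_sd = 0,
                          sre_levels = rep(0:10, 2))
  trials <- generate_trials(cfg, noise = FALSE)
  sre <- vapply(trials, `[[`, numeric(1), "sre")
  stab <- vapply(trials, function(tr) stable_force(tr$force, tr$times),
                 numeric(1))
  yank <- vapply(trials, function(tr)
    force_yank(tr$force, tr$fs, tr$times)$peak, numeric(1))
  o <- order(sre)
  expect_true(all(diff(stab[o]) >= -1e-9))
  expect_true(all(diff(yank[o]) >= -1e-9))
})

test_that("background and carrier generators have the stated spectra", {
  set.seed(1)
  n <- 2^15
  fs <- 512
  x <- stnforce:::band_noise(n, fs, c(13, 30))
  expect_equal(sd(x), 1, tolerance = 1e-6)
  ps <- Mod(fft(x))^2
  f <- stnforce:::fft_freqs(n, fs)
  inband <- sum(ps[abs(f) >= 12 & abs(f) <= 31]) / sum(ps)
  expect_gt(inband, 0.99)
  p <- stnforce:::pink_noise(n, fs, 1)
  expect_equal(sd(p), 1, tolerance = 1e-6)
  # 1/f: power in [1,4] Hz exceeds power in [100,103] Hz
  psp <- Mod(fft(p))^2
  expect_gt(sum(psp[abs(f) >= 1 & abs(f) <= 4]),
            5 * sum(psp[abs(f) >= 100 & abs(f) <= 103]))
})
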