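test_that("within-trial correlation handles perfect, inverted and degenerate cases", {
  set.seed(1)
  meas <- abs(rnorm(100))
  expect_equal(within_trial_r(meas, meas), 1)
  expect_equal(within_trial_r(-meas + 2, meas), -1)
  expect_true(is.na(within_trial_r(rep(0.3, 100), meas)))
  expect_error(within_trial_r(1:2, 1:2), "3 samples")
})

test_that("nRMSE is a percentage of the maximal measured value", {
  meas <- c(0.2, 0.5, 1, 0.4)
  expect_equal(nrmse(meas, meas), 0)
  expect_equal(nrmse(meas + 0.1 * max(meas), meas), 10)
  expect_equal(nrmse(numeric(4), rep(0.7, 4)), 100)
  expect_true(is.na(nrmse(meas, numeric(4))))
})

test_that("stable force is the holding-phase mean", {
  times <- feat_times()
  expect_equal(stable_force(rep(0.5, 380), times), 0.5)
  expect_equal(stable_force(numeric(380), times), 0)
  # ramp 0 -> 1 over [1, 2): integral mean 1/2
  ramp <- pmin(pmax(times - 1, 0), 1)
  expect_equal(stable_force(ramp, times), 0.5, tolerance = 1e-3)
  expect_error(stable_force(1:5, 1:5 / 10), "holding window")
})

test_that("stable-force regression across trials", {
  meas <- c(0.1, 0.4, 0.7, 1.0, 0.2)
  r <- stable_force_r(meas, meas)
  expect_equal(r$r, 1)
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  r2 <- stable_force_r(2 * meas, meas)
  expect_equal(r2$r, 1)
  expect_equal(r2$slope, 2)
  expect_true(is.na(stable_force_r(rep(1, 5), meas)$r))
  expect_error(stable_force_r(1, 1), "3 trials")
})

test_that("DifRT is the onset-time difference, excluded when undefined", {
  times <- feat_times()
  f <- ifelse(times >= 0.4, 1, 0)
  expect_equal(dif_rt(f, f, times), 0)
  shifted <- ifelse(times >= 0.5, 1, 0)
  expect_equal(dif_rt(shifted, f, times), 0.1, tolerance = 1e-9)
  expect_true(is.na(dif_rt(numeric(380), f, times)))
})

test_that("BIC follows n*ln(sigma2) + k*ln(n)", {
  expect_equal(bic(sse = 100, n = 100, k = 3), 3 * log(100))
  expect_equal(bic(NULL, 345, 4, sigma2 = 2) - bic(NULL, 345, 3, sigma2 = 2),
               log(345))
  expect_warning(out <- bic(0, 100, 3), "perfect fit")
  expect_true(is.na(out))
  expect_error(bic(1, 0, 3), "positive")
  # penalty signs: smaller variance is better, more parameters worse
  expect_lt(bic(NULL, 200, 3, sigma2 = 0.5), bic(NULL, 200, 3, sigma2 = 1))
  expect_gt(bic(NULL, 200, 9, sigma2 = 1), bic(NULL, 200, 3, sigma2 = 1))
})

test_that("Fisher z is atanh with a guarded domain", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  r <- seq(-0.9, 0.9, by = 0.1)
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_error(fisher_z(1), "\\|r\\| < 1")
})

test_that("effort scaling via Spearman rank correlation", {
  mk <- function(level) list(force = c(numeric(190), rep(level, 190)),
                             times = feat_times(), fs = 100, sre = level)
  up <- lapply(1:6, mk)
  s <- sre_scaling(up)
  expect_equal(s$r_stable, 1)
  sd_ <- sre_scaling(lapply(1:6, function(l)
    list(force = c(numeric(190), rep(7 - l, 190)), times = feat_times(),
         fs = 100, sre = l)))
  expect_equal(sd_$r_stable, -1)
  expect_error(sre_scaling(list(mk(3), mk(3), mk(3))), "distinct SRE")
})

test_that("noisy synthetic sessions keep strong effort scaling", {
  # stated world: noise_sd = 0.05, 30 trials; median over 20 seeds > 0.8
  rs <- vapply(1:20, function(s) {
    trials <- generate_trials(synthetic_config(n_trials = 30, seed = 500 + s))
    sre_scaling(trials)$r_stable
  }, numeric(1))
  expect_gt(median(rs), 0.8)
})

test_that("exponential performance-vs-modulation fit recovers its truth", {
  x <- seq(0.02, 0.5, length.out = 12)
  y <- -0.8 * exp(-10 * x) + 0.9
  fit <- performance_vs_modulation(x, y)
  expect_equal(fit$a, -0.8, tolerance = 0.01)
  expect_equal(fit$b, 10, tolerance = 0.1)
  expect_equal(fit$k, 0.9, tolerance = 0.01)
  expect_equal(fit$r_squared, 1, tolerance = 1e-6)
  flat <- performance_vs_modulation(x, rep(0.4, 12))
  expect_true(flat$degenerate)
  expect_error(performance_vs_modulation(1:3, 1:3), ">= 4")
})

test_that("metrics are invariant to joint rescaling of both traces", {
  set.seed(3)
  meas <- abs(smooth_input()) + 0.05
  pred <- meas + rnorm(380, sd = 0.02)
  for (c in c(0.1, 10)) {
    expect_equal(within_trial_r(c * pred, c * meas),
                 within_trial_r(pred, meas))
    expect_equal(nrmse(c * pred, c * meas), nrmse(pred, meas))
  }
})
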