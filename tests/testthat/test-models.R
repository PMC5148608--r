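test_that("model registry describes the eight structures", {
  sp <- model_spec(2)
  expect_s3_class(sp, "stn_model_spec")
  expect_setequal(sp$inputs, c("beta", "gamma"))
  expect_identical(sp$par_names, c("Kp1", "Kp2", "Tp", "Td"))
  expect_equal(unname(sp$lower[c("Tp", "Td")]), c(0.01, 0))
  expect_equal(unname(sp$upper[c("Tp", "Td")]), c(5, 0.5))
  expect_error(model_spec(9), "unknown model id")
  expect_error(model_spec(0), "unknown model id")
  expect_identical(count_free_parameters(model_spec(5)), 9L)
})

test_that("combine_inputs builds the documented branch inputs", {
  n <- 50
  tr <- flat_trace(n, gamma = rep(0.3, n), beta = rep(-0.2, n),
                   alpha = rep(0.1, n))
  expect_equal(combine_inputs(1, tr)[[1]], rep(0.5, n))
  expect_equal(combine_inputs(2, tr, gains = c(2, -1))[[1]],
               rep(2 * 0.3 + 1 * 0.2, n))
  expect_equal(combine_inputs(4, tr, gains = c(2, -1, 3))[[1]],
               rep(0.6 + 0.2 + 0.3, n))
  expect_named(combine_inputs(5, tr), c("gamma", "beta", "alpha"))
  expect_error(combine_inputs(2, tr), "needs gains")
  # nesting: id2 with (K, -K) equals id1 with Kp = K on random traces
  set.seed(1)
  for (k in c(0.7, 2.3)) {
    rt <- flat_trace(n, gamma = rnorm(n), beta = rnorm(n))
    y1 <- simulate_forward(1, c(Kp = k, Tp = 0.15, Td = 0.1), rt, clamp = FALSE)
    y2 <- simulate_forward(2, c(Kp1 = k, Kp2 = -k, Tp = 0.15, Td = 0.1), rt,
                           clamp = FALSE)
    expect_equal(y1, y2, tolerance = 1e-12)
  }
})

test_that("forward simulation reproduces the analytic first-order response", {
  t <- feat_times()
  tr <- flat_trace(gamma = step_input())
  y <- simulate_forward(8, c(Kp = 2, Tp = 0.1, Td = 0), tr)
  analytic <- ifelse(t >= 0.005, 2 * (1 - exp(-(t - 0.005) / 0.1)), 0)
  expect_lt(max(abs(y - analytic)), 1e-12)
  # value at 0.1 s after the step is Kp*(1 - exp(-1))
  expect_equal(y[which.min(abs(t - 0.105))], 2 * (1 - exp(-1)),
               tolerance = 1e-10)
  expect_equal(y[length(y)], 2, tolerance = 1e-3)   # steady state
  # Kp = 0 gives silence; negative steady state is clamped to zero
  expect_equal(simulate_forward(8, c(Kp = 0, Tp = 0.1, Td = 0), tr),
               numeric(380))
  y_neg <- simulate_forward(8, c(Kp = 1, Tp = 0.1, Td = 0),
                            flat_trace(gamma = -step_input()))
  expect_equal(y_neg, numeric(380))
  expect_error(simulate_forward(8, c(Kp = 1, Tp = -1, Td = 0), tr), "Tp")
  expect_error(simulate_forward(8, c(Kp = 1, Tp = 0.1, Td = -0.1), tr), "Td")
})

test_that("linearity, superposition, steady-state gain and dead-time shift hold", {
  set.seed(7)
  t <- feat_times()
  for (rep in 1:3) {
    tr <- flat_trace(gamma = abs(smooth_input()), beta = -abs(smooth_input()),
                     alpha = abs(smooth_input()))
    p3 <- c(Kp1 = 1.5, Tp1 = 0.2, Td1 = 0.1, Kp2 = -0.8, Tp2 = 0.3, Td2 = 0.2)
    y3 <- simulate_forward(3, p3, tr, clamp = FALSE)
    yg <- simulate_forward(8, c(Kp = 1.5, Tp = 0.2, Td = 0.1), tr, clamp = FALSE)
    yb <- simulate_forward(7, c(Kp = -0.8, Tp = 0.3, Td = 0.2), tr, clamp = FALSE)
    expect_equal(y3, yg + yb, tolerance = 1e-12)           # superposition
    y2 <- simulate_forward(8, c(Kp = 1.5, Tp = 0.2, Td = 0.1),
                           flat_trace(gamma = 3 * tr$gamma), clamp = FALSE)
    expect_equal(y2, 3 * yg, tolerance = 1e-12)            # linearity
  }
  # steady-state gain: constant input -> Kp * u0 within 0.1% after 7 Tp
  u0 <- 0.4
  y <- simulate_forward(8, c(Kp = 2.5, Tp = 0.2, Td = 0),
                        flat_trace(gamma = rep(u0, 380)))
  expect_equal(y[t > -1 + 7 * 0.2 + 0.1][1], 2.5 * u0, tolerance = 1e-3)
  # dead-time: step output rise starts Td after the input step
  for (td in c(0.1, 0.2, 0.3)) {
    ys <- simulate_forward(8, c(Kp = 1, Tp = 0.05, Td = td),
                           flat_trace(gamma = step_input()))
    first_rise <- t[which(ys > 1e-9)[1]]
    expect_equal(first_rise, 0.005 + td + 0.01, tolerance = 0.011)
  }
})

test_that("ZOH recursion agrees with the dense RK4 oracle", {
  set.seed(11)
  for (rep in 1:10) {
    tr <- flat_trace(gamma = smooth_input(), beta = -abs(smooth_input()))
    p <- c(Kp = runif(1, 0.5, 3), Tp = runif(1, 0.06, 0.5),
           Td = runif(1, 0, 0.4))
    a <- simulate_forward(1, p, tr, clamp = FALSE)
    b <- time_domain_oracle(1, p, tr, clamp = FALSE)
    expect_lt(max(abs(a - b)) / diff(range(a)), 1e-6)
  }
  # zero input -> zero output through both routes
  z <- flat_trace()
  expect_equal(time_domain_oracle(7, c(Kp = 2, Tp = 0.2, Td = 0.1), z),
               numeric(380))
})

test_that("fit_model recovers generating parameters and respects its contract", {
  tr <- recovery_trials(2, seed = 3)
  fit <- fit_model(2, tr)
  expect_true(fit$converged)
  expect_lt(max_rel_err(fit$params, default_true_params(2)), 0.01)
  expect_equal(fit$n_obs, 12L * 380L)

  # nesting recovery: data generated by id1, fitted with id2
  tr1 <- recovery_trials(1, seed = 5)
  fit2 <- fit_model(2, tr1)
  expect_equal(unname(fit2$params["Kp1"]), 1.5, tolerance = 0.02)
  expect_equal(unname(fit2$params["Kp2"]), -1.5, tolerance = 0.02)

  # zero force with non-zero inputs -> gains ~ 0, SSE ~ 0
  tr0 <- lapply(tr[1:4], function(x) { x$force <- numeric(380); x })
  fit0 <- fit_model(2, tr0)
  expect_lt(max(abs(fit0$params[c("Kp1", "Kp2")])), 1e-4)
  expect_lt(fit0$sse, 1e-8)

  # all-zero features are unidentifiable; too few observations error
  trz <- list(list(band_trace = flat_trace(), force = numeric(380)))
  expect_error(fit_model(2, trz), "unidentifiable")
  short <- list(list(band_trace = flat_trace(3), force = numeric(3)))
  expect_error(fit_model(2, short), "observations")
})

test_that("fitted models serialise to JSON with their convention", {
  fit <- fit_model(8, recovery_trials(8, seed = 2, n_trials = 4L))
  js <- jsonlite::fromJSON(fit_to_json(fit))
  expect_identical(js$model_id, 8L)
  expect_equal(js$params$Kp, unname(fit$params["Kp"]), tolerance = 1e-12)
  expect_match(js$feature_convention, "fractional")
  path <- withr::local_tempfile(fileext = ".json")
  fit_to_json(fit, path)
  expect_true(file.exists(path))
})
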