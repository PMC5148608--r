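# Eight first-order linear dynamic models with dead time mapping band-power
# inputs (alpha/beta/gamma relative power change) to gripping force.
#
# Every model is built from branches of the form
#   Force = u * Kp / (Tp*s + 1) * exp(-Td*s)
# where u is a band signal or a gain-weighted combination of bands, Kp the
# steady-state gain, Tp the time constant and Td the dead time.

#' Band names used throughout the package
#' @keywords internal
BAND_NAMES <- c("alpha", "beta", "gamma")

# model registry: inputs, structure, free-parameter count and parameter names
.MODEL_TABLE <- list(
  `1` = list(inputs = c("beta", "gamma"), structure = "differenced-input",
             k = 3L, par_names = c("Kp", "Tp", "Td")),
  `2` = list(inputs = c("beta", "gamma"), structure = "shared-lag",
             k = 4L, par_names = c("Kp1", "Kp2", "Tp", "Td")),
  `3` = list(inputs = c("beta", "gamma"), structure = "per-band-lag",
             k = 6L, par_names = c("Kp1", "Tp1", "Td1", "Kp2", "Tp2", "Td2")),
  `4` = list(inputs = c("alpha", "beta", "gamma"), structure = "shared-lag",
             k = 5L, par_names = c("Kp1", "Kp2", "Kp3", "Tp", "Td")),
  `5` = list(inputs = c("alpha", "beta", "gamma"), structure = "per-band-lag",
             k = 9L, par_names = c("Kp1", "Tp1", "Td1", "Kp2", "Tp2", "Td2",
                                   "Kp3", "Tp3", "Td3")),
  `6` = list(inputs = "alpha", structure = "single-band",
             k = 3L, par_names = c("Kp", "Tp", "Td")),
  `7` = list(inputs = "beta", structure = "single-band",
             k = 3L, par_names = c("Kp", "Tp", "Td")),
  `8` = list(inputs = "gamma", structure = "single-band",
             k = 3L, par_names = c("Kp", "Tp", "Td"))
)

#' Model specification for one of the eight force-decoding models
#'
#' The family covers: a differenced gamma-minus-beta input (model 1), shared
#' lag with separate band gains (models 2 and 4, without/with alpha), fully
#' separate first-order branches per band (models 3 and 5), and single-band
#' models (6: alpha, 7: beta, 8: gamma).
#'
#' @param model_id integer 1-8.
#' @return A list with elements `model_id`, `inputs` (subset of
#'   alpha/beta/gamma), `structure`, `k` (number of free parameters),
#'   `par_names`, and box bounds `lower`/`upper` used during fitting
#'   (gains in \[-100, 100\], `Tp` in \[0.01, 5\] s, `Td` in \[0, 0.5\] s).
#' @export
#' @examples
#' model_spec(2)$k    # 4
model_spec <- function(model_id) {
  key <- as.character(model_id)
  if (length(model_id) != 1L || is.na(model_id) || !key %in% names(.MODEL_TABLE))
    stopf("unknown model id: %s (must be 1..8)", paste(model_id, collapse = ","))
  sp <- .MODEL_TABLE[[key]]
  sp$model_id <- as.integer(model_id)
  is_tp <- grepl("^Tp", sp$par_names)
  is_td <- grepl("^Td", sp$par_names)
  sp$lower <- ifelse(is_tp, 0.01, ifelse(is_td, 0, -100))
  sp$upper <- ifelse(is_tp, 5,    ifelse(is_td, 0.5, 100))
  names(sp$lower) <- names(sp$upper) <- sp$par_names
  class(sp) <- "stn_model_spec"
  sp
}

#' Number of free parameters of a decoding model
#'
#' @param model_id integer 1-8 (or a spec from [model_spec()]).
#' @return integer count used as `k` in the BIC penalty.
#' @export
count_free_parameters <- function(model_id) {
  if (inherits(model_id, "stn_model_spec")) return(model_id$k)
  model_spec(model_id)$k
}

# coerce a band trace (list with alpha/beta/gamma, or a 3-column matrix /
# data.frame) to a named list of equal-length numeric vectors
as_band_trace <- function(trace) {
  if (is.matrix(trace) || is.data.frame(trace)) {
    if (!all(BAND_NAMES %in% colnames(trace)))
      stopf("band trace matrix must have columns %s",
            paste(BAND_NAMES, collapse = ", "))
    trace <- list(alpha = as.numeric(trace[, "alpha"]),
                  beta = as.numeric(trace[, "beta"]),
                  gamma = as.numeric(trace[, "gamma"]))
  }
  missing <- setdiff(BAND_NAMES, names(trace))
  if (length(missing))
    stopf("band trace is missing band(s): %s", paste(missing, collapse = ", "))
  n <- unique(lengths(trace[BAND_NAMES]))
  if (length(n) != 1L)
    stopf("band traces must have equal length")
  trace[BAND_NAMES]
}

#' Combine band traces into per-branch model inputs
#'
#' Returns the pre-lag input sequence of every branch of a model: the
#' differenced signal gamma - beta for model 1, the gain-weighted sum for the
#' shared-lag models (2, 4), the raw per-band branch inputs for the
#' per-band-lag models (3, 5), and the single band for models 6-8.
#'
#' @param model_id integer 1-8.
#' @param trace band trace: list with `alpha`, `beta`, `gamma` vectors (or a
#'   3-column matrix).
#' @param gains named/positional gain vector; required for models 2 and 4
#'   (`Kp1` weighs gamma, `Kp2` beta, `Kp3` alpha), ignored otherwise.
#' @return list of numeric branch-input sequences.
#' @export
combine_inputs <- function(model_id, trace, gains = NULL) {
  sp <- model_spec(model_id)
  tr <- as_band_trace(trace)
  switch(as.character(sp$model_id),
    `1` = list(tr$gamma - tr$beta),
    `2` = {
      if (length(gains) < 2L) stopf("model 2 needs gains Kp1 (gamma), Kp2 (beta)")
      list(gains[[1L]] * tr$gamma + gains[[2L]] * tr$beta)
    },
    `3` = list(gamma = tr$gamma, beta = tr$beta),
    `4` = {
      if (length(gains) < 3L)
        stopf("model 4 needs gains Kp1 (gamma), Kp2 (beta), Kp3 (alpha)")
      list(gains[[1L]] * tr$gamma + gains[[2L]] * tr$beta +
             gains[[3L]] * tr$alpha)
    },
    `5` = list(gamma = tr$gamma, beta = tr$beta, alpha = tr$alpha),
    `6` = list(tr$alpha),
    `7` = list(tr$beta),
    `8` = list(tr$gamma)
  )
}

# continuous dead-time shift of the columns of u by Td seconds, linear
# interpolation between samples; before the window start the input is taken
# constant at its first sample (rest)
delay_shift <- function(u, dt, Td) {
  if (Td < 0) stopf("dead time Td must be >= 0")
  if (Td == 0) return(u)
  n <- nrow(u)
  s <- Td / dt
  k <- floor(s)
  f <- s - k
  i1 <- pmax(seq_len(n) - k, 1L)       # sample at t - k*dt
  i2 <- pmax(i1 - 1L, 1L)              # sample at t - (k+1)*dt
  (1 - f) * u[i1, , drop = FALSE] + f * u[i2, , drop = FALSE]
}

check_dynamics <- function(Tp, Td, n, dt) {
  if (!is.finite(Tp) || Tp <= 0) stopf("time constant Tp must be > 0")
  if (!is.finite(Td) || Td < 0) stopf("dead time Td must be >= 0")
  if (Td > (n - 1) * dt) stopf("dead time Td exceeds the trace duration")
}

# one first-order branch: gain * lag(delay(u)); u is an n x m matrix
sim_branch <- function(u, dt, Kp, Tp, Td) {
  check_dynamics(Tp, Td, nrow(u), dt)
  Kp * zoh_lag_filter(delay_shift(u, dt, Td), dt, Tp)
}

# forward-simulate a model on band matrices (n x m, trials in columns);
# returns the unclamped n x m prediction
sim_model <- function(model_id, par, bands, dt) {
  p <- function(nm) unname(par[[nm]])
  switch(as.character(model_id),
    `1` = sim_branch(bands$gamma - bands$beta, dt, p("Kp"), p("Tp"), p("Td")),
    `2` = sim_branch(p("Kp1") * bands$gamma + p("Kp2") * bands$beta,
                     dt, 1, p("Tp"), p("Td")),
    `3` = sim_branch(bands$gamma, dt, p("Kp1"), p("Tp1"), p("Td1")) +
          sim_branch(bands$beta,  dt, p("Kp2"), p("Tp2"), p("Td2")),
    `4` = sim_branch(p("Kp1") * bands$gamma + p("Kp2") * bands$beta +
                       p("Kp3") * bands$alpha, dt, 1, p("Tp"), p("Td")),
    `5` = sim_branch(bands$gamma, dt, p("Kp1"), p("Tp1"), p("Td1")) +
          sim_branch(bands$beta,  dt, p("Kp2"), p("Tp2"), p("Td2")) +
          sim_branch(bands$alpha, dt, p("Kp3"), p("Tp3"), p("Td3")),
    `6` = sim_branch(bands$alpha, dt, p("Kp"), p("Tp"), p("Td")),
    `7` = sim_branch(bands$beta,  dt, p("Kp"), p("Tp"), p("Td")),
    `8` = sim_branch(bands$gamma, dt, p("Kp"), p("Tp"), p("Td")),
    stopf("unknown model id: %s", model_id)
  )
}

# band trace (list) -> list of single-column matrices, plus sanity checks
bands_as_matrices <- function(trace) {
  tr <- as_band_trace(trace)
  lapply(tr, function(x) matrix(as.numeric(x), ncol = 1L))
}

coerce_params <- function(sp, params) {
  params <- unlist(params)
  if (length(params) != sp$k)
    stopf("model %d expects %d parameters (%s), got %d", sp$model_id, sp$k,
          paste(sp$par_names, collapse = ", "), length(params))
  if (is.null(names(params)) || !all(nzchar(names(params))))
    names(params) <- sp$par_names
  if (!setequal(names(params), sp$par_names))
    stopf("parameter names must be %s", paste(sp$par_names, collapse = ", "))
  params[sp$par_names]
}

#' Forward-simulate a force-decoding model
#'
#' Each first-order branch `Kp / (Tp*s + 1) * exp(-Td*s)` is simulated by the
#' exact causal zero-order-hold recursion `y[n] = a*y[n-1] + (1-a)*u[n-1]`
#' with `a = exp(-dt/Tp)`; the dead time is a continuous shift with linear
#' interpolation between samples, so `Td` is a smooth optimisation variable.
#' The initial condition is zero (the decode window opens at rest, 1 s before
#' the cue). Branch outputs are summed and, by default, clamped at zero: the
#' plant cannot pull force negative.
#'
#' @param model_id integer 1-8.
#' @param params named numeric parameter vector matching
#'   `model_spec(model_id)$par_names` (unnamed vectors are taken in that
#'   order).
#' @param trace band trace (list with `alpha`, `beta`, `gamma` or a 3-column
#'   matrix) sampled at `fs_feature`.
#' @param fs_feature feature sampling rate in Hz (default 100).
#' @param clamp clamp the summed output at >= 0 (default TRUE).
#' @return numeric vector of predicted force, same length as the trace.
#' @export
#' @examples
#' tr <- list(alpha = numeric(380), beta = numeric(380),
#'            gamma = c(numeric(100), rep(0.3, 280)))
#' f <- simulate_forward(8, c(Kp = 2, Tp = 0.2, Td = 0.1), tr)
simulate_forward <- function(model_id, params, trace, fs_feature = 100,
                             clamp = TRUE) {
  sp <- model_spec(model_id)
  params <- coerce_params(sp, params)
  bands <- bands_as_matrices(trace)
  if (nrow(bands$alpha) < 2L) stopf("trace must have at least 2 samples")
  y <- sim_model(sp$model_id, params, bands, 1 / fs_feature)
  y <- as.numeric(y)
  if (clamp) y <- pmax(y, 0)
  y
}

# RK4 integration of Tp*y' = u - y with the same causal-hold input model,
# n_sub substeps per sample interval (input constant inside each interval,
# so no discontinuity crosses an integration step)
ode_lag <- function(u, dt, Tp, n_sub = 20L) {
  n <- length(u)
  y <- numeric(n)
  h <- dt / n_sub
  yc <- 0
  for (i in 2:n) {
    uin <- u[i - 1L]
    for (s in seq_len(n_sub)) {
      k1 <- (uin - yc) / Tp
      k2 <- (uin - (yc + h / 2 * k1)) / Tp
      k3 <- (uin - (yc + h / 2 * k2)) / Tp
      k4 <- (uin - (yc + h * k3)) / Tp
      yc <- yc + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    y[i] <- yc
  }
  y
}

#' Independent ODE oracle for the first-order force models
#'
#' Integrates the time-domain form `Force(t) + Tp * dForce/dt = Kp * u(t-Td)`
#' of every branch with a dense fixed-step Runge-Kutta (RK4) scheme under the
#' same causal sample-hold input convention as [simulate_forward()]. The two
#' routes share only the input interpolation; the recursion vs numerical
#' integration paths are independent, making this the reference
#' implementation for equivalence testing.
#'
#' @inheritParams simulate_forward
#' @param n_sub RK4 substeps per feature sample (default 20).
#' @return numeric vector of predicted force (clamped like
#'   [simulate_forward()] when `clamp = TRUE`).
#' @export
time_domain_oracle <- function(model_id, params, trace, fs_feature = 100,
                               clamp = TRUE, n_sub = 20L) {
  sp <- model_spec(model_id)
  params <- coerce_params(sp, params)
  bands <- bands_as_matrices(trace)
  dt <- 1 / fs_feature
  n <- nrow(bands$alpha)
  branch <- function(u, Kp, Tp, Td) {
    check_dynamics(Tp, Td, n, dt)
    ud <- delay_shift(u, dt, Td)
    Kp * ode_lag(as.numeric(ud), dt, Tp, n_sub)
  }
  p <- function(nm) unname(params[[nm]])
  y <- switch(as.character(sp$model_id),
    `1` = branch(bands$gamma - bands$beta, p("Kp"), p("Tp"), p("Td")),
    `2` = branch(p("Kp1") * bands$gamma + p("Kp2") * bands$beta,
                 1, p("Tp"), p("Td")),
    `3` = branch(bands$gamma, p("Kp1"), p("Tp1"), p("Td1")) +
          branch(bands$beta,  p("Kp2"), p("Tp2"), p("Td2")),
    `4` = branch(p("Kp1") * bands$gamma + p("Kp2") * bands$beta +
                   p("Kp3") * bands$alpha, 1, p("Tp"), p("Td")),
    `5` = branch(bands$gamma, p("Kp1"), p("Tp1"), p("Td1")) +
          branch(bands$beta,  p("Kp2"), p("Tp2"), p("Td2")) +
          branch(bands$alpha, p("Kp3"), p("Tp3"), p("Td3")),
    `6` = branch(bands$alpha, p("Kp"), p("Tp"), p("Td")),
    `7` = branch(bands$beta,  p("Kp"), p("Tp"), p("Td")),
    `8` = branch(bands$gamma, p("Kp"), p("Tp"), p("Td"))
  )
  if (clamp) y <- pmax(y, 0)
  y
}

# variable-projection structure of each model: branch input builders, the
# (Tp, Td) slots each branch reads from the nonlinear parameter vector, and
# the re-assembly of the full named parameter vector from (theta, gains)
varpro_structure <- function(sp) {
  g_ <- function(b) function(bands) bands[[b]]
  diff_ <- function(bands) bands$gamma - bands$beta
  br <- function(input, tp, td) list(input = input, tp = tp, td = td)
  switch(as.character(sp$model_id),
    `1` = list(branches = list(br(diff_, 1L, 2L)),
               theta_names = c("Tp", "Td"),
               assemble = function(th, g)
                 c(Kp = g[1], Tp = th[1], Td = th[2])),
    `2` = list(branches = list(br(g_("gamma"), 1L, 2L), br(g_("beta"), 1L, 2L)),
               theta_names = c("Tp", "Td"),
               assemble = function(th, g)
                 c(Kp1 = g[1], Kp2 = g[2], Tp = th[1], Td = th[2])),
    `3` = list(branches = list(br(g_("gamma"), 1L, 2L), br(g_("beta"), 3L, 4L)),
               theta_names = c("Tp1", "Td1", "Tp2", "Td2"),
               assemble = function(th, g)
                 c(Kp1 = g[1], Tp1 = th[1], Td1 = th[2],
                   Kp2 = g[2], Tp2 = th[3], Td2 = th[4])),
    `4` = list(branches = list(br(g_("gamma"), 1L, 2L), br(g_("beta"), 1L, 2L),
                               br(g_("alpha"), 1L, 2L)),
               theta_names = c("Tp", "Td"),
               assemble = function(th, g)
                 c(Kp1 = g[1], Kp2 = g[2], Kp3 = g[3],
                   Tp = th[1], Td = th[2])),
    `5` = list(branches = list(br(g_("gamma"), 1L, 2L), br(g_("beta"), 3L, 4L),
                               br(g_("alpha"), 5L, 6L)),
               theta_names = c("Tp1", "Td1", "Tp2", "Td2", "Tp3", "Td3"),
               assemble = function(th, g)
                 c(Kp1 = g[1], Tp1 = th[1], Td1 = th[2],
                   Kp2 = g[2], Tp2 = th[3], Td2 = th[4],
                   Kp3 = g[3], Tp3 = th[5], Td3 = th[6])),
    `6` = list(branches = list(br(g_("alpha"), 1L, 2L)),
               theta_names = c("Tp", "Td"),
               assemble = function(th, g)
                 c(Kp = g[1], Tp = th[1], Td = th[2])),
    `7` = list(branches = list(br(g_("beta"), 1L, 2L)),
               theta_names = c("Tp", "Td"),
               assemble = function(th, g)
                 c(Kp = g[1], Tp = th[1], Td = th[2])),
    `8` = list(branches = list(br(g_("gamma"), 1L, 2L)),
               theta_names = c("Tp", "Td"),
               assemble = function(th, g)
                 c(Kp = g[1], Tp = th[1], Td = th[2]))
  )
}

# bounded Levenberg-Marquardt least squares: numerical forward-difference
# Jacobian, Marquardt diagonal scaling, steps projected onto the box
lm_bounded <- function(par, fn, lower, upper, max_iter = 100L, ftol = 1e-12) {
  par <- pmin(pmax(par, lower), upper)
  r <- fn(par)
  sse <- sum(r^2)
  lambda <- 1e-3
  k <- length(par)
  converged <- FALSE
  stall <- 0L
  for (it in seq_len(max_iter)) {
    J <- matrix(0, length(r), k)
    for (j in seq_len(k)) {
      h <- 1e-6 * max(abs(par[j]), 1e-2)
      if (par[j] + h > upper[j]) h <- -h
      pj <- par
      pj[j] <- pj[j] + h
      J[, j] <- (fn(pj) - r) / h
    }
    g <- crossprod(J, r)
    A <- crossprod(J)
    improved <- FALSE
    for (tries in 1:12) {
      Areg <- A + lambda * diag(pmax(diag(A), 1e-12), k)
      delta <- tryCatch(solve(Areg, -g), error = function(e) NULL)
      if (is.null(delta)) { lambda <- lambda * 10; next }
      newp <- pmin(pmax(par + as.numeric(delta), lower), upper)
      rn <- fn(newp)
      sn <- sum(rn^2)
      if (is.finite(sn) && sn < sse) {
        rel <- (sse - sn) / max(sse, 1e-300)
        par <- newp; r <- rn; sse <- sn
        lambda <- max(lambda * 0.3, 1e-12)
        improved <- TRUE
        if (rel < ftol) converged <- TRUE
        # repeated near-stalls: progress is below resolvable curvature
        stall <- if (rel < 1e-9) stall + 1L else 0L
        if (stall >= 3L) converged <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!improved) { converged <- TRUE; break }
    if (converged) break
  }
  list(par = par, sse = sse, converged = converged)
}

# assemble fitting matrices from a list of trials (each with $band_trace and
# $force) or from a single trial-like list
fitting_data <- function(trials) {
  if (!is.null(trials$band_trace)) trials <- list(trials)
  if (!length(trials)) stopf("no trials to fit on")
  traces <- lapply(trials, function(tr) as_band_trace(tr$band_trace))
  n <- length(traces[[1L]]$alpha)
  ok <- vapply(trials, function(tr) length(tr$force) == n, logical(1)) &
    vapply(traces, function(tr) length(tr$alpha) == n, logical(1))
  if (!all(ok)) stopf("all trials must share the same trace length")
  bands <- lapply(setNames(BAND_NAMES, BAND_NAMES), function(b)
    vapply(traces, `[[`, numeric(n), b))
  bands <- lapply(bands, function(x) matrix(x, nrow = n))
  force <- matrix(vapply(trials, function(tr) as.numeric(tr$force),
                         numeric(n)), nrow = n)
  list(bands = bands, force = force, n_obs = length(force))
}

#' Fit a force-decoding model by bounded multi-start least squares
#'
#' Minimises the sum of squared errors between measured force and the model
#' prediction over the concatenated training trials, within box bounds
#' (gains in \[-100, 100\], `Tp` in \[0.01, 5\] s, `Td` in \[0, 0.5\] s,
#' covering the 0-277 ms dead times seen empirically). Because the gains
#' enter the output linearly, they are profiled out by exact linear least
#' squares (variable projection) and a bounded Levenberg-Marquardt search
#' runs over the dynamic parameters only, restarted from a deterministic
#' grid of dead times \{0, 0.1, 0.2, 0.3, 0.4\} s crossed with two time
#' constants \{0.1, 0.3\} s; the best SSE is kept (gain-sign restarts are
#' redundant under variable projection: the sign comes out of the linear
#' solve). Clamping at zero is *not* applied inside the objective (it is
#' applied to final predictions only), keeping the objective smooth.
#'
#' @param model_id integer 1-8.
#' @param trials a list of trials, each a list with `band_trace` (see
#'   [simulate_forward()]) and `force` (numeric, same length); a single trial
#'   is also accepted.
#' @param fs_feature feature sampling rate in Hz (default 100).
#' @param td_grid multi-start dead-time grid in seconds.
#' @param control passed to [stats::optim()].
#' @return object of class `stn_fit`: list with `model_id`, `params` (named),
#'   `sse`, `n_obs`, `converged`, `n_starts_used`.
#' @export
fit_model <- function(model_id, trials, fs_feature = 100,
                      td_grid = seq(0, 0.4, by = 0.1), control = list()) {
  sp <- model_spec(model_id)
  dat <- fitting_data(trials)
  if (dat$n_obs <= sp$k)
    stopf("need more observations (%d) than free parameters (%d)",
          dat$n_obs, sp$k)
  band_norm <- vapply(dat$bands[unique(sp$inputs)],
                      function(x) sum(x^2), numeric(1))
  if (all(band_norm == 0))
    stopf("model %d is unidentifiable: all input features are zero",
          sp$model_id)
  dt <- 1 / fs_feature
  # Variable projection: for fixed dynamics theta = (Tp, Td per branch) the
  # model output is linear in the gains, so the gains are solved exactly by
  # linear least squares on the branch basis and only theta is optimised.
  # This removes the near-flat gain/dynamics valleys of the raw
  # 9-parameter problem and makes the multi-start cheap.
  vp <- varpro_structure(sp)
  n_th <- length(vp$theta_names)
  yvec <- as.numeric(dat$force)
  basis <- function(theta) {
    cols <- lapply(vp$branches, function(br) {
      u <- br$input(dat$bands)
      as.numeric(sim_branch(u, dt, 1, theta[br$tp], theta[br$td]))
    })
    do.call(cbind, cols)
  }
  solve_gains <- function(B) {
    A <- crossprod(B)
    b <- crossprod(B, yvec)
    g <- tryCatch(as.numeric(solve(A, b)), error = function(e) NULL)
    if (is.null(g)) {                       # rank-deficient basis
      g <- qr.coef(qr(B), yvec)
      g[is.na(g)] <- 0
    }
    g
  }
  resid_fn <- function(theta) {
    B <- basis(theta)
    yvec - as.numeric(B %*% solve_gains(B))
  }
  lower <- rep(c(0.01, 0), n_th / 2)     # (Tp, Td) per branch
  upper <- rep(c(5, 0.5), n_th / 2)
  ctrl <- modifyList(list(max_iter = 100L, ftol = 1e-12), control)
  best <- NULL
  n_used <- 0L
  sse_floor <- 1e-14 * (sum(yvec^2) + 1)
  for (td0 in td_grid) {
    for (tp0 in c(0.1, 0.3)) {
      start <- rep(c(tp0, td0), n_th / 2)
      res <- tryCatch(
        lm_bounded(start, resid_fn, lower, upper,
                   max_iter = ctrl$max_iter, ftol = ctrl$ftol),
        error = function(e) NULL)
      n_used <- n_used + 1L
      if (is.null(res)) next
      if (is.null(best) || res$sse < best$sse) best <- res
      if (best$sse <= sse_floor) break
    }
    if (!is.null(best) && best$sse <= sse_floor) break
  }
  if (is.null(best))
    stopf("model %d: no optimisation start converged", sp$model_id)
  gains <- solve_gains(basis(best$par))
  gains <- pmin(pmax(gains, -100), 100)  # box bound on gains
  params <- vp$assemble(best$par, gains)
  structure(list(model_id = sp$model_id, params = params,
                 sse = best$sse, n_obs = dat$n_obs,
                 converged = isTRUE(best$converged),
                 n_starts_used = n_used),
            class = "stn_fit")
}

#' @export
print.stn_fit <- function(x, ...) {
  cat(sprintf("Model %d fit (%d obs, SSE %.6g, %sconverged)\n", x$model_id,
              x$n_obs, x$sse, if (x$converged) "" else "NOT "))
  print(round(x$params, 4))
  invisible(x)
}

#' Predict force from a fitted model
#'
#' @param object an `stn_fit` from [fit_model()].
#' @param trace band trace to decode.
#' @param fs_feature feature rate in Hz.
#' @param clamp clamp predictions at zero (default TRUE, matching the
#'   convention that predicted force may not fall below zero).
#' @param ... unused.
#' @return numeric vector of predicted force.
#' @export
predict.stn_fit <- function(object, trace, fs_feature = 100, clamp = TRUE,
                            ...) {
  simulate_forward(object$model_id, object$params, trace, fs_feature, clamp)
}

#' Serialise a fitted model to JSON
#'
#' Records the parameter convention (band features as *fractional* power
#' change) alongside the estimates so gains are interpretable downstream.
#'
#' @param fit an `stn_fit`.
#' @param path output file; when NULL the JSON string is returned.
#' @return path (invisibly) or JSON string.
#' @export
fit_to_json <- function(fit, path = NULL) {
  sp <- model_spec(fit$model_id)
  obj <- list(model_id = fit$model_id, params = as.list(fit$params),
              bounds = list(lower = as.list(sp$lower),
                            upper = as.list(sp$upper)),
              sse = fit$sse, n_obs = fit$n_obs,
              feature_convention = "fractional power change (0 = baseline)")
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}
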