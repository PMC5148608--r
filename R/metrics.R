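# Decoding metrics: within-trial correlation, normalised RMSE, stable-force
# statistics, onset-time difference, BIC, Fisher-z, effort scaling, and the
# performance-vs-modulation exponential fit.

#' Within-trial correlation between predicted and measured force
#'
#' Pearson correlation over the decode window; returns `NA` (excluded, never
#' imputed) when either trace has zero variance.
#'
#' @param pred,meas numeric vectors of equal length (>= 3).
#' @return Pearson r, or `NA_real_` for degenerate input.
#' @export
within_trial_r <- function(pred, meas) {
  stopifnot(length(pred) == length(meas))
  if (length(pred) < 3L) stopf("need at least 3 samples")
  if (sd(pred) == 0 || sd(meas) == 0) return(NA_real_)
  cor(pred, meas)
}

#' Normalised root-mean-square error (percent)
#'
#' RMSE between prediction and measurement as a percentage of the maximal
#' measured value.
#'
#' @param pred,meas numeric vectors of equal length.
#' @return nRMSE in percent, or `NA_real_` when `max(meas) <= 0`.
#' @export
nrmse <- function(pred, meas) {
  stopifnot(length(pred) == length(meas))
  m <- max(meas)
  if (!is.finite(m) || m <= 0) return(NA_real_)
  100 * sqrt(mean((pred - meas)^2)) / m
}

#' Mean force over the holding phase
#'
#' The holding phase is 1-2 s after the cue, when grip force is relatively
#' stable; its mean is the "stable force" (start inclusive, end exclusive).
#'
#' @param trace numeric force trace.
#' @param times sample times (s relative to cue).
#' @param window holding window, default c(1, 2).
#' @return mean force over the window.
#' @export
stable_force <- function(trace, times, window = c(1, 2)) {
  sel <- times >= window[1] & times < window[2]
  if (!any(sel)) stopf("holding window lies outside the trace")
  mean(trace[sel])
}

#' Across-trial correlation of predicted vs measured stable force
#'
#' Pearson correlation, OLS slope and intercept of predicted on measured
#' holding-phase means across trials.
#'
#' @param pred_stable,meas_stable numeric vectors (one value per trial,
#'   >= 3 trials).
#' @return list with `r`, `slope`, `intercept`, `n`.
#' @export
stable_force_r <- function(pred_stable, meas_stable) {
  stopifnot(length(pred_stable) == length(meas_stable))
  ok <- is.finite(pred_stable) & is.finite(meas_stable)
  if (sum(ok) < 3L) stopf("need at least 3 trials")
  p <- pred_stable[ok]; m <- meas_stable[ok]
  if (sd(p) == 0 || sd(m) == 0)
    return(list(r = NA_real_, slope = NA_real_, intercept = NA_real_,
                n = sum(ok)))
  fit <- lm(p ~ m)
  list(r = cor(p, m), slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]), n = sum(ok))
}

#' Difference between predicted and measured force-onset times
#'
#' `DifRT = onset(predicted) - onset(measured)` using [detect_onset()];
#' `NA` when either onset is undefined (such trials are excluded and
#' counted, never imputed).
#'
#' @param pred,meas force traces over the decode window.
#' @param times sample times (s relative to cue).
#' @return onset difference in seconds, or `NA_real_`.
#' @export
dif_rt <- function(pred, meas, times) {
  op <- detect_onset(pred, times)
  om <- detect_onset(meas, times)
  if (is.na(op) || is.na(om)) return(NA_real_)
  op - om
}

#' Bayesian information criterion for a force decoder
#'
#' `BIC = n * ln(sigma_e^2) + k * ln(n)` with `sigma_e^2` the error variance
#' `(1/n) * sum((F - Fhat)^2)` over the evaluated time points, `n` the number
#' of time points and `k` the model's free-parameter count.
#'
#' @param sse sum of squared errors (or pass `sigma2` directly).
#' @param n number of time points (> 0).
#' @param k number of free parameters.
#' @param sigma2 error variance; overrides `sse` when given.
#' @return BIC value; `NA_real_` with a "perfect fit" warning when the error
#'   variance is zero (BIC undefined).
#' @export
bic <- function(sse, n, k, sigma2 = NULL) {
  if (n <= 0) stopf("n must be positive")
  if (is.null(sigma2)) sigma2 <- sse / n
  if (sigma2 <= 0) {
    warning("zero error variance: perfect fit, BIC undefined", call. = FALSE)
    return(NA_real_)
  }
  n * log(sigma2) + k * log(n)
}

#' Fisher z-transform of a correlation coefficient
#'
#' `z = atanh(r)`; applied to correlation coefficients before statistical
#' comparison.
#'
#' @param r correlation in (-1, 1).
#' @return z value.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stopf("fisher_z requires |r| < 1")
  atanh(r)
}

#' Effort scaling of stable force and peak force yank
#'
#' Spearman rank correlations of the per-trial holding-phase force and of the
#' initialisation-phase peak yank against the self-rated effort (SRE).
#'
#' @param trials list of trials with `force`, `times`, `fs`, `sre`.
#' @return list with `r_stable`, `r_yank`, `n`.
#' @export
sre_scaling <- function(trials) {
  sre <- vapply(trials, function(tr) as.numeric(tr$sre), numeric(1))
  if (length(trials) < 3L || length(unique(sre)) < 2L)
    stopf("need >= 3 trials with >= 2 distinct SRE levels")
  stab <- vapply(trials, function(tr) stable_force(tr$force, tr$times),
                 numeric(1))
  yank <- vapply(trials, function(tr)
    force_yank(tr$force, tr$fs, tr$times)$peak, numeric(1))
  list(r_stable = cor(stab, sre, method = "spearman"),
       r_yank = cor(yank, sre, method = "spearman"),
       n = length(trials))
}

#' Exponential fit of decoding performance against band modulation
#'
#' Fits `y = a * exp(-b * x) + k` (e.g. per-session median WithinR against
#' mean gamma modulation) by separable least squares: for each candidate
#' decay rate `b` the amplitude `a` and offset `k` are solved by linear
#' regression, and `b` is profiled with a golden-section search bracketed by
#' a coarse grid. Degenerate (constant) data are flagged rather than fitted.
#'
#' @param x,y numeric vectors (>= 4 points for 3 parameters).
#' @param b_range search interval for `b` (default c(-100, 100)).
#' @return list with `a`, `b`, `k`, `r_squared`, `fitted`, `degenerate`.
#' @export
performance_vs_modulation <- function(x, y, b_range = c(-100, 100)) {
  if (length(x) != length(y) || length(x) < 4L)
    stopf("need >= 4 (x, y) points to fit 3 parameters")
  if (sd(y) == 0 || sd(x) == 0)
    return(list(a = NA_real_, b = NA_real_, k = NA_real_,
                r_squared = NA_real_, fitted = rep(mean(y), length(y)),
                degenerate = TRUE))
  prof <- function(b) {
    e <- exp(-b * x)
    if (sd(e) < 1e-12) return(list(sse = sum((y - mean(y))^2),
                                   a = 0, k = mean(y)))
    fit <- lm(y ~ e)
    list(sse = sum(fit$residuals^2), a = unname(coef(fit)[2]),
         k = unname(coef(fit)[1]))
  }
  grid <- sort(unique(c(seq(b_range[1], b_range[2], length.out = 81), 0)))
  sses <- vapply(grid, function(b) prof(b)$sse, numeric(1))
  i <- which.min(sses)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  b_opt <- optimize(function(b) prof(b)$sse, c(lo, hi))$minimum
  if (prof(grid[i])$sse < prof(b_opt)$sse) b_opt <- grid[i]
  sol <- prof(b_opt)
  fitted <- sol$a * exp(-b_opt * x) + sol$k
  ss_tot <- sum((y - mean(y))^2)
  list(a = sol$a, b = b_opt, k = sol$k,
       r_squared = 1 - sol$sse / ss_tot, fitted = fitted,
       degenerate = abs(sol$a) < 1e-10)
}
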