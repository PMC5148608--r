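# Morlet continuous wavelet transform and baseline-relative power change.

#' Morlet continuous wavelet transform
#'
#' Complex Morlet CWT computed by FFT convolution with analytic Gaussian
#' frequency-domain kernels. At frequency `f` the wavelet's temporal s.d. is
#' `n_cycles / (2*pi*f)` (7 cycles by default), trading temporal for
#' spectral resolution in the usual way. The kernel is normalised so a pure
#' sinusoid of amplitude A yields power A^2 at its own frequency.
#'
#' @param signal numeric vector.
#' @param fs sampling rate in Hz (must exceed twice `max(freqs)`).
#' @param freqs frequency grid in Hz (default 1-90 Hz in 1 Hz steps).
#' @param n_cycles Morlet cycle number (default 7).
#' @param t0 time (s) of the first sample (times are `t0 + (0:(n-1))/fs`).
#' @return list of class `stn_tfmap`: `freqs`, `times`, `power`
#'   (freq x time matrix of squared magnitudes), and `edge`, a logical
#'   freq x time matrix flagging samples within two wavelet temporal s.d.
#'   of either end of the signal.
#' @export
morlet_cwt <- function(signal, fs, freqs = 1:90, n_cycles = 7, t0 = 0) {
  n <- length(signal)
  if (any(freqs <= 0)) stopf("frequencies must be positive")
  if (fs <= 2 * max(freqs))
    stopf("fs (%g Hz) must exceed twice the maximum analysis frequency (%g Hz)",
          fs, max(freqs))
  N <- nextn(n)
  X <- fft(c(signal, numeric(N - n)))
  f_grid <- fft_freqs(N, fs)
  pos <- f_grid > 0
  power <- matrix(0, nrow = length(freqs), ncol = n)
  sigma_t <- n_cycles / (2 * pi * freqs)
  for (k in seq_along(freqs)) {
    sigma_f <- 1 / (2 * pi * sigma_t[k])
    H <- numeric(N)
    H[pos] <- 2 * exp(-(f_grid[pos] - freqs[k])^2 / (2 * sigma_f^2))
    W <- fft(X * H, inverse = TRUE) / N
    power[k, ] <- Mod(W[seq_len(n)])^2
  }
  times <- t0 + (seq_len(n) - 1) / fs
  t_rel <- (seq_len(n) - 1) / fs
  edge <- outer(2 * sigma_t, t_rel, function(s, t) t < s | t > (n - 1) / fs - s)
  structure(list(freqs = freqs, times = times, power = power, edge = edge),
            class = "stn_tfmap")
}

#' Baseline-relative power change
#'
#' Normalises a time-frequency power map against the mean power per
#' frequency over a pre-cue baseline window: the result is
#' `P(f,t) / mean_baseline(P(f)) - 1`, so 0 means power equal to baseline,
#' +1 a doubling (ERS) and negative values a suppression (ERD). Band traces
#' are the simple mean of the fractional-change map over the frequency rows
#' inside each band's inclusive limits.
#'
#' @param tf an `stn_tfmap` from [morlet_cwt()] with `times` relative to the
#'   cue.
#' @param baseline two-element window (s) defining the baseline
#'   (default c(-1, 0), the second before the cue; start inclusive, end
#'   exclusive).
#' @param bands named list of band limits in Hz (inclusive on both edges).
#' @return list with `relchange` (freq x time fractional-change matrix),
#'   `band_traces` (list of per-band numeric vectors), `times`.
#' @export
relative_power_change <- function(tf, baseline = c(-1, 0),
                                  bands = list(alpha = c(4, 12),
                                               beta = c(13, 30),
                                               gamma = c(55, 90))) {
  sel <- tf$times >= baseline[1] & tf$times < baseline[2]
  if (!any(sel)) stopf("baseline window lies outside the map")
  base <- rowMeans(tf$power[, sel, drop = FALSE])
  if (any(base <= 0))
    stopf("zero baseline power at %d frequencies; cannot normalise",
          sum(base <= 0))
  rel <- sweep(tf$power, 1, base, `/`) - 1
  band_traces <- lapply(bands, function(b) {
    rows <- tf$freqs >= b[1] & tf$freqs <= b[2]
    colMeans(rel[rows, , drop = FALSE])
  })
  list(relchange = rel, band_traces = band_traces, times = tf$times)
}
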