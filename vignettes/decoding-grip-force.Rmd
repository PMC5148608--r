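---
title: "Decoding gripping force from subthalamic LFP band power: models, assumptions, and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding gripping force from subthalamic LFP band power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stnforce)
```

## The scientific problem

During a cued isometric grip, the local field potential (LFP) recorded from
the subthalamic nucleus (STN) through a quadripolar DBS electrode shows a
stereotyped spectral signature: power in the beta band (13--30 Hz) is
suppressed (event-related desynchronisation, ERD) and power in a broad gamma
band (55--90 Hz) increases (event-related synchronisation, ERS), both scaling
with the effort of the grip. `stnforce` implements a decoding pipeline that
treats these band-power changes as the *control input* to the musculoskeletal
plant and models the generated force as the output of a first-order linear
dynamic system with dead time:

$$\mathrm{Force} = u(t) \ast \frac{K_p}{T_p s + 1} e^{-T_d s},$$

where $K_p$ is the steady-state gain, $T_p$ the time constant (how quickly
force follows the neural drive) and $T_d$ a pure input--output delay. Eight
model structures differ in how the band features enter $u(t)$: the
gamma-minus-beta difference (model 1), a gain-weighted sum of gamma and beta
through a shared lag (model 2), fully separate first-order branches per band
(model 3), the same two structures extended with the theta/alpha band
(models 4 and 5), and single-band models (6: alpha, 7: beta, 8: gamma).
Model comparison uses the Bayesian information criterion,
$\mathrm{BIC} = n\ln\sigma_e^2 + k\ln n$, on held-out predictions.

## Pipeline and parameters that matter

1. **Bipolar derivation.** Neighbouring contacts are subtracted (pairs 01,
   12, 23), cancelling any signal common to all contacts (mains, reference,
   movement artifact). This is exact: common-mode rejection is a structural
   property, tested to floating-point tolerance.
2. **Time--frequency decomposition.** Complex Morlet CWT with 7 cycles on a
   1--90 Hz grid in 1 Hz steps. The temporal s.d. at frequency $f$ is
   $7/(2\pi f)$; trials are epoched with 2 s of padding before the transform
   so wavelet edge effects never enter the decode window.
3. **Baseline normalisation.** Power at each frequency is divided by its
   mean over the second before the cue, minus one: 0 means baseline, $+1$ a
   doubling. Band traces are the simple mean over the band's inclusive
   frequency rows. The decoder works with *fractional* change throughout
   (percent only for display).
4. **Channel selection.** The bipolar pair with the deepest movement-related
   beta suppression over (up to) three maximal-effort trials. For this
   estimator, and for the modulation-significance report, power is averaged
   across trials *before* normalisation: ratios of short-baseline power
   estimates are noisy and biased upward by roughly $2/\mathrm{dof}$, and
   trial-averaging the numerator and denominator first divides that bias by
   the trial count. Per-trial decoding features keep the per-trial
   normalisation.
5. **Significance rule.** A band is significantly modulated when at least
   50% (inclusive) of the samples in the second after movement onset fall
   below the 5th (ERD) or above the 95th (ERS) percentile of the
   trial-averaged baseline samples. Movement onset comes from the force
   channel (first sustained excursion above baseline mean plus
   $\max(5\%\ \mathrm{peak},\,3\,\mathrm{s.d.})$ for $\ge$100 ms), with a
   cue$+0.3$ s fallback.
6. **Decode window and feature rate.** $[-1, 2.8)$ s around the cue (the
   rest, initiation, development and holding phases; force release is out of
   scope), bin-averaged to 100 Hz -- 380 samples per trial. Force is
   normalised so the mean maximal-effort peak is 1.
7. **Fitting.** Bounded least squares with gains in $[-100, 100]$, $T_p \in
   [0.01, 5]$ s, $T_d \in [0, 0.5]$ s (the empirical dead-time range is
   0--277 ms). Because the gains enter linearly, they are profiled out
   exactly (variable projection) and a bounded Levenberg--Marquardt search
   runs over the dynamic parameters only, restarted from a deterministic
   grid of dead times $\{0, 0.1, 0.2, 0.3, 0.4\}$ s $\times$ time constants
   $\{0.1, 0.3\}$ s. Clamping of predictions at zero is applied to final
   predictions only, never inside the objective, which keeps it smooth.
8. **Evaluation.** Effort-split cross-validation (fit on trials with
   self-rated effort $\le 5$, test on $>5$, and vice versa; BIC on the
   concatenated test points of both directions) and seeded k-fold
   cross-validation over individual trials (5 folds; 4 folds for the
   20-trial validation-cohort scheme). Metrics: per-trial Pearson
   correlation (WithinTrialR), RMSE as % of the maximal measured value
   (nRMSE), the across-trial correlation and OLS line of holding-phase
   (1--2 s) means (StableFrcR), and the predicted-minus-measured onset
   difference (DifRT). Correlations are Fisher-z transformed before any
   statistical comparison; undefined metrics are excluded and counted,
   never imputed.

## The synthetic world

Patient recordings are not redistributable, so every stage is exercised
against a generator (`synthetic_config()`, `generate_session()`,
`generate_trials()`) whose defaults state the emulated world:

* cue-paced 3 s grips every 11--13 s, ~30 trials per session, self-rated
  efforts (SRE, 0--10) covering the whole scale with maximal-effort trials
  always present;
* band-power envelopes that are zero through the pre-cue second and rise to
  an effort-scaled plateau: beta $-30\%$, gamma $+30\%$, alpha $+20\%$ at
  maximal effort. Gamma rises fast ($\tau = 80$ ms, latency 100 ms) with a
  brief onset burst indexing vigour; beta suppression develops slowly
  ($\tau = 500$ ms, latency 350 ms); alpha rises slowly with a sharp
  onset-phase emphasis burst (the low-frequency increase is empirically
  strongest around force onset). These distinct temporal signatures are what
  make the contribution of each band identifiable in multi-band models;
* band-specific effort curves by default: beta saturates over the low-effort
  range while gamma tracks effort linearly and alpha saturates gently,
  mirroring the reported band-specific effort coding (beta informative at
  low, gamma at high efforts). A `"linear"` option scales every band by
  $\mathrm{SRE}/10$. With strictly proportional scaling the band mixture is
  identical in every trial and multi-band gains become ill-determined --
  the generator's own parameter-recovery contract (1% noiseless, 10% at 5%
  noise) is unattainable in that world, which is why banded scaling is the
  default;
* force generated by a known model (default: model 2 with
  $K_{p1} = 2$, $K_{p2} = -1$, $T_p = 0.2$ s, $T_d = 0.2$ s), plus Gaussian
  measurement noise (s.d. 5% of the maximal-effort steady force) and
  clamping at zero;
* four monopolar contacts, each a gain-weighted sum of three per-band
  carriers whose *power* tracks $1+\mathrm{envelope}$, over independent
  $1/f$ background noise and a common-mode artifact identical on all
  contacts. The contact-gain profile makes bipolar pair 12 the most
  reactive in expectation.

### What the carriers are, and are not

The carriers are 3-tone combs (90% of carrier power; tones spaced 3, 7 and
14 Hz in the alpha, beta and gamma bands) over a band-limited Gaussian
carpet. This is a deliberate idealisation. The wavelet-scale band power of a
purely stochastic (Gaussian) carrier fades chi-squared-like at the
time--bandwidth limit -- single-trial band traces then fluctuate by 30--70%
of baseline, 1-s baseline ratios are biased upward by up to $+50\%$ at
4--6 Hz, and least-squares fitting on such noisy *inputs* systematically
prefers noise-suppressing dynamics (inflated $T_p$, collapsed $T_d$). The
tone comb keeps each band's in-band power deterministic (tone-beat ripple
sits above the force band, where the plant lag filters it out) while still
exercising multi-row band averaging in the CWT. Setting
`carrier_tone_frac = 0` restores fully Gaussian carriers; with them the
pipeline still *decodes* well (the plant lag smooths feature noise out of
predictions) but end-to-end parameter estimates from CWT features are
biased -- a limitation shared by the method on real data, and consistent
with empirically estimated dead times clustering near zero.

A green test on this world therefore establishes: the algebra and dynamics
of the eight models, the exactness of the discretisation, the estimation
machinery (recovery of generating parameters from the envelope-to-force
path), the calibration of the significance rule, common-mode rejection, and
the plumbing of the full raw-signal pipeline. It does *not* establish
robustness to bursty real-LFP power statistics, movement artifacts beyond
the common-mode term, non-stationary baselines, or electrode-to-electrode
variability in real patients.

## Numerical choices

* **Discretisation.** Each first-order branch uses the causal zero-order
  hold: $y[n] = a\,y[n-1] + (1-a)\,u[n-1]$ with $a = e^{-\Delta t/T_p}$ and
  zero initial state (the window opens at rest). With this convention the
  sampled response to a sample-aligned step equals
  $K_p(1 - e^{-t/T_p})$ *exactly*; placing the input at the interval end
  instead would lead the analytic response by one sample. Dead time is a
  continuous shift with linear interpolation between samples, so $T_d$ is a
  smooth optimisation variable (integer rounding would create objective
  plateaus).
* **Oracle.** An independent dense RK4 integrator of the time-domain form
  $\mathrm{Force}(t) + T_p\,\dot{\mathrm{Force}}(t) = K_p u(t - T_d)$ under
  the same causal-hold input convention; recursion and integrator agree to
  better than $10^{-6}$ of the output range.
* **Optimiser.** Variable projection (exact linear solve for gains at fixed
  dynamics) removes the near-flat gain/dynamics valleys of the raw
  parameterisation; a raw 9-parameter search on model 5 is both an order of
  magnitude slower and systematically trapped at interior local optima.
  Multi-starts are deterministic; no randomness enters fitting.
* **Ties and degenerate input.** Channel-selection ties go to the lowest
  pair index; the significance rule is inclusive at exactly 50%; zero-variance
  traces yield `NA` metrics (excluded and counted); all-zero features are an
  identifiability error; a zero baseline power is a hard error rather than
  an Inf.
* **nRMSE normaliser.** The maximal measured value within the evaluated
  trial; effort-split directions are evaluated per direction and BIC on the
  concatenated residuals of both.

## Known limitations

* Per-trial baseline normalisation at low frequencies (alpha band) is noisy
  and positively biased with a 1-s baseline; this is inherent to 7-cycle
  wavelets and short baselines, and is why the alpha features carry the
  least reliable single-trial information.
* End-to-end dead-time estimates from CWT features are biased low (see the
  carrier discussion); parameter-recovery guarantees apply to the
  envelope-to-force path.
* Channel selection from three maximal-effort trials is noisy by
  construction in a realistic world; the default world makes every pair
  decode-capable so a borderline selection does not break decoding.
* No EMG, no force-release phase, no biophysical field modelling, no
  artifact pathology beyond the common-mode term; group-level inference is
  left to standard statistical routines on the tidy per-trial tables the
  package emits.
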