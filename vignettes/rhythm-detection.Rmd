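---
title: "Detecting ultradian and infradian rhythms in capacitation indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ultradian and infradian rhythms in capacitation indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caprhythm)
```

## The problem

Sperm capacitation has no direct readout, so its dynamics are studied
through net indicator percentages: the induced acrosome reaction (%ARi)
and chemotactic recruitment (%Chex). Both rise along a 24-h capacitating
incubation with superimposed fluctuations, and both vary across the year
when sampled monthly. `caprhythm` formalizes two questions:

1. **Ultradian:** are the hourly fluctuations a rhythm (a cycle of a few
   hours) or a short-range stochastic process?
2. **Infradian:** do the monthly series carry a 6- or 12-month seasonal
   component, and how is it phased relative to photoperiod and
   temperature?

Two complementary detectors answer them: an autocorrelation classification
(timing-domain, integer-lag resolution) and a continuous wavelet transform
(time–period localization), combined by `analyze_rhythm()` into a single
verdict with an explicit consistency check.

## Data model and assumptions

All analyses act on `cap_ts` objects: uniformly sampled, gap-free numeric
series with an explicit unit (hours or months). Irregular sampling and
missing values are hard errors, never imputed — the estimators below assume
a regular grid, and the intended designs (one sample per hour, one per
month) have no structural gaps. Replicates sharing a time axis are bundled
in a `cap_panel`, whose mean series is what the rhythm analyses consume.

Monthly series use a month *index* 1–36 (month 1 = mid-January of the first
year); each index represents a mid-month sample, which is also the day used
when evaluating photoperiod.

## Autocorrelation analysis

`cap_acf()` computes the biased sample autocorrelation with the global
mean,

$$C(s) = \frac{\sum_{t=1}^{n-s}(x_t-\bar x)(x_{t+s}-\bar x)}
              {\sum_{t=1}^{n}(x_t-\bar x)^2},$$

which guarantees $C(0)=1$ and $|C(s)|\le 1$. Indicators trend upward along
incubation, so a least-squares line is removed first by default
(`detrend = TRUE`); the ACF then reflects the fluctuations around the
trend. Tunables, with defaults:

* `max_lag` — `floor(n/2)` (12 lags for a 24-h hourly design, 18 for 36
  monthly points). The estimator is increasingly biased and noisy beyond
  half the series.
* `band_multiplier` — 2, giving the large-sample white-noise band
  $\pm 2/\sqrt n$. Under white noise, individual coefficients exceed it
  with probability ≈ 5 %.

The classification operationalizes the visual criteria used in
chronobiology:

* **periodic** — some lag has $C$ below $-$band and a *later* local
  maximum rises above $+$band (negative values followed by positive ones:
  sign alternation);
* **short_range_stochastic** — the curve decays into the band without such
  an alternation, the signature of a linear stochastic process with
  short-range correlations (e.g. AR(1));
* **unclassified** — anything else (typically a residual trend keeping all
  coefficients high), reported rather than forced into a class.

The estimated period is the lag of the first local maximum above the band,
converted to time units. Resolution is deliberately one sampling interval
— no sub-lag interpolation — because the designs report integer periods
(2 h, 6 months, 12 months). Plateaus take their left edge; the smallest
qualifying lag wins.

With fewer than 4 lags the shape cannot be judged and the classification
is `"unclassified"`. A zero-variance series (or an exact line, which is
constant after detrending) is a degenerate-series error.

## Continuous wavelet transform

`cwt_transform()` computes

$$W(a,b) = a^{-1/2}\sum_k x_k\,\psi^*\!\left(\frac{k-b}{a}\right)\Delta t$$

by direct summation of the sampled mother wavelet over the full series
(implicit zero padding). Two mother wavelets are provided:

* **cmor1-1.5** (default): $\psi(t) = (\pi f_b)^{-1/2} e^{2\pi i f_c t}
  e^{-t^2/f_b}$ with bandwidth $f_b = 1$ and center frequency $f_c = 1.5$.
  This is the `cmor` convention of the common wavelet toolboxes; note its
  squared norm is $(2\pi f_b)^{-1/2}$, not 1 — results are reported as
  coefficients of this conventional kernel, so they are directly
  comparable with those toolboxes.
* **cgau1**: the L2-normalized first derivative of $e^{-it}e^{-t^2}$,
  $\psi(t) = (2\pi)^{-1/4}(-i-2t)e^{-it-t^2}$. Its center frequency is an
  intrinsic constant — the peak of $|\hat\psi(f)| \propto |f|
  e^{-\pi^2(f+1/2\pi)^2}$, which is exactly $1/\pi$ — verified in the test
  suite against an FFT-grid oracle and frozen in the package.

Scales are dimensionless multiples of the sampling interval and convert to
periods by the pseudo-frequency rule $\text{period} = a\,\Delta t/f_c$;
for cmor1-1.5 on monthly data, scales 0.3–30 correspond to periods 0.2–20
months. The default grid is 60 logarithmically spaced scales over
[0.3, 30], giving a uniform relative period resolution of about 8 % per
step.

### Numerical choices

* **Edge handling.** Coefficients within the e-folding distance of the
  wavelet's power envelope from either end, $a\sqrt{f_b/2}$ samples, are
  flagged in a cone-of-influence mask. (The envelope $e^{-t^2/f_b}$ gives
  $|\psi|^2 \propto e^{-2t^2/f_b}$, which has decayed by $1/e$ at
  $t = a\sqrt{f_b/2}$.) On a 36-point monthly series this leaves the
  central ten positions usable at the 12-month scale — a wider cone would
  disqualify the very scale the circannual analysis targets, while leaving
  edge positions unmasked lets boundary artifacts dominate.
* **Dominant period.** `dominant_period()` maximizes the time-averaged
  power outside the cone, *rectified* by dividing by the scale
  ($\langle|W|^2\rangle/a$). Raw wavelet power grows linearly with scale
  for oscillations of equal amplitude, biasing the argmax toward long
  periods; rectification removes that bias so a pure sinusoid's argmax
  sits at its true period up to grid resolution.
* **Nyquist guard.** Periods below two sampling intervals are excluded
  from the dominant-period search. At sub-sample scales the point-sampled
  wavelet degenerates toward a delta function and its response aliases
  (it simply copies the series scaled by $a^{-1/2}$); such scales are
  computed — the transform is defined on the full grid for scalogram
  display — but never reported as a dominant period. For the same reason
  the zero-mean (admissibility) property of the wavelet holds numerically
  only at adequately resolved scales: a constant series produces
  negligible coefficients at moderate scales deep in the interior, but
  not at sub-sample scales.
* **Determinism.** The transform, the dominant period and the verdict are
  pure functions of their inputs; rerunning an analysis is bit-identical.

## Wavelet synchrony

`offset_scan_synchrony()` extracts $\mathrm{Re}(W)$ of both series at the
grid scale nearest a target period and scans the Spearman rank correlation
(average ranks on ties) over integer offsets $d \in [-d_{max}, d_{max}]$,
pairing $a(t)$ with $b(t+d)$ over the shrinking overlap (no wraparound;
$d_{max} \le n/3$, default 4). It reports $\rho^2$ per offset — the
familiar $R^2$-versus-offset curve — plus the signed $\rho$, and a best
offset; positive means the first series leads.

Two design choices matter here:

* **In-phase restriction.** $\rho^2$ is sign-blind: for near-sinusoidal
  rhythms of period $P$, a lead of $d$ and an anti-phase lag of $d - P/2$
  produce equal $\rho^2$, and either can win the argmax on short series.
  The best offset is therefore chosen among in-phase alignments
  ($\rho > 0$), falling back to the global maximum only if no offset
  correlates positively. Ties break toward the smallest $|d|$.
* **No cone masking by default.** At the 12-month scale of a 36-point
  series, masking leaves at most ten usable positions; rank correlations
  on so few points are brittle (near-ties flip the argmax), and the
  overlap bookkeeping $n_{overlap} = n - |d|$ holds exactly only without
  masking. `mask_cone = TRUE` is available for longer series where the
  cone is a small fraction of the span.

Fewer than five overlapping points at any scanned offset is an error.

## The rhythm pipeline

`analyze_rhythm()` chains detrend → ACF → classification, and for
infradian series adds the cmor1-1.5 transform and its dominant period as a
cross-check. The verdict is *rhythmic* only when the ACF is periodic and,
if the wavelet ran, both period estimates agree within `agreement_tol`
(default 25 % relative — about three grid steps of the default scale grid,
and narrower than the 6-versus-12-month distinction it must preserve). The
reported period is the ACF one (integer sampling intervals, matching how
the designs report periods); disagreement produces an *aperiodic* verdict
with an explicit note, never a silent choice of one detector. All
thresholds live in `rhythm_config()`, which can be loaded from a YAML or
JSON file.

`peak_valley_compare()` smooths the series with a centered moving average
of half the detected period (rounded, forced odd), finds strict local
extrema, and compares original values at peaks versus valleys with a
two-sided Welch t-test (unequal variances; the groups are small and their
spreads need not match). Near the series ends the smoothing window is
filled by periodic extension at the detected period: for a genuine rhythm
of that period the extension is exact, whereas truncated or reflected
windows distort the smoothed curve enough to create or destroy extrema in
the first and last half-window. Endpoints never count as extrema; if both
groups have zero variance (e.g. an exactly alternating series) the t-test
is undefined and the p-value is `NA`.

## Synthetic data: what it emulates, and what it does not

`synthetic_config()` fixes the generative models; the seed fully
determines every generated value, and the caller's RNG state is left
untouched.

**Hourly presets** (24 points, t = 0–23 h, 8 replicates): a saturating
trend $T_{max}\,t/(t+\tau)$ ($\tau$ = 4 h) emulating the plateauing rise of
capacitation, plus, for `chex_hourly`, a 2-h sinusoidal oscillation
(amplitude 4 %, phase 0.5 h so that hourly sampling catches the
oscillation at full swing rather than at its zero crossings) with iid
Gaussian replicate noise (sd 1.5 % absolute); `ari_hourly` instead has no
oscillation and AR(1) replicate noise (coefficient 0.5, marginal sd
1.5 %), the short-range stochastic alternative. Values are clipped to
[0, 100] after noise.

**Monthly panel** (36 points): the ARi-like series is a 12-month cosine
with mean 29 % and amplitude 17 %, peaking at month 10 (mid-October, i.e.
austral spring), so its noise-free peak and valley values are exactly 46 %
and 12 %; the Chex-like series is a 6-month cosine (mean 8.5 %, amplitude
3.5 %, peaks mid-March and mid-September: autumn and spring; an optional
12-month admixture exists behind `chex_amp_12`) with noise-free extremes
12 % and 5 %. Monthly noise defaults (sd 4 % for ARi, 1.5 % for Chex) are
calibration choices putting the peak/valley standard errors in the few-
percent range. Temperature is a 12-month cosine (mean 17.5 °C, amplitude
7 °C, peak mid-January) with 1 °C weather noise; photoperiod is the
astronomical day length at 31.82°S evaluated on the 15th of each month —
deterministic, from the declination model
$\delta = -23.44°\cos(2\pi(d+10)/365.25)$ and
$DL = (24/\pi)\arccos(-\tan\phi\tan\delta)$ (no polar handling; the model
is cross-checked in the tests against an independent astronomical
formula).

The phasing encodes the studied seasonality: the ARi annual rhythm peaks
about two months before the photoperiod maximum (December solstice) and
about three before the temperature maximum, so the synchrony scan should
report the indicator leading by a small positive offset.

What the generators do **not** emulate: donor-to-donor variance components
(replicate noise is single-level iid), non-sinusoidal seasonal shapes,
missing months, measurement floor/ceiling effects beyond hard clipping,
and any mechanistic link between weather and physiology. Passing the
recovery tests therefore shows that the detectors recover the rhythms they
were designed for under realistic noise — it does not certify performance
on real donor data with richer error structure.

## Validation strategy and problem sizes

The test suite checks every estimator against an independent brute-force
oracle (double-loop ACF, direct-sum CWT, quadrature wavelet norms,
normal-equation line fits) on batches of 50–100 random series of length up
to 48–50, and exercises the full parameter-recovery surface: the 2-h
ultradian period, the 12- and 6-month dominant wavelet periods and the
short-range-stochastic contrast each across 100 seeds (with ≥ 90 %
required recovery), white-noise specificity across 200 seeds, and the
peak/valley contrast's significance across 200 seeds (≥ 95 % at
p < 0.05). These sizes match the designs the package targets (24 hourly,
36 monthly points) while keeping the default test run fast.

## Known limitations

* Period resolution is one sampling interval (ACF) or one grid step
  (wavelet); no sub-resolution interpolation is attempted.
* The ACF classification is a binary band rule; it does not estimate how
  *strongly* periodic a series is, and near-threshold curves can flip
  class under resampling.
* The wavelet analysis has no significance test against red-noise nulls;
  the dominant period is descriptive.
* Synchrony offsets are whole sampling intervals, and the $R^2$ curve
  inherits the half-period sign ambiguity discussed above.
* A 36-point series supports at most ~1.5 observed cycles at the
  20-month end of the period range; periods beyond ~16 months are fully
  edge-contaminated and never reported as dominant.
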