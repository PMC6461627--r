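# caprhythm

Dual-timescale rhythm detection for sperm capacitation time series.

Human sperm capacitation — the maturation step that makes a spermatozoon
able to fertilize — has no direct marker, so it is tracked through proxy
indicators: the net induced acrosome reaction (%ARi, induced minus
spontaneous reactors) and net chemotactic recruitment (%Chex, recovered
with minus without a progesterone gradient). Along a 24-h capacitating
incubation these indicators rise with fluctuations; across years of monthly
sampling they wax and wane with the seasons. `caprhythm` asks, and answers
quantitatively, whether such fluctuations are rhythms: an ultradian cycle
of a few hours, or an infradian (circannual) cycle of 6–12 months locked to
photoperiod and temperature.

The package is aimed at reproductive biologists and chronobiologists with
uniformly sampled indicator series (hourly or monthly), and at
methodologists who want a compact, fully tested reference implementation of
the analysis chain.

## Methods at a glance

* **Autocorrelation analysis.** The biased sample ACF with global mean,
  `C(s) = Σ_{t≤n−s}(x_t − x̄)(x_{t+s} − x̄) / Σ_t (x_t − x̄)²`, computed after
  optional linear detrending. A curve whose coefficients fall below the
  white-noise band `−2/√n` and later rise above `+2/√n` at a local maximum
  is classified *periodic* (period = lag of the first significant peak); a
  curve decaying into the band without sign alternation is a *short-range
  stochastic* process.
* **Continuous wavelet transform.** `W(a,b) = a^{−1/2} Σ_k x_k ψ*((k−b)/a) Δt`
  with the complex Morlet `cmor1-1.5`, `ψ(t) = (π f_b)^{−1/2} e^{2πi f_c t}
  e^{−t²/f_b}` (`f_b = 1`, `f_c = 1.5`), or the complex Gaussian `cgau1`.
  Scales convert to periods by `period = a·Δt/f_c` (so scales 0.3–30 on
  monthly data span periods 0.2–20 months). The dominant period maximizes
  the scale-rectified, cone-of-influence-masked mean power `⟨|W|²⟩/a`.
* **Wavelet synchrony.** Spearman correlation between `Re(W)` of two series
  at a fixed scale, scanned over integer offsets; the squared correlation
  per offset and the best in-phase offset quantify who leads whom (e.g. the
  %ARi annual rhythm versus photoperiod).
* **Peak-versus-valley contrast.** Strict local extrema of the
  half-period-smoothed series, compared by a two-sided Welch t-test.
* **Synthetic generators.** Seeded hourly (saturating trend + 2-h
  oscillation + replicate noise) and 36-month seasonal panels (12-month
  ARi-like and 6-month Chex-like components, astronomical photoperiod at
  31.82°S, sinusoidal temperature) reproduce the statistical structure the
  analysis assumes, so the whole chain is verifiable end to end.

## Worked example

```r
library(caprhythm)

cfg    <- synthetic_config(seed = 42)
panel  <- simulate_hourly_capacitation(cfg, "chex_hourly")
report <- analyze_rhythm(panel$mean_series, "ultradian")
report
#> <rhythm_report> 'mean', ultradian analysis
#>   ACF: periodic (period 2 hours)
#>   verdict: rhythmic with period 2 hours

monthly <- simulate_monthly_panel(cfg)
round(dominant_period(cwt_transform(monthly$ari)), 2)
#> [1] 11.58

sync <- offset_scan_synchrony(monthly$ari, monthly$photoperiod, period = 12)
sync
#> <cap_synchrony> period 11.6 months, offsets -4..4: best offset 2 (first series leads), R^2 = 0.759

peak_valley_compare(monthly$ari, 12)
#> <peak_valley> 3 peaks 42.7 +/- 2 vs 3 valleys 11.3 +/- 3.2 (Welch p = 0.00231)
```

Reading: the hourly chemotaxis indicator carries a significant 2-h
ultradian cycle on top of its saturating rise; the monthly ARi-like series
is dominated by a circannual (~12-month) component whose annual rhythm
peaks about two months before photoperiod; and indicator levels in peak
months significantly exceed valley months.

A command-line interface wrapping the same functions is installed at
`inst/cli/caprhythm` (subcommands `simulate`, `acf`, `cwt`, `synchrony`,
`analyze`, `fixtures`).

## Documentation

The methods vignette (`vignettes/rhythm-detection.Rmd`) describes the
models, the detection rules and their thresholds, the numerical choices in
the wavelet discretization, what the synthetic generators do and do not
emulate, and known limitations.
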