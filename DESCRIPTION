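Package: caprhythm
Title: Dual-Timescale Rhythm Detection for Sperm Capacitation Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects ultradian and infradian (circannual) rhythms in time
    series of sperm capacitation indicators such as the net induced acrosome
    reaction (%ARi) and net chemotactic recruitment (%Chex). Provides a
    normalized autocorrelation analysis with a periodic versus short-range
    stochastic classification, a continuous wavelet transform with complex
    Morlet and complex Gaussian mother wavelets including scale-to-period
    conversion and cone-of-influence masking, lagged Spearman synchrony
    between wavelet coefficients of an indicator and meteorological drivers
    (photoperiod, temperature), a peak-versus-valley comparison, and seeded
    synthetic-data generators that emulate hourly capacitation kinetics and
    multi-year monthly seasonal panels so that the whole analysis chain can
    be exercised and validated without access to donor data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr
Config/testthat/edition: 3
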