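test_that("mother wavelets take their defining values", {
  cmor <- wavelet_spec()
  expect_equal(wavelet_eval(cmor, 0), complex(real = 1 / sqrt(pi)),
               tolerance = 1e-12)
  # envelope symmetry
  t <- seq(0.1, 3, by = 0.3)
  expect_equal(Mod(wavelet_eval(cmor, t)), Mod(wavelet_eval(cmor, -t)),
               tolerance = 1e-12)
  # the cmor family convention carries squared norm (2*pi*fb)^(-1/2)
  expect_equal(oracle_wavelet_norm2(cmor), 1 / sqrt(2 * pi), tolerance = 1e-6)

  cgau <- wavelet_spec("cgau", order = 1)
  expect_equal(oracle_wavelet_norm2(cgau), 1, tolerance = 1e-6)

  expect_error(wavelet_spec("cmor", bandwidth = 0), "positive")
  expect_error(wavelet_spec("cgau", order = 2), "order 1")
})

test_that("cgau1 center frequency equals the Fourier magnitude peak", {
  # FFT-grid oracle: evaluate psi on a fine grid, locate argmax of |fft|
  lim <- 16; n <- 2^15
  t <- seq(-lim, lim, length.out = n + 1)[-(n + 1)]
  dt <- t[2] - t[1]
  y <- wavelet_eval(wavelet_spec("cgau"), t)
  sp <- Mod(stats::fft(y))
  freqs <- seq(0, n - 1) / (n * dt)
  freqs[freqs >= 1 / (2 * dt)] <- freqs[freqs >= 1 / (2 * dt)] - 1 / dt
  f_peak <- abs(freqs[which.max(sp)])
  expect_equal(wavelet_spec("cgau")$center_frequency, 1 / pi, tolerance = 1e-12)
  expect_lt(abs(f_peak - 1 / pi), 2 / (n * dt))
})

test_that("scale/period conversion reproduces the published endpoints exactly", {
  spec <- wavelet_spec()   # cmor1-1.5
  expect_equal(scale_to_period(30, spec, 1), 20, tolerance = 1e-12)
  expect_equal(scale_to_period(0.3, spec, 1), 0.2, tolerance = 1e-12)
  # identity case: scale equal to fc, unit sampling
  expect_equal(scale_to_period(1.5, spec, 1), 1, tolerance = 1e-12)
  # round trip and monotonicity
  a <- default_scale_grid()
  expect_equal(period_to_scale(scale_to_period(a, spec, 1), spec, 1), a,
               tolerance = 1e-12)
  expect_true(all(diff(scale_to_period(a, spec, 1)) > 0))
  expect_error(scale_to_period(-1, spec), "positive")
  expect_error(period_to_scale(0, spec), "positive")
})

test_that("CWT is linear, null on zero input and exact on an impulse", {
  n <- 24
  scales <- c(1, 2, 4, 8)
  spec <- wavelet_spec()
  zero <- cap_ts(seq_len(n), rep(0, n))
  expect_true(all(Mod(cwt_transform(zero, scales, spec)$coefficients) == 0))

  # impulse at position k: the double sum collapses to a single term
  k <- 10
  x <- rep(0, n); x[k] <- 1
  W <- cwt_transform(cap_ts(seq_len(n), x), scales, spec)$coefficients
  for (i in seq_along(scales)) {
    b <- seq_len(n)
    want <- Conj(wavelet_eval(spec, (k - b) / scales[i])) / sqrt(scales[i])
    expect_equal(W[i, ], want, tolerance = 1e-12)
  }

  # linearity
  set.seed(31)
  x1 <- rnorm(n); x2 <- rnorm(n)
  Wa <- cwt_transform(cap_ts(seq_len(n), x1), scales, spec)$coefficients
  Wb <- cwt_transform(cap_ts(seq_len(n), x2), scales, spec)$coefficients
  Wab <- cwt_transform(cap_ts(seq_len(n), 2 * x1 - 3 * x2), scales,
                       spec)$coefficients
  expect_equal(Wab, 2 * Wa - 3 * Wb, tolerance = 1e-9)

  expect_error(cwt_transform(zero, numeric(0)), "empty")
  expect_error(cwt_transform(zero, c(2, 1)), "ascending")
})

test_that("CWT matches the brute-force direct-sum oracle to 1e-10", {
  set.seed(77)
  scales <- c(0.7, 1.3, 3, 6.5, 12)
  for (spec in list(wavelet_spec(), wavelet_spec("cgau"))) {
    for (i in 1:50) {
      n <- sample(8:48, 1)
      x <- rnorm(n)
      got <- cwt_transform(cap_ts(seq_len(n), x), scales, spec)$coefficients
      expect_equal(got, oracle_cwt(x, scales, spec), tolerance = 1e-10)
    }
  }
})

test_that("a constant series produces no response where the wavelet is resolved", {
  # the zero-mean property holds where the sampled wavelet is both well
  # resolved (scale above ~2 samples) and untruncated (deep interior); at
  # sub-sample scales the point-sampled wavelet degenerates and responds.
  n <- 36
  cw <- cwt_transform(cap_ts(1:n, rep(5, n), unit = "months"),
                      scales = c(0.3, 4), spec = wavelet_spec())
  center <- ceiling(n / 2)
  expect_lt(Mod(cw$coefficients[2, center]), 1e-6)
  expect_gt(Mod(cw$coefficients[1, center]), 1)   # degenerate small scale
})

test_that("periods increase with scale and the cone widens", {
  cw <- cwt_transform(cap_ts(1:36, cos(2 * pi * (1:36) / 12), unit = "months"))
  expect_true(all(diff(cw$periods) > 0))
  expect_equal(dim(cw$coefficients), c(60, 36))
  expect_true(all(is.finite(Re(cw$coefficients))))
  # cone coverage is monotone in scale
  cone_frac <- rowMeans(cw$cone_of_influence)
  expect_true(all(diff(cone_frac) >= 0))
  expect_equal(cone_frac[60], 1)   # scale 30 fully edge-contaminated
})

test_that("dominant period recovers pure and mixed sinusoids within a grid step", {
  m <- 1:36
  step <- exp(log(100) / 59)   # default grid ratio
  for (P in c(6, 9, 12)) {
    cw <- cwt_transform(cap_ts(m, cos(2 * pi * m / P), unit = "months"))
    expect_lt(abs(log(dominant_period(cw) / P)), log(step) + 1e-9)
  }
  # 6-month component 3x larger than the 12-month one wins
  mix <- cap_ts(m, cos(2 * pi * m / 12) + 3 * cos(2 * pi * m / 6),
                unit = "months")
  expect_lt(abs(log(dominant_period(cwt_transform(mix)) / 6)),
            log(step) + 1e-9)
})

test_that("scale covariance: stretching the period moves the argmax accordingly", {
  m <- 1:36
  step <- exp(log(100) / 59)
  p1 <- dominant_period(cwt_transform(cap_ts(m, cos(2 * pi * m / 6))))
  p2 <- dominant_period(cwt_transform(cap_ts(m, cos(2 * pi * m / 9))))
  expect_lt(abs(log((p2 / p1) / 1.5)), 2 * log(step) + 1e-9)
})

test_that("real part at a scale tracks the oscillation on the original axis", {
  m <- 1:36
  P <- 12
  ts <- cap_ts(m, cos(2 * pi * m / P), unit = "months")
  cw <- cwt_transform(ts)
  r <- real_part_at_scale(cw, P)
  expect_s3_class(r, "cap_ts")
  expect_equal(length(r), length(ts))
  expect_equal(r$times, ts$times)
  # zero crossings spaced about half a period apart
  sgn <- sign(r$values)
  crossings <- which(diff(sgn) != 0)
  expect_true(all(abs(diff(crossings) - P / 2) <= 1))

  zr <- real_part_at_scale(cwt_transform(cap_ts(m, rep(0, 36))), P)
  expect_true(all(zr$values == 0))
  expect_error(real_part_at_scale(cw, 100), "outside")
})

test_that("CWT serializes to long CSV", {
  cw <- cwt_transform(cap_ts(1:12, rnorm(12)), scales = c(2, 4))
  f <- tempfile(fileext = ".csv")
  write_cwt(cw, f)
  tab <- read.csv(f)
  expect_equal(nrow(tab), 2 * 12)
  expect_named(tab, c("scale", "period", "time", "re", "im", "in_cone"))
})
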