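test_that("configuration validates fields and rejects unknown keys", {
  cfg <- synthetic_config(seed = 7, monthly = list(noise_sd_ari = 0))
  expect_equal(cfg$monthly$noise_sd_ari, 0)
  expect_equal(cfg$monthly$ari_mean, 29)       # untouched default
  expect_error(synthetic_config(hourly = list(bogus = 1)), "unknown hourly")
  expect_error(synthetic_config(hourly = list(osc_amplitude = -2)),
               "non-negative")
  expect_error(synthetic_config(hourly = list(ar1_coeff = 1.2)), "ar1_coeff")
  expect_error(synthetic_config(n_replicates = 0), "replicate")
})

test_that("noise-free, oscillation-free hourly series equal the saturating trend", {
  cfg <- synthetic_config(seed = 1, n_replicates = 2,
                          hourly = list(noise_sd = 0, osc_amplitude = 0))
  pan <- simulate_hourly_capacitation(cfg, "chex_hourly")
  t <- 0:23
  trend <- 12 * t / (t + 4)
  for (r in pan$replicates) expect_equal(r$values, trend, tolerance = 1e-12)
})

test_that("generation is fully determined by the seed", {
  p1 <- simulate_hourly_capacitation(synthetic_config(seed = 5), "chex_hourly")
  p2 <- simulate_hourly_capacitation(synthetic_config(seed = 5), "chex_hourly")
  expect_identical(p1$mean_series$values, p2$mean_series$values)
  p3 <- simulate_hourly_capacitation(synthetic_config(seed = 6), "chex_hourly")
  expect_false(identical(p1$mean_series$values, p3$mean_series$values))

  m1 <- simulate_monthly_panel(synthetic_config(seed = 5))
  m2 <- simulate_monthly_panel(synthetic_config(seed = 5))
  expect_identical(m1$ari$values, m2$ari$values)

  n1 <- simulate_null_series(24, "ar1", seed = 3)
  n2 <- simulate_null_series(24, "ar1", seed = 3)
  expect_identical(n1$values, n2$values)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  a <- rnorm(1)
  set.seed(123)
  invisible(simulate_monthly_panel(synthetic_config(seed = 99)))
  b <- rnorm(1)
  expect_identical(a, b)
})

test_that("replicate means converge to trend plus oscillation", {
  cfg <- synthetic_config(seed = 2, n_replicates = 500)
  pan <- simulate_hourly_capacitation(cfg, "chex_hourly")
  h <- cfg$hourly
  t <- 0:23
  expected <- h$trend_max * t / (t + h$trend_halftime) +
    h$osc_amplitude * sin(2 * pi * (t - h$osc_phase) / h$osc_period_h)
  # check only points at least 3 noise sd above the clipping floor, where
  # the [0, 100] clipping leaves the mean essentially unbiased
  keep <- expected > 3 * h$noise_sd
  dev <- abs(pan$mean_series$values - expected)
  expect_true(all(dev[keep] < 3 * pan$sem_series$values[keep] + 0.05))
})

test_that("the noise-free monthly panel hits the anchored peak and valley levels", {
  cfg <- synthetic_config(seed = 1,
                          monthly = list(noise_sd_ari = 0, noise_sd_chex = 0))
  mp <- simulate_monthly_panel(cfg)
  expect_equal(max(mp$ari$values), 46)
  expect_equal(min(mp$ari$values), 12)
  expect_equal(max(mp$chex$values), 12)
  expect_equal(min(mp$chex$values), 5)
  # ARi peaks every October sample, valleys every April
  expect_equal(which(mp$ari$values == 46), c(10, 22, 34))
  expect_equal(which(mp$ari$values == 12), c(4, 16, 28))
})

test_that("photoperiod peaks in December and bottoms in June at the study latitude", {
  mp <- simulate_monthly_panel(synthetic_config(seed = 1))
  ph <- mp$photoperiod$values
  expect_equal(sort(order(ph, decreasing = TRUE)[1:3]), c(12, 24, 36))
  expect_equal(sort(order(ph)[1:3]), c(6, 18, 30))
  expect_true(all(ph > 0 & ph < 24))
  # photoperiod is deterministic astronomy: identical across years
  expect_equal(ph[1:12], ph[13:24], tolerance = 1e-12)
})

test_that("generated percentage series always stay inside [0, 100]", {
  for (s in 1:20) {
    cfg <- synthetic_config(seed = s,
                            hourly = list(noise_sd = 30),
                            monthly = list(noise_sd_ari = 60))
    pan <- simulate_hourly_capacitation(cfg, "chex_hourly")
    for (r in pan$replicates) {
      expect_true(all(r$values >= 0 & r$values <= 100))
    }
    mp <- simulate_monthly_panel(cfg)
    expect_true(all(mp$ari$values >= 0 & mp$ari$values <= 100))
    expect_true(all(mp$chex$values >= 0 & mp$chex$values <= 100))
  }
})

test_that("day length follows solar geometry", {
  # equator: about 12 h all year
  doys <- c(1, 80, 172, 266, 355)
  expect_true(all(abs(day_length(0, doys) - 12) < 0.1))
  # equinoxes: about 12 h at any supported latitude
  for (lat in c(-60, -31.82, 10, 45)) {
    expect_lt(abs(day_length(lat, 80) - 12), 0.2)
  }
  # southern-hemisphere December solstice is the long day
  dec <- day_length(-31.82, 355)
  jun <- day_length(-31.82, 172)
  expect_gt(dec, jun)
  # frozen regression values from the declination formula itself
  expect_equal(dec, 14.081, tolerance = 0.001)
  expect_equal(jun, 9.919, tolerance = 0.001)
  expect_error(day_length(70, 100), "polar")
  expect_error(day_length(0, 0), "1..365")
})

test_that("day length agrees with an independent astronomical model", {
  # geosphere::daylength implements Forsythe et al.'s model; the two should
  # agree to within the models' approximation error
  for (lat in c(-45, -31.82, 0, 30)) {
    for (doy in c(15, 105, 196, 288, 355)) {
      expect_lt(abs(day_length(lat, doy) - geosphere::daylength(lat, doy)),
                0.25)
    }
  }
})

test_that("null generators have the advertised second-order structure", {
  z <- simulate_null_series(50, "white", sd = 0, seed = 1)
  expect_true(all(z$values == 0))

  x <- simulate_null_series(10000, "ar1", ar1_coeff = 0.5, seed = 4)
  r1 <- cap_acf(x, max_lag = 2, detrend = FALSE)$coefficients[2]
  expect_lt(abs(r1 - 0.5), 0.03)
  # marginal sd close to the requested one
  expect_lt(abs(sd(x$values) - 1), 0.05)

  expect_error(simulate_null_series(4, "white"), "n >= 8")
  expect_error(simulate_null_series(20, "ar1", ar1_coeff = 1), "stationarity")
})

test_that("the fixtures command writes the full canonical dataset", {
  d <- file.path(tempdir(), "fixdir")
  files <- write_fixtures(d, seed = 3)
  expect_length(files, 6)
  expect_true(all(file.exists(files)))
  back <- read_series_csv(file.path(d, "monthly_ari.csv"), unit = "months")
  mp <- simulate_monthly_panel(synthetic_config(seed = 3))
  expect_equal(back$values, mp$ari$values, tolerance = 1e-7)
  unlink(d, recursive = TRUE)
})
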