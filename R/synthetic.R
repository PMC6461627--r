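# Seeded synthetic-data generators emulating the study designs the analysis
# expects: 24-h hourly capacitation time courses with replicate noise, and
# 36-month seasonal panels of two capacitation indicators plus photoperiod
# and mean temperature at a mid-latitude southern-hemisphere site.

# Run code with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic-data configuration
#'
#' Full parameterization of the hourly and monthly generative models. The
#' defaults are the package's canonical study conditions: a 24-h hourly
#' design with a saturating capacitation trend, a 2-h oscillation for the
#' chemotaxis indicator and replicate noise of 1.5 % absolute; and a 36-month
#' panel in which the ARi-like indicator carries a 12-month component peaking
#' mid-October with noise-free peak/valley values of 46 %/12 %, the Chex-like
#' indicator a 6-month component peaking mid-March and mid-September with
#' peak/valley 12 %/5 %, temperature a 12-month sinusoid peaking mid-January
#' and photoperiod the astronomical day length at 31.82 degrees South.
#'
#' @param seed Integer seed; fully determines generator output.
#' @param n_replicates Replicates per hourly panel (default 8 donors).
#' @param hourly,monthly,site Named lists overriding individual defaults
#'   (partial lists are merged into the defaults).
#' @return An object of class `synthetic_config`.
#' @examples
#' cfg <- synthetic_config(seed = 42, monthly = list(noise_sd_ari = 0))
#' @export
synthetic_config <- function(seed = 1, n_replicates = 8,
                             hourly = list(), monthly = list(), site = list()) {
  h_def <- list(
    n_hours = 24,          # hourly samples over one incubation day (t = 0..23 h)
    trend_max = 12,        # asymptote of the saturating rise (chex preset), %
    ari_trend_max = 35,    # asymptote for the ari preset (rises higher), %
    trend_halftime = 4,    # half-saturation time, h
    osc_amplitude = 4,     # ultradian oscillation amplitude, %
    osc_period_h = 2,      # ultradian period, h
    osc_phase = 0.5,       # oscillation time offset, h
    noise_sd = 1.5,        # replicate noise sd, % absolute
    ar1_coeff = 0.5        # AR(1) coefficient for the ari preset noise
  )
  m_def <- list(
    n_months = 36,         # three consecutive years, sampled mid-month
    ari_mean = 29,         # ARi annual mean, %  (peak 46, valley 12)
    ari_amp_12 = 17,       # ARi 12-month amplitude, %
    ari_peak_month = 10,   # ARi peak month index (10 = mid-October)
    chex_mean = 8.5,       # Chex semiannual mean, %  (peak 12, valley 5)
    chex_amp_6 = 3.5,      # Chex 6-month amplitude, %
    chex_peak_month = 3,   # first Chex peak month (3 = mid-March; next mid-Sep)
    chex_amp_12 = 0,       # optional 12-month admixture for Chex
    noise_sd_ari = 4,      # monthly noise sd for ARi, %
    noise_sd_chex = 1.5    # monthly noise sd for Chex, %
  )
  s_def <- list(
    latitude_deg = -31.82, # study site latitude (southern hemisphere)
    temp_mean = 17.5,      # annual mean temperature, deg C
    temp_amplitude = 7,    # seasonal amplitude, deg C
    temp_peak_month = 1,   # warmest mid-month sample (1 = mid-January)
    temp_noise_sd = 1      # month-to-month weather noise, deg C
  )
  chk <- function(user, def, what) {
    extra <- setdiff(names(user), names(def))
    if (length(extra)) {
      stop(sprintf("unknown %s field(s): %s", what,
                   paste(extra, collapse = ", ")), call. = FALSE)
    }
    utils::modifyList(def, user)
  }
  cfg <- structure(
    list(
      seed = as.integer(seed),
      n_replicates = as.integer(n_replicates),
      hourly = chk(hourly, h_def, "hourly"),
      monthly = chk(monthly, m_def, "monthly"),
      site = chk(site, s_def, "site")
    ),
    class = "synthetic_config"
  )
  amps <- c(cfg$hourly$osc_amplitude, cfg$monthly$ari_amp_12,
            cfg$monthly$chex_amp_6, cfg$monthly$chex_amp_12)
  if (any(amps < 0)) stop("amplitudes must be non-negative", call. = FALSE)
  if (cfg$n_replicates < 1) stop("need at least one replicate", call. = FALSE)
  if (abs(cfg$hourly$ar1_coeff) >= 1) {
    stop("ar1_coeff must lie in (-1, 1)", call. = FALSE)
  }
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "<synthetic_config> seed %d, %d replicates; hourly n = %d, monthly n = %d, lat %.2f\n",
    x$seed, x$n_replicates, x$hourly$n_hours, x$monthly$n_months,
    x$site$latitude_deg
  ))
  invisible(x)
}

# AR(1) noise with given marginal sd (stationary start).
ar1_noise <- function(n, phi, marginal_sd) {
  if (marginal_sd == 0) return(rep(0, n))
  innov_sd <- marginal_sd * sqrt(1 - phi^2)
  as.numeric(stats::arima.sim(model = list(ar = phi), n = n,
                              sd = innov_sd, n.start = 50))
}

#' Simulate hourly capacitation time courses
#'
#' Each replicate follows a saturating trend
#' `trend_max * t / (t + trend_halftime)` plus, for the `chex_hourly`
#' preset, a sinusoidal ultradian oscillation
#' `osc_amplitude * sin(2*pi*(t - osc_phase)/osc_period_h)` with iid
#' Gaussian noise; the `ari_hourly` preset has no oscillation and AR(1)
#' replicate noise instead (a short-range stochastic fluctuation). Values
#' are clipped to \[0, 100\] after noise.
#'
#' @param config A [synthetic_config()].
#' @param preset `"chex_hourly"` or `"ari_hourly"`.
#' @return A [cap_panel()] of `config$n_replicates` hourly series.
#' @export
simulate_hourly_capacitation <- function(config = synthetic_config(),
                                         preset = c("chex_hourly", "ari_hourly")) {
  stopifnot(inherits(config, "synthetic_config"))
  preset <- match.arg(preset)
  h <- config$hourly
  t <- seq(0, h$n_hours - 1)
  top <- if (preset == "ari_hourly") h$ari_trend_max else h$trend_max
  trend <- top * t / (t + h$trend_halftime)
  osc <- if (preset == "ari_hourly") 0 else
    h$osc_amplitude * sin(2 * pi * (t - h$osc_phase) / h$osc_period_h)
  with_seed(config$seed, {
    reps <- lapply(seq_len(config$n_replicates), function(r) {
      eps <- if (preset == "ari_hourly") {
        ar1_noise(length(t), h$ar1_coeff, h$noise_sd)
      } else {
        stats::rnorm(length(t), sd = h$noise_sd)
      }
      cap_ts(t, pmin(pmax(trend + osc + eps, 0), 100), unit = "hours",
             label = sprintf("%s_rep%d", preset, r))
    })
    cap_panel(reps)
  })
}

#' Simulate the 36-month seasonal panel
#'
#' Generates four monthly series sharing the month axis 1..36 (month 1 =
#' mid-January of year one): an ARi-like indicator with a 12-month cosine
#' peaking in spring, a Chex-like indicator with a 6-month cosine peaking in
#' autumn and spring, mean temperature as a 12-month cosine peaking in
#' mid-January, and photoperiod as the astronomical day length at the site
#' latitude evaluated on the 15th of each month (noise-free: astronomy, not
#' weather).
#'
#' @param config A [synthetic_config()].
#' @return Named list of [cap_ts()]: `ari`, `chex`, `temperature`,
#'   `photoperiod`.
#' @export
simulate_monthly_panel <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  m <- config$monthly
  s <- config$site
  mo <- seq_len(m$n_months)
  ari0 <- m$ari_mean + m$ari_amp_12 * cos(2 * pi * (mo - m$ari_peak_month) / 12)
  chex0 <- m$chex_mean + m$chex_amp_6 * cos(2 * pi * (mo - m$chex_peak_month) / 6) +
    m$chex_amp_12 * cos(2 * pi * (mo - m$chex_peak_month) / 12)
  temp0 <- s$temp_mean + s$temp_amplitude * cos(2 * pi * (mo - s$temp_peak_month) / 12)
  mid_month_doy <- c(15, 46, 74, 105, 135, 166, 196, 227, 258, 288, 319, 349)
  photo <- day_length(s$latitude_deg, mid_month_doy[((mo - 1) %% 12) + 1])
  with_seed(config$seed, {
    ari <- pmin(pmax(ari0 + stats::rnorm(m$n_months, sd = m$noise_sd_ari), 0), 100)
    chex <- pmin(pmax(chex0 + stats::rnorm(m$n_months, sd = m$noise_sd_chex), 0), 100)
    temp <- temp0 + stats::rnorm(m$n_months, sd = s$temp_noise_sd)
    list(
      ari = cap_ts(mo, ari, unit = "months", label = "ari_monthly"),
      chex = cap_ts(mo, chex, unit = "months", label = "chex_monthly"),
      temperature = cap_ts(mo, temp, unit = "months", label = "temperature"),
      photoperiod = cap_ts(mo, photo, unit = "months", label = "photoperiod")
    )
  })
}

#' Astronomical day length
#'
#' Hours of daylight from standard solar geometry: declination
#' `delta = -23.44 * cos(2*pi*(day + 10)/365.25)` degrees and day length
#' `(24/pi) * acos(-tan(lat) * tan(delta))`, clamped to \[0, 24\]. Polar
#' latitudes (beyond 66.5 degrees) are rejected; the study site is
#' mid-latitude.
#'
#' @param latitude_deg Latitude in degrees, `abs(latitude_deg) < 66.5`.
#' @param day_of_year Integer day(s) of the year, 1-365.
#' @return Day length(s) in hours.
#' @examples
#' day_length(0, 172)        # equator: ~12 h year-round
#' day_length(-31.82, 355)   # southern summer solstice: > 12 h
#' @export
day_length <- function(latitude_deg, day_of_year) {
  if (abs(latitude_deg) >= 66.5) {
    stop("polar latitudes are not supported", call. = FALSE)
  }
  if (any(day_of_year < 1 | day_of_year > 365)) {
    stop("day_of_year must be in 1..365", call. = FALSE)
  }
  decl <- -23.44 * cos(2 * pi * (day_of_year + 10) / 365.25)
  arg <- -tan(latitude_deg * pi / 180) * tan(decl * pi / 180)
  (24 / pi) * acos(pmin(pmax(arg, -1), 1))
}

#' Simulate a null (rhythm-free) series
#'
#' White Gaussian noise or a stationary AR(1) process, used as the null
#' model when checking the specificity of the periodicity classification.
#'
#' @param n Series length (at least 8).
#' @param model `"white"` or `"ar1"`.
#' @param sd Marginal standard deviation.
#' @param ar1_coeff AR(1) coefficient, `abs(.) < 1` (ar1 model only).
#' @param seed Integer seed.
#' @param unit Time unit of the returned series.
#' @return A [cap_ts()] on times `0..n-1`.
#' @export
simulate_null_series <- function(n, model = c("white", "ar1"), sd = 1,
                                 ar1_coeff = 0.5, seed = 1,
                                 unit = c("hours", "months")) {
  model <- match.arg(model)
  unit <- match.arg(unit)
  if (n < 8) stop("null series need n >= 8", call. = FALSE)
  if (model == "ar1" && abs(ar1_coeff) >= 1) {
    stop("ar1_coeff must lie in (-1, 1) for stationarity", call. = FALSE)
  }
  with_seed(seed, {
    x <- if (model == "white") stats::rnorm(n, sd = sd)
         else ar1_noise(n, ar1_coeff, sd)
    cap_ts(seq(0, n - 1), x, unit = unit, label = paste0(model, "_null"))
  })
}

#' Write the canonical seeded fixture datasets
#'
#' Emits the CSV files the examples and tests work from: both hourly presets
#' (replicate long format) and the four monthly series, all generated from
#' one seed.
#'
#' @param dir Output directory (created if missing).
#' @param seed Fixture seed.
#' @return Character vector of files written, invisibly.
#' @export
write_fixtures <- function(dir, seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- synthetic_config(seed = seed)
  files <- character(0)
  for (p in c("chex_hourly", "ari_hourly")) {
    f <- file.path(dir, paste0(p, ".csv"))
    write_series_csv(simulate_hourly_capacitation(cfg, p), f)
    files <- c(files, f)
  }
  panel <- simulate_monthly_panel(cfg)
  for (nm in names(panel)) {
    f <- file.path(dir, paste0("monthly_", nm, ".csv"))
    write_series_csv(panel[[nm]], f)
    files <- c(files, f)
  }
  invisible(files)
}
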