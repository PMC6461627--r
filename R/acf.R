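# Autocorrelation analysis: normalized ACF, classification of the dynamics
# as periodic versus short-range stochastic, and ACF-based period estimation.
#
# The estimator is the biased (1/n-normalized) sample ACF with the global
# mean,
#
#   C(s) = sum_{t=1}^{n-s} (x_t - xbar)(x_{t+s} - xbar) /
#          sum_{t=1}^{n}   (x_t - xbar)^2 ,
#
# which guarantees C(0) = 1 and |C(s)| <= 1.  This is exactly what
# stats::acf(type = "correlation", demean = TRUE) computes; a brute-force
# double-loop oracle backs it in the test suite.

#' Normalized autocorrelation of a time series
#'
#' Computes the biased sample autocorrelation `C(s)` up to `max_lag`, the
#' large-sample white-noise confidence band `+/- 2/sqrt(n)` and (on request)
#' classifies the dynamics. Capacitation indicators rise along incubation, so
#' by default a linear trend is removed first; the ACF then reflects the
#' fluctuations around the trend.
#'
#' @param series A [cap_ts()].
#' @param max_lag Largest lag, in sampling intervals. Defaults to
#'   `floor(n/2)`; the estimator is unreliable beyond half the series.
#' @param detrend Remove a least-squares line first (default `TRUE`).
#' @param band_multiplier Width of the significance band in units of
#'   `1/sqrt(n)` (default 2).
#' @return An object of class `cap_acf` with fields `lags`, `coefficients`,
#'   `n`, `confidence_band`, `classification`, `estimated_period`,
#'   `sampling_interval`, `unit`.
#' @seealso [classify_dynamics()], [estimate_period_acf()]
#' @export
cap_acf <- function(series, max_lag = NULL, detrend = TRUE,
                    band_multiplier = 2) {
  stopifnot(inherits(series, "cap_ts"))
  n <- length(series)
  if (is.null(max_lag)) max_lag <- floor(n / 2)
  max_lag <- as.integer(max_lag)
  if (max_lag < 1 || max_lag > floor(n / 2)) {
    stop(sprintf("max_lag must be in [1, floor(n/2)] = [1, %d]", floor(n / 2)),
         call. = FALSE)
  }
  x <- if (detrend) detrend_linear(series)$values else series$values
  if (stats::var(x) <= .Machine$double.eps * max(1, mean(x)^2)) {
    stop("degenerate series: zero variance after detrending", call. = FALSE)
  }
  co <- as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE,
                              demean = TRUE, type = "correlation")$acf)
  res <- structure(
    list(
      lags = 0:max_lag,
      coefficients = co,
      n = n,
      confidence_band = band_multiplier / sqrt(n),
      classification = NA_character_,
      estimated_period = NA_real_,
      sampling_interval = series$sampling_interval,
      unit = series$unit,
      detrended = detrend,
      label = series$label
    ),
    class = "cap_acf"
  )
  if (max_lag >= 4) {
    res$classification <- classify_dynamics(res)
    if (res$classification == "periodic") {
      res$estimated_period <- estimate_period_acf(res)
    }
  } else {
    res$classification <- "unclassified"   # too few lags to judge the shape
  }
  res
}

#' @export
print.cap_acf <- function(x, ...) {
  cat(sprintf(
    "<cap_acf> n = %d, lags 0..%d, band +/- %.3f, classification: %s%s\n",
    x$n, max(x$lags), x$confidence_band, x$classification,
    if (!is.na(x$estimated_period))
      sprintf(", period %g %s", x$estimated_period, x$unit) else ""
  ))
  invisible(x)
}

#' @export
as.data.frame.cap_acf <- function(x, ...) {
  data.frame(lag = x$lags, coefficient = x$coefficients)
}

# Interior local maxima of C(s) over s = 1..max_lag; plateaus take their
# left edge, and the last lag counts when it rises above its predecessor.
acf_local_maxima <- function(co) {
  s_max <- length(co) - 1L
  if (s_max < 2L) return(integer(0))
  peaks <- integer(0)
  for (s in 1:s_max) {
    left <- co[s]              # C(s-1)
    mid <- co[s + 1L]          # C(s)
    right <- if (s < s_max) co[s + 2L] else -Inf
    if (mid > left && mid >= right) peaks <- c(peaks, s)
  }
  peaks
}

#' Classify series dynamics from its autocorrelation
#'
#' A series is `"periodic"` when the correlation curve alternates sign:
#' some lag with `C` below the negative band is later followed by a local
#' maximum above the positive band (negative values followed by positive
#' ones, as seen for a 2-h capacitation cycle). It is
#' `"short_range_stochastic"` when the coefficients decay into the band
#' without such an alternation, the signature of a linear stochastic process
#' with short-range correlations. Anything else (e.g. a strong residual
#' trend keeping all coefficients high) is `"unclassified"`.
#'
#' @param result A `cap_acf`.
#' @return One of `"periodic"`, `"short_range_stochastic"`, `"unclassified"`.
#' @export
classify_dynamics <- function(result) {
  stopifnot(inherits(result, "cap_acf"))
  co <- result$coefficients
  band <- result$confidence_band
  s_max <- length(co) - 1L
  if (s_max < 4L) stop("classification needs max_lag >= 4", call. = FALSE)
  peaks <- acf_local_maxima(co)
  for (s in peaks) {
    if (co[s + 1L] > band && any(co[seq_len(s)][-1L] < -band)) {
      # note co[2..s] are lags 1..s-1
      return("periodic")
    }
  }
  # first-lag special case: a local max at the smallest lags needs a
  # preceding negative excursion among lags 1..s-1; none exists for s = 1.
  if (any(co[-1L] < band)) "short_range_stochastic" else "unclassified"
}

#' ACF-based period estimate
#'
#' The period is the lag (converted to time units) of the first local
#' maximum of `C(s)` at `s > 0` exceeding the confidence band — the interval
#' at which high values recur. Resolution is one sampling interval; the
#' smallest qualifying lag wins.
#'
#' @param result A `cap_acf` classified as periodic.
#' @return Period in the series' time units.
#' @export
estimate_period_acf <- function(result) {
  stopifnot(inherits(result, "cap_acf"))
  if (!identical(classify_dynamics(result), "periodic")) {
    stop("period estimation requires a periodic classification", call. = FALSE)
  }
  co <- result$coefficients
  band <- result$confidence_band
  peaks <- acf_local_maxima(co)
  ok <- peaks[co[peaks + 1L] > band]
  ok[1L] * result$sampling_interval
}

#' Export an ACF result
#'
#' Writes the lag/coefficient table as CSV, or the full result (including
#' classification, band and period) as JSON.
#'
#' @param result A `cap_acf`.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_acf <- function(result, path, format = c("csv", "json")) {
  stopifnot(inherits(result, "cap_acf"))
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(result), path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(
      list(
        n = result$n,
        confidence_band = result$confidence_band,
        classification = result$classification,
        estimated_period = result$estimated_period,
        unit = result$unit,
        lags = result$lags,
        coefficients = result$coefficients
      ),
      path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}
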