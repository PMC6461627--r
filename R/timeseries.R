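# Core time-series container and CSV I/O.
#
# A cap_ts is a uniformly sampled numeric series with an explicit time unit
# ("hours" for incubation time courses, "months" for multi-year seasonal
# series).  Uniform sampling is a hard requirement of the downstream
# autocorrelation and wavelet analyses, so it is validated at construction
# and irregular series are rejected rather than resampled.

#' Uniformly sampled time series
#'
#' Construct a validated time series for rhythm analysis. Times must be
#' strictly increasing and uniformly spaced (relative deviation from the
#' sampling interval below `tol`); values must be finite with no missing
#' entries.
#'
#' @param times Numeric vector of timestamps, strictly increasing.
#' @param values Numeric vector of observations, same length as `times`.
#' @param unit Time unit, `"hours"` or `"months"`.
#' @param label Free-text label for the series.
#' @param tol Relative tolerance on spacing uniformity.
#' @return An object of class `cap_ts` with fields `times`, `values`,
#'   `sampling_interval`, `unit`, `label`.
#' @examples
#' ts <- cap_ts(0:23, 10 + sin(pi * (0:23 - 0.5)), unit = "hours")
#' ts$sampling_interval
#' @export
cap_ts <- function(times, values, unit = c("hours", "months"), label = "",
                   tol = 1e-9) {
  unit <- match.arg(unit)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("`times` and `values` must have the same length", call. = FALSE)
  }
  if (length(times) < 2) {
    stop("a time series needs at least 2 points", call. = FALSE)
  }
  if (anyNA(times) || any(!is.finite(times))) {
    stop("non-finite timestamps", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values))[1L]
    stop(sprintf("non-finite or missing value at row %d", bad), call. = FALSE)
  }
  dt <- diff(times)
  if (any(dt <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  interval <- mean(dt)
  if (max(abs(dt - interval)) > tol * max(interval, 1)) {
    stop(sprintf(
      "non-uniform sampling: intervals range %g to %g (expected %g)",
      min(dt), max(dt), interval
    ), call. = FALSE)
  }
  structure(
    list(
      times = times, values = values,
      sampling_interval = interval, unit = unit, label = as.character(label)
    ),
    class = "cap_ts"
  )
}

#' @export
print.cap_ts <- function(x, ...) {
  cat(sprintf(
    "<cap_ts> %s%d points, every %g %s, t = [%g, %g]\n",
    if (nzchar(x$label)) paste0("'", x$label, "': ") else "",
    length(x$values), x$sampling_interval, x$unit,
    min(x$times), max(x$times)
  ))
  invisible(x)
}

#' @export
length.cap_ts <- function(x) length(x$values)

#' @export
as.data.frame.cap_ts <- function(x, ...) {
  data.frame(time = x$times, value = x$values,
             label = if (nzchar(x$label)) x$label else NA_character_)
}

#' Replicate panel
#'
#' Bundle replicate series sharing a common time axis, together with their
#' pointwise mean and standard error (sd/sqrt(n)).
#'
#' @param replicates List of `cap_ts` objects with identical times.
#' @return An object of class `cap_panel` with fields `replicates`,
#'   `mean_series`, `sem_series`, `n_replicates`.
#' @export
cap_panel <- function(replicates) {
  if (!is.list(replicates) || length(replicates) < 1 ||
      !all(vapply(replicates, inherits, logical(1), "cap_ts"))) {
    stop("`replicates` must be a non-empty list of cap_ts", call. = FALSE)
  }
  t0 <- replicates[[1L]]$times
  for (r in replicates) {
    if (length(r$times) != length(t0) || any(abs(r$times - t0) > 1e-9)) {
      stop("all replicates must share identical times", call. = FALSE)
    }
  }
  m <- do.call(cbind, lapply(replicates, `[[`, "values"))
  n <- ncol(m)
  mu <- rowMeans(m)
  sem <- if (n > 1) apply(m, 1L, stats::sd) / sqrt(n) else rep(0, nrow(m))
  unit <- replicates[[1L]]$unit
  structure(
    list(
      replicates = replicates,
      mean_series = cap_ts(t0, mu, unit = unit, label = "mean"),
      sem_series = cap_ts(t0, sem, unit = unit, label = "sem"),
      n_replicates = n
    ),
    class = "cap_panel"
  )
}

#' @export
print.cap_panel <- function(x, ...) {
  cat(sprintf("<cap_panel> %d replicates of %d points (%s)\n",
              x$n_replicates, length(x$mean_series), x$mean_series$unit))
  invisible(x)
}

#' Read a time series (or replicate panel) from CSV
#'
#' Expects a comma-separated file with a header row. Rows are sorted by time
#' before validation. When `replicate_column` is given the file is split by
#' replicate id and returned as a [cap_panel()].
#'
#' @param path Path to a CSV file.
#' @param time_column,value_column Column names holding time and value.
#' @param replicate_column Optional column naming the replicate each row
#'   belongs to.
#' @param unit Time unit of the series.
#' @param label Label attached to the series.
#' @return A `cap_ts`, or a `cap_panel` when `replicate_column` is given.
#' @export
read_series_csv <- function(path, time_column = "time", value_column = "value",
                            replicate_column = NULL,
                            unit = c("hours", "months"), label = "") {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c(time_column, value_column, replicate_column)) {
    if (!col %in% names(df)) {
      stop(sprintf("column '%s' not found in %s", col, path), call. = FALSE)
    }
  }
  tvals <- suppressWarnings(as.numeric(df[[time_column]]))
  vvals <- suppressWarnings(as.numeric(df[[value_column]]))
  if (anyNA(tvals)) {
    stop(sprintf("non-numeric or missing time at row %d", which(is.na(tvals))[1L]),
         call. = FALSE)
  }
  if (anyNA(vvals)) {
    stop(sprintf("non-numeric or missing value at row %d", which(is.na(vvals))[1L]),
         call. = FALSE)
  }
  if (is.null(replicate_column)) {
    ord <- order(tvals)
    return(cap_ts(tvals[ord], vvals[ord], unit = unit, label = label))
  }
  ids <- df[[replicate_column]]
  reps <- lapply(split(seq_len(nrow(df)), ids), function(idx) {
    ord <- idx[order(tvals[idx])]
    cap_ts(tvals[ord], vvals[ord], unit = unit, label = as.character(ids[idx[1L]]))
  })
  cap_panel(reps)
}

#' Write a time series (or panel) to CSV
#'
#' Values are written with full double precision (15 significant digits) so
#' that a read/write round-trip preserves them to well below analysis
#' tolerances.
#'
#' @param x A `cap_ts` or `cap_panel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(x, path) {
  fmt <- function(v) vapply(v, function(x) sprintf("%.15g", x), character(1))
  if (inherits(x, "cap_ts")) {
    df <- data.frame(time = fmt(x$times), value = fmt(x$values))
    if (nzchar(x$label)) df$label <- x$label
  } else if (inherits(x, "cap_panel")) {
    df <- do.call(rbind, lapply(x$replicates, function(r) {
      data.frame(time = fmt(r$times), value = fmt(r$values),
                 replicate = if (nzchar(r$label)) r$label else "r")
    }))
  } else {
    stop("x must be a cap_ts or cap_panel", call. = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove a linear trend
#'
#' Fits an ordinary least-squares line to the series and returns the
#' residuals as a new series. Rhythm detection by autocorrelation acts on
#' fluctuations around the trend, so slowly rising capacitation time courses
#' are detrended before the ACF is computed.
#'
#' @param series A `cap_ts` of length at least 3.
#' @return A `cap_ts` of residuals (mean zero).
#' @export
detrend_linear <- function(series) {
  stopifnot(inherits(series, "cap_ts"))
  if (length(series) < 3) {
    stop("detrending needs at least 3 points", call. = FALSE)
  }
  fit <- stats::lm(series$values ~ series$times)
  cap_ts(series$times, as.numeric(stats::residuals(fit)),
         unit = series$unit,
         label = if (nzchar(series$label)) paste0(series$label, " (detrended)") else "")
}
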