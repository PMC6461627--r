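# Continuous wavelet transform with complex Morlet (cmor) and complex
# Gaussian (cgau) mother wavelets, scale <-> period conversion, dominant
# period extraction and per-scale coefficient series.
#
# Conventions:
#   cmor(fb, fc):  psi(t) = (pi*fb)^(-1/2) * exp(2*pi*i*fc*t) * exp(-t^2/fb)
#                  (the cmor family convention of the MATLAB/PyWavelets
#                  toolboxes; not unit L2 norm — its squared norm is
#                  (2*pi*fb)^(-1/2)).
#   cgau(m):       L2-normalized m-th derivative of exp(-i*t)*exp(-t^2).
#   transform:     W(a, b) = a^(-1/2) * sum_k x_k * Conj(psi((k - b)/a)) * dt
#                  with k, b sample indices and a in sampling intervals
#                  (direct sum over the full series; edges are implicitly
#                  zero-padded and flagged by the cone of influence).
#   period:        period = a * dt / fc   (the scales-to-frequency rule).

# Center frequency of cgau1: argmax over f of |f| * exp(-pi^2*(f + 1/(2*pi))^2)
# is exactly 1/pi (root of 2*pi^2*f^2 + pi*f*... verified by the FFT oracle
# in the test suite, where the constant is frozen).
CGAU1_CENTER_FREQUENCY <- 1 / pi

#' Mother-wavelet specification
#'
#' Describes a complex Morlet (`cmor`) or complex Gaussian (`cgau`) mother
#' wavelet. The default is cmor with bandwidth 1 and center frequency 1.5
#' (cmor1-1.5), the wavelet used for the monthly infradian analysis. For the
#' cgau family the center frequency is an intrinsic constant (the peak of the
#' Fourier magnitude; 1/pi for order 1) and cannot be chosen freely.
#'
#' @param family `"cmor"` or `"cgau"`.
#' @param bandwidth Bandwidth parameter fb (cmor only).
#' @param center_frequency Center frequency fc in cycles per unit of the
#'   mother wavelet's own time axis (cmor only).
#' @param order Derivative order m (cgau only; only order 1 is implemented).
#' @return An object of class `wavelet_spec`.
#' @examples
#' wavelet_spec()                  # cmor1-1.5
#' wavelet_spec("cgau", order = 1)
#' @export
wavelet_spec <- function(family = c("cmor", "cgau"), bandwidth = 1,
                         center_frequency = 1.5, order = 1) {
  family <- match.arg(family)
  if (family == "cmor") {
    if (!(is.numeric(bandwidth) && bandwidth > 0)) {
      stop("cmor bandwidth must be positive", call. = FALSE)
    }
    if (!(is.numeric(center_frequency) && center_frequency > 0)) {
      stop("cmor center frequency must be positive", call. = FALSE)
    }
    spec <- list(family = "cmor", bandwidth = bandwidth,
                 center_frequency = center_frequency, order = NA_integer_)
  } else {
    if (!identical(as.integer(order), 1L)) {
      stop("only cgau order 1 is implemented", call. = FALSE)
    }
    spec <- list(family = "cgau", bandwidth = NA_real_,
                 center_frequency = CGAU1_CENTER_FREQUENCY, order = 1L)
  }
  structure(spec, class = "wavelet_spec")
}

#' @export
print.wavelet_spec <- function(x, ...) {
  if (x$family == "cmor") {
    cat(sprintf("<wavelet_spec> cmor%g-%g\n", x$bandwidth, x$center_frequency))
  } else {
    cat(sprintf("<wavelet_spec> cgau%d (fc = %.6f)\n", x$order,
                x$center_frequency))
  }
  invisible(x)
}

#' Evaluate a mother wavelet
#'
#' Returns the complex value `psi(t)` of the mother wavelet at one or more
#' time offsets.
#'
#' @param spec A [wavelet_spec()].
#' @param t Numeric vector of time offsets.
#' @return Complex vector of the same length as `t`.
#' @examples
#' wavelet_eval(wavelet_spec(), 0)   # (pi)^(-1/2) ~ 0.5642
#' @export
wavelet_eval <- function(spec, t) {
  stopifnot(inherits(spec, "wavelet_spec"))
  if (spec$family == "cmor") {
    fb <- spec$bandwidth
    fc <- spec$center_frequency
    (pi * fb)^(-0.5) * exp(2i * pi * fc * t) * exp(-t^2 / fb)
  } else {
    # d/dt [exp(-i t - t^2)] = (-i - 2 t) exp(-i t - t^2); L2 norm (2*pi)^(1/4)
    (2 * pi)^(-0.25) * (-1i - 2 * t) * exp(-1i * t - t^2)
  }
}

#' Default scale grid for the infradian analysis
#'
#' 60 logarithmically spaced scales spanning `[0.3, 30]` sampling intervals,
#' which for cmor1-1.5 on monthly data covers periods from 0.2 to 20 months
#' with a grid step below 6 % in period.
#'
#' @param n_scales Number of scales.
#' @param scale_min,scale_max Scale range, in sampling intervals.
#' @return Numeric vector of scales, ascending.
#' @export
default_scale_grid <- function(n_scales = 60, scale_min = 0.3, scale_max = 30) {
  stopifnot(scale_min > 0, scale_max > scale_min, n_scales >= 2)
  exp(seq(log(scale_min), log(scale_max), length.out = n_scales))
}

#' Convert a wavelet scale to a period
#'
#' Pseudo-frequency conversion: `frequency = fc / (scale * dt)`, hence
#' `period = scale * dt / fc`. For cmor1-1.5 on monthly data scale 30 maps
#' to 20 months and scale 0.3 to 0.2 months.
#'
#' @param scale Scale(s), in sampling intervals (positive).
#' @param spec A [wavelet_spec()].
#' @param sampling_interval Sampling interval `dt` in time units.
#' @return Period(s) in time units.
#' @export
scale_to_period <- function(scale, spec, sampling_interval = 1) {
  stopifnot(inherits(spec, "wavelet_spec"))
  if (any(scale <= 0) || sampling_interval <= 0) {
    stop("scale and sampling interval must be positive", call. = FALSE)
  }
  scale * sampling_interval / spec$center_frequency
}

#' @rdname scale_to_period
#' @param period Period(s) in time units (positive).
#' @export
period_to_scale <- function(period, spec, sampling_interval = 1) {
  stopifnot(inherits(spec, "wavelet_spec"))
  if (any(period <= 0) || sampling_interval <= 0) {
    stop("period and sampling interval must be positive", call. = FALSE)
  }
  period * spec$center_frequency / sampling_interval
}

# Cone-of-influence half width at scale a, in samples: the distance from an
# edge within which the wavelet power of an edge discontinuity has not yet
# decayed by 1/e.  For the Gaussian envelope exp(-t^2/fb), |psi|^2 drops by
# e at t = sqrt(fb/2), i.e. a * sqrt(fb/2) samples at scale a.
coi_half_width <- function(scale, spec) {
  fb <- if (spec$family == "cmor") spec$bandwidth else 1
  scale * sqrt(fb / 2)
}

#' Continuous wavelet transform
#'
#' Computes the full complex coefficient matrix `W(a, b)` of a series over a
#' grid of scales by direct summation against the sampled, scaled mother
#' wavelet (implicit zero padding beyond the ends). Positions closer to an
#' edge than the e-folding distance of the wavelet's power are flagged in
#' the cone-of-influence mask.
#'
#' @param series A [cap_ts()] of length at least 4.
#' @param scales Positive scales in sampling intervals, ascending. Defaults
#'   to [default_scale_grid()].
#' @param spec A [wavelet_spec()]; defaults to cmor1-1.5.
#' @return An object of class `cap_cwt` with fields `scales`, `periods`,
#'   `coefficients` (complex matrix, scales x time), `cone_of_influence`
#'   (logical matrix, `TRUE` inside the cone), `times`, `sampling_interval`,
#'   `unit`, `spec`.
#' @export
cwt_transform <- function(series, scales = default_scale_grid(),
                          spec = wavelet_spec()) {
  stopifnot(inherits(series, "cap_ts"), inherits(spec, "wavelet_spec"))
  n <- length(series)
  if (n < 4) stop("series too short for a wavelet transform", call. = FALSE)
  if (length(scales) == 0) stop("empty scale grid", call. = FALSE)
  if (any(scales <= 0)) stop("scales must be positive", call. = FALSE)
  if (is.unsorted(scales, strictly = TRUE)) {
    stop("scales must be strictly ascending", call. = FALSE)
  }
  x <- series$values
  dt <- series$sampling_interval
  k <- seq_len(n)
  W <- matrix(0i, nrow = length(scales), ncol = n)
  coi <- matrix(FALSE, nrow = length(scales), ncol = n)
  offsets <- (-(n - 1L)):(n - 1L)
  for (i in seq_along(scales)) {
    a <- scales[i]
    psi <- Conj(wavelet_eval(spec, offsets / a))
    # W[i, b] = a^(-1/2) * dt * sum_k x_k psi[(k - b)]
    for (b in k) {
      W[i, b] <- sum(x * psi[(k - b) + n]) * dt / sqrt(a)
    }
    hw <- coi_half_width(a, spec)
    edge_dist <- pmin(k - 1L, n - k)
    coi[i, ] <- edge_dist < hw
  }
  structure(
    list(
      scales = scales,
      periods = scale_to_period(scales, spec, dt),
      coefficients = W,
      cone_of_influence = coi,
      times = series$times,
      sampling_interval = dt,
      unit = series$unit,
      spec = spec,
      label = series$label
    ),
    class = "cap_cwt"
  )
}

#' @export
print.cap_cwt <- function(x, ...) {
  cat(sprintf(
    "<cap_cwt> %s, %d scales (periods %.3g to %.3g %s) x %d positions\n",
    if (x$spec$family == "cmor")
      sprintf("cmor%g-%g", x$spec$bandwidth, x$spec$center_frequency)
    else sprintf("cgau%d", x$spec$order),
    length(x$scales), min(x$periods), max(x$periods), x$unit, ncol(x$coefficients)
  ))
  invisible(x)
}

#' @export
as.data.frame.cap_cwt <- function(x, ...) {
  ns <- length(x$scales); nt <- length(x$times)
  data.frame(
    scale = rep(x$scales, times = nt),
    period = rep(x$periods, times = nt),
    time = rep(x$times, each = ns),
    re = as.vector(Re(x$coefficients)),
    im = as.vector(Im(x$coefficients)),
    in_cone = as.vector(x$cone_of_influence)
  )
}

#' Dominant period of a wavelet transform
#'
#' Returns the period of the scale maximizing the time-averaged squared
#' coefficient magnitude, rectified by dividing by the scale (the
#' bias-corrected wavelet power of Liu, Liang and Weisberg; raw `|W|^2`
#' grows linearly with scale for equal-amplitude oscillations, which would
#' tilt the maximum toward long periods). With `exclude_cone = TRUE` (the
#' default) the average runs only over positions outside the cone of
#' influence, and scales whose every position is edge-contaminated are
#' dropped — on a 36-month series this restricts the search to periods that
#' complete roughly two cycles. Periods below `min_period` (default two
#' sampling intervals, the Nyquist limit) are also excluded: at sub-sample
#' scales the point-sampled wavelet degenerates and its response aliases.
#'
#' @param result A `cap_cwt`.
#' @param exclude_cone Ignore cone-of-influence positions (default `TRUE`).
#' @param rectify Divide the time-averaged power by the scale (default
#'   `TRUE`).
#' @param min_period Smallest admissible period, in time units; defaults to
#'   twice the sampling interval.
#' @return Dominant period, in time units.
#' @export
dominant_period <- function(result, exclude_cone = TRUE, rectify = TRUE,
                            min_period = 2 * result$sampling_interval) {
  stopifnot(inherits(result, "cap_cwt"))
  p2 <- Mod(result$coefficients)^2
  power <- vapply(seq_along(result$scales), function(i) {
    if (result$periods[i] < min_period) return(NA_real_)
    keep <- if (exclude_cone) !result$cone_of_influence[i, ] else
      rep(TRUE, ncol(p2))
    if (!any(keep)) return(NA_real_)
    mean(p2[i, keep]) / if (rectify) result$scales[i] else 1
  }, numeric(1))
  if (all(is.na(power))) {
    stop("no admissible scale: every position inside the cone of influence",
         call. = FALSE)
  }
  result$periods[which.max(power)]
}

#' Real part of the transform at a target period
#'
#' Extracts `Re(W(a*, .))` at the grid scale whose period is nearest the
#' target, as a time series on the original axis. This is the oscillatory
#' component displayed alongside the raw monthly series and fed to the
#' synchrony analysis.
#'
#' @param result A `cap_cwt`.
#' @param period Target period in time units; must lie within the analyzed
#'   period range.
#' @return A [cap_ts()] of real coefficients.
#' @export
real_part_at_scale <- function(result, period) {
  stopifnot(inherits(result, "cap_cwt"))
  pr <- range(result$periods)
  if (period < pr[1] || period > pr[2]) {
    stop(sprintf("period %g outside analyzed range [%g, %g]",
                 period, pr[1], pr[2]), call. = FALSE)
  }
  i <- which.min(abs(result$periods - period))
  cap_ts(result$times, Re(result$coefficients[i, ]), unit = result$unit,
         label = sprintf("Re(cwt) at %.3g-%s period", result$periods[i],
                         result$unit))
}

#' Write a wavelet transform to CSV (long format)
#'
#' One row per (scale, time) with real and imaginary parts and the
#' cone-of-influence flag.
#'
#' @param result A `cap_cwt`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cwt <- function(result, path) {
  stopifnot(inherits(result, "cap_cwt"))
  utils::write.csv(as.data.frame(result), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
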