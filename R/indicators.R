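# Capacitation indicators: net percentages, quartile-exceedance gating and
# threshold binning of sample cohorts.

#' Net percentage of responding cells
#'
#' Both capacitation indicators are net percentages: the induced acrosome
#' reaction (%ARi) is the induced minus the spontaneous percentage of
#' acrosome-reacted cells, and chemotactic recruitment (%Chex) is the
#' percentage recovered with minus without the attractant. A negative net
#' value (control above treatment) is preserved, not clamped, and flagged via
#' the `"negative_net"` attribute so time-course means are not biased.
#'
#' @param treated_pct,control_pct Percentages in \[0, 100\] (vectorized).
#' @return Numeric vector `treated_pct - control_pct` with a logical
#'   attribute `negative_net` marking negative entries.
#' @examples
#' net_percentage(35, 5)
#' @export
net_percentage <- function(treated_pct, control_pct) {
  if (any(!is.finite(treated_pct)) || any(!is.finite(control_pct)) ||
      any(treated_pct < 0 | treated_pct > 100) ||
      any(control_pct < 0 | control_pct > 100)) {
    stop("percentages must be finite and within [0, 100]", call. = FALSE)
  }
  out <- treated_pct - control_pct
  attr(out, "negative_net") <- out < 0
  out
}

#' Percentage of a sample exceeding the reference third quartile
#'
#' Flow-cytometry readouts (tyrosine phosphorylation, intracellular calcium,
#' membrane potential) are summarized as the percentage of cells whose
#' fluorescence strictly exceeds the third quartile of a reference
#' (non-capacitated) sample. The quartile uses the linear-interpolation
#' convention (type 7, the default of mainstream numeric stacks); ties at the
#' quartile do not count as exceeding.
#'
#' @param reference_values Numeric sample defining the Q3 threshold.
#' @param test_values Numeric sample gated against the threshold.
#' @return Percentage of `test_values` strictly above Q3(`reference_values`).
#' @export
q3_exceedance <- function(reference_values, test_values) {
  if (length(reference_values) == 0 || length(test_values) == 0) {
    stop("samples must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(reference_values)) || any(!is.finite(test_values))) {
    stop("samples must be finite", call. = FALSE)
  }
  q3 <- unname(stats::quantile(reference_values, probs = 0.75, type = 7))
  100 * mean(test_values > q3)
}

#' Fractions of samples below, between and above two cutoffs
#'
#' Bins a cohort of indicator values into three ranges: `[0, cut_low)`,
#' `[cut_low, cut_high]` and `(cut_high, 100]`, reporting each as a
#' percentage of the cohort. Used to describe how many semen samples show
#' low, intermediate or high indicator levels.
#'
#' @param samples Numeric values (percentages).
#' @param cut_low,cut_high Cutoffs with `cut_low < cut_high`.
#' @return Named numeric vector `c(below, between, above)` summing to 100.
#' @examples
#' threshold_fractions(c(1, 2, 5, 12), 3, 10)
#' @export
threshold_fractions <- function(samples, cut_low, cut_high) {
  if (length(samples) == 0) stop("`samples` must be non-empty", call. = FALSE)
  if (any(!is.finite(samples))) stop("`samples` must be finite", call. = FALSE)
  if (!(cut_low < cut_high)) stop("cut_low must be below cut_high", call. = FALSE)
  n <- length(samples)
  below <- sum(samples < cut_low)
  above <- sum(samples > cut_high)
  between <- n - below - above
  out <- 100 * c(below = below, between = between, above = above) / n
  out
}
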