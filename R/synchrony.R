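# Lagged synchrony between the wavelet coefficients of two series at a
# fixed scale: the Re(cwt) of each series is extracted at the scale nearest
# a target period and their Spearman correlation is scanned over integer
# time offsets, reporting R^2 per offset.  Used to ask whether the annual
# rhythm of a capacitation indicator leads or lags photoperiod/temperature.

#' Offset-scanned wavelet synchrony
#'
#' For each offset `d` in `[-max_offset, max_offset]` computes the Spearman
#' rank correlation (average ranks on ties) between `Re(cwt_a)(t)` and
#' `Re(cwt_b)(t + d)` over their overlap and stores the squared coefficient.
#' A positive best offset means the first series leads the second by that
#' many sampling intervals. The best offset is the squared-correlation
#' maximum among in-phase alignments (`rho > 0`): squared correlations are
#' sign-blind, so without this restriction a lead of `d` and an anti-phase
#' lag of `d - period/2` would be indistinguishable for near-sinusoidal
#' rhythms. The overlap shrinks with `|d|` (no wraparound). Setting
#' `mask_cone = TRUE` additionally excludes cone-of-influence positions; at
#' long periods of short series this leaves few points, so all positions are
#' used by default.
#'
#' @param series_a,series_b [cap_ts()] objects sharing length and sampling
#'   interval.
#' @param period Target period (time units) selecting the analysis scale.
#' @param spec A [wavelet_spec()]; defaults to cmor1-1.5.
#' @param max_offset Largest offset scanned, in sampling intervals; at most
#'   a third of the series length. Default 4.
#' @param scales Scale grid for the underlying transforms.
#' @param mask_cone Exclude cone-of-influence positions (default `FALSE`).
#' @return An object of class `cap_synchrony` with fields `scale_period`,
#'   `offsets`, `r_squared`, `rho` (signed), `n_overlap`, `best_offset`.
#' @export
offset_scan_synchrony <- function(series_a, series_b, period,
                                  spec = wavelet_spec(), max_offset = 4,
                                  scales = default_scale_grid(),
                                  mask_cone = FALSE) {
  stopifnot(inherits(series_a, "cap_ts"), inherits(series_b, "cap_ts"))
  n <- length(series_a)
  if (length(series_b) != n ||
      abs(series_a$sampling_interval - series_b$sampling_interval) >
        1e-9 * series_a$sampling_interval) {
    stop("series must share length and sampling interval", call. = FALSE)
  }
  max_offset <- as.integer(max_offset)
  if (max_offset < 0 || max_offset > floor(n / 3)) {
    stop("max_offset must be between 0 and n/3", call. = FALSE)
  }
  cw_a <- cwt_transform(series_a, scales = scales, spec = spec)
  cw_b <- cwt_transform(series_b, scales = scales, spec = spec)
  i <- which.min(abs(cw_a$periods - period))
  ra <- Re(cw_a$coefficients[i, ])
  rb <- Re(cw_b$coefficients[i, ])
  valid <- if (mask_cone) !cw_a$cone_of_influence[i, ] else rep(TRUE, n)

  offsets <- (-max_offset):max_offset
  rho <- numeric(length(offsets))
  n_overlap <- integer(length(offsets))
  for (j in seq_along(offsets)) {
    d <- offsets[j]
    ta <- seq_len(n)
    tb <- ta + d
    keep <- tb >= 1 & tb <= n & valid[ta] & valid[pmin(pmax(tb, 1L), n)]
    n_overlap[j] <- sum(keep)
    if (n_overlap[j] < 5) {
      stop(sprintf(
        "insufficient overlap at offset %d (%d points, need 5); reduce max_offset",
        d, n_overlap[j]
      ), call. = FALSE)
    }
    rho[j] <- stats::cor(ra[ta[keep]], rb[tb[keep]], method = "spearman")
  }
  r2 <- rho^2
  # in-phase alignments only (all offsets if none correlate positively);
  # ties broken toward the smallest |d|
  pool <- which(rho > 0)
  if (length(pool) == 0) pool <- seq_along(offsets)
  best_idx <- pool[r2[pool] == max(r2[pool])]
  best_idx <- best_idx[which.min(abs(offsets[best_idx]))]
  structure(
    list(
      scale_period = cw_a$periods[i],
      offsets = offsets,
      r_squared = r2,
      rho = rho,
      n_overlap = n_overlap,
      best_offset = offsets[best_idx],
      unit = series_a$unit,
      labels = c(series_a$label, series_b$label)
    ),
    class = "cap_synchrony"
  )
}

#' @export
print.cap_synchrony <- function(x, ...) {
  lead <- if (x$best_offset > 0) "first series leads" else
    if (x$best_offset < 0) "first series lags" else "in phase"
  cat(sprintf(
    "<cap_synchrony> period %.3g %s, offsets %d..%d: best offset %d (%s), R^2 = %.3f\n",
    x$scale_period, x$unit, min(x$offsets), max(x$offsets),
    x$best_offset, lead, max(x$r_squared)
  ))
  invisible(x)
}

#' @export
as.data.frame.cap_synchrony <- function(x, ...) {
  data.frame(offset = x$offsets, r_squared = x$r_squared, rho = x$rho,
             n_overlap = x$n_overlap)
}

#' Export a synchrony scan
#'
#' @param result A `cap_synchrony`.
#' @param path Output path.
#' @param format `"csv"` (offset table) or `"json"` (summary plus table).
#' @return `path`, invisibly.
#' @export
write_synchrony <- function(result, path, format = c("csv", "json")) {
  stopifnot(inherits(result, "cap_synchrony"))
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(result), path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(
      list(
        scale_period = result$scale_period,
        unit = result$unit,
        best_offset = result$best_offset,
        max_r_squared = max(result$r_squared),
        offsets = result$offsets,
        r_squared = result$r_squared,
        n_overlap = result$n_overlap
      ),
      path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}
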