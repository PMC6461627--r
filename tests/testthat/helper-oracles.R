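# Independent brute-force oracles used to cross-check the package's
# estimators.  These are deliberately written as literal double sums of the
# defining formulas, not via the package's code paths.

# Biased sample autocorrelation with global mean, explicit loops.
oracle_acf <- function(x, max_lag) {
  n <- length(x)
  xbar <- sum(x) / n
  denom <- sum((x - xbar)^2)
  vapply(0:max_lag, function(s) {
    num <- 0
    for (t in seq_len(n - s)) {
      num <- num + (x[t] - xbar) * (x[t + s] - xbar)
    }
    num / denom
  }, numeric(1))
}

# Direct-sum CWT: W(a, b) = a^(-1/2) * sum_k x_k Conj(psi((k - b)/a)) * dt.
oracle_cwt <- function(x, scales, spec, dt = 1) {
  n <- length(x)
  W <- matrix(0i, nrow = length(scales), ncol = n)
  for (i in seq_along(scales)) {
    a <- scales[i]
    for (b in seq_len(n)) {
      acc <- 0i
      for (k in seq_len(n)) {
        acc <- acc + x[k] * Conj(wavelet_eval(spec, (k - b) / a))
      }
      W[i, b] <- acc * dt / sqrt(a)
    }
  }
  W
}

# Trapezoidal quadrature of |psi(t)|^2 over [-lim, lim].
oracle_wavelet_norm2 <- function(spec, lim = 12, n = 200001) {
  t <- seq(-lim, lim, length.out = n)
  y <- Mod(wavelet_eval(spec, t))^2
  h <- t[2] - t[1]
  h * (sum(y) - (y[1] + y[n]) / 2)
}

# Least-squares line by explicit normal equations.
oracle_linear_fit <- function(t, y) {
  n <- length(t)
  st <- sum(t); sy <- sum(y); stt <- sum(t^2); sty <- sum(t * y)
  slope <- (n * sty - st * sy) / (n * stt - st^2)
  intercept <- (sy - slope * st) / n
  intercept + slope * t
}

# Hourly test signal: 2-h oscillation sampled at full amplitude (a zero-phase
# 2-h sinusoid on integer hours would sit on its zero crossings).
alternating_sine <- function(t, period = 2, phase = 0.5, amp = 1) {
  amp * sin(2 * pi * (t - phase) / period)
}
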