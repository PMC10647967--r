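# Internal helpers shared across modules.

# Floor that tolerates floating-point representation of rational inputs
# (e.g. 70 * 1.5 / 0.3 must count as exactly 350).
.fp_floor <- function(x, eps = 1e-9) floor(x + eps)

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .stopf("'%s' must be a single finite number", name)
  if (positive && x <= 0) .stopf("'%s' must be > 0", name)
  if (nonneg && x < 0) .stopf("'%s' must be >= 0", name)
  invisible(x)
}

# 1D moving average with edge replication.
.box_1d <- function(v, window) {
  n <- length(v)
  half <- (window - 1L) %/% 2L
  vp <- c(rep(v[1L], half), v, rep(v[n], half))
  cs <- cumsum(c(0, vp))
  (cs[(window + 1L):(n + window)] - cs[1L:n]) / window
}

# Separable moving-average (box) filter with edge replication; used for the
# local-mean map in AS-image normalization.
.box_filter <- function(mat, window) {
  if (window %% 2L != 1L || window < 1L)
    .stopf("box filter window must be odd and >= 1")
  if (window > nrow(mat) || window > ncol(mat))
    .stopf("window (%d) larger than image (%d x %d)",
           window, nrow(mat), ncol(mat))
  out <- apply(mat, 2L, .box_1d, window = window)   # down columns
  t(apply(out, 1L, .box_1d, window = window))       # across rows
}

# Linear interpolation of a vector at fractional 0-based indices, clamped to
# the valid range.  Used for phase resampling of waveforms.
.interp_at <- function(v, idx0) {
  n <- length(v)
  idx0 <- pmin(pmax(idx0, 0), n - 1)
  stats::approx(x = seq_len(n) - 1, y = v, xout = idx0)$y
}

# Periodic linear interpolation of a cycle sampled at phases k/m (k = 0..m-1)
# evaluated at arbitrary phases in [0, 1).
.interp_cycle <- function(cycle_vals, phases) {
  m <- length(cycle_vals)
  phases <- phases %% 1
  stats::approx(x = (0:m) / m, y = c(cycle_vals, cycle_vals[1L]),
                xout = phases)$y
}

# Empirical percentile with linear interpolation (inclusive endpoints).
.percentile <- function(x, p) {
  unname(stats::quantile(x, probs = p / 100, type = 7, names = FALSE))
}
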