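# Amplitude/phase correction of the short-arc 4D-CBCT waveform using the
# shroud waveform: per-direction phase-inversion handling, global
# percentile matching, and sliding-window local min/max matching.

#' Matching parameters for shroud-based correction
#'
#' @param p_upper,p_lower Percentile levels of the averaged shroud signal
#'   used for global matching; candidate pairs are (100, 0), (85, 10) and
#'   (75, 15).
#' @param w Local-matching window length in frames (odd, >= 3); candidates
#'   11, 21 and 31 frames (2, 4 and 6 s at 0.2 s sampling).
#' @return An object of class \code{matching_params}.
#' @export
matching_params <- function(p_upper = 85, p_lower = 10, w = 21L) {
  if (!(p_lower >= 0 && p_lower < p_upper && p_upper <= 100))
    .stopf("need 0 <= p_lower < p_upper <= 100")
  w <- as.integer(w)
  if (w %% 2L == 0L || w < 3L) .stopf("w must be odd and >= 3")
  structure(list(p_upper = p_upper, p_lower = p_lower, w = w),
            class = "matching_params")
}

#' Detect phase inversion between the shroud and target waveforms
#'
#' Target LR and AP motion is often negatively correlated with the
#' diaphragm SI motion; when the Pearson correlation between the shroud
#' waveform and the direction's target waveform is negative the shroud
#' signal must be multiplied by -1 before matching.
#'
#' @param w_as Shroud waveform (\code{as_waveform} or numeric).
#' @param w_4d Target waveform for one direction (numeric), same length.
#' @return +1 or -1.
#' @export
detect_phase_inversion <- function(w_as, w_4d) {
  a <- if (inherits(w_as, "as_waveform")) w_as$samples else as.numeric(w_as)
  b <- as.numeric(w_4d)
  if (length(a) != length(b)) .stopf("waveform lengths differ")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    .stopf("zero-variance input: correlation undefined")
  if (stats::cor(a, b) < 0) -1 else +1
}

#' Globally match the shroud waveform to the target motion range
#'
#' Affine rescaling mapping the (\code{p_lower}, \code{p_upper}) percentile
#' span of the averaged shroud signal onto the full range (P0, P100) of the
#' target waveform:
#' \deqn{W'_{AS} = \frac{P_{100}(4D) - P_0(4D)}{P_{upper} - P_{lower}}
#'       (W_{AS} - P_{lower}) + P_0(4D).}
#' Percentile pairs narrower than (100, 0) deliberately extend the shroud
#' amplitude beyond the target range, compensating the motion-range
#' underestimation of low-temporal-resolution 4D-CBCT.
#'
#' @param w_as Shroud waveform (sign-handled), numeric or
#'   \code{as_waveform}.
#' @param w_4d Target waveform for the direction, numeric.
#' @param params A \code{\link{matching_params}}.
#' @param as_avg Percentile source: the tiled averaged shroud signal (see
#'   \code{\link{average_as_cycle}}); defaults to \code{w_as} itself.
#' @return Numeric waveform \code{W_AS'} in mm.
#' @export
global_match <- function(w_as, w_4d, params = matching_params(),
                         as_avg = NULL) {
  a <- if (inherits(w_as, "as_waveform")) w_as$samples else as.numeric(w_as)
  if (is.null(as_avg)) as_avg <- a
  pu <- .percentile(as_avg, params$p_upper)
  pl <- .percentile(as_avg, params$p_lower)
  if (pu <= pl)
    .stopf("degenerate percentile span: P%g = P%g", params$p_upper,
           params$p_lower)
  p100 <- max(w_4d); p0 <- min(w_4d)
  (p100 - p0) / (pu - pl) * (a - pl) + p0
}

#' Locally match the target waveform to the rescaled shroud signal
#'
#' A window of \code{w} frames slides over the waveforms with stride 1; in
#' each window the target waveform is linearly transformed so that its
#' minimum and maximum match those of \code{W_AS'} in the same window.
#' Each output frame is the average of the transformed values over all
#' windows covering it. A window in which the target waveform is constant
#' is handled by a pure shift aligning the window means.
#'
#' @param w_4d Target waveform (numeric).
#' @param w_as_prime Globally matched shroud waveform, same length.
#' @param w Window length in frames (odd, >= 3, <= length).
#' @return Numeric waveform \code{W_AS-4D-CBCT} in mm.
#' @export
local_match <- function(w_4d, w_as_prime, w = 21L) {
  q <- as.numeric(w_4d); p <- as.numeric(w_as_prime)
  if (length(q) != length(p)) .stopf("waveform lengths differ")
  w <- as.integer(w)
  if (w %% 2L == 0L || w < 3L) .stopf("w must be odd and >= 3")
  n <- length(q)
  if (w > n) .stopf("window longer than the waveform")
  acc <- numeric(n); cnt <- numeric(n)
  for (s in seq_len(n - w + 1L)) {
    idx <- s:(s + w - 1L)
    qw <- q[idx]; pw <- p[idx]
    rng <- max(qw) - min(qw)
    if (rng == 0) {
      val <- qw - mean(qw) + mean(pw)
    } else {
      a <- (max(pw) - min(pw)) / rng
      val <- a * (qw - min(qw)) + min(pw)
    }
    acc[idx] <- acc[idx] + val
    cnt[idx] <- cnt[idx] + 1
  }
  acc / cnt
}

#' Correct a 4D-CBCT waveform with the shroud signal in all directions
#'
#' Per direction: determine the phase-inversion sign, rescale the
#' (sign-handled) shroud waveform globally onto the direction's target
#' range, then locally match the target waveform to it. The end-inhalation
#' minima of the shroud signal are re-detected on the sign-handled copy
#' when the sign is flipped, since the supplied segmentation belongs to the
#' un-flipped signal.
#'
#' @param w_4d n x 3 matrix (LR/SI/AP) of target positions, mm.
#' @param w_as Shroud waveform (\code{as_waveform} or numeric), length n.
#' @param params A \code{\link{matching_params}}.
#' @param seg_as Optional \code{cycle_segmentation} of \code{w_as};
#'   detected automatically when missing.
#' @param min_separation,dt Passed to \code{\link{detect_local_minima}}
#'   when segmentation is (re-)detected.
#' @return An object of class \code{corrected_waveform}: \code{samples}
#'   (n x 3, W_AS-4D-CBCT), \code{w_as_prime} (n x 3 intermediates),
#'   \code{signs}, \code{params}, and the input \code{w_4d}.
#' @export
correct_waveform <- function(w_4d, w_as, params = matching_params(),
                             seg_as = NULL, min_separation = 2.0, dt = 0.2) {
  stopifnot(inherits(params, "matching_params"))
  a <- if (inherits(w_as, "as_waveform")) w_as$samples else as.numeric(w_as)
  if (is.null(dim(w_4d))) w_4d <- matrix(w_4d, ncol = 1L)
  if (nrow(w_4d) != length(a)) .stopf("waveform lengths differ")
  if (is.null(seg_as))
    seg_as <- detect_local_minima(a, min_separation, dt = dt)
  avg_pos <- average_as_cycle(a, seg_as)

  d <- ncol(w_4d)
  out <- matrix(NA_real_, nrow(w_4d), d, dimnames = dimnames(w_4d))
  prime <- out
  signs <- numeric(d)
  for (k in seq_len(d)) {
    sgn <- detect_phase_inversion(a, w_4d[, k])
    signs[k] <- sgn
    ak <- sgn * a
    if (sgn < 0) {
      seg_k <- tryCatch(detect_local_minima(ak, min_separation, dt = dt),
                        error = function(e) seg_as)
      avg_k <- average_as_cycle(ak, seg_k)
    } else {
      avg_k <- avg_pos
    }
    prime[, k] <- global_match(ak, w_4d[, k], params, as_avg = avg_k$tiled)
    out[, k] <- local_match(w_4d[, k], prime[, k], params$w)
  }
  names(signs) <- colnames(w_4d)
  structure(list(samples = out, w_as_prime = prime, signs = signs,
                 params = params, w_4d = w_4d),
            class = "corrected_waveform")
}
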