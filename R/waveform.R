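# Cycle segmentation of surrogate traces, 8-phase sorting of the gold
# marker waveform into the short-arc 4D-CBCT cycle, and tiling it back to
# the full-length W_4D-CBCT.

# Prominence of a local minimum at index i: walk outwards on each side
# until a sample lower than v[i] (or the boundary) is met, tracking the
# maximum; prominence = min(left bar, right bar) - v[i].
.min_prominence <- function(v, i) {
  n <- length(v)
  bar <- function(idx_seq) {
    m <- -Inf
    for (k in idx_seq) {
      if (v[k] < v[i]) break
      if (v[k] > m) m <- v[k]
    }
    m
  }
  left <- if (i > 1L) bar((i - 1L):1L) else -Inf
  right <- if (i < n) bar((i + 1L):n) else -Inf
  lr <- c(left, right)
  lr <- lr[is.finite(lr)]
  if (!length(lr)) return(Inf)
  min(lr) - v[i]
}

#' Detect end-inhalation local minima of a respiratory trace
#'
#' Finds the local minima of the trace (the end-inhalation extremes of an
#' AP surrogate trace under the convention that inhalation moves abdominal
#' markers anteriorly), keeping only minima with at least the requested
#' prominence and pairwise separation. From the detected frames the mean
#' respiratory cycle length \code{T_mean = mean(diff(t_lm))} (in frames) is
#' computed.
#'
#' @param trace Numeric vector sampled on a uniform grid.
#' @param min_separation Minimum separation between kept minima, seconds.
#' @param prominence Minimum prominence in trace units; default 20\% of the
#'   trace interquartile range.
#' @param dt Sampling interval, seconds.
#' @param frame_range Optional 0-based inclusive index range (e.g.
#'   \code{c(0, 301)} for a 60 s training window) to which detection is
#'   restricted.
#' @return An object of class \code{cycle_segmentation}: \code{t_lm}
#'   (0-based frame indices, strictly increasing), \code{n}, \code{t_mean}
#'   (frames).
#' @export
detect_local_minima <- function(trace, min_separation = 2.0,
                                prominence = NULL, dt = 0.2,
                                frame_range = NULL) {
  v <- as.numeric(trace)
  n <- length(v)
  min_sep_frames <- min_separation / dt
  if (n < 2 * min_sep_frames)
    .stopf("trace shorter than twice the minimum separation")
  if (is.null(prominence)) prominence <- 0.2 * stats::IQR(v)

  cand <- which(diff(sign(diff(v))) > 0) + 1L       # strict valley points
  # plateau valleys: first index of a flat run lower than both neighbours
  flat <- which(v[-n] == v[-1L])
  if (length(flat)) {
    for (i in setdiff(flat, c(1L, cand))) {
      j <- i
      while (j < n && v[j + 1L] == v[i]) j <- j + 1L
      if (i > 1L && j < n && v[i - 1L] > v[i] && v[j + 1L] > v[i])
        cand <- c(cand, i)
    }
    cand <- sort(unique(cand))
  }
  if (length(cand)) {
    prom <- vapply(cand, function(i) .min_prominence(v, i), numeric(1L))
    cand <- cand[prom >= prominence]
  }
  if (!is.null(frame_range))
    cand <- cand[cand - 1L >= frame_range[1L] & cand - 1L <= frame_range[2L]]
  # enforce separation: keep deepest first
  kept <- integer(0)
  for (i in cand[order(v[cand])]) {
    if (!length(kept) || all(abs(kept - i) >= min_sep_frames))
      kept <- c(kept, i)
  }
  kept <- sort(kept)
  if (length(kept) < 2L)
    .stopf("fewer than 2 minima detected; mean cycle length undefined")
  t_lm <- kept - 1L                                  # 0-based
  structure(list(t_lm = t_lm, n = length(t_lm),
                 t_mean = mean(diff(t_lm)), dt = dt),
            class = "cycle_segmentation")
}

#' @export
print.cycle_segmentation <- function(x, ...) {
  cat(sprintf("Cycle segmentation: %d end-inhalation minima, T_mean = %.2f frames (%.2f s)\n",
              x$n, x$t_mean, x$t_mean * x$dt))
  invisible(x)
}

#' Phase-sort a waveform into an 8-phase short-arc 4D-CBCT cycle
#'
#' Each respiratory cycle (between consecutive detected end-inhalation
#' minima) is resampled at 8 equally spaced phases k/8 (k = 0..7, phase 0
#' at end-inhalation) by linear interpolation, and the values of each phase
#' are averaged across cycles, emulating phase-based sorting of the target
#' positions into 8 respiratory bins.
#'
#' @param w_gm Numeric vector or n x d matrix (columns LR/SI/AP) of target
#'   positions, mm.
#' @param seg A \code{\link{detect_local_minima}} segmentation on the same
#'   frame grid.
#' @param n_phases Number of phase bins (default 8).
#' @return A \code{phase_binned_cycle}: an \code{n_phases x d} matrix of
#'   mean positions ordered by phase from end-inhalation.
#' @export
phase_sort <- function(w_gm, seg, n_phases = 8L) {
  stopifnot(inherits(seg, "cycle_segmentation"))
  if (is.null(dim(w_gm))) w_gm <- matrix(w_gm, ncol = 1L)
  n <- nrow(w_gm)
  if (max(seg$t_lm) > n - 1L) .stopf("segmentation exceeds waveform length")
  phases <- (seq_len(n_phases) - 1L) / n_phases
  acc <- matrix(0, n_phases, ncol(w_gm))
  ncyc <- seg$n - 1L
  for (j in seq_len(ncyc)) {
    i0 <- seg$t_lm[j]; i1 <- seg$t_lm[j + 1L]
    len <- i1 - i0
    if (len < 1L) .stopf("empty cycle between minima %d and %d", j, j + 1L)
    idx <- i0 + phases * len
    for (d in seq_len(ncol(w_gm)))
      acc[, d] <- acc[, d] + .interp_at(w_gm[, d], idx)
  }
  out <- acc / ncyc
  colnames(out) <- colnames(w_gm)
  structure(out, class = c("phase_binned_cycle", "matrix"))
}

# Shared tiling core: given a cycle sampled at m equally spaced phases,
# reconstruct a full-length waveform following the observed cycle lengths.
# Interior cycles stretch the cycle to each observed length; the head and
# tail use the cycle resampled to T_mean frames (the head takes its last
# t_lm[1] frames, the tail its first frames, wrapping cyclically).
.tile_cycle <- function(cycle_vals, t_lm, t_mean, total_frames) {
  phi <- numeric(total_frames)
  t <- seq_len(total_frames) - 1L                     # 0-based frames
  first <- t_lm[1L]; last <- t_lm[length(t_lm)]
  head_idx <- which(t < first)
  if (length(head_idx))
    phi[head_idx] <- ((t_mean - first + t[head_idx]) / t_mean) %% 1
  for (j in seq_len(length(t_lm) - 1L)) {
    sel <- which(t >= t_lm[j] & t < t_lm[j + 1L])
    phi[sel] <- (t[sel] - t_lm[j]) / (t_lm[j + 1L] - t_lm[j])
  }
  tail_idx <- which(t >= last)
  if (length(tail_idx))
    phi[tail_idx] <- ((t[tail_idx] - last) / t_mean) %% 1
  .interp_cycle(cycle_vals, phi)
}

#' Tile a phase-binned cycle into a full-length waveform
#'
#' Reconstructs the full-length low-temporal-resolution target waveform
#' (W_4D-CBCT) from the 8-phase short-arc cycle: within each observed
#' respiratory cycle the 8-point cycle is resampled (periodic linear
#' interpolation) to the observed cycle length; before the first minimum
#' the last \code{t_lm[1]} frames of the cycle resampled to \code{T_mean}
#' frames are used, and after the last minimum its first frames (repeated
#' cyclically if the tail exceeds one mean cycle).
#'
#' @param cycle A \code{\link{phase_sort}} result.
#' @param seg The \code{cycle_segmentation} used for sorting.
#' @param total_frames Output length; must be at least \code{max(t_lm)+1}.
#' @return An n x d matrix (or vector for d = 1) of positions, mm.
#' @export
tile_waveform <- function(cycle, seg, total_frames) {
  stopifnot(inherits(seg, "cycle_segmentation"))
  cycle <- unclass(cycle)
  if (is.null(dim(cycle))) cycle <- matrix(cycle, ncol = 1L)
  if (total_frames < max(seg$t_lm) + 1L)
    .stopf("total_frames smaller than the last minimum index")
  out <- vapply(seq_len(ncol(cycle)), function(d)
    .tile_cycle(cycle[, d], seg$t_lm, seg$t_mean, total_frames),
    numeric(total_frames))
  colnames(out) <- colnames(cycle)
  if (ncol(out) == 1L) drop(out) else out
}

#' Average the shroud waveform over respiratory cycles
#'
#' Divides the shroud waveform at its own end-inhalation minima (half-open
#' intervals, so each boundary sample belongs to the cycle it starts),
#' resamples every interval to 301 time points by cubic-spline
#' interpolation, averages the intervals pointwise, and tiles the averaged
#' cycle back to the full trace length. The tiled averaged signal is the
#' percentile source for global matching.
#'
#' @param w_as An \code{as_waveform} or numeric vector.
#' @param seg_as Segmentation of the shroud waveform itself (at least 2
#'   minima).
#' @param n_points Points per resampled interval (default 301).
#' @return A list: \code{cycle} (averaged interval, \code{n_points}
#'   values), \code{tiled} (full-length averaged signal), \code{seg_as}.
#' @export
average_as_cycle <- function(w_as, seg_as, n_points = 301L) {
  stopifnot(inherits(seg_as, "cycle_segmentation"))
  v <- if (inherits(w_as, "as_waveform")) w_as$samples else as.numeric(w_as)
  t_lm <- seg_as$t_lm
  acc <- numeric(n_points)
  for (j in seq_len(length(t_lm) - 1L)) {
    i0 <- t_lm[j] + 1L; i1 <- t_lm[j + 1L]           # 1-based, half-open
    xs <- i0:i1
    acc <- acc + stats::spline(x = xs, y = v[xs],
                               xout = seq(i0, i1, length.out = n_points))$y
  }
  cyc <- acc / (length(t_lm) - 1L)
  tiled <- .tile_cycle(cyc, t_lm, seg_as$t_mean, length(v))
  list(cycle = cyc, tiled = tiled, seg_as = seg_as)
}
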