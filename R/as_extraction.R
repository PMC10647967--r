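# Amsterdam Shroud (AS) image construction and diaphragm waveform
# extraction.  Each projection frame is log-transformed, differentiated
# along the cranial-caudal axis and collapsed to one column; columns
# concatenated over time form the AS image, in which diaphragm motion
# appears as a sinuous ridge.  The respiratory waveform is the first
# principal-component score of the locally normalized image.

.new_as_image <- function(matrix, row_pitch, frame_times, provenance,
                          row_offset = 0L) {
  structure(list(matrix = matrix, row_pitch = row_pitch,
                 frame_times = frame_times, provenance = provenance,
                 row_offset = as.integer(row_offset)),
            class = "as_image")
}

#' Build an Amsterdam Shroud image from a projection stack
#'
#' Per frame: log-transform the pixel values, apply a vertical
#' (cranial-caudal) derivative (central differences, one-sided at the first
#' and last rows), and average across detector columns to obtain one column;
#' columns are concatenated in frame order.
#'
#' @param stack A \code{projection_stack} (see \code{\link{simulate_case}}
#'   or \code{\link{read_projection_stack}}).
#' @param offset Value added to pixel intensities before the log transform;
#'   required to be set (> 0 net values) when the stack contains
#'   non-positive pixels.
#' @return An \code{as_image} whose matrix has one row per SI pixel and one
#'   column per frame.
#' @export
make_as_image <- function(stack, offset = 0) {
  stopifnot(inherits(stack, "projection_stack"))
  fr <- stack$frames
  if (min(fr) + offset <= 0)
    .stopf("non-positive pixel values; supply a positive 'offset'")
  h <- dim(fr)[1L]
  la <- log(fr + offset)
  g <- array(0, dim(la))
  g[2:(h - 1L), , ] <- (la[3:h, , , drop = FALSE] -
                        la[1:(h - 2L), , , drop = FALSE]) / 2
  g[1L, , ] <- la[2L, , ] - la[1L, , ]
  g[h, , ] <- la[h, , ] - la[h - 1L, , ]
  m <- apply(g, 3L, rowMeans)
  .new_as_image(m, stack$pixel_size, stack$frame_times,
                provenance = sprintf("single:%d", stack$imager_id))
}

#' Superimpose two Amsterdam Shroud images
#'
#' Registers the diaphragm content of the second image to the first in the
#' SI direction by the integer row shift maximizing the cross-correlation of
#' the time-averaged row profiles, then averages element-wise over the
#' overlapping rows.
#'
#' @param as1,as2 \code{as_image} objects with equal column counts and row
#'   pitch.
#' @param max_shift Largest row shift searched (default 50).
#' @return An \code{as_image} restricted to the overlap; the applied shift
#'   is stored in attribute \code{"shift"}.
#' @export
superimpose_as <- function(as1, as2, max_shift = 50L) {
  stopifnot(inherits(as1, "as_image"), inherits(as2, "as_image"))
  m1 <- as1$matrix; m2 <- as2$matrix
  if (ncol(m1) != ncol(m2)) .stopf("mismatched frame counts")
  if (as1$row_pitch != as2$row_pitch) .stopf("mismatched row pitch")
  h <- nrow(m1)
  p1 <- rowMeans(m1); p2 <- rowMeans(m2)
  shifts <- seq.int(-min(max_shift, h - 2L), min(max_shift, h - 2L))
  score <- vapply(shifts, function(s) {
    r1 <- seq.int(max(1L, 1L + s), min(h, h + s))
    a <- p1[r1]; b <- p2[r1 - s]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(-Inf)
    stats::cor(a, b)
  }, numeric(1L))
  s <- shifts[which.max(score)]
  rows <- seq.int(max(1L, 1L + s), min(h, h + s))
  out <- .new_as_image((m1[rows, , drop = FALSE] +
                        m2[rows - s, , drop = FALSE]) / 2,
                       as1$row_pitch, as1$frame_times, provenance = "dual",
                       row_offset = as1$row_offset + rows[1L] - 1L)
  attr(out, "shift") <- s
  out
}

#' Trim an Amsterdam Shroud image to the band around the diaphragm trace
#'
#' @param as An \code{as_image}.
#' @param band Integer range \code{c(first_row, last_row)} to retain, or
#'   \code{"auto"}: the row of maximum temporal variance plus/minus
#'   \code{margin} rows (clipped to the image).
#' @param margin Half-height of the auto band in rows.
#' @return The trimmed \code{as_image}; \code{row_offset} records the
#'   original index of the first retained row.
#' @export
trim_as <- function(as, band = "auto", margin = 25L) {
  stopifnot(inherits(as, "as_image"))
  h <- nrow(as$matrix)
  if (identical(band, "auto")) {
    v <- apply(as$matrix, 1L, stats::var)
    center <- which.max(v)
    band <- c(max(1L, center - margin), min(h, center + margin))
  }
  band <- as.integer(band)
  if (length(band) != 2L || band[1L] > band[2L] ||
      band[1L] < 1L || band[2L] > h)
    .stopf("empty or out-of-range band")
  out <- .new_as_image(as$matrix[band[1L]:band[2L], , drop = FALSE],
                       as$row_pitch, as$frame_times, as$provenance,
                       row_offset = as$row_offset + band[1L] - 1L)
  out
}

# Per-column ridge row: intensity centroid weighted by squared deviation
# from the image median, robust to the sign and offset of the ridge
# contrast.  Increases when the diaphragm moves inferiorly; used as the
# default sign reference for the PCA waveform.
.ridge_centroid <- function(m) {
  wgt <- (m - stats::median(m))^2
  rows <- seq_len(nrow(m))
  tot <- colSums(wgt)
  tot[tot == 0] <- 1
  colSums(wgt * rows) / tot
}

# Moving minimum with edge replication (alternative reading of the "LM map").
.min_filter <- function(mat, window) {
  half <- (window - 1L) %/% 2L
  run1d <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1L], half), v, rep(v[n], half))
    vapply(seq_len(n), function(i) min(vp[i:(i + window - 1L)]), numeric(1L))
  }
  out <- apply(mat, 2L, run1d)
  t(apply(out, 1L, run1d))
}

#' Locally normalize an Amsterdam Shroud image
#'
#' Subtracts a local-statistic map (moving window, default the local mean)
#' and applies clip-limited tile-based histogram equalization,
#' approximately equalizing the mean and variance of pixel values across
#' local regions. Each tile's values are mapped to (0, 1) by a blend of
#' the tile's empirical distribution (average ranks) and a clipped linear
#' standardization (tile mean to 0.5, clamped at 3 tile SDs); the clip
#' factor is the weight of the linear part, mirroring how clipping a
#' histogram redistributes mass uniformly. A tile with no spread maps to a
#' constant 0.5.
#'
#' @param as An \code{as_image}.
#' @param window Odd window size (pixels, >= 3) of the local-statistic map;
#'   clamped to the image when larger.
#' @param statistic \code{"mean"} (default) or \code{"min"} for the
#'   subtracted map.
#' @param tile_rows,tile_cols Tile grid for equalization; defaults to 8
#'   tiles along each axis (tile height about 1/8 of the trimmed image).
#' @param clip Weight in [0, 1] of the clipped linear stretch versus the
#'   pure rank equalization (0 = plain equalization, 1 = linear stretch).
#' @return The normalized \code{as_image} with values in [0, 1].
#' @export
local_normalize <- function(as, window = 101L,
                            statistic = c("mean", "min"),
                            tile_rows = 8L, tile_cols = 8L, clip = 0.9) {
  stopifnot(inherits(as, "as_image"))
  statistic <- match.arg(statistic)
  m <- as$matrix
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 3L)
    .stopf("window must be odd and >= 3")
  if (window > nrow(m) || window > ncol(m))
    .stopf("window (%d) larger than image (%d x %d)",
           window, nrow(m), ncol(m))
  lm_map <- if (statistic == "mean") .box_filter(m, window)
            else .min_filter(m, window)
  sub <- m - lm_map

  h <- nrow(sub); w <- ncol(sub)
  rb <- ceiling(seq_len(h) / (h / min(tile_rows, h)))
  cb <- ceiling(seq_len(w) / (w / min(tile_cols, w)))
  out <- sub
  for (i in unique(rb)) {
    ri <- which(rb == i)
    for (j in unique(cb)) {
      cj <- which(cb == j)
      tile <- sub[ri, cj]
      n <- length(tile)
      u_rank <- (rank(tile, ties.method = "average") - 0.5) / n
      s <- stats::sd(tile)
      u_lin <- if (s == 0) rep(0.5, n)
               else pmin(pmax(0.5 + (tile - mean(tile)) / (6 * s), 0), 1)
      out[ri, cj] <- (1 - clip) * u_rank + clip * u_lin
    }
  }
  .new_as_image(out, as$row_pitch, as$frame_times, as$provenance,
                as$row_offset)
}

#' Extract the respiratory waveform from a normalized shroud image
#'
#' Principal component analysis along the vertical direction: columns
#' (frames) are the observations, rows the features; the first
#' principal-component score per frame is the waveform. The PCA sign is
#' arbitrary, so it is fixed so that the waveform correlates positively
#' with a reference trace: by default the per-column intensity-weighted
#' centroid row, which increases when the diaphragm moves inferiorly.
#'
#' @param as_norm A (normalized) \code{as_image} with at least 2 frames.
#' @param reference Optional numeric reference trace (one value per frame)
#'   replacing the centroid-row default.
#' @return An object of class \code{as_waveform}: \code{samples} (arbitrary
#'   units), \code{frame_times}, \code{sign_convention} (+1 = inferior
#'   diaphragm displacement).
#' @export
extract_as_waveform <- function(as_norm, reference = NULL) {
  stopifnot(inherits(as_norm, "as_image"))
  m <- as_norm$matrix
  if (ncol(m) < 2L) .stopf("need at least 2 frames")
  if (all(apply(m, 1L, stats::sd) == 0))
    .stopf("zero-variance image: no waveform to extract")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE, rank. = 1L)
  s <- pc$x[, 1L]
  if (is.null(reference)) reference <- .ridge_centroid(m)
  if (stats::sd(reference) > 0 && stats::sd(s) > 0 &&
      stats::cor(s, reference) < 0) s <- -s
  structure(list(samples = unname(s), frame_times = as_norm$frame_times,
                 sign_convention = +1L),
            class = "as_waveform")
}

#' Run the full shroud pipeline on one or two projection stacks
#'
#' Convenience wrapper: build the AS image per stack, superimpose when two
#' stacks are given, smooth vertically, trim to the band of appreciable
#' temporal variance, locally normalize, and extract the waveform. The
#' vertical moving-average smoothing suppresses pixel noise and broadens
#' the diaphragm response so that the first principal component varies
#' linearly with its displacement; the trim band is the contiguous row span
#' whose temporal variance exceeds 2\% of the maximum, expanded by
#' \code{margin} rows. The PCA sign reference is the ridge-centroid trace
#' of the trimmed (pre-normalization) image.
#'
#' @param stacks A single \code{projection_stack} or a list of one or two.
#' @param frames Optional integer vector of 1-based frame (column) indices
#'   to retain before trimming (e.g. the training window).
#' @param smooth Odd width (rows) of the vertical moving-average filter.
#' @param margin Rows added on each side of the variance-support band.
#' @param window,statistic,clip Passed to \code{\link{local_normalize}}
#'   (the window is clamped to the trimmed image).
#' @return An \code{as_waveform}.
#' @export
extract_as_signal <- function(stacks, frames = NULL, smooth = 61L,
                              margin = 20L, window = 101L,
                              statistic = "mean", clip = 0.9) {
  if (inherits(stacks, "projection_stack")) stacks <- list(stacks)
  imgs <- lapply(stacks, make_as_image)
  img <- if (length(imgs) == 2L) superimpose_as(imgs[[1L]], imgs[[2L]])
         else imgs[[1L]]
  if (!is.null(frames)) {
    img$matrix <- img$matrix[, frames, drop = FALSE]
    img$frame_times <- img$frame_times[frames]
  }
  if (smooth > 1L) {
    smooth <- min(smooth, nrow(img$matrix))
    if (smooth %% 2L == 0L) smooth <- smooth - 1L
    img$matrix <- apply(img$matrix, 2L, .box_1d, window = smooth)
  }
  v <- apply(img$matrix, 1L, stats::var)
  sup <- range(which(v >= 0.02 * max(v)))
  band <- c(max(1L, sup[1L] - margin),
            min(nrow(img$matrix), sup[2L] + margin))
  img <- trim_as(img, band)
  ref <- .ridge_centroid(img$matrix)
  win <- min(window, nrow(img$matrix) - 1L, ncol(img$matrix) - 1L)
  if (win %% 2L == 0L) win <- win - 1L
  img <- local_normalize(img, window = win, statistic = statistic,
                         clip = clip)
  extract_as_waveform(img, reference = ref)
}

#' @export
print.as_image <- function(x, ...) {
  cat(sprintf("AS image: %d rows x %d frames (%s, row offset %d)\n",
              nrow(x$matrix), ncol(x$matrix), x$provenance, x$row_offset))
  invisible(x)
}
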