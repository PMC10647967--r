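# Quadratic position-velocity surrogate regression:
# F(x, v) = a x^2 + b x + c + d v^2 + e v, fitted per IR marker per target
# direction by ordinary least squares; a single representative model is the
# element-wise mean of the per-marker parameter sets, and predictions are
# made from the across-marker mean position and velocity.

#' Estimate surrogate velocity from a position trace
#'
#' Central differences \code{(x[t+1] - x[t-1]) / (2 dt)} on a uniform grid,
#' one-sided differences at the ends.
#'
#' @param x Numeric position trace in mm (>= 3 samples), or a matrix
#'   (columns processed independently).
#' @param dt Sampling interval, seconds.
#' @param time Optional sample times; if given, the grid must be uniform.
#' @return Velocity in mm/s, same shape as \code{x}.
#' @export
compute_velocity <- function(x, dt = 0.2, time = NULL) {
  if (!is.null(time)) {
    dts <- diff(time)
    if (max(abs(dts - dts[1L])) > 1e-8 * dts[1L])
      .stopf("non-uniform sampling grid")
    dt <- dts[1L]
  }
  if (is.matrix(x))
    return(apply(x, 2L, compute_velocity, dt = dt))
  n <- length(x)
  if (n < 3L) .stopf("need at least 3 samples")
  v <- numeric(n)
  v[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * dt)
  v[1L] <- (x[2L] - x[1L]) / dt
  v[n] <- (x[n] - x[n - 1L]) / dt
  v
}

#' Fit quadratic position-velocity prediction models
#'
#' For each IR marker, fits \code{F(x, v) = a x^2 + b x + c + d v^2 + e v}
#' by ordinary least squares between the marker's AP position/velocity and
#' each target direction. The representative model is the element-wise mean
#' of the per-marker parameter sets.
#'
#' @param ir_traces n x m matrix of IR-marker AP positions (mm), one column
#'   per marker, on the training grid.
#' @param target n x d matrix of target positions (mm), columns LR/SI/AP.
#' @param dt Sampling interval, seconds.
#' @return An object of class \code{pm_parameters}: \code{coef} (5 x d
#'   representative parameters, rows a, b, c, d, e), \code{per_marker}
#'   (5 x d x m array), \code{n_markers}, \code{dt}.
#' @export
fit_pm <- function(ir_traces, target, dt = 0.2) {
  if (is.null(dim(ir_traces))) ir_traces <- matrix(ir_traces, ncol = 1L)
  if (is.null(dim(target))) target <- matrix(target, ncol = 1L)
  n <- nrow(ir_traces)
  if (nrow(target) != n) .stopf("trace and target lengths differ")
  if (n < 5L) .stopf("need at least 5 samples to fit 5 parameters")
  m <- ncol(ir_traces); d <- ncol(target)
  per <- array(NA_real_, dim = c(5L, d, m),
               dimnames = list(c("a", "b", "c", "d", "e"),
                               colnames(target), NULL))
  for (k in seq_len(m)) {
    x <- ir_traces[, k]
    v <- compute_velocity(x, dt)
    X <- cbind(x^2, x, 1, v^2, v)
    qrX <- qr(X)
    if (qrX$rank < 5L) {
      deg <- if (stats::sd(x) == 0) "position (x) is constant"
             else if (stats::sd(v) == 0) "velocity (v) is constant"
             else "collinear position/velocity regressors"
      .stopf("rank-deficient design for marker %d: %s", k, deg)
    }
    per[, , k] <- qr.coef(qrX, target)
  }
  coef <- apply(per, c(1L, 2L), mean)
  structure(list(coef = coef, per_marker = per, n_markers = m, dt = dt),
            class = "pm_parameters")
}

#' Predict target positions from IR-marker traces
#'
#' The across-marker mean position and velocity are fed to the
#' representative model: the prediction per direction is
#' \code{F(mean(x), mean(v))}.
#'
#' @param object A fitted \code{\link{fit_pm}} model.
#' @param ir_traces n x m matrix of IR-marker AP positions, mm.
#' @param ... Unused.
#' @return n x d matrix of predicted target positions, mm.
#' @export
predict.pm_parameters <- function(object, ir_traces, ...) {
  if (is.null(dim(ir_traces))) ir_traces <- matrix(ir_traces, ncol = 1L)
  if (ncol(ir_traces) != object$n_markers)
    warning(sprintf("model fitted with %d markers, predicting from %d; %s",
                    object$n_markers, ncol(ir_traces),
                    "only the averaged input is used"), call. = FALSE)
  x <- rowMeans(ir_traces)
  v <- compute_velocity(x, object$dt)
  X <- cbind(x^2, x, 1, v^2, v)
  out <- X %*% object$coef
  colnames(out) <- colnames(object$coef)
  out
}

#' @export
print.pm_parameters <- function(x, ...) {
  cat(sprintf("Quadratic position-velocity PM (%d marker%s averaged)\n",
              x$n_markers, if (x$n_markers > 1L) "s" else ""))
  print(round(x$coef, 5))
  invisible(x)
}
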