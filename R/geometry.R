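#' Build a gantry acquisition schedule
#'
#' Frames are acquired at a fixed angular interval while the gantry rotates
#' at constant speed, as in rotational kV imaging for 4D-CBCT: the frame
#' count is \code{floor(duration * speed / interval) + 1} (the initial frame
#' is included) and frame times are \code{index * interval / speed}.
#'
#' @param speed Gantry rotation speed in degrees/s (> 0). Default 1.5.
#' @param duration Acquisition duration in seconds (>= 0). Default 70.
#' @param interval Angular spacing between frames in degrees (> 0).
#'   Default 0.3.
#' @param start_angle Gantry angle of the first frame in degrees.
#'   Default 320 (left-lung clockwise arc preset).
#' @param direction \code{"clockwise"} (increasing angle) or
#'   \code{"counterclockwise"}.
#' @return An object of class \code{gantry_schedule}: a data frame with
#'   columns \code{frame} (0-based index), \code{time_s} and
#'   \code{angle_deg} (reduced modulo 360), with the acquisition parameters
#'   stored as attributes.
#' @examples
#' sched <- build_schedule(1.5, 70, 0.3)
#' nrow(sched)            # 351 frames
#' @export
build_schedule <- function(speed = 1.5, duration = 70, interval = 0.3,
                           start_angle = 320,
                           direction = c("clockwise", "counterclockwise")) {
  direction <- match.arg(direction)
  .check_scalar(speed, "speed", positive = TRUE)
  .check_scalar(interval, "interval", positive = TRUE)
  .check_scalar(duration, "duration", nonneg = TRUE)
  .check_scalar(start_angle, "start_angle")
  n <- .fp_floor(duration * speed / interval) + 1L
  idx <- seq_len(n) - 1L
  sgn <- if (direction == "clockwise") 1 else -1
  sched <- data.frame(
    frame = idx,
    time_s = idx * interval / speed,
    angle_deg = (start_angle + sgn * idx * interval) %% 360
  )
  attr(sched, "speed") <- speed
  attr(sched, "interval") <- interval
  attr(sched, "direction") <- direction
  attr(sched, "start_angle") <- start_angle
  class(sched) <- c("gantry_schedule", "data.frame")
  sched
}

#' Imager geometry for an orthogonal kV pair
#'
#' Describes one flat-panel imager rotating in sync with the gantry. The
#' detector vertical axis is superior-inferior (SI); the horizontal axis
#' lies in the LR/AP plane at \code{angular_offset} degrees from the gantry
#' reference. The two imagers of an orthogonal pair have offsets 90 degrees
#' apart.
#'
#' @param imager_id 1 or 2.
#' @param angular_offset Offset in degrees from the gantry angle; defaults
#'   to 0 for imager 1 and 90 for imager 2.
#' @return An object of class \code{imager_geometry}.
#' @export
imager_geometry <- function(imager_id, angular_offset = NULL) {
  if (!imager_id %in% c(1L, 2L)) .stopf("imager_id must be 1 or 2")
  if (is.null(angular_offset))
    angular_offset <- if (imager_id == 1L) 0 else 90
  structure(list(imager_id = as.integer(imager_id),
                 angular_offset = angular_offset),
            class = "imager_geometry")
}

#' Project a 3D point onto an imager
#'
#' Ideal parallel-ray (orthographic) model: the detector vertical coordinate
#' \code{v} equals the SI coordinate, and the horizontal coordinate \code{u}
#' is the in-plane LR/AP component along the imager axis at the current
#' gantry angle.
#'
#' @param p Numeric length-3 vector (LR, SI, AP) in mm, or an n x 3 matrix.
#' @param angle Gantry angle in degrees (scalar or length n).
#' @param geom An \code{\link{imager_geometry}}.
#' @return A numeric vector \code{c(u, v)} in mm, or an n x 2 matrix.
#' @export
project_point <- function(p, angle, geom) {
  stopifnot(inherits(geom, "imager_geometry"))
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  if (ncol(p) != 3L) .stopf("p must have 3 columns (LR, SI, AP)")
  if (!all(is.finite(p))) .stopf("coordinates must be finite")
  a <- (angle + geom$angular_offset) * pi / 180
  u <- p[, 1L] * cos(a) + p[, 3L] * sin(a)
  out <- cbind(u = u, v = p[, 2L])
  if (nrow(out) == 1L) drop(out) else out
}

#' Triangulate a 3D position from paired 2D detections
#'
#' Recovers the 3D fiducial position from simultaneous detections on two
#' imagers at the same gantry angle by least squares: the SI component is
#' the mean of the two vertical detections, and the LR/AP components solve
#' the 2 x 2 in-plane system. With exact orthogonal detections the residual
#' is zero.
#'
#' @param det1,det2 Length-2 vectors \code{c(u, v)} in mm from imagers 1
#'   and 2 (same frame).
#' @param angle Gantry angle in degrees of that frame.
#' @param geoms List of the two \code{\link{imager_geometry}} objects.
#' @return Numeric length-3 vector (LR, SI, AP) in mm.
#' @export
triangulate <- function(det1, det2, angle, geoms) {
  stopifnot(length(det1) == 2L, length(det2) == 2L, length(geoms) == 2L)
  a1 <- (angle + geoms[[1L]]$angular_offset) * pi / 180
  a2 <- (angle + geoms[[2L]]$angular_offset) * pi / 180
  A <- rbind(c(cos(a1), sin(a1)),
             c(cos(a2), sin(a2)))
  if (abs(det(A)) < 1e-8)
    .stopf("rank-deficient geometry: imager axes are not distinct")
  q <- solve(A, c(det1[1L], det2[1L]))
  c(LR = q[1L], SI = (det1[2L] + det2[2L]) / 2, AP = q[2L])
}

#' @export
print.gantry_schedule <- function(x, ...) {
  cat(sprintf(
    "Gantry schedule: %d frames, %.3g deg/s, %.3g deg interval, %s from %g deg\n",
    nrow(x), attr(x, "speed"), attr(x, "interval"),
    attr(x, "direction"), attr(x, "start_angle")))
  invisible(x)
}
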