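# Synthetic respiratory acquisition simulator: quasi-periodic breathing
# traces, external IR surrogate markers, 3D fiducial trajectories, diaphragm
# motion and projection images with a rendered diaphragm edge.  Provides
# ground truth for closed-loop testing of the whole pipeline.

# Evaluate an expression under a fixed seed without touching the caller's
# RNG stream; seeds are explicit fields, never global state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# cos^(2n) breathing profile: 1 at integer phase (end-inhalation extreme of
# the driving function), a wide flat plateau around half-integer phase
# (end-exhalation).  Position traces subtract this, so end-inhalation is a
# local minimum with a steep approach and end-exhalation a flat plateau.
.breathing_shape <- function(phase, n) cos(pi * phase)^(2 * n)

#' Breathing and acquisition parameters for the simulator
#'
#' Defaults emulate the motion statistics typical of free-breathing lung
#' cancer patients: breathing cycles around 3.7 s (3.0-4.5 s), fiducial
#' peak-to-trough amplitudes of about 11.4 mm SI, 3.3 mm AP and 1.7 mm LR,
#' abdominal IR-marker AP amplitudes of about 6.2 mm, with optional baseline
#' drift of the external surrogate.
#'
#' @param mean_period Mean respiratory cycle length in seconds (> 0).
#' @param period_sd Cycle-to-cycle SD of the period in seconds (>= 0).
#' @param amplitude Named length-3 vector, peak-to-trough target amplitude
#'   in mm for LR, SI, AP (all >= 0).
#' @param ir_amplitude Mean peak-to-trough AP amplitude of the IR markers
#'   in mm; individual markers scatter around it.
#' @param n_ir_markers Number of abdominal IR markers (default 4).
#' @param shape_exponent Exponent n of the cos^(2n) profile; larger n gives
#'   a flatter end-exhalation plateau and a steeper end-inhalation extreme.
#' @param drift_rate Baseline drift of the IR markers in mm/min (positive =
#'   posterior).
#' @param noise_sd Additive Gaussian noise SD on the IR traces, mm.
#' @param phase_lag Lag of the external surrogate behind the internal
#'   motion, as a fraction of a cycle.
#' @param correlation_sign Named length-3 vector of +1/-1: sign of the
#'   correlation of each target axis with the diaphragm SI motion. LR and
#'   AP target motion is often negatively correlated with the diaphragm,
#'   hence the LR default of -1.
#' @param diaphragm_scale Ratio of diaphragm SI excursion to target SI
#'   amplitude (diaphragm excursions exceed tumor excursions).
#' @param proj_noise_sd Gaussian pixel-noise SD of rendered projections, as
#'   a fraction of the edge contrast.
#' @param seed Integer seed; identical parameters and seed give a
#'   bit-identical case.
#' @return An object of class \code{breathing_params}.
#' @export
breathing_params <- function(mean_period = 3.7,
                             period_sd = 0.3,
                             amplitude = c(LR = 1.7, SI = 11.4, AP = 3.3),
                             ir_amplitude = 6.2,
                             n_ir_markers = 4L,
                             shape_exponent = 2,
                             drift_rate = 0,
                             noise_sd = 0.1,
                             phase_lag = 0,
                             correlation_sign = c(LR = -1, SI = 1, AP = 1),
                             diaphragm_scale = 1.5,
                             proj_noise_sd = 0,
                             seed = 1L) {
  .check_scalar(mean_period, "mean_period", positive = TRUE)
  .check_scalar(period_sd, "period_sd", nonneg = TRUE)
  .check_scalar(ir_amplitude, "ir_amplitude", nonneg = TRUE)
  .check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  .check_scalar(shape_exponent, "shape_exponent", positive = TRUE)
  if (length(amplitude) != 3L || any(amplitude < 0))
    .stopf("amplitude must be 3 non-negative values (LR, SI, AP)")
  names(amplitude) <- c("LR", "SI", "AP")
  if (length(correlation_sign) != 3L || !all(abs(correlation_sign) == 1))
    .stopf("correlation_sign must be three values in {-1, +1}")
  names(correlation_sign) <- c("LR", "SI", "AP")
  structure(list(mean_period = mean_period, period_sd = period_sd,
                 amplitude = amplitude, ir_amplitude = ir_amplitude,
                 n_ir_markers = as.integer(n_ir_markers),
                 shape_exponent = shape_exponent, drift_rate = drift_rate,
                 noise_sd = noise_sd, phase_lag = phase_lag,
                 correlation_sign = correlation_sign,
                 diaphragm_scale = diaphragm_scale,
                 proj_noise_sd = proj_noise_sd,
                 seed = as.integer(seed)),
            class = "breathing_params")
}

# Draw per-cycle periods and build the piecewise-linear phase function on the
# 0.2 s grid.  Returns phase(t), ground-truth cycle-start times and periods.
.simulate_phase <- function(params, t_max, start_phase = 0) {
  periods <- numeric(0)
  total <- -start_phase * params$mean_period
  while (total < t_max + 2 * params$mean_period) {
    p <- stats::rnorm(1L, params$mean_period, params$period_sd)
    while (p < 0.25 * params$mean_period)
      p <- stats::rnorm(1L, params$mean_period, params$period_sd)
    periods <- c(periods, p)
    total <- total + p
  }
  starts <- -start_phase * periods[1L] + c(0, cumsum(periods[-length(periods)]))
  phase_fun <- function(t) {
    j <- findInterval(t, starts)
    j <- pmax(j, 1L)
    (j - 1) + (t - starts[j]) / periods[j]
  }
  list(phase = phase_fun, cycle_starts = starts, periods = periods)
}

#' Simulate a quasi-periodic breathing trace
#'
#' Generates \code{s(t) = baseline - A cos^(2n)(pi phase(t)) + drift t +
#' noise} on the 0.2 s sampling grid, with per-cycle periods drawn around
#' \code{mean_period}. End-inhalation (integer phase) is a local minimum of
#' the noiseless component and each cycle contains exactly one.
#'
#' @param params A \code{\link{breathing_params}} object (the SI amplitude
#'   and trace noise are used).
#' @param n_frames Number of samples (>= 2).
#' @param dt Sampling interval, s.
#' @return A list of class \code{breathing_trace}: \code{time},
#'   \code{samples} (mm), \code{cycle_starts} (ground-truth end-inhalation
#'   times, s), \code{cycle_start_frames} (0-based indices), \code{periods}.
#' @export
simulate_breathing <- function(params, n_frames, dt = 0.2) {
  stopifnot(inherits(params, "breathing_params"))
  if (n_frames < 2L) .stopf("n_frames must be >= 2")
  .with_seed(params$seed, {
    time <- (seq_len(n_frames) - 1L) * dt
    start_phase <- stats::runif(1L)
    ph <- .simulate_phase(params, max(time), start_phase)
    a <- params$amplitude[["SI"]]
    clean <- -a * .breathing_shape(ph$phase(time), params$shape_exponent)
    samples <- clean + params$drift_rate * time / 60 +
      stats::rnorm(n_frames, 0, params$noise_sd)
    cs <- ph$cycle_starts[ph$cycle_starts >= 0 & ph$cycle_starts <= max(time)]
    structure(list(time = time, samples = samples,
                   cycle_starts = cs,
                   cycle_start_frames = round(cs / dt),
                   periods = ph$periods),
              class = "breathing_trace")
  })
}

#' Render one projection frame with a diaphragm edge
#'
#' Produces a grayscale frame whose intensity falls from a bright cranial
#' (lung) region to a dark caudal (abdomen) region across the diaphragm,
#' with a linear transition of configurable width so that the edge position
#' is defined to sub-pixel accuracy. Optional smooth anatomy texture and
#' Gaussian noise are added; pixel values stay positive so the log transform
#' of the shroud pipeline is defined.
#'
#' @param diaphragm_row Edge position in pixel rows (fractional allowed).
#' @param angle Gantry angle, degrees (modulates the anatomy texture).
#' @param image_shape \code{c(rows, cols)}.
#' @param noise_sd Gaussian noise SD in intensity units.
#' @param hi,lo Intensities above/below the edge.
#' @param edge_width Transition width in pixels. The default 80 px (16 mm
#'   at 0.2 mm/px) approximates the gradual attenuation change across the
#'   projected dome apex of the diaphragm.
#' @param shape \code{"cosine"} (raised-cosine transition, default) or
#'   \code{"linear"} (straight ramp).
#' @param texture_amp Amplitude of the smooth low-frequency texture.
#' @return A \code{rows x cols} intensity matrix.
#' @export
render_projection <- function(diaphragm_row, angle = 0,
                              image_shape = c(256L, 256L), noise_sd = 0,
                              hi = 0.95, lo = 0.2, edge_width = 80,
                              shape = c("cosine", "linear"),
                              texture_amp = 0) {
  shape <- match.arg(shape)
  h <- image_shape[1L]; w <- image_shape[2L]
  r <- seq_len(h)
  # high->low transition centred on the (possibly fractional) edge row
  frac <- (r - (diaphragm_row - edge_width / 2)) / edge_width
  frac <- pmin(pmax(frac, 0), 1)
  if (shape == "cosine") frac <- (1 - cos(pi * frac)) / 2
  col_profile <- hi - (hi - lo) * frac
  img <- matrix(col_profile, nrow = h, ncol = w)
  if (texture_amp > 0) {
    tex <- texture_amp *
      outer(sin(2 * pi * r / h + angle * pi / 180),
            cos(2 * pi * seq_len(w) / w))
    img <- img + tex
  }
  if (noise_sd > 0)
    img <- img + matrix(stats::rnorm(h * w, 0, noise_sd), h, w)
  # detector signal normalized to (0, 1]; bright extremes saturate
  pmin(pmax(img, 1e-3), 1)
}

#' Simulate a full synthetic acquisition case
#'
#' Drives all signals from one quasi-periodic breathing phase: the target
#' SI trace follows the breathing profile, LR/AP are scaled copies with the
#' configured correlation signs, the diaphragm SI motion is a scaled target
#' SI, the IR markers follow the (optionally lagged) external phase with
#' independent noise and baseline drift, and projection frames with the
#' diaphragm edge are rendered per imager. Fiducial 2D detections are ideal
#' projections of the true 3D positions.
#'
#' @param params A \code{\link{breathing_params}}.
#' @param schedule A \code{\link{build_schedule}} result.
#' @param imagers 2 (orthogonal pair) or 1.
#' @param image_shape \code{c(rows, cols)} of rendered projections.
#' @param pixel_size mm per pixel at the isocenter plane.
#' @param edge_width Diaphragm transition width in pixels (see
#'   \code{\link{render_projection}}).
#' @param render Logical; set \code{FALSE} to skip projection rendering when
#'   only waveforms are needed.
#' @return An object of class \code{synthetic_case}: \code{time},
#'   \code{true_target} (n x 3, mm), \code{diaphragm_si} (mm, superior
#'   positive), \code{ir_traces} (n x markers, mm AP), \code{projections}
#'   (list of \code{projection_stack}), \code{detections} (list of n x 2
#'   matrices, mm), \code{diaphragm_row} (true edge rows), plus the inputs.
#' @export
simulate_case <- function(params, schedule = build_schedule(),
                          imagers = 2L, image_shape = c(256L, 256L),
                          pixel_size = 0.2, edge_width = 80,
                          render = TRUE) {
  stopifnot(inherits(params, "breathing_params"),
            inherits(schedule, "gantry_schedule"))
  n <- nrow(schedule)
  dt <- schedule$time_s[2L] - schedule$time_s[1L]
  .with_seed(params$seed, {
    time <- schedule$time_s
    start_phase <- stats::runif(1L)
    ph <- .simulate_phase(params, max(time), start_phase)
    u_int <- .breathing_shape(ph$phase(time), params$shape_exponent)
    u_ext <- .breathing_shape(
      ph$phase(time - params$phase_lag * params$mean_period),
      params$shape_exponent)

    amp <- params$amplitude; cs <- params$correlation_sign
    target <- cbind(LR = -cs[["LR"]] * amp[["LR"]] * u_int,
                    SI = -cs[["SI"]] * amp[["SI"]] * u_int,
                    AP = -cs[["AP"]] * amp[["AP"]] * u_int)

    dia <- -params$diaphragm_scale * amp[["SI"]] * u_int

    m <- params$n_ir_markers
    scales <- stats::runif(m, 0.9, 1.1)   # inter-marker amplitude scatter
    ir <- sapply(seq_len(m), function(k) {
      -scales[k] * params$ir_amplitude * u_ext +
        params$drift_rate * time / 60 +
        stats::rnorm(n, 0, params$noise_sd)
    })
    colnames(ir) <- paste0("IR", seq_len(m))

    geoms <- list(imager_geometry(1L), imager_geometry(2L))[seq_len(imagers)]
    detections <- lapply(geoms, function(g)
      project_point(target, schedule$angle_deg, g))

    projections <- NULL
    dia_row <- NULL
    if (render) {
      h <- image_shape[1L]
      excursion_px <- params$diaphragm_scale * amp[["SI"]] / pixel_size
      row0 <- round(h * 0.4)
      if (row0 + excursion_px + edge_width / 2 > h - 1 ||
          row0 - edge_width / 2 < 2)
        .stopf("diaphragm excursion (%.1f px) exceeds the field of view",
               excursion_px)
      dia_row <- row0 - dia / pixel_size   # inferior motion = larger row
      projections <- lapply(geoms, function(g) {
        frames <- array(0, dim = c(h, image_shape[2L], n))
        for (i in seq_len(n)) {
          frames[, , i] <- render_projection(
            dia_row[i], schedule$angle_deg[i], image_shape,
            noise_sd = params$proj_noise_sd * 0.8,  # contrast hi-lo = 0.8
            edge_width = edge_width, texture_amp = 0.03)
        }
        structure(list(frames = frames, pixel_size = pixel_size,
                       imager_id = g$imager_id,
                       frame_times = time, angles = schedule$angle_deg),
                  class = "projection_stack")
      })
    }

    structure(list(time = time, dt = dt, true_target = target,
                   diaphragm_si = dia, ir_traces = ir,
                   projections = projections, detections = detections,
                   diaphragm_row = dia_row,
                   cycle_starts = ph$cycle_starts[
                     ph$cycle_starts >= 0 & ph$cycle_starts <= max(time)],
                   schedule = schedule, geoms = geoms, params = params),
              class = "synthetic_case")
  })
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf(
    "Synthetic acquisition: %d frames (%.1f s), %d IR markers, %s imager(s)\n",
    length(x$time), max(x$time), ncol(x$ir_traces),
    if (is.null(x$projections)) "no rendered" else length(x$projections)))
  invisible(x)
}
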