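# Scenario assembly, prediction-error metrics, baseline-drift statistic and
# the matching-parameter grid report.

.scenario_ids <- c("CL", "4D-CBCT", "AS-4D-CBCT-dual",
                   "AS-4D-CBCT-single1", "AS-4D-CBCT-single2")

# Triangulated per-frame gold-marker positions (falls back to the true
# trajectory when only one imager's detections exist).
.gold_marker_waveform <- function(case) {
  if (length(case$detections) >= 2L) {
    n <- length(case$time)
    t(vapply(seq_len(n), function(i)
      triangulate(case$detections[[1L]][i, ], case$detections[[2L]][i, ],
                  case$schedule$angle_deg[i], case$geoms),
      numeric(3L)))
  } else {
    case$true_target
  }
}

# Shared training/testing bookkeeping for scenarios and the grid report.
.scenario_inputs <- function(case, train_end = 301L, min_separation = 2.0) {
  n <- length(case$time)
  if (train_end + 1L >= n) .stopf("training window covers the whole case")
  ti <- seq_len(train_end + 1L)              # frames 0..train_end
  si <- (train_end + 2L):n                   # held-out short-term window
  wgm <- .gold_marker_waveform(case)
  colnames(wgm) <- c("LR", "SI", "AP")
  ir_avg <- rowMeans(case$ir_traces)
  seg <- detect_local_minima(ir_avg, min_separation, dt = case$dt,
                             frame_range = c(0L, train_end))
  list(n = n, ti = ti, si = si, wgm = wgm,
       ir_train = case$ir_traces[ti, , drop = FALSE],
       ir_test = case$ir_traces[si, , drop = FALSE],
       seg = seg, dt = case$dt)
}

.shrink <- function(w, factor) {
  if (factor == 1) return(w)
  ctr <- matrix(colMeans(w), nrow(w), ncol(w), byrow = TRUE)
  ctr + factor * (w - ctr)
}

# Training target per scenario; AS waveform may be supplied precomputed.
.training_target <- function(inp, scenario, case, params, amplitude_shrink,
                             w_as = NULL, min_separation = 2.0) {
  wgm_train <- inp$wgm[inp$ti, , drop = FALSE]
  if (scenario == "CL") return(wgm_train)
  cyc <- phase_sort(wgm_train, inp$seg)
  w4d <- .shrink(tile_waveform(cyc, inp$seg, length(inp$ti)),
                 amplitude_shrink)
  if (scenario == "4D-CBCT") return(w4d)
  if (is.null(w_as)) {
    stacks <- switch(scenario,
      "AS-4D-CBCT-dual" = {
        if (length(case$projections) < 2L)
          .stopf("dual-imager scenario requires two projection stacks")
        case$projections
      },
      "AS-4D-CBCT-single1" = case$projections[1L],
      "AS-4D-CBCT-single2" = {
        if (length(case$projections) < 2L)
          .stopf("imager 2 stack not available")
        case$projections[2L]
      })
    w_as <- extract_as_signal(stacks, frames = inp$ti)
  }
  corr <- correct_waveform(w4d, w_as, params,
                           min_separation = min_separation, dt = inp$dt)
  corr$samples
}

#' Run one prediction-model scenario on a case
#'
#' Builds the scenario's training target waveform, fits the quadratic
#' position-velocity model on the training window, predicts on the
#' evaluation window and computes prediction-error metrics against the
#' actual gold-marker positions. Scenarios: \code{"CL"} (clinical: the
#' per-frame triangulated gold-marker waveform is used as-is),
#' \code{"4D-CBCT"} (the 8-phase tiled short-arc waveform),
#' \code{"AS-4D-CBCT-dual"} (shroud-corrected, shroud from the superimposed
#' orthogonal pair), \code{"AS-4D-CBCT-single1"}/\code{"single2"}
#' (shroud from one imager).
#'
#' @param case A \code{\link{simulate_case}} result (or an equivalent list
#'   for real acquisitions).
#' @param scenario One of the scenario identifiers above.
#' @param params \code{\link{matching_params}} for shroud correction.
#' @param train_end Last 0-based frame of the training window (default 301,
#'   i.e. 60 s at 0.2 s sampling); the remaining frames are the short-term
#'   evaluation window.
#' @param amplitude_shrink Factor applied to the short-arc waveform
#'   amplitude to emulate the motion-range underestimation of
#'   low-temporal-resolution 4D-CBCT (1 = none).
#' @param threshold 3D error threshold in mm for the passing rate.
#' @param eval_case Optional second simulated session: when given, the
#'   fitted model is additionally evaluated on all frames of that session
#'   (long-term evaluation).
#' @param min_separation Minimum cycle separation (s) for minima detection.
#' @return An object of class \code{scenario_result}: \code{scenario},
#'   \code{pm}, \code{predicted}, \code{actual}, \code{metrics},
#'   \code{window} ("short-term"), \code{training_target}, and optionally
#'   \code{long_term} (metrics on \code{eval_case}).
#' @export
run_scenario <- function(case, scenario = "CL",
                         params = matching_params(), train_end = 301L,
                         amplitude_shrink = 1, threshold = 3,
                         eval_case = NULL, min_separation = 2.0) {
  scenario <- match.arg(scenario, .scenario_ids)
  inp <- .scenario_inputs(case, train_end, min_separation)
  target_train <- .training_target(inp, scenario, case, params,
                                   amplitude_shrink,
                                   min_separation = min_separation)
  pm <- fit_pm(inp$ir_train, target_train, dt = inp$dt)
  pred <- predict(pm, inp$ir_test)
  actual <- inp$wgm[inp$si, , drop = FALSE]
  metrics <- error_metrics(pred, actual, threshold)
  res <- list(scenario = scenario, pm = pm, predicted = pred,
              actual = actual, metrics = metrics, window = "short-term",
              training_target = target_train, params = params)
  if (!is.null(eval_case)) {
    wgm2 <- .gold_marker_waveform(eval_case)
    pred2 <- predict(pm, eval_case$ir_traces)
    res$long_term <- error_metrics(pred2, wgm2, threshold)
  }
  class(res) <- "scenario_result"
  res
}

#' Prediction-error metrics
#'
#' Per-direction RMSE, 3D RMSE (root mean of the squared per-frame 3D error
#' norms) and the percentage of frames whose 3D error is strictly below the
#' threshold.
#'
#' @param pred,actual n x d matrices (mm), equal size, n >= 1.
#' @param threshold 3D error threshold, mm (default 3).
#' @param strict Use strict inequality for the passing rate (default TRUE).
#' @return List: \code{rmse} (per direction), \code{rmse_3d},
#'   \code{pct_within} (0-100), \code{n}, \code{threshold}.
#' @export
error_metrics <- function(pred, actual, threshold = 3, strict = TRUE) {
  if (is.null(dim(pred))) pred <- matrix(pred, ncol = 1L)
  if (is.null(dim(actual))) actual <- matrix(actual, ncol = 1L)
  if (!all(dim(pred) == dim(actual))) .stopf("dimension mismatch")
  if (nrow(pred) == 0L) .stopf("empty evaluation window")
  err <- pred - actual
  norms <- sqrt(rowSums(err^2))
  within <- if (strict) norms < threshold else norms <= threshold
  list(rmse = sqrt(colMeans(err^2)),
       rmse_3d = sqrt(mean(norms^2)),
       pct_within = 100 * mean(within),
       n = nrow(pred), threshold = threshold)
}

#' Baseline drift of the averaged IR-marker trace
#'
#' Per window the baseline is \code{BL = (MED_ex + MED_in) / 2}, where
#' \code{MED_in} and \code{MED_ex} are the medians of the trace values at
#' its end-inhalation minima and end-exhalation maxima; the reported drift
#' is \code{BL_test - BL_train}. A positive value indicates a drift in the
#' posterior direction.
#'
#' @param ir_avg_train,ir_avg_test Averaged IR-marker AP traces (mm) for
#'   the two windows; each must contain at least 2 minima and 2 maxima.
#' @param min_separation,prominence,dt Passed to
#'   \code{\link{detect_local_minima}}.
#' @return List of class \code{drift_report}: \code{bl_train},
#'   \code{bl_test}, \code{drift} (mm), \code{med_in}, \code{med_ex} per
#'   window.
#' @export
baseline_drift <- function(ir_avg_train, ir_avg_test, min_separation = 2.0,
                           prominence = NULL, dt = 0.2) {
  one <- function(v) {
    seg_min <- detect_local_minima(v, min_separation, prominence, dt)
    seg_max <- detect_local_minima(-v, min_separation, prominence, dt)
    med_in <- stats::median(v[seg_min$t_lm + 1L])
    med_ex <- stats::median(v[seg_max$t_lm + 1L])
    list(bl = (med_ex + med_in) / 2, med_in = med_in, med_ex = med_ex)
  }
  tr <- one(as.numeric(ir_avg_train))
  te <- one(as.numeric(ir_avg_test))
  structure(list(bl_train = tr$bl, bl_test = te$bl,
                 drift = te$bl - tr$bl,
                 med_in = c(train = tr$med_in, test = te$med_in),
                 med_ex = c(train = tr$med_ex, test = te$med_ex)),
            class = "drift_report")
}

#' Matching-parameter grid report
#'
#' Exhaustively evaluates the dual-imager shroud-corrected scenario over
#' the grid of percentile pairs and local window widths, reporting the
#' percentage of 3D prediction errors within the threshold pooled over all
#' cases. Ties at the optimum are broken toward the smaller window, then
#' the wider percentile span.
#'
#' @param cases A \code{synthetic_case} or list of them.
#' @param percentile_candidates List of \code{c(p_upper, p_lower)} pairs.
#' @param window_candidates Integer window widths in frames.
#' @param scenario Scenario evaluated over the grid (a shroud-corrected
#'   one).
#' @param train_end,amplitude_shrink,threshold,min_separation As in
#'   \code{\link{run_scenario}}.
#' @return List of class \code{grid_report}: \code{grid} (data frame with
#'   w, p_upper, p_lower, pct_within), \code{table} (w x percentile-pair
#'   matrix), \code{best} (the selected \code{matching_params}).
#' @export
parameter_grid_report <- function(cases,
                                  percentile_candidates = list(
                                    c(100, 0), c(85, 10), c(75, 15)),
                                  window_candidates = c(11L, 21L, 31L),
                                  scenario = "AS-4D-CBCT-dual",
                                  train_end = 301L, amplitude_shrink = 1,
                                  threshold = 3, min_separation = 2.0) {
  if (inherits(cases, "synthetic_case")) cases <- list(cases)
  scenario <- match.arg(scenario, .scenario_ids[3:5])
  # precompute per-case pieces once; only the correction depends on params
  prep <- lapply(cases, function(case) {
    inp <- .scenario_inputs(case, train_end, min_separation)
    stacks <- switch(scenario,
      "AS-4D-CBCT-dual" = case$projections,
      "AS-4D-CBCT-single1" = case$projections[1L],
      "AS-4D-CBCT-single2" = case$projections[2L])
    w_as <- extract_as_signal(stacks, frames = inp$ti)
    cyc <- phase_sort(inp$wgm[inp$ti, , drop = FALSE], inp$seg)
    w4d <- .shrink(tile_waveform(cyc, inp$seg, length(inp$ti)),
                   amplitude_shrink)
    list(inp = inp, w_as = w_as, w4d = w4d)
  })
  rows <- list()
  for (w in window_candidates) for (pc in percentile_candidates) {
    pars <- matching_params(pc[1L], pc[2L], w)
    nwithin <- 0L; ntot <- 0L
    for (pr in prep) {
      corr <- correct_waveform(pr$w4d, pr$w_as, pars,
                               min_separation = min_separation,
                               dt = pr$inp$dt)
      pm <- fit_pm(pr$inp$ir_train, corr$samples, dt = pr$inp$dt)
      pred <- predict(pm, pr$inp$ir_test)
      m <- error_metrics(pred, pr$inp$wgm[pr$inp$si, , drop = FALSE],
                         threshold)
      nwithin <- nwithin + m$pct_within / 100 * m$n
      ntot <- ntot + m$n
    }
    rows[[length(rows) + 1L]] <- data.frame(
      w = w, p_upper = pc[1L], p_lower = pc[2L],
      pct_within = 100 * nwithin / ntot)
  }
  grid <- do.call(rbind, rows)
  ord <- order(-grid$pct_within, grid$w,
               -(grid$p_upper - grid$p_lower))
  best <- grid[ord[1L], ]
  tab <- matrix(grid$pct_within,
                nrow = length(window_candidates), byrow = TRUE,
                dimnames = list(
                  paste0("w=", window_candidates),
                  vapply(percentile_candidates, function(p)
                    sprintf("(P%g,P%g)", p[1L], p[2L]), character(1L))))
  structure(list(grid = grid, table = tab,
                 best = matching_params(best$p_upper, best$p_lower,
                                        best$w)),
            class = "grid_report")
}

#' @export
print.scenario_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("Scenario %s (%s): 3D RMSE %.2f mm; %.1f%% of frames < %g mm\n",
              x$scenario, x$window, m$rmse_3d, m$pct_within, m$threshold))
  cat(sprintf("  per-direction RMSE [mm]: LR %.2f, SI %.2f, AP %.2f\n",
              m$rmse[1L], m$rmse[2L], m$rmse[3L]))
  if (!is.null(x$long_term))
    cat(sprintf("  long-term: 3D RMSE %.2f mm; %.1f%% < %g mm\n",
                x$long_term$rmse_3d, x$long_term$pct_within,
                x$long_term$threshold))
  invisible(x)
}

#' @export
print.grid_report <- function(x, ...) {
  cat("Matching-parameter grid (% of 3D errors within threshold):\n")
  print(round(x$table, 1))
  b <- x$best
  cat(sprintf("Best: (P%g, P%g), w = %d\n", b$p_upper, b$p_lower, b$w))
  invisible(x)
}

#' @export
print.drift_report <- function(x, ...) {
  cat(sprintf("Baseline drift: %+.2f mm (BL train %.2f, test %.2f; positive = posterior)\n",
              x$drift, x$bl_train, x$bl_test))
  invisible(x)
}
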