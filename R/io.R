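# Disk formats: multi-page TIFF per imager plus a frame-index CSV for
# projection stacks; plain CSV for waveforms; YAML echo of simulation
# parameters.

#' Write a synthetic case to disk
#'
#' Writes, under \code{dir}: one multi-page float TIFF per imager
#' (\code{imagerN.tif}) with a frame-index CSV (\code{imagerN_frames.csv}:
#' frame, time_s, angle_deg), trace CSVs (\code{target.csv},
#' \code{diaphragm.csv}, \code{ir_markers.csv}), per-imager fiducial
#' detection CSVs, and the simulation parameters echoed to
#' \code{params.yaml}. Identical cases export byte-identically.
#'
#' @param case A \code{\link{simulate_case}} result.
#' @param dir Output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_case <- function(case, dir) {
  stopifnot(inherits(case, "synthetic_case"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- data.frame(frame = case$schedule$frame,
                    time_s = case$schedule$time_s,
                    angle_deg = case$schedule$angle_deg)
  for (k in seq_along(case$projections)) {
    st <- case$projections[[k]]
    pages <- lapply(seq_len(dim(st$frames)[3L]),
                    function(i) st$frames[, , i])
    tiff::writeTIFF(pages, file.path(dir, sprintf("imager%d.tif", k)),
                    bits.per.sample = 32L, reduce = FALSE)
    utils::write.csv(idx, file.path(dir, sprintf("imager%d_frames.csv", k)),
                     row.names = FALSE)
  }
  utils::write.csv(
    data.frame(time_s = case$time, case$true_target),
    file.path(dir, "target.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(time_s = case$time, value_mm = case$diaphragm_si),
    file.path(dir, "diaphragm.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(time_s = case$time, case$ir_traces),
    file.path(dir, "ir_markers.csv"), row.names = FALSE)
  for (k in seq_along(case$detections)) {
    utils::write.csv(
      data.frame(frame = case$schedule$frame, imager = k,
                 u_mm = case$detections[[k]][, 1L],
                 v_mm = case$detections[[k]][, 2L]),
      file.path(dir, sprintf("detections_imager%d.csv", k)),
      row.names = FALSE)
  }
  p <- case$params
  p$amplitude <- as.list(p$amplitude)
  p$correlation_sign <- as.list(p$correlation_sign)
  class(p) <- NULL
  yaml::write_yaml(p, file.path(dir, "params.yaml"))
  invisible(dir)
}

#' Read a projection stack from a multi-page TIFF and frame-index CSV
#'
#' @param tiff_path Multi-page grayscale TIFF, one page per frame.
#' @param index_path CSV with columns \code{frame}, \code{time_s},
#'   \code{angle_deg}.
#' @param pixel_size mm per pixel at the isocenter plane.
#' @param imager_id 1 or 2.
#' @return A \code{projection_stack}.
#' @export
read_projection_stack <- function(tiff_path, index_path, pixel_size = 0.2,
                                  imager_id = 1L) {
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  idx <- utils::read.csv(index_path)
  if (length(pages) != nrow(idx))
    .stopf("frame-index CSV (%d rows) does not match TIFF pages (%d)",
           nrow(idx), length(pages))
  frames <- array(unlist(pages),
                  dim = c(nrow(pages[[1L]]), ncol(pages[[1L]]),
                          length(pages)))
  structure(list(frames = frames, pixel_size = pixel_size,
                 imager_id = as.integer(imager_id),
                 frame_times = idx$time_s, angles = idx$angle_deg),
            class = "projection_stack")
}

#' Write a waveform to CSV
#'
#' @param samples Numeric vector or matrix of samples.
#' @param path Output CSV path.
#' @param time Optional sample times (s); defaults to a 0.2 s grid.
#' @param dt Sampling interval used when \code{time} is missing.
#' @export
write_waveform_csv <- function(samples, path, time = NULL, dt = 0.2) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1L,
                                               dimnames = list(NULL, "value_mm"))
  if (is.null(time)) time <- (seq_len(nrow(samples)) - 1L) * dt
  utils::write.csv(
    cbind(data.frame(frame = seq_len(nrow(samples)) - 1L, time_s = time),
          as.data.frame(samples)),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a waveform CSV written by \code{\link{write_waveform_csv}}
#'
#' @param path CSV path.
#' @return A data frame with \code{frame}, \code{time_s} and value columns.
#' @export
read_waveform_csv <- function(path) utils::read.csv(path)
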