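# Shared fixture builders; everything is generated in code at test time.

# Full-length acquisition with narrow detector panels to keep rendering
# cheap; the SI axis keeps its full 256-row extent.
small_case <- function(seed, proj_noise_sd = 0, width = 32L, ...) {
  simulate_case(
    breathing_params(seed = seed, proj_noise_sd = proj_noise_sd, ...),
    build_schedule(1.5, 70, 0.3),
    image_shape = c(256L, width))
}

# Hand-built cycle segmentation (0-based minima indices) for operations
# that take a segmentation as given.
make_seg <- function(t_lm, dt = 0.2) {
  structure(list(t_lm = as.integer(t_lm), n = length(t_lm),
                 t_mean = mean(diff(t_lm)), dt = dt),
            class = "cycle_segmentation")
}

# Projection stack wrapper around a plain frame array.
make_stack <- function(frames, pixel_size = 0.2, imager_id = 1L, dt = 0.2) {
  n <- dim(frames)[3L]
  structure(list(frames = frames, pixel_size = pixel_size,
                 imager_id = imager_id,
                 frame_times = (seq_len(n) - 1L) * dt,
                 angles = rep(0, n)),
            class = "projection_stack")
}

# Stack whose diaphragm edge follows a given row trace.
edge_stack <- function(rows, image_shape = c(256L, 32L), noise_sd = 0,
                       edge_width = 80, texture_amp = 0.03, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  frames <- array(0, c(image_shape, length(rows)))
  for (i in seq_along(rows))
    frames[, , i] <- render_projection(rows[i], 0, image_shape,
                                       noise_sd = noise_sd,
                                       edge_width = edge_width,
                                       texture_amp = texture_amp)
  make_stack(frames)
}
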