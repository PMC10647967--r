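# Base-graphics displays for the main intermediate objects.

#' Display an Amsterdam Shroud image
#'
#' @param x An \code{as_image}.
#' @param ... Passed to \code{\link[graphics]{image}}.
#' @export
plot.as_image <- function(x, ...) {
  graphics::image(x = x$frame_times, y = seq_len(nrow(x$matrix)),
                  z = t(x$matrix[rev(seq_len(nrow(x$matrix))), ]),
                  xlab = "time [s]", ylab = "SI row",
                  main = sprintf("AS image (%s)", x$provenance),
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Plot predicted against actual target positions for a scenario
#'
#' @param x A \code{scenario_result}.
#' @param direction Column to display (default "SI").
#' @param ... Passed to \code{\link[graphics]{matplot}}.
#' @export
plot.scenario_result <- function(x, direction = "SI", ...) {
  graphics::matplot(cbind(x$actual[, direction], x$predicted[, direction]),
                    type = "l", lty = c(1, 2), col = c("black", "red"),
                    xlab = "evaluation frame",
                    ylab = sprintf("%s position [mm]", direction),
                    main = sprintf("Scenario %s (3D RMSE %.2f mm)",
                                   x$scenario, x$metrics$rmse_3d), ...)
  graphics::legend("topright", c("actual", "predicted"),
                   lty = c(1, 2), col = c("black", "red"), bty = "n")
  invisible(x)
}
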