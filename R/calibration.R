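#' Spatial and temporal calibration of a tracking movie or image stack
#'
#' Bundles the physical scale factors that convert raw tracker/image
#' coordinates (pixels, frames, slice indices) into micrometres and
#' seconds. All downstream motion statistics and image quantification
#' operate in physical units, so every reader takes a `calibration`.
#'
#' @param pixel_size Lateral pixel size in micrometres per pixel.
#' @param frame_interval Time between consecutive frames in seconds.
#' @param z_step Axial spacing between z-slices in micrometres
#'   (confocal z-stacks; the default 3 matches a confocal series
#'   acquired in 3-micrometre slices).
#'
#' @return An object of class `"calibration"`: a list with elements
#'   `pixel_size`, `frame_interval` and `z_step`.
#' @examples
#' cal <- calibration(pixel_size = 0.1, frame_interval = 3)
#' um_to_px(px_to_um(5, cal), cal)  # 5
#' @export
calibration <- function(pixel_size = 1, frame_interval = 1, z_step = 3) {
  for (nm in c("pixel_size", "frame_interval", "z_step")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("calibration: '%s' must be a single positive number", nm),
           call. = FALSE)
  }
  structure(
    list(pixel_size = as.numeric(pixel_size),
         frame_interval = as.numeric(frame_interval),
         z_step = as.numeric(z_step)),
    class = "calibration"
  )
}

#' @rdname calibration
#' @param x Object to test or print.
#' @export
is_calibration <- function(x) inherits(x, "calibration")

# unshadowed alias for use where a function argument is named 'calibration'
.default_calibration <- function() calibration()

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf(
    "<calibration> pixel_size = %g um/px, frame_interval = %g s, z_step = %g um\n",
    x$pixel_size, x$frame_interval, x$z_step))
  invisible(x)
}

#' Convert between pixel and micrometre coordinates
#'
#' Linear, invertible unit conversion: `px_to_um(um_to_px(x)) == x`.
#'
#' @param x Numeric vector of coordinates.
#' @param calibration A [calibration()] object.
#' @return Numeric vector in the target unit.
#' @export
px_to_um <- function(x, calibration) {
  stopifnot(is_calibration(calibration))
  x * calibration$pixel_size
}

#' @rdname px_to_um
#' @export
um_to_px <- function(x, calibration) {
  stopifnot(is_calibration(calibration))
  x / calibration$pixel_size
}
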