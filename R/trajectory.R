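#' Single-particle trajectory in physical units
#'
#' A trajectory is a time-ordered series of detections of one particle.
#' Positions are stored in micrometres, time in seconds, with 0-based
#' frame indices (image convention: origin top-left, y increasing
#' downward). Frames need not be contiguous: dropped detections leave a
#' gap, which is recorded in the `has_gaps` attribute rather than being
#' interpolated away — interpolation would bias displacement statistics.
#'
#' @param track_id Identifier (coerced to character).
#' @param frame Integer vector of 0-based frame indices, strictly
#'   increasing.
#' @param x,y Coordinates in micrometres.
#' @param t Optional time stamps in seconds; computed as
#'   `frame * frame_interval` when omitted.
#' @param frame_interval Seconds per frame, used when `t` is missing.
#'
#' @return An object of class `"trajectory"`: a data.frame with columns
#'   `frame`, `t`, `x`, `y`, attributes `track_id` and `has_gaps`.
#' @export
trajectory <- function(track_id, frame, x, y, t = NULL, frame_interval = 1) {
  frame <- as.integer(frame)
  if (length(frame) < 2L)
    stop("trajectory: need at least 2 points", call. = FALSE)
  if (any(frame < 0L))
    stop("trajectory: frames must be >= 0", call. = FALSE)
  if (any(diff(frame) <= 0L))
    stop(sprintf("trajectory: frames must be strictly increasing in track '%s'",
                 track_id), call. = FALSE)
  if (length(x) != length(frame) || length(y) != length(frame))
    stop("trajectory: frame, x, y lengths differ", call. = FALSE)
  if (is.null(t)) t <- frame * frame_interval
  if (any(diff(t) <= 0))
    stop("trajectory: time stamps must be strictly increasing", call. = FALSE)
  out <- data.frame(frame = frame, t = as.numeric(t),
                    x = as.numeric(x), y = as.numeric(y))
  attr(out, "track_id") <- as.character(track_id)
  attr(out, "has_gaps") <- any(diff(frame) > 1L)
  class(out) <- c("trajectory", "data.frame")
  out
}

#' @rdname trajectory
#' @param traj A trajectory.
#' @export
track_id <- function(traj) attr(traj, "track_id")

#' @rdname trajectory
#' @export
has_gaps <- function(traj) isTRUE(attr(traj, "has_gaps"))

#' Ensemble of trajectories sharing one calibration
#'
#' The unit of all motion statistics: a non-empty list of
#' [trajectory()] objects recorded under the same spatial/temporal
#' calibration, plus a log of particles dropped during import.
#'
#' @param trajectories List of [trajectory()] objects.
#' @param calibration A [calibration()] object.
#' @param log Optional named list of import diagnostics (e.g.
#'   `n_dropped_short`, count of particles discarded for having fewer
#'   than two detections).
#'
#' @return An object of class `"trajectory_ensemble"`.
#' @export
trajectory_ensemble <- function(trajectories, calibration, log = list()) {
  if (length(trajectories) == 0L)
    stop("trajectory_ensemble: no trajectories", call. = FALSE)
  ok <- vapply(trajectories, inherits, logical(1), what = "trajectory")
  if (!all(ok))
    stop("trajectory_ensemble: all elements must be trajectories", call. = FALSE)
  stopifnot(is_calibration(calibration))
  structure(
    list(trajectories = trajectories, calibration = calibration, log = log),
    class = "trajectory_ensemble"
  )
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  np <- vapply(x$trajectories, nrow, integer(1))
  cat(sprintf(
    "<trajectory_ensemble> %d tracks, %d-%d points each, frame_interval %g s\n",
    length(x$trajectories), min(np), max(np), x$calibration$frame_interval))
  if (length(x$log))
    cat("  import log:",
        paste(names(x$log), unlist(x$log), sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' @rdname trajectory_ensemble
#' @param x Object to test.
#' @export
is_trajectory_ensemble <- function(x) inherits(x, "trajectory_ensemble")

#' Number of tracks in an ensemble
#' @param ensemble A [trajectory_ensemble()].
#' @return Integer count.
#' @export
n_tracks <- function(ensemble) length(ensemble$trajectories)
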