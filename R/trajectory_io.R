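#' Read particle tracks exported as tracker XML
#'
#' Parses the simplified "exported tracks" XML dialect written by the
#' ImageJ/Fiji particle tracker for downstream displacement analysis: a
#' root element containing one element per particle, each holding one
#' element per detection with `t`, `x` and `y` attributes. The full
#' tracker project format (spots + edges) is out of scope.
#'
#' Coordinates are converted to micrometres on load when the file
#' stores pixels (`units = "pixel"`, the default); files already in
#' micrometres pass `units = "um"`. Detections are sorted by frame.
#' Particles with fewer than two detections cannot support a
#' displacement and are dropped; the count of dropped particles is
#' recorded in the ensemble's `log$n_dropped_short`.
#'
#' @param path Path to the XML file.
#' @param calibration A [calibration()] object.
#' @param units Unit of the stored coordinates: `"pixel"` (scaled by
#'   `pixel_size` on load) or `"um"` (used as is).
#' @return A [trajectory_ensemble()].
#' @export
read_tracker_xml <- function(path, calibration, units = c("pixel", "um")) {
  units <- match.arg(units)
  stopifnot(is_calibration(calibration))
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) stop(sprintf("read_tracker_xml: malformed XML in '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE))
  particles <- xml2::xml_find_all(doc, ".//particle")
  if (length(particles) == 0L)
    stop(sprintf("read_tracker_xml: no particle elements in '%s'", path),
         call. = FALSE)
  scale <- if (units == "pixel") calibration$pixel_size else 1
  n_dropped <- 0L
  trajs <- list()
  for (i in seq_along(particles)) {
    dets <- xml2::xml_find_all(particles[[i]], "./detection")
    if (length(dets) < 2L) {
      n_dropped <- n_dropped + 1L
      next
    }
    frame <- as.integer(xml2::xml_attr(dets, "t"))
    x <- as.numeric(xml2::xml_attr(dets, "x")) * scale
    y <- as.numeric(xml2::xml_attr(dets, "y")) * scale
    ord <- order(frame)
    trajs[[length(trajs) + 1L]] <- trajectory(
      track_id = as.character(i), frame = frame[ord],
      x = x[ord], y = y[ord],
      frame_interval = calibration$frame_interval)
  }
  if (n_dropped > 0L)
    warning(sprintf("read_tracker_xml: dropped %d particle(s) with < 2 detections",
                    n_dropped), call. = FALSE)
  if (length(trajs) == 0L)
    stop("read_tracker_xml: no trajectories with >= 2 detections", call. = FALSE)
  trajectory_ensemble(trajs, calibration,
                      log = list(n_dropped_short = n_dropped))
}

#' Write an ensemble in tracker-XML form
#'
#' Inverse of [read_tracker_xml()]: emits the same simplified dialect,
#' with coordinates stored in the unit requested. Round-tripping
#' through write-then-read reproduces coordinates to numeric printing
#' precision.
#'
#' @param ensemble A [trajectory_ensemble()].
#' @param path Output file path.
#' @param units Unit for stored coordinates (see [read_tracker_xml()]).
#' @return `path`, invisibly.
#' @export
write_tracker_xml <- function(ensemble, path, units = c("pixel", "um")) {
  units <- match.arg(units)
  stopifnot(is_trajectory_ensemble(ensemble))
  scale <- if (units == "pixel") 1 / ensemble$calibration$pixel_size else 1
  root <- xml2::xml_new_root("Tracks",
                             nTracks = as.character(n_tracks(ensemble)))
  for (traj in ensemble$trajectories) {
    p <- xml2::xml_add_child(root, "particle",
                             nSpots = as.character(nrow(traj)))
    for (k in seq_len(nrow(traj))) {
      xml2::xml_add_child(p, "detection",
                          t = as.character(traj$frame[k]),
                          x = sprintf("%.10g", traj$x[k] * scale),
                          y = sprintf("%.10g", traj$y[k] * scale))
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' Read/write trajectories as CSV
#'
#' CSV layout: header row with columns `track_id, frame, x, y` and
#' optionally `t` ('.' decimal separator). `x`/`y` are in micrometres;
#' when `t` is absent it is derived as `frame * frame_interval`.
#' Writing then reading is the identity on ids and coordinates.
#'
#' @param path CSV file path.
#' @param calibration A [calibration()] object.
#' @return [read_trajectories_csv()]: a [trajectory_ensemble()];
#'   [write_trajectories_csv()]: `path`, invisibly.
#' @export
read_trajectories_csv <- function(path, calibration) {
  stopifnot(is_calibration(calibration))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("track_id", "frame", "x", "y")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(sprintf("read_trajectories_csv: missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (nrow(df) == 0L)
    stop("read_trajectories_csv: no trajectories", call. = FALSE)
  has_t <- "t" %in% names(df)
  trajs <- lapply(split(df, factor(df$track_id, levels = unique(df$track_id))),
                  function(d) {
    if (any(diff(d$frame) <= 0))
      stop(sprintf(
        "read_trajectories_csv: non-monotone frames in track '%s'",
        d$track_id[1]), call. = FALSE)
    trajectory(track_id = d$track_id[1], frame = d$frame,
               x = d$x, y = d$y,
               t = if (has_t) d$t else NULL,
               frame_interval = calibration$frame_interval)
  })
  trajectory_ensemble(unname(trajs), calibration)
}

#' @rdname read_trajectories_csv
#' @param ensemble A [trajectory_ensemble()].
#' @export
write_trajectories_csv <- function(ensemble, path) {
  stopifnot(is_trajectory_ensemble(ensemble))
  rows <- lapply(ensemble$trajectories, function(traj)
    data.frame(track_id = track_id(traj), frame = traj$frame,
               x = traj$x, y = traj$y, t = traj$t))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Calibrated fluorescence image stack
#'
#' A stack of 2-D intensity planes along either time (timelapse) or
#' depth (confocal z-stack), with the calibration needed to express
#' results in physical units. Intensities are non-negative and, for
#' TIFF round-trip fidelity, kept in the `[0, 1]` range by the
#' synthetic generators.
#'
#' @param data Numeric array `planes x height x width`, or a list of
#'   equally sized matrices.
#' @param axis_kind `"time"` (frames) or `"depth"` (z-slices).
#' @param calibration A [calibration()] object.
#' @param channel_label Free-text channel description.
#' @return An object of class `"image_stack"`.
#' @export
image_stack <- function(data, axis_kind = c("time", "depth"),
                        calibration = NULL,
                        channel_label = "") {
  axis_kind <- match.arg(axis_kind)
  if (is.null(calibration)) calibration <- .default_calibration()
  if (is.list(data)) {
    dims <- unique(lapply(data, dim))
    if (length(dims) != 1L)
      stop("image_stack: planes differ in size", call. = FALSE)
    arr <- array(0, c(length(data), dims[[1]][1], dims[[1]][2]))
    for (i in seq_along(data)) arr[i, , ] <- data[[i]]
    data <- arr
  }
  if (!is.array(data) || length(dim(data)) != 3L || dim(data)[1] < 1L)
    stop("image_stack: data must be a planes x height x width array",
         call. = FALSE)
  if (any(data < 0))
    stop("image_stack: negative intensities", call. = FALSE)
  stopifnot(is_calibration(calibration))
  structure(
    list(data = data, axis_kind = axis_kind, calibration = calibration,
         channel_label = as.character(channel_label)),
    class = "image_stack"
  )
}

#' @rdname image_stack
#' @param x Object to test.
#' @export
is_image_stack <- function(x) inherits(x, "image_stack")

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d %s plane(s) of %d x %d px (%s)\n",
              d[1], x$axis_kind, d[2], d[3],
              if (nzchar(x$channel_label)) x$channel_label else "unlabelled"))
  invisible(x)
}

#' Number of planes and physical axis of an image stack
#'
#' For a `"time"` stack the axis is `frame * frame_interval` seconds;
#' for a `"depth"` stack it is `slice * z_step` micrometres, 0-based,
#' so a 36-slice stack at a 3-um z-step spans 0-105 um.
#'
#' @param stack An [image_stack()].
#' @return `n_planes()`: integer; `stack_axis()`: numeric vector of
#'   plane positions in seconds (time) or micrometres (depth).
#' @export
n_planes <- function(stack) dim(stack$data)[1]

#' @rdname n_planes
#' @export
stack_axis <- function(stack) {
  idx <- seq_len(n_planes(stack)) - 1
  if (stack$axis_kind == "time") idx * stack$calibration$frame_interval
  else idx * stack$calibration$z_step
}

#' Read/write a multi-page TIFF as an image stack
#'
#' Thin wrappers over the `tiff` package. Plane count and values are
#' preserved (32-bit float storage; values must lie in `[0, 1]`).
#' Reading a single-page file as a depth stack is allowed but warned
#' about, since a one-slice "z-stack" usually indicates a mis-set
#' acquisition export.
#'
#' @param path TIFF file path.
#' @param calibration A [calibration()] object.
#' @param axis_kind `"time"` or `"depth"`.
#' @param channel_label Channel description attached to the stack.
#' @return [read_stack()]: an [image_stack()]; [write_stack()]:
#'   `path`, invisibly.
#' @export
read_stack <- function(path, calibration, axis_kind = c("time", "depth"),
                       channel_label = "") {
  axis_kind <- match.arg(axis_kind)
  if (!file.exists(path))
    stop(sprintf("read_stack: cannot read '%s'", path), call. = FALSE)
  planes <- tryCatch(
    tiff::readTIFF(path, all = TRUE),
    error = function(e) stop(sprintf("read_stack: cannot read '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE))
  if (!is.list(planes)) planes <- list(planes)
  planes <- lapply(planes, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  if (length(planes) == 1L && axis_kind == "depth")
    warning("read_stack: single-page file read as depth stack", call. = FALSE)
  image_stack(planes, axis_kind = axis_kind, calibration = calibration,
              channel_label = channel_label)
}

#' @rdname read_stack
#' @param stack An [image_stack()].
#' @export
write_stack <- function(stack, path) {
  stopifnot(is_image_stack(stack))
  if (max(stack$data) > 1)
    stop("write_stack: intensities must be in [0, 1] for TIFF storage",
         call. = FALSE)
  planes <- lapply(seq_len(n_planes(stack)), function(i) stack$data[i, , ])
  tiff::writeTIFF(planes, path, bits.per.sample = 32L)
  invisible(path)
}
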