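#' Segment a fluorescence plane into foreground and area
#'
#' Thresholds a 2-D intensity plane (Otsu's method on a 256-bin
#' histogram via \pkg{EBImage}, or a fixed intensity), then removes
#' connected components smaller than `min_object_px` to reject
#' sub-diffraction speckle. Area is the foreground pixel count times
#' `pixel_size^2`.
#'
#' @param plane Numeric matrix of intensities.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold Intensity threshold, required for
#'   `method = "fixed"`; ignored for Otsu.
#' @param min_object_px Minimum connected-component size in pixels
#'   kept as foreground. Default 9 (despeckle at typical confocal
#'   sampling).
#' @param pixel_size um per pixel used for the area.
#' @return A list with `mask` (logical matrix), `area` (um^2),
#'   `area_px` (count) and `threshold` (the intensity used).
#' @export
segment_fluorescence <- function(plane, method = c("otsu", "fixed"),
                                 threshold = NULL, min_object_px = 9L,
                                 pixel_size = 1) {
  method <- match.arg(method)
  if (!is.matrix(plane) || length(plane) == 0L)
    stop("segment_fluorescence: plane must be a non-empty matrix", call. = FALSE)
  if (method == "otsu") {
    rng <- range(plane)
    if (diff(rng) == 0)
      stop("segment_fluorescence: degenerate histogram (constant image)",
           call. = FALSE)
    threshold <- EBImage::otsu(EBImage::Image(plane), range = rng)
  } else if (is.null(threshold)) {
    stop("segment_fluorescence: fixed method needs a threshold", call. = FALSE)
  }
  mask <- plane >= threshold
  if (min_object_px > 1L && any(mask)) {
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    sizes <- tabulate(as.integer(lab))
    keep <- which(sizes >= min_object_px)
    mask <- matrix(as.integer(lab) %in% keep, nrow(plane), ncol(plane))
  }
  area_px <- sum(mask)
  list(mask = mask, area = area_px * pixel_size^2, area_px = area_px,
       threshold = as.numeric(threshold))
}

#' Prey-biomass area as a function of time
#'
#' Segments every frame of a fluorescence timelapse and reports the
#' colony area per frame, plus the series normalized to the first
#' frame — the form in which clearance rates are compared across
#' conditions. Thresholding is per-frame (Otsu by default) so slow
#' illumination drift does not masquerade as biomass change.
#'
#' @param stack An [image_stack()] with `axis_kind = "time"`. Frame
#'   times come from the calibration; a timelapse captured hourly has
#'   `frame_interval = 3600`.
#' @param method,threshold,min_object_px Passed to
#'   [segment_fluorescence()].
#' @param time_unit `"h"` (default) or `"s"` for the reported times.
#' @return An object of class `"biomass_series"`: data.frame with
#'   columns `time`, `area` (um^2) and `normalized`.
#' @export
biomass_timeseries <- function(stack, method = "otsu", threshold = NULL,
                               min_object_px = 9L, time_unit = c("h", "s")) {
  time_unit <- match.arg(time_unit)
  stopifnot(is_image_stack(stack))
  if (stack$axis_kind != "time")
    stop("biomass_timeseries: stack must have axis_kind = 'time'", call. = FALSE)
  px <- stack$calibration$pixel_size
  areas <- vapply(seq_len(n_planes(stack)), function(i)
    segment_fluorescence(stack$data[i, , ], method = method,
                         threshold = threshold,
                         min_object_px = min_object_px,
                         pixel_size = px)$area,
    numeric(1))
  times <- stack_axis(stack)
  if (time_unit == "h") times <- times / 3600
  biomass_series(times, areas)
}

#' @rdname biomass_timeseries
#' @param times Increasing time points.
#' @param areas Non-negative areas (um^2), same length.
#' @export
biomass_series <- function(times, areas) {
  if (length(times) != length(areas))
    stop("biomass_series: times and areas lengths differ", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("biomass_series: times must be increasing", call. = FALSE)
  if (any(areas < 0))
    stop("biomass_series: areas must be >= 0", call. = FALSE)
  norm <- if (areas[1] > 0) areas / areas[1] else rep(NA_real_, length(areas))
  out <- data.frame(time = times, area = areas, normalized = norm)
  class(out) <- c("biomass_series", "data.frame")
  out
}

#' Quadratic trend of a biomass series with 95% confidence band
#'
#' Ordinary least-squares fit of `A(t) = a0 + a1 t + a2 t^2` with the
#' pointwise 95% confidence band of the predicted mean from the usual
#' linear-model variance (t distribution on `n - 3` df). With zero
#' residuals the coefficients are recovered exactly and the band has
#' zero width.
#'
#' @param series A `"biomass_series"` (at least 4 points).
#' @param on `"area"` (default) or `"normalized"`: which column to fit.
#' @return An object of class `"quadratic_trend"`: list with
#'   `coefficients` (a0, a1, a2), `fitted`, `lower`, `upper`, `times`
#'   and the underlying `lm` fit.
#' @export
fit_quadratic_trend <- function(series, on = c("area", "normalized")) {
  on <- match.arg(on)
  stopifnot(inherits(series, "biomass_series"))
  if (nrow(series) < 4L)
    stop("fit_quadratic_trend: need >= 4 points", call. = FALSE)
  d <- data.frame(t = series$time, A = series[[on]])
  fit <- stats::lm(A ~ t + I(t^2), data = d)
  pred <- stats::predict(fit, newdata = d, interval = "confidence",
                         level = 0.95)
  structure(
    list(coefficients = stats::setNames(stats::coef(fit),
                                        c("a0", "a1", "a2")),
         fitted = unname(pred[, "fit"]), lower = unname(pred[, "lwr"]),
         upper = unname(pred[, "upr"]), times = series$time, lm = fit),
    class = "quadratic_trend"
  )
}

#' @export
print.quadratic_trend <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("<quadratic_trend> A(t) = %.4g + %.4g t + %.4g t^2\n",
              co[1], co[2], co[3]))
  invisible(x)
}

#' Biomass clearance rate and experimental/control rate ratio
#'
#' The primary rate is the endpoint difference of the normalized area
#' over the observation window, in fraction of initial biomass per
#' hour; the quadratic initial slope `-a1` of the normalized trend is
#' reported alongside for comparison, but the endpoint definition is
#' the headline number because it makes no shape assumption.
#'
#' `clearance_rate_ratio()` divides the experimental endpoint rate by
#' the control's. A control that did not lose biomass (rate <= 0)
#' makes the ratio meaningless; it is returned as `NA` with
#' `undefined = TRUE` rather than an infinity.
#'
#' @param series,experimental,control `"biomass_series"` objects.
#' @return `clearance_rate()`: list with `rate` (normalized fraction
#'   per time unit), `rate_absolute` (um^2 per time unit) and
#'   `rate_quadratic` (initial slope `-a1` of the normalized fit, `NA`
#'   for series shorter than 4 points).
#'   `clearance_rate_ratio()`: list with `ratio`, `rate_experimental`,
#'   `rate_control`, `undefined`.
#' @export
clearance_rate <- function(series) {
  stopifnot(inherits(series, "biomass_series"))
  n <- nrow(series)
  span <- series$time[n] - series$time[1]
  rate_quad <- if (n >= 4L)
    -unname(fit_quadratic_trend(series, on = "normalized")$coefficients["a1"])
  else NA_real_
  list(rate = (series$normalized[1] - series$normalized[n]) / span,
       rate_absolute = (series$area[1] - series$area[n]) / span,
       rate_quadratic = rate_quad)
}

#' @rdname clearance_rate
#' @export
clearance_rate_ratio <- function(experimental, control) {
  re <- clearance_rate(experimental)$rate
  rc <- clearance_rate(control)$rate
  if (rc <= 0) {
    warning("clearance_rate_ratio: control rate <= 0; ratio undefined",
            call. = FALSE)
    return(list(ratio = NA_real_, rate_experimental = re, rate_control = rc,
                undefined = TRUE))
  }
  list(ratio = re / rc, rate_experimental = re, rate_control = rc,
       undefined = FALSE)
}

#' Depth profile of phage coverage in a biofilm z-stack
#'
#' Per-slice fraction of pixels above threshold in the phage channel,
#' against depth `z = slice_index * z_step` (0-based, top slice at
#' `z = 0`). A single global Otsu threshold over the whole stack keeps
#' slice coverages comparable along the axial direction — per-slice
#' thresholds would flatten the very depth profile being measured.
#' `peak_z` is the depth of maximum coverage; ties resolve to the
#' shallowest slice and are flagged.
#'
#' @param stack An [image_stack()] with `axis_kind = "depth"`.
#' @param method `"otsu"` (global, default) or `"fixed"`.
#' @param threshold Intensity threshold for `method = "fixed"`.
#' @return An object of class `"depth_profile"`: list with `z` (um),
#'   `coverage` (per-slice fractions between 0 and 1), `peak_z` (um),
#'   `peak_coverage`
#'   and `tied_peak` (logical).
#' @export
phage_depth_profile <- function(stack, method = c("otsu", "fixed"),
                                threshold = NULL) {
  method <- match.arg(method)
  stopifnot(is_image_stack(stack))
  if (stack$axis_kind != "depth")
    stop("phage_depth_profile: stack must have axis_kind = 'depth'",
         call. = FALSE)
  if (method == "otsu") {
    rng <- range(stack$data)
    if (diff(rng) == 0)
      stop("phage_depth_profile: degenerate histogram (constant stack)",
           call. = FALSE)
    threshold <- EBImage::otsu(EBImage::Image(as.vector(stack$data)),
                               range = rng)
  } else if (is.null(threshold)) {
    stop("phage_depth_profile: fixed method needs a threshold", call. = FALSE)
  }
  coverage <- vapply(seq_len(n_planes(stack)), function(i)
    mean(stack$data[i, , ] >= threshold), numeric(1))
  if (all(coverage == 0))
    stop("phage_depth_profile: no foreground in any slice; peak undefined",
         call. = FALSE)
  z <- stack_axis(stack)
  peaks <- which(coverage == max(coverage))
  structure(
    list(z = z, coverage = coverage, peak_z = z[peaks[1]],
         peak_coverage = max(coverage), tied_peak = length(peaks) > 1L,
         threshold = as.numeric(threshold)),
    class = "depth_profile"
  )
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> %d slices, 0-%g um; peak coverage %.3f at %g um%s\n",
              length(x$z), max(x$z), x$peak_coverage, x$peak_z,
              if (x$tied_peak) " (tied, shallowest reported)" else ""))
  invisible(x)
}

#' Write biomass and depth results as CSV
#'
#' `write_biomass_csv()` emits `time_h, area_um2, normalized`;
#' `write_depth_csv()` emits `z_um, coverage`.
#'
#' @param series A `"biomass_series"`.
#' @param profile A `"depth_profile"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_biomass_csv <- function(series, path) {
  stopifnot(inherits(series, "biomass_series"))
  utils::write.csv(
    data.frame(time_h = series$time, area_um2 = series$area,
               normalized = series$normalized),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_biomass_csv
#' @export
write_depth_csv <- function(profile, path) {
  stopifnot(inherits(profile, "depth_profile"))
  utils::write.csv(data.frame(z_um = profile$z, coverage = profile$coverage),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
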