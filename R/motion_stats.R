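#' Ensemble mean-squared displacement of a trajectory ensemble
#'
#' For lag time `tau = k * frame_interval` the MSD is the mean of
#' `|r(t + tau) - r(t)|^2` over valid (trajectory, start-time) pairs.
#' Two averaging modes are provided:
#' \describe{
#'   \item{`"ensemble"`}{one displacement per particle per lag, taken
#'     from each particle's first detection — the convention behind an
#'     ensemble MSD-versus-time curve of many short particle tracks;}
#'   \item{`"time_averaged"`}{all start times within each track
#'     contribute, giving smoother curves on long synthetic tracks.}
#' }
#' Pairs spanning a detection gap are excluded rather than
#' interpolated. Lags are limited to `max_lag_fraction` of the
#' shortest track's duration; lag statistics beyond that are dominated
#' by noise because few displacement pairs remain.
#'
#' @param ensemble A [trajectory_ensemble()].
#' @param max_lag_fraction Fraction (0, 1] of the shortest track
#'   duration up to which lags are reported. Default 0.25.
#' @param mode `"ensemble"` (default) or `"time_averaged"`.
#' @return An object of class `"msd_curve"`: data.frame with columns
#'   `lag` (s), `msd` (um^2) and `n_pairs`, restricted to lags with at
#'   least one valid pair.
#' @export
ensemble_msd <- function(ensemble, max_lag_fraction = 0.25,
                         mode = c("ensemble", "time_averaged")) {
  mode <- match.arg(mode)
  stopifnot(is_trajectory_ensemble(ensemble))
  if (!is.numeric(max_lag_fraction) || max_lag_fraction <= 0 ||
      max_lag_fraction > 1)
    stop("ensemble_msd: max_lag_fraction must be in (0, 1]", call. = FALSE)
  dtf <- ensemble$calibration$frame_interval
  n_frames_span <- vapply(ensemble$trajectories,
                          function(tr) diff(range(tr$frame)), numeric(1))
  k_max <- floor(max_lag_fraction * min(n_frames_span))
  if (k_max < 1L)
    stop("ensemble_msd: tracks too short for the requested lag range",
         call. = FALSE)
  lags_k <- seq_len(k_max)
  sums <- numeric(k_max)
  counts <- integer(k_max)
  for (tr in ensemble$trajectories) {
    # index positions by frame so gap-spanning pairs drop out naturally
    idx_of_frame <- integer(max(tr$frame) + 1L)
    idx_of_frame[tr$frame + 1L] <- seq_len(nrow(tr))
    for (k in lags_k) {
      if (mode == "ensemble") {
        f0 <- tr$frame[1]
        j <- if (f0 + k <= max(tr$frame)) idx_of_frame[f0 + k + 1L] else 0L
        if (j > 0L) {
          sums[k] <- sums[k] +
            (tr$x[j] - tr$x[1])^2 + (tr$y[j] - tr$y[1])^2
          counts[k] <- counts[k] + 1L
        }
      } else {
        f_start <- tr$frame[tr$frame + k <= max(tr$frame)]
        if (!length(f_start)) next
        i <- idx_of_frame[f_start + 1L]
        j <- idx_of_frame[f_start + k + 1L]
        ok <- i > 0L & j > 0L
        if (!any(ok)) next
        i <- i[ok]; j <- j[ok]
        sums[k] <- sums[k] +
          sum((tr$x[j] - tr$x[i])^2 + (tr$y[j] - tr$y[i])^2)
        counts[k] <- counts[k] + length(i)
      }
    }
  }
  keep <- counts >= 1L
  if (!any(keep))
    stop("ensemble_msd: tracks too short", call. = FALSE)
  out <- data.frame(lag = lags_k[keep] * dtf, msd = sums[keep] / counts[keep],
                    n_pairs = counts[keep])
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("<msd_curve> %d lags, %g-%g s, msd %g-%g um^2\n",
              nrow(x), min(x$lag), max(x$lag), min(x$msd), max(x$msd)))
  invisible(x)
}

.lag_window <- function(curve, fit_lag_range) {
  if (is.null(fit_lag_range)) rep(TRUE, nrow(curve))
  else curve$lag >= fit_lag_range[1] & curve$lag <= fit_lag_range[2]
}

#' Power-law fit of an MSD curve
#'
#' Fits `msd = exp(log_prefactor) * lag^alpha` by ordinary least
#' squares of `log(msd)` on `log(lag)` over the chosen lag window.
#' The exponent `alpha` classifies the motion: 1 for simple diffusion,
#' above 1 superdiffusive (actively driven), below 1 subdiffusive
#' (hindered).
#'
#' @param curve An `"msd_curve"` from [ensemble_msd()].
#' @param fit_lag_range Length-2 numeric `(lo, hi)` in seconds, or
#'   `NULL` (default) for all lags in the curve.
#' @return An object of class `"power_law_fit"`: list with `alpha`,
#'   `log_prefactor`, `r_squared` and `fit_lag_range`.
#' @export
fit_msd_power_law <- function(curve, fit_lag_range = NULL) {
  stopifnot(inherits(curve, "msd_curve"))
  sel <- .lag_window(curve, fit_lag_range)
  lag <- curve$lag[sel]; msd <- curve$msd[sel]
  if (length(lag) < 3L)
    stop("fit_msd_power_law: need >= 3 lag points in range", call. = FALSE)
  if (any(msd <= 0))
    stop("fit_msd_power_law: msd must be strictly positive in range (log undefined)",
         call. = FALSE)
  fit <- stats::lm(log(msd) ~ log(lag))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((log(msd) - mean(log(msd)))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(alpha = unname(stats::coef(fit)[2]),
         log_prefactor = unname(stats::coef(fit)[1]),
         r_squared = max(0, min(1, r2)),
         fit_lag_range = range(lag)),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> alpha = %.3f, r^2 = %.4f over lags %g-%g s\n",
              x$alpha, x$r_squared, x$fit_lag_range[1], x$fit_lag_range[2]))
  invisible(x)
}

#' Classify motion from the anomalous-diffusion exponent
#'
#' A particle with MSD exponent `alpha` below the diffusive band is
#' subdiffusive, above it superdiffusive (actively transported), and
#' inside it consistent with simple diffusion. The band's default
#' (0.9, 1.1) brackets the theoretical diffusive value alpha = 1.
#'
#' @param fit A `"power_law_fit"`.
#' @param band Length-2 numeric `(low, high)` with `low < 1 < high`.
#' @return An object of class `"motion_class"`: list with `label`
#'   (`"subdiffusive"`, `"diffusive"` or `"superdiffusive"`), `alpha`
#'   and `band`.
#' @export
classify_motion <- function(fit, band = c(0.9, 1.1)) {
  stopifnot(inherits(fit, "power_law_fit"))
  if (!(band[1] < 1 && band[2] > 1))
    stop("classify_motion: band must satisfy low < 1 < high", call. = FALSE)
  label <- if (fit$alpha < band[1]) "subdiffusive"
           else if (fit$alpha > band[2]) "superdiffusive"
           else "diffusive"
  structure(list(label = label, alpha = fit$alpha, band = band),
            class = "motion_class")
}

#' @export
print.motion_class <- function(x, ...) {
  cat(sprintf("<motion_class> %s (alpha = %.3f, band %g-%g)\n",
              x$label, x$alpha, x$band[1], x$band[2]))
  invisible(x)
}

#' Diffusion coefficient from the Einstein relation
#'
#' For simple diffusion in `n` dimensions the MSD grows as
#' `<dr^2> = 2 n D tau`, so `D` is the slope of the MSD-versus-lag
#' line through the origin divided by `2 n` — 4 in planar tracking.
#' Some reports divide `<dr^2>/tau` by `n` instead of `2 n`; that
#' convention is available as `convention = "n_dt"` but the standard
#' `2 n` form is the default, being the only one consistent with the
#' closed-form 2-D Brownian MSD.
#'
#' @param curve An `"msd_curve"`.
#' @param dimensionality 1, 2 (default, planar tracking) or 3.
#' @param fit_lag_range Lag window in seconds, or `NULL` for all lags.
#' @param convention `"2n_dt"` (standard, divide slope by `2 n`) or
#'   `"n_dt"` (divide by `n`).
#' @return An object of class `"diffusion_estimate"`: list with `D`
#'   (um^2/s), `dimensionality`, `convention` and `fit_lag_range`.
#'   A negative fitted slope is clamped to `D = 0` with a warning.
#' @export
diffusion_from_msd <- function(curve, dimensionality = 2L,
                               fit_lag_range = NULL,
                               convention = c("2n_dt", "n_dt")) {
  convention <- match.arg(convention)
  stopifnot(inherits(curve, "msd_curve"))
  if (!dimensionality %in% 1:3)
    stop("diffusion_from_msd: dimensionality must be 1, 2 or 3", call. = FALSE)
  sel <- .lag_window(curve, fit_lag_range)
  lag <- curve$lag[sel]; msd <- curve$msd[sel]
  if (length(lag) < 2L)
    stop("diffusion_from_msd: need >= 2 lag points in range", call. = FALSE)
  # least squares through the origin: msd = slope * lag
  slope <- sum(lag * msd) / sum(lag^2)
  if (slope < 0) {
    warning("diffusion_from_msd: negative fitted slope; D clamped to 0",
            call. = FALSE)
    slope <- 0
  }
  divisor <- if (convention == "2n_dt") 2 * dimensionality else dimensionality
  structure(
    list(D = slope / divisor, dimensionality = as.integer(dimensionality),
         convention = convention, fit_lag_range = range(lag)),
    class = "diffusion_estimate"
  )
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("<diffusion_estimate> D = %.4g um^2/s (%d-D, %s convention)\n",
              x$D, x$dimensionality, x$convention))
  invisible(x)
}

#' Per-track speed statistics
#'
#' Per-track speed is the total path length divided by track duration,
#' reported in micrometres per minute. An optional boxcar smoothing of
#' the positions (window in frames) suppresses localization jitter
#' before the path length is summed; path-length speed is invariant
#' under global translation and rotation of the coordinates.
#'
#' @param ensemble A [trajectory_ensemble()].
#' @param smoothing_window Odd integer window (frames) for boxcar
#'   position smoothing; 1 (default) disables smoothing.
#' @return An object of class `"speed_stats"`: list with
#'   `per_track_speed` (um/min), `mean` and `sd`.
#' @export
speed_stats <- function(ensemble, smoothing_window = 1L) {
  stopifnot(is_trajectory_ensemble(ensemble))
  w <- as.integer(smoothing_window)
  if (w < 1L || w %% 2L == 0L)
    stop("speed_stats: smoothing_window must be a positive odd integer",
         call. = FALSE)
  speeds <- vapply(ensemble$trajectories, function(tr) {
    x <- tr$x; y <- tr$y
    if (w > 1L && nrow(tr) >= w) {
      kern <- rep(1 / w, w)
      x <- stats::filter(x, kern, sides = 2)
      y <- stats::filter(y, kern, sides = 2)
      keep <- !is.na(x)
      x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
      tt <- tr$t[keep]
    } else tt <- tr$t
    path <- sum(sqrt(diff(x)^2 + diff(y)^2))
    dur <- tt[length(tt)] - tt[1]
    60 * path / dur  # um/s -> um/min
  }, numeric(1))
  structure(
    list(per_track_speed = speeds, mean = mean(speeds),
         sd = if (length(speeds) > 1L) stats::sd(speeds) else 0),
    class = "speed_stats"
  )
}

#' @export
print.speed_stats <- function(x, ...) {
  cat(sprintf("<speed_stats> %d tracks, mean %.2f +/- %.2f um/min\n",
              length(x$per_track_speed), x$mean, x$sd))
  invisible(x)
}

#' Write an MSD curve to CSV
#'
#' Columns: `lag_s, msd_um2, n_pairs`.
#'
#' @param curve An `"msd_curve"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_msd_csv <- function(curve, path) {
  stopifnot(inherits(curve, "msd_curve"))
  utils::write.csv(
    data.frame(lag_s = curve$lag, msd_um2 = curve$msd, n_pairs = curve$n_pairs),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' One-shot motion summary of a trajectory ensemble
#'
#' Convenience wrapper chaining [ensemble_msd()],
#' [fit_msd_power_law()], [diffusion_from_msd()], [classify_motion()]
#' and [speed_stats()] into the summary a tracking experiment usually
#' reports: alpha, D, mean speed and the motion class.
#'
#' @param ensemble A [trajectory_ensemble()].
#' @param max_lag_fraction Passed to [ensemble_msd()].
#' @param mode MSD averaging mode.
#' @param band Diffusive classification band.
#' @return A list with elements `msd`, `fit`, `diffusion`, `speed`,
#'   `class` and a flat `summary` list (alpha, r_squared, D_um2_s,
#'   mean_speed_um_min, sd_speed_um_min, motion_class).
#' @export
motion_summary <- function(ensemble, max_lag_fraction = 0.25,
                           mode = "ensemble", band = c(0.9, 1.1)) {
  curve <- ensemble_msd(ensemble, max_lag_fraction, mode)
  fit <- fit_msd_power_law(curve)
  dif <- diffusion_from_msd(curve)
  spd <- speed_stats(ensemble)
  cls <- classify_motion(fit, band)
  list(msd = curve, fit = fit, diffusion = dif, speed = spd, class = cls,
       summary = list(alpha = fit$alpha, r_squared = fit$r_squared,
                      D_um2_s = dif$D, mean_speed_um_min = spd$mean,
                      sd_speed_um_min = spd$sd, motion_class = cls$label))
}
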