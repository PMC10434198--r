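#' Generate trajectory ensembles with known motion ground truth
#'
#' Emulates the three motion regimes seen in phage-tracking
#' experiments on swarm plates, with the generating parameters
#' retained so estimator tests are self-checking:
#' \describe{
#'   \item{`"brownian"`}{i.i.d. Gaussian steps per axis with variance
#'     `2 D dt`, the thin-liquid-film diffusion null model;}
#'   \item{`"fbm"`}{fractional Brownian motion per axis with Hurst
#'     exponent `H = alpha_target / 2`, synthesized exactly from the
#'     position covariance
#'     `D (s^alpha + t^alpha - |t - s|^alpha)` (Cholesky), giving a
#'     2-D ensemble MSD of `4 D tau^alpha` — subdiffusive crowding for
#'     `alpha < 1`, persistent active motion for `alpha > 1`;}
#'   \item{`"advective"`}{Brownian steps plus a drift `v dt` along a
#'     fixed heading, or a heading rotating at a constant angular rate
#'     (`heading = "swarm-circular"`) mimicking transport around a
#'     vortexing swarm.}
#' }
#' All models are bit-reproducible under `(params, seed)`.
#'
#' @param model `"brownian"`, `"fbm"` or `"advective"`.
#' @param D Diffusion coefficient, um^2/s (for `"fbm"` the
#'   generalized coefficient in um^2/s^alpha). Default 0.041, the
#'   wet-agar surface value for lambda phage.
#' @param v Drift speed for `"advective"`, um/min. Default 20.71, the
#'   mean speed of swarm-carried phages.
#' @param heading Drift direction in radians, or `"swarm-circular"`.
#' @param angular_rate Heading rotation rate (rad/s) for
#'   `"swarm-circular"`; default one revolution per track duration.
#' @param alpha_target MSD exponent in (0, 2), required for `"fbm"`.
#' @param dt Frame interval, s. Default 1.
#' @param n_steps Number of steps per track (tracks have
#'   `n_steps + 1` points). Default 200.
#' @param n_particles Number of tracks. Default 300.
#' @param pixel_size um/px recorded in the calibration (positions are
#'   generated directly in um).
#' @param seed Integer RNG seed.
#' @return A list with `ensemble` (a [trajectory_ensemble()]) and
#'   `truth` (the generating parameters).
#' @export
gen_trajectories <- function(model = c("brownian", "fbm", "advective"),
                             D = 0.041, v = 20.71, heading = 0,
                             angular_rate = NULL, alpha_target = NULL,
                             dt = 1, n_steps = 200L, n_particles = 300L,
                             pixel_size = 0.1, seed = 1L) {
  model <- match.arg(model)
  if (D < 0) stop("gen_trajectories: D must be >= 0", call. = FALSE)
  if (n_steps < 2L) stop("gen_trajectories: n_steps must be >= 2", call. = FALSE)
  if (model == "fbm") {
    if (is.null(alpha_target) || alpha_target <= 0 || alpha_target >= 2)
      stop("gen_trajectories: fbm requires alpha_target in (0, 2)",
           call. = FALSE)
  }
  cal <- calibration(pixel_size = pixel_size, frame_interval = dt)
  n_pts <- n_steps + 1L
  trajs <- withr::with_seed(as.integer(seed), {
    if (model == "fbm") {
      tms <- seq_len(n_steps) * dt
      a <- alpha_target
      # position covariance of fBm scaled so per-axis Var X(t) = 2 D t^a
      cov <- D * (outer(tms^a, tms^a, `+`) -
                    abs(outer(tms, tms, `-`))^a)
      L <- t(chol(cov))
      xs <- rbind(0, L %*% matrix(stats::rnorm(n_steps * n_particles),
                                  n_steps))
      ys <- rbind(0, L %*% matrix(stats::rnorm(n_steps * n_particles),
                                  n_steps))
    } else {
      step_sd <- sqrt(2 * D * dt)
      xs <- apply(rbind(0, matrix(stats::rnorm(n_steps * n_particles,
                                               sd = step_sd), n_steps)),
                  2, cumsum)
      ys <- apply(rbind(0, matrix(stats::rnorm(n_steps * n_particles,
                                               sd = step_sd), n_steps)),
                  2, cumsum)
      if (model == "advective") {
        v_um_s <- v / 60
        if (identical(heading, "swarm-circular")) {
          if (is.null(angular_rate)) angular_rate <- 2 * pi / (n_steps * dt)
          th <- angular_rate * (seq_len(n_steps) - 1L) * dt
        } else th <- rep(as.numeric(heading), n_steps)
        drift_x <- cumsum(c(0, v_um_s * dt * cos(th)))
        drift_y <- cumsum(c(0, v_um_s * dt * sin(th)))
        xs <- xs + drift_x
        ys <- ys + drift_y
      }
    }
    lapply(seq_len(n_particles), function(i)
      trajectory(track_id = as.character(i), frame = 0:n_steps,
                 x = xs[, i], y = ys[, i], frame_interval = dt))
  })
  truth <- list(model = model, D = D, dt = dt, n_steps = n_steps,
                n_particles = n_particles, seed = as.integer(seed))
  if (model == "advective") {
    truth$v_um_min <- v
    truth$heading <- heading
  }
  if (model == "fbm") truth$alpha <- alpha_target else truth$alpha <- 1
  list(ensemble = trajectory_ensemble(trajs, cal), truth = truth)
}

.disc_mask_dist <- function(size_px) {
  ctr <- (size_px + 1) / 2
  d <- seq_len(size_px) - ctr
  sqrt(outer(d^2, d^2, `+`))
}

#' Generate a shrinking fluorescent colony timelapse
#'
#' Emulates an hourly fluorescence timelapse of a prey colony whose
#' biomass decays quadratically: the normalized area follows
#' `A(t) = clip(1 - a1 t - a2 t^2, 0, 1)`, rendered as a centred disc
#' of matching area with Gaussian pixel noise. The default decay
#' halves the biomass over 20 hours of imaging, the experimental
#' (phage-delivery) condition; a slowly decaying control is obtained
#' by scaling `a1`/`a2` down tenfold. Intensities stay in `[0, 1]`
#' (values clipped after noise) so stacks round-trip through TIFF.
#'
#' @param size_px Image side length in pixels. Default 200.
#' @param pixel_size um/px. Default 2.
#' @param initial_radius Initial colony radius, um. Default 150.
#' @param frames Number of frames. Default 21 (hourly, 0-20 h).
#' @param frame_interval_h Hours between frames. Default 1.
#' @param a1,a2 Linear and quadratic decay coefficients of the
#'   normalized area, per hour and per hour^2. Defaults 0.015 and
#'   5e-4 (50% biomass loss at 20 h).
#' @param fg,bg Foreground/background intensities. Defaults 0.8, 0.1.
#' @param noise_sd Gaussian pixel-noise SD. Default 0.07, i.e. a
#'   contrast-to-noise ratio of 10.
#' @param seed Integer RNG seed.
#' @return A list with `stack` (time [image_stack()]) and `truth`
#'   (a ground-truth `"biomass_series"` plus the parameters).
#' @export
gen_colony_timelapse <- function(size_px = 200L, pixel_size = 2,
                                 initial_radius = 150, frames = 21L,
                                 frame_interval_h = 1, a1 = 0.015,
                                 a2 = 5e-4, fg = 0.8, bg = 0.1,
                                 noise_sd = 0.07, seed = 1L) {
  if (initial_radius / pixel_size > size_px / 2)
    stop("gen_colony_timelapse: initial radius does not fit in the frame",
         call. = FALSE)
  if (fg < 0 || bg < 0 || fg > 1 || bg > 1)
    stop("gen_colony_timelapse: intensities must be in [0, 1]", call. = FALSE)
  times_h <- (seq_len(frames) - 1L) * frame_interval_h
  norm <- pmin(1, pmax(0, 1 - a1 * times_h - a2 * times_h^2))
  r0_px <- initial_radius / pixel_size
  radii_px <- r0_px * sqrt(norm)
  dist <- .disc_mask_dist(size_px)
  arr <- withr::with_seed(as.integer(seed), {
    a <- array(0, c(frames, size_px, size_px))
    for (i in seq_len(frames)) {
      img <- ifelse(dist <= radii_px[i], fg, bg)
      if (noise_sd > 0)
        img <- img + matrix(stats::rnorm(size_px^2, sd = noise_sd),
                            size_px)
      a[i, , ] <- pmin(1, pmax(0, img))
    }
    a
  })
  cal <- calibration(pixel_size = pixel_size,
                     frame_interval = frame_interval_h * 3600)
  truth_series <- biomass_series(times_h, norm * pi * initial_radius^2)
  list(stack = image_stack(arr, axis_kind = "time", calibration = cal,
                           channel_label = "prey biomass (synthetic)"),
       truth = list(series = truth_series, a1 = a1, a2 = a2,
                    initial_radius = initial_radius,
                    noise_sd = noise_sd, seed = as.integer(seed)))
}

#' Generate a biofilm z-stack with a known phage depth distribution
#'
#' Emulates a confocal z-stack of the phage channel through a biofilm
#' (36 slices at a 3-um z-step, spanning 0-105 um): each slice
#' receives a Poisson number of fluorescent spots with expectation
#' proportional to the chosen depth law, rendered as Gaussian blobs
#' over background noise.
#'
#' Depth laws:
#' \describe{
#'   \item{`"gaussian"`}{spot density peaked at `mu_z` (default 50 um,
#'     mid-biofilm delivery by an invading swarm) with SD `sigma_z`;
#'     the default `sigma_z = 5` keeps the density fall-off between
#'     neighbouring 3-um slices large against Poisson counting noise,
#'     so the coverage argmax is statistically resolvable at the slice
#'     spacing;}
#'   \item{`"surface_exponential"`}{density decaying from the top
#'     slice with length `decay_um` — the control geometry where
#'     phages pile up on the biofilm surface and the coverage peak
#'     sits at `z = 0`.}
#' }
#'
#' @param slices Number of z-slices. Default 36.
#' @param z_step um between slices. Default 3.
#' @param size_px Slice side length in pixels. Default 160.
#' @param pixel_size um/px. Default 0.5.
#' @param law `"gaussian"` or `"surface_exponential"`.
#' @param mu_z,sigma_z Gaussian law: peak depth and SD, um.
#' @param decay_um Exponential law: decay length, um. Default 10.
#' @param spots_scale Expected spot count per slice where the depth
#'   law equals 1 (its peak). Default 600.
#' @param spot_radius_px Gaussian blob SD in pixels. Default 2.
#' @param spot_intensity Blob peak intensity. Default 0.8.
#' @param bg Background level. Default 0.05.
#' @param noise_sd Gaussian pixel-noise SD. Default 0.02.
#' @param seed Integer RNG seed.
#' @return A list with `stack` (depth [image_stack()]) and `truth`
#'   (slice depths `z`, `expected_spots` per slice, `peak_z` = depth
#'   of maximal expected density, plus the parameters).
#' @export
gen_biofilm_zstack <- function(slices = 36L, z_step = 3, size_px = 160L,
                               pixel_size = 0.5,
                               law = c("gaussian", "surface_exponential"),
                               mu_z = 50, sigma_z = 5, decay_um = 10,
                               spots_scale = 600, spot_radius_px = 2,
                               spot_intensity = 0.8, bg = 0.05,
                               noise_sd = 0.02, seed = 1L) {
  law <- match.arg(law)
  z <- (seq_len(slices) - 1L) * z_step
  if (law == "gaussian" && (mu_z < 0 || mu_z > max(z)))
    stop("gen_biofilm_zstack: mu_z must lie within the stack depth",
         call. = FALSE)
  density <- switch(law,
    gaussian = exp(-(z - mu_z)^2 / (2 * sigma_z^2)),
    surface_exponential = exp(-z / decay_um))
  lambda <- spots_scale * density
  half <- ceiling(3 * spot_radius_px)
  patch_idx <- -half:half
  blob <- spot_intensity *
    exp(-outer(patch_idx^2, patch_idx^2, `+`) / (2 * spot_radius_px^2))
  arr <- withr::with_seed(as.integer(seed), {
    a <- array(0, c(slices, size_px, size_px))
    for (s in seq_len(slices)) {
      img <- matrix(bg, size_px, size_px)
      n_spots <- stats::rpois(1, lambda[s])
      if (n_spots > 0) {
        cx <- sample.int(size_px, n_spots, replace = TRUE)
        cy <- sample.int(size_px, n_spots, replace = TRUE)
        for (k in seq_len(n_spots)) {
          rows <- cx[k] + patch_idx
          cols <- cy[k] + patch_idx
          ok_r <- rows >= 1L & rows <= size_px
          ok_c <- cols >= 1L & cols <= size_px
          img[rows[ok_r], cols[ok_c]] <-
            img[rows[ok_r], cols[ok_c]] + blob[ok_r, ok_c]
        }
      }
      if (noise_sd > 0)
        img <- img + matrix(stats::rnorm(size_px^2, sd = noise_sd), size_px)
      a[s, , ] <- pmin(1, pmax(0, img))
    }
    a
  })
  cal <- calibration(pixel_size = pixel_size, frame_interval = 1,
                     z_step = z_step)
  truth <- list(z = z, expected_spots = lambda,
                peak_z = z[which.max(lambda)], law = law,
                mu_z = if (law == "gaussian") mu_z else NA_real_,
                sigma_z = if (law == "gaussian") sigma_z else NA_real_,
                decay_um = if (law == "surface_exponential") decay_um
                           else NA_real_,
                spots_scale = spots_scale, seed = as.integer(seed))
  list(stack = image_stack(arr, axis_kind = "depth", calibration = cal,
                           channel_label = "phage (synthetic)"),
       truth = truth)
}

#' Write a generator's ground truth as sidecar JSON
#'
#' Generators emit their ground truth alongside the data so recovery
#' tests compare against the recorded truth instead of re-deriving it.
#'
#' @param truth The `truth` element returned by a generator.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(truth, path) {
  if (inherits(truth$series, "biomass_series"))
    truth$series <- as.data.frame(truth$series)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
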