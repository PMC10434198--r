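test_that("segmentation recovers a known disc area and handles edge cases", {
  size <- 128
  d <- seq_len(size) - (size + 1) / 2
  dist <- sqrt(outer(d^2, d^2, `+`))
  plane <- ifelse(dist <= 50, 0.9, 0.05)
  seg <- segment_fluorescence(plane, pixel_size = 1)
  expect_lt(abs(seg$area - pi * 50^2) / (pi * 50^2), 0.02)

  # nothing above a fixed threshold -> zero area
  seg0 <- segment_fluorescence(matrix(0.1, 32, 32), method = "fixed",
                               threshold = 0.5)
  expect_equal(seg0$area, 0)

  expect_error(segment_fluorescence(matrix(1, 16, 16)), "degenerate")
  expect_error(segment_fluorescence(matrix(0.5, 8, 8), method = "fixed"),
               "needs a threshold")
})

test_that("segmented area is monotone non-increasing in a fixed threshold", {
  g <- gen_colony_timelapse(size_px = 96, initial_radius = 70, frames = 2,
                            seed = 21)
  plane <- g$stack$data[1, , ]
  areas <- vapply(seq(0.2, 0.9, by = 0.1), function(th)
    segment_fluorescence(plane, method = "fixed", threshold = th)$area_px,
    numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("despeckling removes objects below min_object_px", {
  plane <- matrix(0, 64, 64)
  plane[10:20, 10:20] <- 1        # 121 px object
  plane[40, 40] <- 1              # single-pixel speckle
  seg <- segment_fluorescence(plane, method = "fixed", threshold = 0.5,
                              min_object_px = 9)
  expect_equal(seg$area_px, 121)
})

test_that("biomass series tracks known disc sequences", {
  size <- 128
  d <- seq_len(size) - (size + 1) / 2
  dist <- sqrt(outer(d^2, d^2, `+`))
  mk <- function(r) ifelse(dist <= r, 0.9, 0.05)
  stack <- image_stack(list(mk(50), mk(40), mk(30)), axis_kind = "time",
                       calibration = calibration(pixel_size = 1,
                                                 frame_interval = 3600))
  ser <- biomass_timeseries(stack)
  expect_true(all(diff(ser$area) < 0))
  expect_equal(ser$area, pi * c(50, 40, 30)^2, tolerance = 0.02)
  expect_equal(ser$time, 0:2)
  expect_equal(ser$normalized[1], 1)

  const <- image_stack(list(mk(40), mk(40), mk(40)), axis_kind = "time",
                       calibration = calibration(frame_interval = 3600))
  expect_equal(diff(biomass_timeseries(const)$area), c(0, 0))

  expect_error(
    biomass_timeseries(image_stack(array(0.5, c(2, 8, 8)),
                                   axis_kind = "depth")),
    "axis_kind")
})

test_that("generated timelapse areas are recovered within 5% elementwise", {
  g <- gen_colony_timelapse(seed = 14)  # contrast-to-noise 10 by default
  ser <- biomass_timeseries(g$stack)
  expect_equal(nrow(ser), 21L)
  rel <- abs(ser$area - g$truth$series$area) / g$truth$series$area
  expect_lt(max(rel), 0.05)
})

test_that("quadratic trend is exact on noiseless input with zero-width band", {
  t <- seq(0, 9)
  A <- 100 - 2 * t - 0.5 * t^2  # positive over the sampled window
  tr <- fit_quadratic_trend(biomass_series(t, A))
  expect_equal(unname(tr$coefficients), c(100, -2, -0.5), tolerance = 1e-9)
  expect_lt(max(tr$upper - tr$lower), 1e-6)

  trc <- fit_quadratic_trend(biomass_series(t, rep(10, length(t))))
  expect_equal(unname(trc$coefficients[2:3]), c(0, 0), tolerance = 1e-9)
  expect_error(fit_quadratic_trend(biomass_series(0:2, c(3, 2, 1))), ">= 4")
})

test_that("95% confidence band holds its nominal pointwise coverage", {
  t <- seq(0, 18, by = 2)
  truthA <- 100 - 1.5 * t - 0.1 * t^2  # stays well above zero
  sigma <- 2
  withr::with_seed(99, {
    cov <- replicate(500, {
      tr <- fit_quadratic_trend(
        biomass_series(t, truthA + rnorm(length(t), sd = sigma)))
      mean(truthA >= tr$lower & truthA <= tr$upper)
    })
  })
  expect_gt(mean(cov), 0.92)
  expect_lt(mean(cov), 0.98)
})

test_that("clearance rates: arithmetic, identity and undefined control", {
  t <- 0:20
  exp_ser <- biomass_series(t, 1000 * (1 - 0.025 * t))   # -50% over 20 h
  ctl_ser <- biomass_series(t, 1000 * (1 - 0.0025 * t))  # -5% over 20 h
  r <- clearance_rate_ratio(exp_ser, ctl_ser)
  expect_equal(r$ratio, 10, tolerance = 1e-12)
  expect_equal(clearance_rate_ratio(exp_ser, exp_ser)$ratio, 1)

  flat <- biomass_series(t, rep(1000, 21))
  expect_warning(r0 <- clearance_rate_ratio(exp_ser, flat), "undefined")
  expect_true(r0$undefined)
  expect_true(is.na(r0$ratio))
})

test_that("built-in 10x clearance-rate ratio is recovered from images", {
  ge <- gen_colony_timelapse(seed = 3)                       # -50%/20 h
  gc <- gen_colony_timelapse(a1 = 0.0015, a2 = 5e-5, seed = 4)  # -5%/20 h
  truth_ratio <- clearance_rate_ratio(ge$truth$series, gc$truth$series)$ratio
  expect_equal(truth_ratio, 10, tolerance = 1e-12)
  meas <- clearance_rate_ratio(biomass_timeseries(ge$stack),
                               biomass_timeseries(gc$stack))
  expect_lt(abs(meas$ratio - 10) / 10, 0.15)
})

test_that("depth profile finds the engineered peak and control surface", {
  bz <- gen_biofilm_zstack(seed = 18)  # gaussian peak at 50 um
  prof <- phage_depth_profile(bz$stack)
  expect_equal(length(prof$z), 36L)
  expect_true(all(prof$coverage >= 0 & prof$coverage <= 1))
  expect_lte(abs(prof$peak_z - 50), 3)

  ctrl <- gen_biofilm_zstack(law = "surface_exponential", seed = 18)
  expect_equal(phage_depth_profile(ctrl$stack)$peak_z, 0)

  empty <- image_stack(array(0.05, c(4, 16, 16)), axis_kind = "depth")
  expect_error(phage_depth_profile(empty), "degenerate|no foreground")
})

test_that("Otsu depth coverage is invariant to uniform intensity rescaling", {
  bz <- gen_biofilm_zstack(size_px = 64, spots_scale = 80, seed = 6)
  p1 <- phage_depth_profile(bz$stack)
  half <- image_stack(bz$stack$data * 0.5, axis_kind = "depth",
                      calibration = bz$stack$calibration)
  p2 <- phage_depth_profile(half)
  expect_equal(p2$coverage, p1$coverage)
  expect_equal(p2$peak_z, p1$peak_z)
})
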