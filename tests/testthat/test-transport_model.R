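test_that("Stokes-Einstein diffusivity and its scalings", {
  # direct formula evaluation: k_B * 298 / (6 pi * 1e-3 * 30e-9)
  expect_equal(stokes_einstein_diffusivity(30e-9), 7.27574e-12,
               tolerance = 1e-5)
  D1 <- stokes_einstein_diffusivity(10e-9)
  expect_equal(stokes_einstein_diffusivity(20e-9), D1 / 2, tolerance = 1e-12)
  expect_equal(stokes_einstein_diffusivity(10e-9, temperature = 596),
               2 * D1, tolerance = 1e-12)
  expect_error(stokes_einstein_diffusivity(0), "radius")
})

test_that("diffusive slow-down factor is the radius ratio", {
  expect_equal(diffusivity_ratio(1e-9, 30e-9), 30)
  expect_equal(diffusivity_ratio(5, 5), 1)
  expect_equal(diffusivity_ratio(2, 6), 3)
  expect_error(diffusivity_ratio(0, 1), "> 0")
})

test_that("vortexing-to-linear swarm speed is s1 / pi", {
  expect_equal(swarm_linear_speed(20), 20 / pi, tolerance = 1e-12)
  expect_gte(swarm_linear_speed(20), 6.36)
  expect_lte(swarm_linear_speed(20), 6.37)
  expect_equal(swarm_linear_speed(0), 0)
  expect_equal(swarm_linear_speed(pi), 1)
  expect_error(swarm_linear_speed(-1), ">= 0")
})

test_that("pde_run enforces stability bounds and names the admissible dt", {
  expect_error(pde_run(D = 0.5, domain_length = 10, dx = 1, dt = 2,
                       t_final = 10),
               "D\\*dt/dx\\^2.*max admissible dt = 1")
  expect_error(pde_run(D = 0, v_d = 2, domain_length = 10, dx = 1, dt = 1,
                       t_final = 10),
               "CFL.*max admissible dt = 0.5")
  run <- pde_run(D = 0.5, v_d = 0.1, domain_length = 10, t_final = 10)
  expect_equal(run$dt, 0.5)  # half the tighter (diffusive) bound
  expect_error(simulate_transport_1d(run, 20), "beyond t_final")
})

test_that("zero-flux runs conserve mass and keep C nonnegative", {
  init <- numeric(201); init[51] <- 2; init[120] <- 1
  run <- pde_run(D = 0.3, v_d = 0.05, domain_length = 200, t_final = 800,
                 initial = init)
  fields <- simulate_transport_1d(run, c(0, 400, 800))
  mass0 <- sum(init) * run$dx
  for (f in fields) {
    expect_lt(abs(sum(f$C) * run$dx - mass0) / mass0, 1e-6)
    expect_true(all(f$C >= 0))
  }
})

test_that("pure diffusion keeps the centre of mass fixed and variance = 2Dt", {
  init <- numeric(401); init[201] <- 1
  run <- pde_run(D = 0.228, v_d = 0, domain_length = 400, dx = 1,
                 t_final = 2000, initial = init)
  fields <- simulate_transport_1d(run, c(0, 1000, 2000))
  com <- vapply(fields, function(f) sum(f$x * f$C) / sum(f$C), numeric(1))
  expect_lt(max(abs(com - com[1])) / com[1], 1e-6)
  f <- fields[[3]]
  v <- sum((f$x - com[3])^2 * f$C) / sum(f$C)
  expect_lt(abs(v - 2 * 0.228 * f$t) / (2 * 0.228 * f$t), 0.02)
})

test_that("diffusion-free advection translates a point release exactly", {
  run <- pde_run(D = 0, v_d = 1, domain_length = 200, dx = 1, t_final = 100)
  f <- simulate_transport_1d(run, 100)[[1]]
  expect_equal(f$x[which.max(f$C)], 100)
})

test_that("numerical solution matches the translated Gaussian closed form", {
  D <- 0.228; v <- 0.008; t <- 8000; x0 <- 400
  init <- numeric(801); init[x0 + 1] <- 1
  run <- pde_run(D = D, v_d = v, domain_length = 800, dx = 1, t_final = t,
                 initial = init)
  f <- simulate_transport_1d(run, t)[[1]]
  oracle <- exp(-(f$x - x0 - v * t)^2 / (4 * D * t)) / sqrt(4 * pi * D * t)
  expect_lt(max(abs(f$C - oracle)) / max(oracle), 0.01)
})

test_that("front_distance reads the Gaussian tail and degenerate profiles", {
  x <- 0:2000
  sigma <- 73.6
  gauss <- structure(list(x = x, C = exp(-(x - 1259)^2 / (2 * sigma^2)),
                          t = 0), class = "concentration_field")
  # C >= 0.01 max out to 1259 + sqrt(2 ln 100) sigma = 1482.4 um
  expect_equal(front_distance(gauss, 0.01), 1482)

  unif <- structure(list(x = 0:50, C = rep(1, 51), t = 0),
                    class = "concentration_field")
  expect_equal(front_distance(unif, 0.5), 50)

  peak <- structure(list(x = 0:50, C = c(rep(0.001, 30), 1, rep(0.001, 20)),
                         t = 0), class = "concentration_field")
  expect_equal(front_distance(peak, 0.999), 30)

  zero <- structure(list(x = 0:10, C = rep(0, 11), t = 0),
                    class = "concentration_field")
  expect_error(front_distance(zero), "all-zero")
  expect_error(front_distance(gauss, 1.5), "fraction")
})

test_that("front distance grows with time under nonnegative drift", {
  dists <- vapply(c(1, 2, 3), function(th)
    predict_travel_distance(D = 0.1, v_d = 2, t = th)$distance_um, numeric(1))
  expect_true(all(diff(dists) > 0))
})

test_that("travel-distance limits: immobile stays put, advection scales linearly", {
  expect_equal(predict_travel_distance(D = 0, v_d = 0, t = 5)$distance_um, 0)
  d1 <- predict_travel_distance(D = 0, v_d = 3, t = 1)$distance_um
  d2 <- predict_travel_distance(D = 0, v_d = 3, t = 2)$distance_um
  expect_equal(d2, 2 * d1, tolerance = 1e-2)
})

test_that("reported travel distance is stable under grid refinement", {
  # first-order upwind smears the front by ~ v dx / 2, so the raw front
  # moves a few um when dx halves; the reported (nearest-100-um) distance
  # must not.
  d1 <- predict_travel_distance(D = 0.228, v_d = 6.36, t = 3.3,
                                dx = 1)$distance_um
  d2 <- predict_travel_distance(D = 0.228, v_d = 6.36, t = 3.3,
                                dx = 0.5)$distance_um
  expect_lt(abs(d1 - d2) / d1, 0.01)
  expect_equal(round(d1 / 100), round(d2 / 100))
})

test_that("swarm-transport prediction reproduces ~1500 um in 3.3 h", {
  res <- predict_travel_distance(D = 0.228, v_d = 6.36, t = 3.3,
                                 fraction = 0.01, dx = 1)
  expect_equal(round(res$distance_um / 100) * 100, 1500)
  # closed-form cross-check: v t + 3.035 sqrt(2 D t)
  t_s <- 3.3 * 3600
  closed <- (6.36 / 60) * t_s + 3.035 * sqrt(2 * 0.228 * t_s)
  expect_lt(abs(res$distance_um - closed), 50)
})
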