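test_that("initial pressure is Grueneisen x absorption x fluence", {
  mu <- matrix(0, 10, 8)
  phi <- matrix(2, 10, 8)
  expect_true(all(initial_pressure(mu, phi) == 0))

  mu[5, 4] <- 1.5
  p <- initial_pressure(mu, phi, grueneisen = 0.8)
  expect_equal(sum(p != 0), 1)                      # point absorber only
  expect_equal(p[5, 4], 0.8 * 1.5 * 2)
  expect_equal(initial_pressure(mu, 2 * phi), 2 * initial_pressure(mu, phi))
  expect_error(initial_pressure(mu, matrix(1, 3, 3)), "grid")
})

test_that("PA RF arrival matches an independent delay oracle", {
  geom <- tiny_geometry(8L)
  grid <- image_grid(c(-1e-3, 1e-3), c(9e-3, 11e-3), dx = 0.1e-3, dz = 0.1e-3)
  p0 <- matrix(0, grid$nz, grid$nx)
  iz <- which.min(abs(grid$z - 10e-3))
  ix <- which.min(abs(grid$x))
  p0[iz, ix] <- 1
  rf <- simulate_pa_rf(p0, geom, grid)

  # expected arrival per element, computed independently of the simulator
  src <- c(grid$x[ix], 0, grid$z[iz])
  for (e in c(1, 4, 8)) {
    d <- sqrt(sum((src - geom$element_positions[e, ])^2))
    t_true <- d / geom$sound_speed
    env <- Mod(analytic_signal(rf$samples[e, ]))
    t_peak <- (which.max(env) - 1) / rf$sampling_rate
    expect_lt(abs(t_peak - t_true), 1 / rf$sampling_rate)  # < 1 sample
  }
  # the element above the source at z = 10 mm peaks near 6.49 us
  mid <- which.min(abs(geom$element_positions[, 1]))
  env <- Mod(analytic_signal(rf$samples[mid, ]))
  expect_equal((which.max(env) - 1) / rf$sampling_rate, 6.49e-6,
               tolerance = 0.01)

  # zero pressure, zero noise -> all-zero frame
  rf0 <- simulate_pa_rf(matrix(0, grid$nz, grid$nx), geom, grid)
  expect_true(all(rf0$samples == 0))
  expect_error(simulate_pa_rf(p0, geom, grid, noise_sigma = -1), ">= 0")
})

test_that("simulators are linear in source strength", {
  geom <- tiny_geometry(8L)
  grid <- image_grid(c(-1e-3, 1e-3), c(9e-3, 11e-3), dx = 0.1e-3, dz = 0.1e-3)
  p1 <- matrix(0, grid$nz, grid$nx); p1[5, 5] <- 1
  p2 <- matrix(0, grid$nz, grid$nx); p2[15, 12] <- 2
  rf_sum <- simulate_pa_rf(p1 + p2, geom, grid)
  rf_a <- simulate_pa_rf(p1, geom, grid)
  rf_b <- simulate_pa_rf(p2, geom, grid)
  expect_equal(rf_sum$samples, rf_a$samples + rf_b$samples, tolerance = 1e-12)
})

test_that("US pulse-echo delays follow the two-way oracle", {
  geom <- tiny_geometry(8L)
  grid <- image_grid(c(-1e-3, 1e-3), c(5e-3, 9e-3), dx = 0.1e-3, dz = 0.1e-3)
  sc <- cbind(x = 0.4e-3, z = 7e-3, reflectivity = 1)
  rf <- simulate_us_rf(sc, geom, grid)
  for (e in c(1, 5)) {
    d <- sqrt(sum((c(sc[1, "x"], 0, sc[1, "z"]) -
                     geom$element_positions[e, ])^2))
    t_true <- sc[1, "z"] / geom$sound_speed + d / geom$sound_speed
    env <- Mod(analytic_signal(rf$samples[e, ]))
    t_peak <- (which.max(env) - 1) / rf$sampling_rate
    expect_lt(abs(t_peak - t_true), 1 / rf$sampling_rate)
  }
  # empty scatterer set -> zero frame
  rf0 <- simulate_us_rf(sc[0, , drop = FALSE], geom, grid)
  expect_true(all(rf0$samples == 0))
})

test_that("axial shift of the medium shifts the RF cross-correlation lag", {
  geom <- tiny_geometry(16L)
  grid <- image_grid(c(-2e-3, 2e-3), c(5e-3, 9e-3), dx = 0.1e-3, dz = 0.1e-3)
  ph <- make_phantom(grid, list(), scatterers_per_cell = 8, seed = 3)
  delta <- 0.2e-3
  s1 <- ph$scatterers
  s2 <- s1; s2[, "z"] <- s2[, "z"] + delta
  rf1 <- simulate_us_rf(s1, geom, grid)
  rf2 <- simulate_us_rf(s2, geom, grid)
  # two-way: expected lag ~ 2 * delta / c in samples, via 1-D correlation
  e <- 8
  cc <- ccf(rf2$samples[e, ], rf1$samples[e, ], lag.max = 40, plot = FALSE)
  lag_est <- cc$lag[which.max(cc$acf)]
  lag_true <- 2 * delta / geom$sound_speed * rf1$sampling_rate
  expect_lt(abs(lag_est - lag_true), 1.5)
})

test_that("pulse spectrum peaks at the center frequency", {
  p <- gauss_pulse(15e6, 0.6)
  fs <- 250e6
  t <- seq(-4 * p$sigma_t, 4 * p$sigma_t, by = 1 / fs)
  w <- pulse_waveform(p, t)
  n <- length(w)
  spec <- Mod(fft(w))[1:(n %/% 2)]
  f_peak <- (which.max(spec) - 1) * fs / n
  expect_equal(f_peak, 15e6, tolerance = 0.02)
})
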