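test_that("DAS localizes a point source within half an acoustic wavelength", {
  geom <- probe_geometry(n_elements = 64, element_pitch = 0.15e-3)
  grid <- image_grid(c(-1e-3, 1e-3), c(9e-3, 11e-3),
                     dx = 0.025e-3, dz = 0.025e-3)
  half_wl <- geom$sound_speed / geom$center_frequency / 2   # ~51 um
  for (pos in list(c(0, 10e-3), c(0.5e-3, 9.6e-3))) {
    p0 <- matrix(0, grid$nz, grid$nx)
    iz <- which.min(abs(grid$z - pos[2]))
    ix <- which.min(abs(grid$x - pos[1]))
    p0[iz, ix] <- 1
    img <- das_pa(simulate_pa_rf(p0, geom, grid), geom, grid)
    pk <- which(Mod(img$data) == max(Mod(img$data)), arr.ind = TRUE)
    expect_lt(abs(grid$z[pk[1]] - grid$z[iz]), half_wl)
    expect_lt(abs(grid$x[pk[2]] - grid$x[ix]), half_wl)
  }
})

test_that("DAS is linear and zero in gives zero out", {
  geom <- tiny_geometry(8L)
  grid <- image_grid(c(-1e-3, 1e-3), c(9e-3, 11e-3), dx = 0.1e-3, dz = 0.1e-3)
  rf0 <- simulate_pa_rf(matrix(0, grid$nz, grid$nx), geom, grid)
  expect_true(all(das_pa(rf0, geom, grid)$data == 0))

  p1 <- matrix(0, grid$nz, grid$nx); p1[6, 6] <- 1
  p2 <- matrix(0, grid$nz, grid$nx); p2[14, 14] <- 1
  img_sum <- das_pa(simulate_pa_rf(p1 + 2 * p2, geom, grid), geom, grid)$data
  img_1 <- das_pa(simulate_pa_rf(p1, geom, grid), geom, grid)$data
  img_2 <- das_pa(simulate_pa_rf(p2, geom, grid), geom, grid)$data
  expect_equal(img_sum, img_1 + 2 * img_2, tolerance = 1e-10)

  # two well-separated points produce local maxima at both positions
  env <- Mod(img_sum)
  near <- function(iz, ix) max(env[(iz - 2):(iz + 2), (ix - 2):(ix + 2)])
  expect_gt(near(6, 6), 0.5 * max(env))
  expect_gt(near(14, 14), 0.5 * max(env))

  expect_error(das_pa(structure(list(kind = "us"), class = "paus_rf"),
                      geom, grid), "PA RF")
})

test_that("B-mode localizes a scatterer and uniform speckle is Rayleigh", {
  geom <- probe_geometry(n_elements = 48, element_pitch = 0.18e-3)
  grid <- image_grid(c(-1.5e-3, 1.5e-3), c(6e-3, 9e-3),
                     dx = 0.05e-3, dz = 0.05e-3)
  sc <- cbind(x = -0.4e-3, z = 7.5e-3, reflectivity = 1)
  env <- das_us(simulate_us_rf(sc, geom, grid), geom, grid)
  pk <- which(env == max(env), arr.ind = TRUE)
  wl_ac <- geom$sound_speed / geom$center_frequency
  expect_lt(abs(grid$z[pk[1]] - 7.5e-3), wl_ac)
  expect_lt(abs(grid$x[pk[2]] - (-0.4e-3)), wl_ac)

  # fully developed speckle: envelope SNR (mean/sd) ~ 1.91
  ph <- make_phantom(grid, list(), scatterers_per_cell = 12, seed = 5)
  b <- das_us(simulate_us_rf(ph$scatterers, geom, grid), geom, grid)
  roi <- b[10:(grid$nz - 10), 10:(grid$nx - 10)]
  expect_equal(mean(roi) / sd(roi), 1.91, tolerance = 0.2)
})

test_that("coherent compounding adds signal linearly and noise in power", {
  grid_dim <- c(8, 8)
  sig <- matrix(complex(real = 1), grid_dim[1], grid_dim[2])
  subs <- lapply(1:5, function(i) {
    structure(list(data = sig, wavelength = 800, fiber = i),
              class = "paus_subimage")
  })
  comp <- compound_subimages(subs)
  expect_equal(comp$envelope, Mod(sig) * 5)     # x N for identical inputs
  expect_equal(comp$n_subimages, 5)

  expect_error(compound_subimages(list()), "at least one")
  subs[[2]]$wavelength <- 850
  expect_error(compound_subimages(subs), "mixed wavelengths")

  # noise-only stacks: compounded noise power ~ K x single sub-image power
  set.seed(42)
  K <- 20; n_trials <- 1e4
  noise <- matrix(complex(real = rnorm(n_trials * K),
                          imaginary = rnorm(n_trials * K)), n_trials, K)
  ratio <- mean(Mod(rowSums(noise))^2) / mean(Mod(noise[, 1])^2)
  expect_equal(ratio, K, tolerance = 0.05)

  # SNR gain of coherent summation over K replicas = 10 log10 K
  for (K in c(4, 9, 16)) {
    r <- snr_compound_gain_db(K, n_trials = 2e4, seed = 3)
    expect_equal(r$gain_db, 10 * log10(K), tolerance = 0.35)
  }
})

test_that("log compression clamps to the dynamic range", {
  env <- matrix(c(1, 0.1, 1e-6), 1, 3)
  lc <- log_compress(env, 40)
  expect_equal(lc[1, 1], 0)
  expect_equal(lc[1, 2], -20)
  expect_equal(lc[1, 3], -40)     # clamped
})
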