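# one small stack shared by several spectral tests (built once per file)
local_stack <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- tiny_config()
      geom <- pauskit:::config_geometry(cfg)
      grid <- pauskit:::config_grid(cfg)
      seqc <- pauskit:::config_sequence(cfg, geom)
      ph <- pauskit:::config_phantom(cfg, grid, seed = 5)
      cache <<- list(
        stack = simulate_acquisition(ph, geom, seqc, grid, noise = cfg$noise,
                                     seed = 77, bmode_refine = 1L,
                                     f_number = 2),
        phantom = ph, cfg = cfg)
    }
    cache
  }
})

test_that("noise floor comes from the laser-off frame", {
  x <- local_stack()
  floor_map <- estimate_noise_floor(x$stack)
  expect_true(all(floor_map >= 0))
  # receiver noise is i.i.d.: the floor is spatially near-uniform
  expect_lt(sd(floor_map) / mean(floor_map), 0.3)

  # a zero-noise acquisition has an exactly zero floor
  cfg <- x$cfg
  geom <- pauskit:::config_geometry(cfg)
  grid <- pauskit:::config_grid(cfg)
  seqc <- pauskit:::config_sequence(cfg, geom)
  ph <- x$phantom
  st0 <- simulate_acquisition(ph, geom, seqc, grid,
                              noise = list(pa_sigma = 0, us_sigma = 0),
                              seed = 1, bmode_refine = 1L)
  expect_true(all(estimate_noise_floor(st0) == 0))

  st_no_off <- st0
  st_no_off$laser_energy <- rep(1, length(st0$laser_energy))
  expect_error(estimate_noise_floor(st_no_off), "laser-off")
})

test_that("mu_eff recovery from synthetic per-fiber amplitudes", {
  geom <- probe_geometry()
  grid <- image_grid(c(-4.8e-3, 4.8e-3), c(3e-3, 11e-3),
                     dx = 0.15e-3, dz = 0.15e-3)
  d_all <- pauskit:::fiber_distances_cm(geom, grid)
  set.seed(31)
  r <- d_all[sample(nrow(d_all), 150), ]

  # noiseless: recovered on the grid within one step
  A <- exp(-2 * r) / (4 * pi * (1 / 30) * r)
  fit <- estimate_mu_eff(amplitudes = A, distances_cm = r)
  expect_equal(fit$mu_eff_hat, 2, tolerance = 0.051)
  expect_equal(fit$beer_mu0, 2, tolerance = 1e-6)

  # zero attenuation: estimate sits at the grid's lower bound
  A0 <- 1 / (4 * pi * (1 / 30) * r)
  expect_equal(estimate_mu_eff(amplitudes = A0, distances_cm = r)$mu_eff_hat, 0)

  # cached model profiles give the identical answer
  prof <- fluence_model_profiles(r, fluence_search_grid()$mu_eff)
  fit_c <- estimate_mu_eff(amplitudes = A, distances_cm = r,
                           model_profiles = prof)
  expect_equal(fit_c$mu_eff_hat, fit$mu_eff_hat)

  expect_error(estimate_mu_eff(amplitudes = A[0, , drop = FALSE],
                               distances_cm = r[0, , drop = FALSE]),
               "no pixels")
})

test_that("stack-route fit masks pixels above the noise floor", {
  x <- local_stack()
  act <- x$stack$sequence$wavelengths[x$stack$laser_energy > 0]
  fit <- estimate_mu_eff(x$stack, wavelength = act[2])
  w <- match(act[2], x$stack$sequence$wavelengths)
  expect_gt(fit$n_pixels, 10)
  expect_equal(fit$mu_eff_hat, x$stack$mu_eff_true[w], tolerance = 0.45)

  # an all-FALSE mask is rejected
  empty <- matrix(FALSE, x$stack$grid$nz, x$stack$grid$nx)
  expect_error(estimate_mu_eff(x$stack, wavelength = act[2], mask = empty),
               "no pixels above noise floor")
  expect_error(estimate_mu_eff(x$stack, wavelength = 700), "active")
})

test_that("uniform fluence compensation only rescales", {
  x <- local_stack()
  st <- x$stack
  act <- which(st$laser_energy > 0)
  # mu_eff -> 0 fits: fluence map is 1/(4 pi D r); after the neutral global
  # rescale the per-pixel spectrum SHAPE across wavelengths is unchanged
  fits <- lapply(act, function(w) {
    structure(list(wavelength = st$sequence$wavelengths[w], mu_eff_hat = 0,
                   D_hat = 1 / 30, mask = NULL, n_pixels = 0),
              class = "paus_fluence_fit")
  })
  stc <- compensate_fluence(st, fits)
  s_raw <- pixel_spectra(st)
  s_cmp <- pixel_spectra(stc, compensated = TRUE)
  iz <- 10; ix <- 12
  expect_equal(s_cmp[iz, ix, ] / s_raw[iz, ix, ],
               rep((s_cmp[iz, ix, 1] / s_raw[iz, ix, 1]), dim(s_raw)[3]),
               tolerance = 1e-10)
  expect_error(compensate_fluence(st, fits[-1]), "one fluence fit")
})

test_that("sigma-lambda compounding is coherent over active wavelengths", {
  x <- local_stack()
  st <- x$stack
  st$corrected <- TRUE
  act <- which(st$laser_energy > 0)
  sl <- sigma_lambda_compound(st)
  expect_equal(sl$n_subimages, length(act))

  # identical frames: amplitude x N
  stI <- st
  for (w in act) stI$comp[[w]] <- st$comp[[act[1]]]
  slI <- sigma_lambda_compound(stI)
  expect_equal(slI$envelope, Mod(st$comp[[act[1]]]) * length(act))

  # single active wavelength: identity
  st1 <- st
  st1$laser_energy <- rep(0, length(st$laser_energy))
  st1$laser_energy[act[1]] <- 1
  expect_equal(sigma_lambda_compound(st1)$complex, st$comp[[act[1]]])

  st$corrected <- FALSE
  expect_warning(sigma_lambda_compound(st), "not motion-corrected")
})

test_that("spectrum NCC and component weighting behave at the extremes", {
  expect_equal(spectrum_ncc(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(spectrum_ncc(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(spectrum_ncc(rep(1, 5), c(1, 2, 3, 2, 1)), 0)  # zero variance

  x <- local_stack()
  st <- x$stack
  st$corrected <- TRUE
  act <- which(st$laser_energy > 0)
  wl_act <- st$sequence$wavelengths[act]

  # craft a stack whose pixel spectra exactly equal the reference
  ref <- chromophore_spectrum("gnr", seq(650, 950, 5))
  vals <- resample_spectrum(ref, wl_act)
  stR <- st
  base <- Mod(st$comp[[act[1]]]) + 1
  for (i in seq_along(act)) stR$comp[[act[i]]] <- base * vals[i] + 0i
  stR$comp_comp <- stR$comp
  stR$compensated <- TRUE
  sl <- sigma_lambda_compound(stR)
  cw <- component_weighted(stR, sl, ref)
  expect_true(all(abs(cw$ncc - 1) < 1e-8))
  expect_true(all(cw$weight >= 0 & cw$weight <= 1))

  # sign-inverted shape: NCC = -1, weight clipped to 0
  for (i in seq_along(act)) {
    stR$comp[[act[i]]] <- base * (2 * mean(vals) - vals[i]) + 0i
  }
  stR$comp_comp <- stR$comp
  cw2 <- component_weighted(stR, sl, ref)
  expect_true(all(abs(cw2$ncc + 1) < 1e-8))
  expect_true(all(cw2$weight == 0))
  expect_true(all(cw2$component == 0))

  # reference must cover the active wavelengths
  narrow <- paus_spectrum(c(720, 760, 800), c(1, 1, 1))
  expect_error(component_weighted(stR, sl, narrow), "cover")

  stU <- st
  stU$compensated <- FALSE
  expect_error(component_weighted(stU, sl, ref), "compensated")
})
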