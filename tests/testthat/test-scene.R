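test_that("gnr spectrum peaks at 776 nm with a 68 nm width at 80% of max", {
  wl <- seq(700, 900, by = 0.25)
  s <- chromophore_spectrum("gnr", wl)
  expect_equal(s$wavelength_nm[which.max(s$value)], 776)

  # width at 80% of maximum, located by root finding on the curve
  f <- approxfun(s$wavelength_nm, s$value - 0.8 * max(s$value))
  lo <- uniroot(f, c(700, 776))$root
  hi <- uniroot(f, c(776, 900))$root
  expect_equal(hi - lo, 68, tolerance = 1e-3)
})

test_that("spectrum construction and normalization", {
  wl <- seq(700, 860, by = 20)  # 9 points spanning 160 nm
  s <- chromophore_spectrum("flat", wl)
  n <- normalize_spectrum(s)
  expect_equal(n$value, rep(1 / 160, 9))      # uniform area normalization
  expect_equal(pauskit:::trapz(n$wavelength_nm, n$value), 1)

  ink <- chromophore_spectrum("ink", seq(650, 950, 10))
  expect_true(all(diff(ink$value) < 0))       # monotone decreasing
  expect_true(all(chromophore_spectrum("water", wl)$value == 0))

  expect_error(chromophore_spectrum("nope", wl))
  expect_error(chromophore_spectrum("gnr", c(500, 700)), "650-950")
  expect_error(paus_spectrum(c(700, 700), c(1, 1)), "increasing")
  expect_error(paus_spectrum(700, -1), "non-negative")
})

test_that("phantom composition is reproducible and linear in concentration", {
  grid <- tiny_grid()
  wl <- seq(650, 950, 5)
  inc <- function(conc) list(
    list(center = c(0, 6e-3), radius = 0.8e-3,
         spectrum = chromophore_spectrum("gnr", wl), concentration = conc))
  p1 <- make_phantom(grid, inc(1), seed = 7)
  p2 <- make_phantom(grid, inc(1), seed = 7)
  expect_identical(p1$scatterers, p2$scatterers)   # same seed, same phantom
  expect_identical(mu_a_map(p1, 776), mu_a_map(p2, 776))

  # inside an inclusion mu_a = c * eps(lambda): linear superposition
  pa <- make_phantom(grid, inc(1), seed = 7)
  pb <- make_phantom(grid, inc(3), seed = 7)
  inside <- pa$owner == 1
  expect_equal(mu_a_map(pb, 776)[inside], 3 * mu_a_map(pa, 776)[inside])

  # no inclusions: background everywhere
  p0 <- make_phantom(grid, list(), seed = 7)
  expect_true(all(mu_a_map(p0, 800) == mu_a_background(p0, 800)))

  # three-tube scene: mu_a at the resonance is maximal inside the GNR tube
  incs <- list(
    list(center = c(-1.5e-3, 6e-3), radius = 0.6e-3,
         spectrum = chromophore_spectrum("gnr", wl), concentration = 2),
    list(center = c(0, 6e-3), radius = 0.6e-3,
         spectrum = chromophore_spectrum("water", wl), concentration = 1),
    list(center = c(1.5e-3, 6e-3), radius = 0.6e-3,
         spectrum = chromophore_spectrum("ink", wl), concentration = 2))
  p3 <- make_phantom(grid, incs, seed = 1)
  m <- mu_a_map(p3, 776)
  expect_equal(p3$owner[which.max(m)], 1L)

  # overlapping inclusions warn and resolve last-writer-wins
  over <- list(incs[[1]],
               modifyList(incs[[1]], list(concentration = 5)))
  expect_warning(p4 <- make_phantom(grid, over, seed = 1), "last writer")
  eps776 <- resample_spectrum(chromophore_spectrum("gnr", wl), 776)
  expect_equal(max(mu_a_map(p4, 776)), 5 * eps776)
})

test_that("motion models produce the stated displacement fields", {
  grid <- tiny_grid()
  none <- motion_model("none")
  f <- sample_motion(none, 5, grid)
  expect_true(all(f$ux == 0) && all(f$uz == 0))

  rigid <- motion_model("rigid", per_frame = c(0, 0.1e-3))
  f4 <- sample_motion(rigid, 4, grid)   # frame 4 = 3 steps after reference
  expect_equal(f4$uz, matrix(0.3e-3, grid$nz, grid$nx))
  expect_true(all(f4$ux == 0))
  expect_true(all(sample_motion(rigid, 1, grid)$uz == 0))  # reference frame

  sin_m <- motion_model("sinusoid", amplitude = 0.4e-3, period = 12)
  mx <- max(vapply(2:13, function(k) {
    max(abs(sample_motion(sin_m, k, grid)$uz))
  }, numeric(1)))
  expect_lte(mx, 0.4e-3 + 1e-12)
  expect_gt(mx, 0.38e-3)  # extremum of the temporal sine is attained
})
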