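px_grid <- function(nz, nx) {
  image_grid(c(0, nx * 1e-4), c(0, nz * 1e-4), dx = 1e-4, dz = 1e-4)
}

test_that("identical frames give a zero field with correlation ~ 1", {
  a <- speckle_image(60, 60, seed = 2)
  grid <- px_grid(60, 60)
  # integer search: exactly zero
  f0 <- patchmatch_track(a, a, track_params(seed = 1, subpixel = FALSE,
                                            field_smooth = 0), grid)
  expect_equal(max(abs(f0$uz)), 0)
  expect_equal(max(abs(f0$ux)), 0)
  expect_gt(min(f0$ncc), 0.999)
  # parabolic refinement of an asymmetric NCC surface may move a fraction
  # of a pixel even at a perfect integer optimum
  f <- patchmatch_track(a, a, track_params(seed = 1, field_smooth = 0), grid)
  expect_lt(max(abs(f$uz)) / grid$dz, 0.3)
  expect_lt(max(abs(f$ux)) / grid$dx, 0.3)
})

test_that("integer shifts match the exhaustive block-matching oracle", {
  pair <- shifted_speckle_pair(70, 70, dz = 3, dx = -2, seed = 9)
  grid <- px_grid(70, 70)
  tp <- track_params(seed = 4, field_smooth = 0)
  f <- patchmatch_track(pair$a, pair$b, tp, grid)

  interior <- interior_pixels(70, 70, margin = 14)
  dz_px <- (f$uz / grid$dz)[interior]
  dx_px <- (f$ux / grid$dx)[interior]
  expect_lt(median(abs(dz_px - 3)), 0.15)
  expect_lt(median(abs(dx_px + 2)), 0.15)

  # PatchMatch equals the exhaustive oracle at sampled interior pixels
  set.seed(1)
  sample_px <- sample(interior, 40)
  oracle <- block_match_oracle(pair$a, pair$b, sample_px,
                               half = tp$patch_half, radius = 8)
  expect_true(all(oracle[, "dz"] == 3))
  expect_true(all(oracle[, "dx"] == -2))
  pm_int <- cbind(round(dz_px[match(sample_px, interior)]),
                  round(dx_px[match(sample_px, interior)]))
  expect_true(mean(pm_int[, 1] == oracle[, "dz"] &
                     pm_int[, 2] == oracle[, "dx"]) >= 0.99)

  # randomized search attains >= 95% of the oracle NCC at >= 99% of pixels
  expect_true(mean(f$ncc[sample_px] >= 0.95 * oracle[, "ncc"]) >= 0.99)

  expect_error(patchmatch_track(pair$a, pair$b[1:10, ], tp, grid), "size")
})

test_that("subpixel shifts are recovered within 0.1 px", {
  # synthesize a 0.3 px axial shift by resampling a smooth speckle field
  nz <- 70; nx <- 60
  base <- speckle_image(nz + 4, nx, seed = 13)
  a <- base[2:(nz + 1), ]
  shift <- 0.3
  # scene moves down by 0.3 px: b(p) = a(p - 0.3 e_z)
  rows <- outer(2:(nz + 1) - shift, rep(1, nx))
  cols <- outer(rep(1, nz), 1:nx)
  b <- matrix(pauskit:::bilinear_sample(base, as.vector(rows),
                                        as.vector(cols)), nz, nx)
  grid <- px_grid(nz, nx)
  f <- patchmatch_track(a, b, track_params(seed = 6, field_smooth = 0), grid)
  interior <- interior_pixels(nz, nx, margin = 10)
  expect_lt(abs(mean((f$uz / grid$dz)[interior]) - shift), 0.1)
  expect_lt(abs(mean((f$ux / grid$dx)[interior])), 0.1)
})

test_that("displacement accumulation composes warps, not naive sums", {
  grid <- px_grid(40, 40)
  zero <- matrix(0, 40, 40)
  mk <- function(ux, uz) pauskit:::motion_field(ux, uz, grid)

  expect_error(accumulate_displacements(list()), "empty")

  cum0 <- accumulate_displacements(list(mk(zero, zero), mk(zero, zero)))
  expect_true(all(cum0[[2]]$ux == 0) && all(cum0[[2]]$uz == 0))

  # two uniform translations (1,0) then (0,1) px -> cumulative (1,1) px
  one <- matrix(grid$dx, 40, 40)
  cum <- accumulate_displacements(list(mk(one, zero), mk(zero, one)))
  inner <- 5:35
  expect_equal(cum[[2]]$ux[inner, inner], one[inner, inner])
  expect_equal(cum[[2]]$uz[inner, inner], one[inner, inner])

  # smoothly varying fields: composition tracks the dense trajectory
  xs <- matrix(rep(seq_len(40), each = 40), 40, 40)
  zs <- matrix(rep(seq_len(40), times = 40), 40, 40)
  u_of_t <- function(t) {
    ux <- 1e-4 * 0.8 * t * sin(pi * xs / 40)
    uz <- 1e-4 * 1.2 * t * cos(pi * zs / 80)
    list(ux = ux, uz = uz)
  }
  # pairwise fields between consecutive times, sampled at the *moved* frame
  pair <- list()
  for (k in 1:3) {
    uk <- u_of_t(k - 1); uk1 <- u_of_t(k)
    # displacement of frame k -> k+1 evaluated on frame-k pixel positions:
    # for the small, smooth fields used here the difference field suffices
    pair[[k]] <- mk(uk1$ux - uk$ux, uk1$uz - uk$uz)
  }
  cum3 <- accumulate_displacements(pair)[[3]]
  tru <- u_of_t(3)
  err_px <- max(abs(cum3$ux - tru$ux) / grid$dx,
                abs(cum3$uz - tru$uz) / grid$dz)
  expect_lt(err_px, 0.2)
})

test_that("warping is exact on lattice shifts and invertible on smooth images", {
  grid <- px_grid(50, 50)
  img <- speckle_image(50, 50, seed = 21)
  zero <- matrix(0, 50, 50)
  mk <- function(ux, uz) pauskit:::motion_field(ux, uz, grid)

  expect_equal(warp_image(img, mk(zero, zero)), img,
               ignore_attr = TRUE)

  # uniform integer shift = exact array shift
  f <- mk(zero + 2 * grid$dx, zero)
  w <- warp_image(img, f)
  expect_equal(w[, 1:48], img[, 3:50], ignore_attr = TRUE)
  expect_true(all(w[, 49:50] == 0))            # out-of-frame zero + mask
  expect_false(any(attr(w, "mask")[, 49:50]))

  # warp by a smooth field then by its negation: near-identity on a smooth
  # image (bilinear interpolation error only)
  smooth_img <- outer(sin(seq(0, 3, length.out = 50)),
                      cos(seq(0, 2, length.out = 50))) +
    outer(seq(0, 1, length.out = 50), seq(1, 2, length.out = 50))
  ux <- 0.6 * grid$dx * sin(pi * row(smooth_img) / 50)
  uz <- 0.8 * grid$dz * cos(pi * col(smooth_img) / 100)
  w1 <- warp_image(smooth_img, mk(ux, uz))
  w2 <- warp_image(w1, mk(-ux, -uz))
  inner <- 5:45
  expect_gt(cor(as.vector(w2[inner, inner]),
                as.vector(smooth_img[inner, inner])), 0.99)
})

test_that("tracking on simulated moving speckle stays under half a pixel", {
  geom <- probe_geometry(n_elements = 32, element_pitch = 0.2e-3)
  grid <- image_grid(c(-2e-3, 2e-3), c(5e-3, 9e-3), dx = 0.05e-3, dz = 0.05e-3)
  ph <- make_phantom(grid, list(), scatterers_per_cell = 10, seed = 8)
  shift <- c(2 * grid$dx, 2 * grid$dz)  # 2 px, well under 25% of the patch
  s2 <- ph$scatterers
  s2[, "x"] <- s2[, "x"] + shift[1]
  s2[, "z"] <- s2[, "z"] + shift[2]
  b1 <- das_us(simulate_us_rf(ph$scatterers, geom, grid), geom, grid)
  b2 <- das_us(simulate_us_rf(s2, geom, grid), geom, grid)
  f <- patchmatch_track(b1, b2, track_params(seed = 2), grid)
  interior <- interior_pixels(grid$nz, grid$nx, margin = 12)
  err <- sqrt(((f$ux - shift[1]) / grid$dx)^2 +
                ((f$uz - shift[2]) / grid$dz)^2)
  expect_lt(median(err[interior]), 0.5)
})

test_that("track parameters are validated", {
  expect_error(track_params(patch_half = 0, seed = 1), "3 px")
  expect_error(track_params(search_radius = 0, seed = 1), "radius")
  expect_error(track_params(), "seed")
})
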