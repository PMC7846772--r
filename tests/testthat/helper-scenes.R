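# Shared fixtures: everything is generated in code at test time.

# a very small probe/grid pair for fast end-to-end tests
tiny_geometry <- function(n_elements = 32L) {
  probe_geometry(n_elements = n_elements, element_pitch = 0.2e-3)
}

tiny_grid <- function() {
  image_grid(c(-2.4e-3, 2.4e-3), c(4e-3, 8e-3), dx = 0.2e-3, dz = 0.2e-3)
}

# reduced-size pipeline configuration (one GNR tube, 5 wavelengths)
tiny_config <- function(motion = list(type = "none")) {
  cfg <- paus_config("demo")
  cfg$probe$n_elements <- 32L
  cfg$probe$element_pitch_mm <- 0.2
  cfg$grid <- list(x_mm = c(-2.4, 2.4), z_mm = c(4, 8),
                   dx_mm = 0.2, dz_mm = 0.2)
  cfg$sequence$wavelengths <- c(700, 735, 775, 815, 855)
  cfg$phantom$inclusions <- list(
    list(kind = "gnr", center_mm = c(0, 6), radius_mm = 0.8,
         concentration = 3))
  cfg$phantom$scatterers_per_cell <- 6
  cfg$motion <- motion
  cfg$references <- "gnr"
  cfg
}

# moving two-chromophore scene used by the headline pipeline property
moving_scene_config <- function() {
  cfg <- paus_config("demo")
  cfg$probe$n_elements <- 48L
  cfg$probe$element_pitch_mm <- 0.18
  cfg$grid <- list(x_mm = c(-3.5, 3.5), z_mm = c(4.5, 10),
                   dx_mm = 0.1, dz_mm = 0.1)
  cfg$phantom$inclusions <- list(
    list(kind = "gnr", center_mm = c(-1.8, 6.5), radius_mm = 0.9,
         concentration = 3),
    list(kind = "ink", center_mm = c(1.8, 7.5), radius_mm = 0.9,
         concentration = 1.5))
  cfg$motion <- list(type = "rigid", per_frame_mm = c(0.04, 0.12))
  cfg
}

# smooth speckle-like test image (band-limited positive field)
speckle_image <- function(nz, nx, seed, pad = 12) {
  set.seed(seed)
  big <- matrix(abs(rnorm((nz + 2 * pad) * (nx + 2 * pad))),
                nz + 2 * pad, nx + 2 * pad)
  k <- 2L
  sm <- pauskit:::box_smooth(big, k)
  sm[(pad + 1):(pad + nz), (pad + 1):(pad + nx)]
}

# returns list(a, b) where the scene moves by (dz, dx) pixels from a to b,
# i.e. b(p) = a(p - (dz, dx)), so tracking a -> b should estimate (dz, dx)
shifted_speckle_pair <- function(nz, nx, dz, dx, seed) {
  pad <- max(abs(dz), abs(dx)) + 12
  set.seed(seed)
  big <- pauskit:::box_smooth(
    matrix(abs(rnorm((nz + 2 * pad) * (nx + 2 * pad))),
           nz + 2 * pad, nx + 2 * pad), 2L)
  a <- big[(pad + 1):(pad + nz), (pad + 1):(pad + nx)]
  b <- big[(pad + 1 - dz):(pad + nz - dz), (pad + 1 - dx):(pad + nx - dx)]
  list(a = a, b = b)
}

# independent exhaustive block-matching oracle: best integer displacement
# within +/- radius maximizing patch NCC, evaluated at the given pixels.
# Deliberately written as plain R loops, independent of the PatchMatch path.
block_match_oracle <- function(a, b, pixels, half, radius) {
  patch_ncc_r <- function(iz, ix, dz, dx) {
    nz <- nrow(a); nx <- ncol(a)
    z0 <- max(1, iz - half); z1 <- min(nz, iz + half)
    x0 <- max(1, ix - half); x1 <- min(nx, ix + half)
    if (z0 + dz < 1 || z1 + dz > nz || x0 + dx < 1 || x1 + dx > nx) {
      return(NA_real_)
    }
    pa <- a[z0:z1, x0:x1]
    pb <- b[(z0 + dz):(z1 + dz), (x0 + dx):(x1 + dx)]
    va <- pa - mean(pa); vb <- pb - mean(pb)
    den <- sqrt(sum(va^2) * sum(vb^2))
    if (den <= 0) return(0)
    sum(va * vb) / den
  }
  out <- matrix(NA_real_, length(pixels), 3,
                dimnames = list(NULL, c("dz", "dx", "ncc")))
  for (k in seq_along(pixels)) {
    i <- pixels[k]
    iz <- (i - 1) %% nrow(a) + 1
    ix <- (i - 1) %/% nrow(a) + 1
    best <- c(0, 0, -2)
    for (dz in -radius:radius) {
      for (dx in -radius:radius) {
        v <- patch_ncc_r(iz, ix, dz, dx)
        if (!is.na(v) && v > best[3]) best <- c(dz, dx, v)
      }
    }
    out[k, ] <- best
  }
  out
}

# interior pixel indices (margin away from every border), column-major
interior_pixels <- function(nz, nx, margin) {
  idx <- expand.grid(z = (margin + 1):(nz - margin),
                     x = (margin + 1):(nx - margin))
  (idx$x - 1) * nz + idx$z
}
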