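#' Build a synthetic imaging phantom
#'
#' A phantom combines (i) chromophore inclusions (tubes/discs carrying a
#' spectrum at a concentration), (ii) a scattering/absorbing background with
#' wavelength-dependent reduced scattering, (iii) a dense random scatterer
#' field producing fully developed ultrasound speckle, and (iv) a parametric
#' ground-truth motion model. The per-pixel absorption map is the linear
#' superposition `mu_a(p, lambda) = sum_k c_k(p) eps_k(lambda)` plus the
#' background absorption. The scatterer field is seeded independently of the
#' optical maps.
#'
#' @param grid a [image_grid()].
#' @param inclusions list of inclusions, each a list with `shape = "disc"`,
#'   `center` (x, z in m), `radius` (m), `spectrum` (a [paus_spectrum()],
#'   values in 1/cm at unit concentration) and `concentration`
#'   (dimensionless). Overlaps resolve last-writer-wins with a warning.
#' @param background list with `mu_a_spectrum` (a [paus_spectrum()], 1/cm),
#'   `mu_s_prime_800` reduced scattering at 800 nm (1/cm) and `mie_slope`
#'   exponent of the Intralipid-like power law
#'   `mu_s'(lambda) = mu_s'(800) (lambda/800)^(-mie_slope)`.
#' @param scatterers_per_cell target scatterer count per acoustic resolution
#'   cell (fully developed speckle needs >= ~10); the cell is taken as one
#'   acoustic wavelength squared at `fc_hint`.
#' @param pa_emitters_per_cell density of the random photoacoustic emitter
#'   cloud representing particle-suspension absorbers (ink, nanoparticles,
#'   Prussian-blue background). A continuous-absorber lattice would cancel
#'   coherently in its interior and radiate edge arcs only; random emitters
#'   reproduce the volumetric PA speckle of real suspensions, for which the
#'   per-fiber amplitude ratio at a pixel equals the per-fiber fluence
#'   ratio — the property the fluence fit relies on.
#' @param fc_hint center frequency used to size the resolution cell (Hz).
#' @param sound_speed m/s, for the resolution-cell size.
#' @param grueneisen Grueneisen coefficient (dimensionless PA efficiency).
#' @param motion_model see [motion_model()].
#' @param seed integer seed; the same seed reproduces the phantom exactly.
#' @return object of class `paus_phantom`.
#' @export
make_phantom <- function(grid,
                         inclusions = list(),
                         background = list(
                           mu_a_spectrum = chromophore_spectrum(
                             "background", seq(650, 950, 5), peak_value = 0.25),
                           mu_s_prime_800 = 10,
                           mie_slope = 1.3),
                         scatterers_per_cell = 10,
                         pa_emitters_per_cell = 6,
                         fc_hint = 15e6,
                         sound_speed = 1540,
                         grueneisen = 1,
                         motion_model = NULL,
                         seed = 1L) {
  stopifnot(inherits(grid, "paus_grid"))
  if (is.null(motion_model)) {
    motion_model <- structure(list(type = "none"),
                              class = "paus_motion_model")
  }
  # inclusion occupancy masks, last writer wins
  npx <- grid$nz * grid$nx
  px <- grid_pixels(grid)
  owner <- integer(npx)
  for (k in seq_along(inclusions)) {
    inc <- inclusions[[k]]
    abort_if(is.null(inc$center) || is.null(inc$radius) || is.null(inc$spectrum),
             "each inclusion needs center, radius, spectrum")
    inside <- (px[, 1] - inc$center[1])^2 + (px[, 2] - inc$center[2])^2 <=
      inc$radius^2
    if (any(owner[inside] != 0)) {
      warning(sprintf("inclusion %d overlaps inclusion %d; last writer wins",
                      k, max(owner[inside])))
    }
    owner[inside] <- k
  }

  # speckle scatterers: uniform positions over the grid footprint (padded by
  # one resolution cell so speckle statistics hold up to the frame edge),
  # reflectivities standard normal
  lambda_ac <- sound_speed / fc_hint
  area <- diff(grid$x_range) * diff(grid$z_range)
  n_scat <- max(50L, ceiling(scatterers_per_cell * area / lambda_ac^2))
  scat <- with_seed(derive_seed(seed, "scatterers"), {
    pad <- 2 * lambda_ac
    cbind(
      x = runif(n_scat, grid$x_range[1] - pad, grid$x_range[2] + pad),
      z = runif(n_scat, max(0, grid$z_range[1] - pad), grid$z_range[2] + pad),
      reflectivity = rnorm(n_scat)
    )
  })

  # PA emitter cloud: uniform positions within the grid footprint; weights
  # carry the local absorption at simulation time
  n_em <- max(50L, ceiling(pa_emitters_per_cell * area / lambda_ac^2))
  emitters <- with_seed(derive_seed(seed, "pa-emitters"), {
    cbind(x = runif(n_em, grid$x_range[1], grid$x_range[2]),
          z = runif(n_em, grid$z_range[1], grid$z_range[2]))
  })

  structure(list(
    grid = grid,
    inclusions = inclusions,
    owner = matrix(owner, grid$nz, grid$nx),
    background = background,
    scatterers = scat,
    pa_emitters = emitters,
    grueneisen = grueneisen,
    motion_model = motion_model,
    seed = as.integer(seed)
  ), class = "paus_phantom")
}

#' @export
print.paus_phantom <- function(x, ...) {
  cat(sprintf("PAUS phantom: %d inclusion(s), %d scatterers, motion '%s'\n",
              length(x$inclusions), nrow(x$scatterers), x$motion_model$type))
  invisible(x)
}

#' Background reduced scattering coefficient
#'
#' Intralipid-like power law `mu_s'(lambda) = mu_s'(800) (lambda/800)^-b`.
#'
#' @param phantom a [make_phantom()] phantom.
#' @param wavelength nm.
#' @return 1/cm.
#' @export
mu_s_prime <- function(phantom, wavelength) {
  bg <- phantom$background
  bg$mu_s_prime_800 * (wavelength / 800)^(-bg$mie_slope)
}

#' Background absorption coefficient at a wavelength
#' @inheritParams mu_s_prime
#' @return 1/cm.
#' @export
mu_a_background <- function(phantom, wavelength) {
  resample_spectrum(phantom$background$mu_a_spectrum, wavelength)
}

#' Absorption coefficient at arbitrary material points
#'
#' Outside all inclusions the medium is the absorbing/scattering background;
#' inside a tube the background medium is displaced by the tube's solution,
#' so `mu_a = concentration * eps_k(lambda)` there (a de-ionized water tube
#' is dark). Overlaps resolve last-writer-wins.
#'
#' @inheritParams mu_s_prime
#' @param x,z point coordinates (m).
#' @return vector of `mu_a` (1/cm).
#' @export
mu_a_at <- function(phantom, wavelength, x, z) {
  mu <- rep(mu_a_background(phantom, wavelength), length(x))
  for (inc in phantom$inclusions) {
    inside <- (x - inc$center[1])^2 + (z - inc$center[2])^2 <= inc$radius^2
    conc <- if (is.null(inc$concentration)) 1 else inc$concentration
    eps <- resample_spectrum(inc$spectrum, wavelength)
    mu[inside] <- conc * eps
  }
  mu
}

#' Per-pixel absorption map at a wavelength
#'
#' [mu_a_at()] evaluated at the pixel centers, optionally on a scene
#' displaced by a ground-truth motion field (material points move with the
#' field; the map is pulled back).
#'
#' @inheritParams mu_s_prime
#' @param displacement optional `paus_motion_field` moving the scene.
#' @return `nz x nx` matrix (1/cm).
#' @export
mu_a_map <- function(phantom, wavelength, displacement = NULL) {
  grid <- phantom$grid
  px <- grid_pixels(grid)
  xs <- px[, 1]
  zs <- px[, 2]
  if (!is.null(displacement)) {
    # a point that started at q is now at q + u: evaluate material map at
    # p - u(p) (valid for the smooth, small-strain fields generated here)
    xs <- xs - as.vector(displacement$ux)
    zs <- zs - as.vector(displacement$uz)
  }
  matrix(mu_a_at(phantom, wavelength, xs, zs), grid$nz, grid$nx)
}

#' Ground-truth per-pixel chromophore spectrum
#'
#' The true `mu_a(lambda)` at each pixel of the reference (frame-1) scene,
#' used as the gold standard when scoring reconstructed pixel spectra.
#'
#' @param phantom a phantom.
#' @param wavelengths nm vector.
#' @return array `nz x nx x n_wavelengths`.
#' @export
true_spectra <- function(phantom, wavelengths) {
  out <- array(0, c(phantom$grid$nz, phantom$grid$nx, length(wavelengths)))
  for (i in seq_along(wavelengths)) {
    out[, , i] <- mu_a_map(phantom, wavelengths[i])
  }
  out
}

#' Define a ground-truth motion model
#'
#' @param type `"none"`, `"rigid"` (fixed translation per frame step), or
#'   `"sinusoid"` (spatially smooth field oscillating over frames).
#' @param per_frame for `"rigid"`: c(ux, uz) translation per frame step (m).
#' @param amplitude for `"sinusoid"`: peak displacement (m).
#' @param period for `"sinusoid"`: period in frames.
#' @param spatial_wavelength for `"sinusoid"`: spatial scale of the smooth
#'   modulation (m).
#' @return object of class `paus_motion_model`.
#' @export
motion_model <- function(type = c("none", "rigid", "sinusoid"),
                         per_frame = c(0, 0),
                         amplitude = 0.3e-3,
                         period = 12,
                         spatial_wavelength = 8e-3) {
  type <- match.arg(type)
  structure(list(type = type, per_frame = per_frame, amplitude = amplitude,
                 period = period, spatial_wavelength = spatial_wavelength),
            class = "paus_motion_model")
}

#' Sample the ground-truth displacement field of a frame
#'
#' Displacement of frame `frame_index` relative to frame 1 (frame 1 is the
#' reference, so `frame_index = 1` returns the zero field).
#'
#' @param model a [motion_model()].
#' @param frame_index 1-based frame number.
#' @param grid an [image_grid()].
#' @return `paus_motion_field`: list of `nz x nx` matrices `ux`, `uz` (m).
#' @export
sample_motion <- function(model, frame_index, grid) {
  nz <- grid$nz
  nx <- grid$nx
  zero <- matrix(0, nz, nx)
  k <- frame_index - 1
  if (model$type == "none" || k == 0) {
    return(motion_field(zero, zero, grid))
  }
  if (model$type == "rigid") {
    return(motion_field(zero + k * model$per_frame[1],
                        zero + k * model$per_frame[2], grid))
  }
  # sinusoid: separable smooth spatial modulation, temporal sine
  phase <- sin(2 * pi * k / model$period)
  gx <- cos(pi * (grid$x - mean(grid$x)) / model$spatial_wavelength)
  gz <- cos(pi * (grid$z - mean(grid$z)) / model$spatial_wavelength)
  sp <- outer(gz, gx)               # in [-1, 1], smooth
  motion_field(model$amplitude * phase * sp * 0.4,
               model$amplitude * phase * sp, grid)
}

motion_field <- function(ux, uz, grid) {
  structure(list(ux = ux, uz = uz, grid = grid), class = "paus_motion_field")
}

# displace the scatterer cloud by a motion field (bilinearly sampled at the
# scatterer positions; scatterers outside the grid keep the nearest value)
displace_scatterers <- function(scatterers, field) {
  grid <- field$grid
  rows <- (scatterers[, "z"] - grid$z[1]) / grid$dz + 1
  cols <- (scatterers[, "x"] - grid$x[1]) / grid$dx + 1
  rows <- pmin(pmax(rows, 1), grid$nz)
  cols <- pmin(pmax(cols, 1), grid$nx)
  ux <- bilinear_sample(field$ux, rows, cols)
  uz <- bilinear_sample(field$uz, rows, cols)
  out <- scatterers
  out[, "x"] <- out[, "x"] + ux
  out[, "z"] <- out[, "z"] + uz
  out
}
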