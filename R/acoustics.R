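#' Band-limited transducer pulse
#'
#' Gaussian-modulated cosine. The envelope standard deviation in time is set
#' from the -6 dB fractional bandwidth of the Gaussian amplitude spectrum
#' (`sigma_f = bw fc / 2.355`, `sigma_t = 1/(2 pi sigma_f)`), which puts the
#' spectral peak exactly at the center frequency.
#'
#' @param center_frequency Hz.
#' @param bandwidth_fraction fractional bandwidth (default 0.6).
#' @return object of class `paus_pulse` (list with `fc`, `bw`, `sigma_t`).
#' @export
gauss_pulse <- function(center_frequency = 15e6, bandwidth_fraction = 0.6) {
  abort_if(center_frequency <= 0 || bandwidth_fraction <= 0,
           "pulse parameters must be positive")
  sigma_f <- bandwidth_fraction * center_frequency / 2.355
  structure(list(fc = center_frequency, bw = bandwidth_fraction,
                 sigma_t = 1 / (2 * pi * sigma_f)),
            class = "paus_pulse")
}

#' Evaluate a pulse waveform
#' @param pulse a [gauss_pulse()].
#' @param t time (s), relative to the pulse center.
#' @return waveform samples.
#' @export
pulse_waveform <- function(pulse, t) {
  exp(-0.5 * (t / pulse$sigma_t)^2) * cos(2 * pi * pulse$fc * t)
}

#' Initial photoacoustic pressure map
#'
#' `p0(p) = Gamma mu_a(p, lambda) Phi_total(p, lambda)`: local heating is
#' proportional to the absorbed optical energy.
#'
#' @param mu_a `nz x nx` absorption map (1/cm).
#' @param fluence `nz x nx` fluence map on the same grid (a matrix or a
#'   [total_fluence_map()] whose `total`/one per-fiber slice is used by the
#'   caller).
#' @param grueneisen Grueneisen coefficient.
#' @return `nz x nx` initial pressure map (arbitrary units).
#' @export
initial_pressure <- function(mu_a, fluence, grueneisen = 1) {
  if (inherits(fluence, "paus_fluence")) fluence <- fluence$total
  abort_if(!all(dim(mu_a) == dim(fluence)),
           "mu_a and fluence maps are not on the same grid")
  grueneisen * mu_a * fluence
}

rf_n_time <- function(geometry, grid, pulse, two_way = FALSE) {
  # cover the farthest pixel-element distance plus pulse support
  gx <- range(grid$x)
  gz <- range(grid$z)
  ex <- range(geometry$element_positions[, 1])
  dmax <- sqrt(max(abs(gx[1] - ex[2]), abs(gx[2] - ex[1]))^2 + gz[2]^2)
  tmax <- (if (two_way) gz[2] / geometry$sound_speed else 0) +
    dmax / geometry$sound_speed + 6 * pulse$sigma_t
  ceiling(tmax * geometry$sampling_rate) + 2L
}

#' Simulate photoacoustic RF channel data
#'
#' Point-source superposition: every non-zero pixel of the initial pressure
#' map radiates the band-limited pulse, received with one-way delay and
#' spherical `1/r` spreading by all elements; i.i.d. Gaussian noise is added
#' per sample. No full-wave effects (no N-shape transient, no attenuation) —
#' sufficient to exercise beamforming, tracking and spectroscopy logic.
#'
#' @param p0 `nz x nx` initial pressure map.
#' @param geometry a [probe_geometry()].
#' @param grid an [image_grid()].
#' @param pulse a [gauss_pulse()] (defaults from the geometry).
#' @param noise_sigma standard deviation of the additive RF noise.
#' @param seed integer seed for the noise.
#' @param metadata named list stored on the frame (wavelength, fiber ...).
#' @return object of class `paus_rf`: `samples` (`n_elements x n_time`),
#'   `sampling_rate`, `t0`, `kind = "pa"`, `metadata`.
#' @export
simulate_pa_rf <- function(p0, geometry, grid, pulse = NULL,
                           noise_sigma = 0, seed = 1L, metadata = list()) {
  abort_if(noise_sigma < 0, "noise_sigma must be >= 0")
  abort_if(!all(dim(p0) == c(grid$nz, grid$nx)), "p0 is not on the grid")
  if (is.null(pulse)) {
    pulse <- gauss_pulse(geometry$center_frequency, geometry$bandwidth_fraction)
  }
  n_time <- rf_n_time(geometry, grid, pulse, two_way = FALSE)
  act <- which(p0 != 0)
  px <- grid_pixels(grid)
  rf <- cpp_rf_sim(px[act, 1], rep(0, length(act)), px[act, 2],
                   as.vector(p0)[act], rep(0, length(act)),
                   geometry$element_positions,
                   geometry$sound_speed, geometry$sampling_rate,
                   n_time, 0, pulse$fc, pulse$sigma_t)
  if (noise_sigma > 0) {
    rf <- rf + with_seed(seed, matrix(rnorm(length(rf), sd = noise_sigma),
                                      nrow(rf), ncol(rf)))
  }
  structure(list(samples = rf, sampling_rate = geometry$sampling_rate,
                 t0 = 0, kind = "pa", pulse = pulse, metadata = metadata),
            class = "paus_rf")
}

#' Simulate pulse-echo ultrasound RF channel data (plane-wave transmit)
#'
#' Two-way delays: a single zero-angle plane wave reaches a scatterer at
#' depth `z` after `z/c`; the echo returns to each element over the direct
#' path. Dense random scatterers produce fully developed speckle.
#'
#' @param scatterers matrix with columns `x`, `z`, `reflectivity` (m, a.u.).
#' @inheritParams simulate_pa_rf
#' @return `paus_rf` with `kind = "us"`.
#' @export
simulate_us_rf <- function(scatterers, geometry, grid, pulse = NULL,
                           noise_sigma = 0, seed = 1L, metadata = list()) {
  abort_if(noise_sigma < 0, "noise_sigma must be >= 0")
  if (is.null(pulse)) {
    pulse <- gauss_pulse(geometry$center_frequency, geometry$bandwidth_fraction)
  }
  n_time <- rf_n_time(geometry, grid, pulse, two_way = TRUE)
  ns <- nrow(scatterers)
  if (ns == 0) {
    rf <- matrix(0, geometry$n_elements, n_time)
  } else {
    rf <- cpp_rf_sim(scatterers[, "x"], rep(0, ns), scatterers[, "z"],
                     scatterers[, "reflectivity"],
                     scatterers[, "z"] / geometry$sound_speed,
                     geometry$element_positions,
                     geometry$sound_speed, geometry$sampling_rate,
                     n_time, 0, pulse$fc, pulse$sigma_t)
  }
  if (noise_sigma > 0) {
    rf <- rf + with_seed(seed, matrix(rnorm(length(rf), sd = noise_sigma),
                                      nrow(rf), ncol(rf)))
  }
  structure(list(samples = rf, sampling_rate = geometry$sampling_rate,
                 t0 = 0, kind = "us", pulse = pulse, metadata = metadata),
            class = "paus_rf")
}
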