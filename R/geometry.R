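#' Build a PAUS probe geometry
#'
#' Lays out a linear transducer array in the imaging plane (elevation y = 0)
#' and two symmetric rows of illumination fibers at elevation `+/-
#' fiber_elevation`, both laterally centered on the array. Coordinates are in
#' meters: x lateral, y elevation, z axial depth (positive into tissue).
#' Defaults mirror a 15-MHz, 128-element array sampled at 62.5 MHz with 20
#' fibers (10 per row) at 1.5 mm pitch, so a 10-fiber row spans
#' (10 - 1) x 1.5 = 13.5 mm.
#'
#' @param n_elements number of transducer elements.
#' @param element_pitch element spacing (m).
#' @param n_fibers_per_row fibers in each of the two elevational rows.
#' @param fiber_pitch fiber spacing within a row (m).
#' @param fiber_elevation elevation offset of each fiber row (m); the beam
#'   entry points sit this far above/below the imaging plane.
#' @param center_frequency transducer center frequency (Hz).
#' @param bandwidth_fraction fractional -6 dB bandwidth of the pulse.
#' @param sampling_rate RF sampling rate (Hz); must exceed twice the center
#'   frequency.
#' @param sound_speed acoustic speed (m/s).
#' @return object of class `paus_probe` with `element_positions` and
#'   `fiber_positions` (n x 3 matrices, columns x/y/z) plus the acoustic
#'   constants.
#' @examples
#' geom <- probe_geometry()
#' diff(range(geom$fiber_positions[geom$fiber_positions[, 2] > 0, 1])) # 13.5 mm
#' @export
probe_geometry <- function(n_elements = 128L,
                           element_pitch = 0.1e-3,
                           n_fibers_per_row = 10L,
                           fiber_pitch = 1.5e-3,
                           fiber_elevation = 6e-3,
                           center_frequency = 15e6,
                           bandwidth_fraction = 0.6,
                           sampling_rate = 62.5e6,
                           sound_speed = 1540) {
  abort_if(n_elements < 1, "n_elements must be >= 1")
  abort_if(element_pitch <= 0, "element_pitch must be positive")
  abort_if(n_fibers_per_row < 1, "n_fibers_per_row must be >= 1")
  abort_if(fiber_pitch <= 0, "fiber_pitch must be positive")
  abort_if(sound_speed <= 0, "sound_speed must be positive")
  abort_if(sampling_rate <= 2 * center_frequency,
           "sampling_rate must exceed twice the center frequency")

  ex <- (seq_len(n_elements) - (n_elements + 1) / 2) * element_pitch
  element_positions <- cbind(x = ex, y = 0, z = 0)

  fx <- (seq_len(n_fibers_per_row) - (n_fibers_per_row + 1) / 2) * fiber_pitch
  # row 1 at +elevation, row 2 mirrored at -elevation; indices 1..n/row then
  # (n/row+1)..2n/row so fiber k and k + n/row face each other
  fiber_positions <- rbind(
    cbind(x = fx, y = fiber_elevation, z = 0),
    cbind(x = fx, y = -fiber_elevation, z = 0)
  )

  structure(list(
    element_positions = element_positions,
    n_elements = as.integer(n_elements),
    fiber_positions = fiber_positions,
    n_fibers = as.integer(2L * n_fibers_per_row),
    n_fibers_per_row = as.integer(n_fibers_per_row),
    fiber_pitch = fiber_pitch,
    fiber_elevation = fiber_elevation,
    element_pitch = element_pitch,
    center_frequency = center_frequency,
    bandwidth_fraction = bandwidth_fraction,
    sampling_rate = sampling_rate,
    sound_speed = sound_speed
  ), class = "paus_probe")
}

#' @export
print.paus_probe <- function(x, ...) {
  cat(sprintf(
    "PAUS probe: %d elements @ %.2f mm pitch, fc = %.1f MHz, fs = %.1f MHz\n",
    x$n_elements, x$element_pitch * 1e3, x$center_frequency / 1e6,
    x$sampling_rate / 1e6))
  cat(sprintf(
    "  %d fibers (%d/row, %.2f mm pitch, row span %.2f mm, elevation %.1f mm)\n",
    x$n_fibers, x$n_fibers_per_row, x$fiber_pitch * 1e3,
    (x$n_fibers_per_row - 1) * x$fiber_pitch * 1e3, x$fiber_elevation * 1e3))
  invisible(x)
}

#' Interleaved fiber firing order
#'
#' Rearranges the firing sequence so that successive firings come from
#' laterally and elevationally distant fibers (1, 15, 2, 14, ... for 20
#' fibers), reducing local surface heating when highly absorbing agents are
#' present. Odd positions step through row one ascending; even positions step
#' through row two descending starting from the fiber three quarters of the
#' way around the ring, wrapping within the second row.
#'
#' @param n_fibers total fiber count (even).
#' @return integer permutation of `1:n_fibers`.
#' @examples
#' head(interleaved_fiber_order(20), 4) # 1 15 2 14
#' @export
interleaved_fiber_order <- function(n_fibers) {
  abort_if(n_fibers < 2 || n_fibers %% 2 != 0, "n_fibers must be even")
  half <- n_fibers / 2
  first <- seq_len(half)
  start <- half + ceiling(half / 2)
  second <- half + 1 + (start - (half + 1) - (seq_len(half) - 1)) %% half
  as.integer(c(rbind(first, second)))
}

#' Build a scan sequence
#'
#' One "single-wavelength frame" is one sweep over all fibers at the laser
#' pulse rate; a spectroscopic cycle repeats that sweep at each wavelength.
#' Derived timing: `frame_time = n_fibers / pulse_rate`,
#' `cycle_time = n_wavelengths * frame_time`,
#' `effective_frame_rate = 1 / frame_time`.
#'
#' @param wavelengths ordered wavelength list (nm). Default is the 10-color
#'   fast-sweep schedule 700, 715, 735, ..., 875 nm.
#' @param n_fibers fibers fired per frame.
#' @param pulse_rate laser pulse repetition rate (Hz).
#' @param laser_off_wavelengths wavelengths fired at zero energy to measure
#'   the noise floor (default 700 nm).
#' @param fiber_order `"ascending"`, `"interleaved"`, or an explicit
#'   permutation of `1:n_fibers`.
#' @return object of class `paus_sequence`.
#' @examples
#' sq <- scan_sequence(n_fibers = 20, pulse_rate = 1000)
#' sq$frame_time_single_wavelength # 0.02 s -> 50 Hz
#' @export
scan_sequence <- function(wavelengths = c(700, seq(715, 875, by = 20)),
                          n_fibers = 20L,
                          pulse_rate = 1000,
                          laser_off_wavelengths = 700,
                          fiber_order = "ascending") {
  abort_if(length(wavelengths) == 0, "wavelengths must be non-empty")
  abort_if(pulse_rate <= 0, "pulse_rate must be positive")
  abort_if(!all(laser_off_wavelengths %in% wavelengths),
           "laser_off_wavelengths must be a subset of wavelengths")
  if (is.character(fiber_order)) {
    fiber_order <- match.arg(fiber_order, c("ascending", "interleaved"))
    fiber_order <- if (fiber_order == "interleaved") {
      interleaved_fiber_order(n_fibers)
    } else {
      seq_len(n_fibers)
    }
  }
  abort_if(!identical(sort(as.integer(fiber_order)), seq_len(as.integer(n_fibers))),
           "fiber_order must be a permutation of 1:n_fibers")

  frame_time <- n_fibers / pulse_rate
  structure(list(
    wavelengths = wavelengths,
    n_wavelengths = length(wavelengths),
    laser_off_wavelengths = laser_off_wavelengths,
    active_wavelengths = setdiff(wavelengths, laser_off_wavelengths),
    fiber_order = as.integer(fiber_order),
    n_fibers = as.integer(n_fibers),
    pulse_rate = pulse_rate,
    frame_time_single_wavelength = frame_time,
    spectroscopic_cycle_time = length(wavelengths) * frame_time,
    effective_frame_rate = 1 / frame_time
  ), class = "paus_sequence")
}

#' @export
print.paus_sequence <- function(x, ...) {
  cat(sprintf(
    "Scan sequence: %d wavelengths x %d fibers @ %g Hz\n",
    x$n_wavelengths, x$n_fibers, x$pulse_rate))
  cat(sprintf(
    "  frame %.1f ms (%.1f Hz), spectroscopic cycle %.1f ms (%.2f Hz)\n",
    x$frame_time_single_wavelength * 1e3, x$effective_frame_rate,
    x$spectroscopic_cycle_time * 1e3, 1 / x$spectroscopic_cycle_time))
  invisible(x)
}

#' Define the shared reconstruction pixel grid
#'
#' All modules of a dataset share one grid: origin at the array center on the
#' tissue surface, x lateral, z axial positive into tissue, grid nodes at
#' pixel centers.
#'
#' @param x_range lateral extent, length-2 (m).
#' @param z_range axial extent, length-2 (m), `z >= 0`.
#' @param dx,dz pixel pitch (m).
#' @return object of class `paus_grid` with node coordinate vectors `x`, `z`.
#' @export
image_grid <- function(x_range = c(-6.4e-3, 6.4e-3),
                       z_range = c(2e-3, 12e-3),
                       dx = 0.15e-3, dz = 0.15e-3) {
  abort_if(dx <= 0 || dz <= 0, "pixel pitch must be positive")
  abort_if(diff(x_range) <= 0 || diff(z_range) <= 0,
           "ranges must be increasing")
  x <- seq(x_range[1] + dx / 2, x_range[2] - dx / 2 + 1e-12, by = dx)
  z <- seq(z_range[1] + dz / 2, z_range[2] - dz / 2 + 1e-12, by = dz)
  structure(list(x = x, z = z, nx = length(x), nz = length(z),
                 dx = dx, dz = dz,
                 x_range = x_range, z_range = z_range),
            class = "paus_grid")
}

#' @export
print.paus_grid <- function(x, ...) {
  cat(sprintf("Image grid: %d x %d px, %.0f x %.0f um pitch, x [%.1f, %.1f] mm, z [%.1f, %.1f] mm\n",
              x$nz, x$nx, x$dz * 1e6, x$dx * 1e6,
              min(x$x) * 1e3, max(x$x) * 1e3, min(x$z) * 1e3, max(x$z) * 1e3))
  invisible(x)
}

# npix x 2 matrix of (x, z) pixel-center coordinates, column-major like the
# nz x nx image matrices used throughout
grid_pixels <- function(grid) {
  cbind(x = rep(grid$x, each = grid$nz), z = rep(grid$z, times = grid$nx))
}
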