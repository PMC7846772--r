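#' Effective optical attenuation coefficient
#'
#' Diffusion-regime effective attenuation `mu_eff = sqrt(3 mu_a mu_s')`,
#' consistent with the diffusion coefficient `D = 1/(3 mu_s')`.
#'
#' @param mu_a absorption coefficient (1/cm), `>= 0`.
#' @param mu_s_prime reduced scattering coefficient (1/cm), `>= 0`.
#' @return `mu_eff` (1/cm).
#' @examples
#' effective_attenuation(0.1, 10) # 1.732
#' @export
effective_attenuation <- function(mu_a, mu_s_prime) {
  abort_if(any(mu_a < 0) || any(mu_s_prime < 0), "coefficients must be >= 0")
  sqrt(3 * mu_a * mu_s_prime)
}

#' Diffusion coefficient from reduced scattering
#' @param mu_s_prime 1/cm.
#' @return D (cm).
#' @export
diffusion_coefficient <- function(mu_s_prime) {
  abort_if(any(mu_s_prime <= 0), "mu_s_prime must be positive")
  1 / (3 * mu_s_prime)
}

#' Point-source fluence (infinite-medium diffusion Green's function)
#'
#' `Phi(r) = exp(-mu_eff r) / (4 pi D r)` for unit source power. The
#' infinite-medium form is used because the fit consumes only the
#' amplitude-versus-distance shape; it is isolated here so a semi-infinite
#' boundary solution can be swapped in.
#'
#' @param r source-to-point distance (cm), `> 0`.
#' @param mu_eff effective attenuation (1/cm).
#' @param D diffusion coefficient (cm).
#' @return relative fluence (1/cm^2 per unit power).
#' @export
fluence_point_source <- function(r, mu_eff, D = 1 / 30) {
  abort_if(any(r <= 0), "r must be > 0 (point-source singularity at r = 0)")
  abort_if(mu_eff < 0 || D <= 0, "need mu_eff >= 0 and D > 0")
  exp(-mu_eff * r) / (4 * pi * D * r)
}

# nz*nx x n_fibers matrix of 3-D pixel-to-fiber distances in cm (includes the
# fiber elevation standoff); column-major pixel order
fiber_distances_cm <- function(geometry, grid, fibers = seq_len(geometry$n_fibers)) {
  px <- grid_pixels(grid)
  fp <- geometry$fiber_positions[fibers, , drop = FALSE]
  d <- matrix(0, nrow(px), nrow(fp))
  for (j in seq_len(nrow(fp))) {
    d[, j] <- sqrt((px[, 1] - fp[j, 1])^2 + fp[j, 2]^2 + (px[, 2] - fp[j, 3])^2)
  }
  d * 100  # m -> cm
}

#' Per-fiber and total fluence maps on the image grid
#'
#' Evaluates the diffusion point-source fluence from each fired fiber at
#' every in-plane pixel; distances are 3-D and include the fiber rows'
#' elevation standoff.
#'
#' @param geometry a [probe_geometry()].
#' @param mu_eff effective attenuation (1/cm).
#' @param D diffusion coefficient (cm).
#' @param grid an [image_grid()].
#' @param fired_fibers fiber indices contributing to the total map.
#' @return object of class `paus_fluence`: list with `per_fiber` (array
#'   `nz x nx x n_fired`), `total` (`nz x nx`), `fired_fibers`, `mu_eff`, `D`.
#' @export
total_fluence_map <- function(geometry, mu_eff, D, grid,
                              fired_fibers = seq_len(geometry$n_fibers)) {
  abort_if(length(fired_fibers) == 0, "fired_fibers must be non-empty")
  d <- fiber_distances_cm(geometry, grid, fired_fibers)
  phi <- fluence_point_source(d, mu_eff, D)
  per_fiber <- array(phi, c(grid$nz, grid$nx, length(fired_fibers)))
  structure(list(per_fiber = per_fiber,
                 total = matrix(rowSums(phi), grid$nz, grid$nx),
                 fired_fibers = fired_fibers,
                 mu_eff = mu_eff, D = D, grid = grid),
            class = "paus_fluence")
}

#' Maximum permissible exposure for skin (700-1400 nm window)
#'
#' ANSI-style skin limits with the wavelength correction factor
#' `C_A = 1` for `lambda <= 700` nm, `10^(0.002 (lambda - 700))` for
#' 700-1050 nm and `5` above 1050 nm:
#' \itemize{
#'   \item single 1-100 ns pulse: `20 C_A` mJ/cm^2;
#'   \item exposure `1e-7 s < t <= 10 s`: `1.1 C_A t^0.25` J/cm^2
#'     (average irradiance = limit / t);
#'   \item `t > 10 s`: `0.2 C_A` W/cm^2.
#' }
#'
#' @param wavelength nm, within 400-1400.
#' @param exposure either the string `"pulse"` (single ns pulse) or an
#'   exposure duration in seconds.
#' @return object of class `paus_mpe`: list with `wavelength`, `C_A`, and
#'   the applicable `limit_fluence_per_pulse_mJ_cm2`, `limit_fluence_J_cm2`,
#'   `limit_irradiance_W_cm2` entries.
#' @examples
#' mpe_skin(700, "pulse")$limit_fluence_per_pulse_mJ_cm2  # 20
#' mpe_skin(1064, Inf)$limit_irradiance_W_cm2             # 1
#' mpe_skin(700, 1)$limit_irradiance_W_cm2                # 1.1
#' @export
mpe_skin <- function(wavelength, exposure) {
  abort_if(wavelength < 400 || wavelength > 1400,
           "wavelength outside 400-1400 nm")
  ca <- if (wavelength <= 700) {
    1
  } else {
    # capped at 5 (the 1050-1400 nm plateau), which also keeps C_A
    # monotone through the 1050 nm seam
    min(10^(0.002 * (wavelength - 700)), 5)
  }
  out <- list(wavelength = wavelength, C_A = ca, exposure = exposure)
  if (identical(exposure, "pulse")) {
    out$limit_fluence_per_pulse_mJ_cm2 <- 20 * ca
  } else {
    t <- as.numeric(exposure)
    abort_if(!is.finite(t) && !is.infinite(t), "exposure must be a time or 'pulse'")
    abort_if(is.finite(t) && t <= 1e-7,
             "sub-100 ns exposures: use exposure = 'pulse'")
    if (t > 10) {
      out$limit_irradiance_W_cm2 <- 0.2 * ca
    } else {
      out$limit_fluence_J_cm2 <- 1.1 * ca * t^0.25
      out$limit_irradiance_W_cm2 <- out$limit_fluence_J_cm2 / t
    }
  }
  class(out) <- "paus_mpe"
  out
}

#' @export
print.paus_mpe <- function(x, ...) {
  cat(sprintf("MPE (skin) at %g nm, C_A = %.3f:\n", x$wavelength, x$C_A))
  if (!is.null(x$limit_fluence_per_pulse_mJ_cm2)) {
    cat(sprintf("  per-pulse fluence limit: %.1f mJ/cm^2\n",
                x$limit_fluence_per_pulse_mJ_cm2))
  }
  if (!is.null(x$limit_fluence_J_cm2)) {
    cat(sprintf("  fluence limit over %g s: %.3f J/cm^2\n",
                as.numeric(x$exposure), x$limit_fluence_J_cm2))
  }
  if (!is.null(x$limit_irradiance_W_cm2)) {
    cat(sprintf("  average irradiance limit: %.3f W/cm^2\n",
                x$limit_irradiance_W_cm2))
  }
  invisible(x)
}
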