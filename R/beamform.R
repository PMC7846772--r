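#' Analytic signal along the time axis
#'
#' Hilbert transform of each element's RF trace via FFT, returning the
#' complex analytic signal; its magnitude is the detected envelope.
#'
#' @param x numeric matrix `n_elements x n_time` (or a vector).
#' @return complex array of the same shape.
#' @export
analytic_signal <- function(x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  X <- mvfft(t(x)) * h
  out <- t(mvfft(X, inverse = TRUE)) / n
  if (vec) out <- drop(out)
  out
}

#' @rdname analytic_signal
#' @export
envelope <- function(x) Mod(x)

#' Log-compress an envelope image for display
#'
#' dB relative to the image maximum, floored at `-dynamic_range` (default
#' 40 dB display convention).
#'
#' @param env non-negative envelope image.
#' @param dynamic_range dB.
#' @return matrix in `[-dynamic_range, 0]` dB.
#' @export
log_compress <- function(env, dynamic_range = 40) {
  m <- max(env)
  abort_if(m <= 0, "cannot log-compress an all-zero image")
  pmax(20 * log10(pmax(env, .Machine$double.xmin) / m), -dynamic_range)
}

das_core <- function(rf, geometry, grid, two_way, f_number = 0) {
  a <- analytic_signal(rf$samples)
  px <- grid_pixels(grid)
  # warn when part of the grid maps outside the recorded time window
  dmax <- max(sqrt((px[, 1] - min(geometry$element_positions[, 1]))^2 + px[, 2]^2),
              sqrt((px[, 1] - max(geometry$element_positions[, 1]))^2 + px[, 2]^2))
  tmax <- (if (two_way) max(px[, 2]) / geometry$sound_speed else 0) +
    dmax / geometry$sound_speed
  if ((tmax - rf$t0) * rf$sampling_rate > ncol(rf$samples) - 1) {
    warning("grid extends beyond the RF time window; out-of-window pixels zero-filled")
  }
  out <- cpp_das(Re(a), Im(a), geometry$element_positions,
                 px[, 1], px[, 2], geometry$sound_speed,
                 rf$sampling_rate, rf$t0, two_way, f_number)
  matrix(complex(real = out$re, imaginary = out$im), grid$nz, grid$nx)
}

#' Delay-and-sum a photoacoustic firing into a complex sub-image
#'
#' One-way delays (source-to-element), rectangular apodization, analytic
#' signal retained so that sub-images can be compounded coherently before
#' envelope detection.
#'
#' @param rf a `paus_rf` with `kind = "pa"`.
#' @param geometry a [probe_geometry()].
#' @param grid an [image_grid()].
#' @param f_number receive f-number gating: only elements within
#'   `|x_e - x_p| <= z_p / (2 f_number)` contribute to a pixel (0 = full
#'   aperture). Gating shortens the long lateral arc wings of the
#'   limited-view one-way PSF at the cost of a broader main lobe.
#' @return object of class `paus_subimage`: `data` (complex `nz x nx`),
#'   `fiber`, `wavelength` copied from the RF metadata.
#' @export
das_pa <- function(rf, geometry, grid, f_number = 0) {
  abort_if(!identical(rf$kind, "pa"), "das_pa expects a PA RF frame")
  structure(list(data = das_core(rf, geometry, grid, two_way = FALSE,
                                 f_number = f_number),
                 fiber = rf$metadata$fiber, wavelength = rf$metadata$wavelength,
                 grid = grid),
            class = "paus_subimage")
}

#' Delay-and-sum a pulse-echo frame into a B-mode envelope image
#'
#' Two-way delays (plane-wave transmit + receive path), dynamic receive
#' focusing everywhere, envelope detected.
#'
#' @inheritParams das_pa
#' @param rf a `paus_rf` with `kind = "us"`.
#' @return non-negative envelope matrix `nz x nx`.
#' @export
das_us <- function(rf, geometry, grid, f_number = 0) {
  abort_if(!identical(rf$kind, "us"), "das_us expects a US RF frame")
  envelope(das_core(rf, geometry, grid, two_way = TRUE,
                    f_number = f_number))
}

#' Coherently compound per-fiber sub-images into one PA image
#'
#' Complex sum over all sub-images of one wavelength, then envelope. With a
#' coherent signal split over K firings and independent per-firing noise,
#' signal adds linearly while noise adds in quadrature — the origin of the
#' fast-sweep SNR trade-off.
#'
#' @param subimages list of `paus_subimage` sharing one grid and wavelength.
#' @return object of class `paus_paimage`: `complex`, `envelope`,
#'   `wavelength`, `n_subimages`.
#' @export
compound_subimages <- function(subimages) {
  abort_if(length(subimages) == 0, "need at least one sub-image")
  wl <- unique(vapply(subimages, function(s) {
    if (is.null(s$wavelength)) NA_real_ else s$wavelength
  }, numeric(1)))
  abort_if(length(wl[!is.na(wl)]) > 1,
           "sub-images from mixed wavelengths cannot be compounded")
  acc <- subimages[[1]]$data
  if (length(subimages) > 1) {
    for (s in subimages[-1]) {
      abort_if(!all(dim(s$data) == dim(acc)), "sub-image grids differ")
      acc <- acc + s$data
    }
  }
  structure(list(complex = acc, envelope = Mod(acc),
                 wavelength = wl[!is.na(wl)][1],
                 n_subimages = length(subimages)),
            class = "paus_paimage")
}
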