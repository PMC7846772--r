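#' PatchMatch speckle-tracking parameters
#'
#' @param patch_half patch half-size in pixels (patch is
#'   `(2*patch_half+1)^2`; default 5, i.e. 11 x 11).
#' @param n_iterations propagation/random-search sweeps (default 5).
#' @param search_radius initial random-search radius in pixels (default 16),
#'   halving each draw.
#' @param radius_decay multiplicative radius decay per draw.
#' @param max_disp hard bound on the searched displacement (px).
#' @param subpixel parabolic subpixel refinement of the NCC surface.
#' @param field_smooth half-width (m) of the box filter applied to the
#'   estimated displacement components. Physiologic tissue motion is
#'   spatially smooth while the per-pixel speckle-tracking error is not —
#'   and that error repeats from pair to pair (it is determined by the
#'   same speckle pattern), so without smoothing it accumulates linearly
#'   over a spectroscopic sequence. 0 disables.
#' @param seed integer seed for the randomized search (mandatory).
#' @return list of class `paus_track_params`.
#' @export
track_params <- function(patch_half = 5L, n_iterations = 5L,
                         search_radius = 16L, radius_decay = 0.5,
                         max_disp = search_radius, subpixel = TRUE,
                         field_smooth = 0.5e-3, seed) {
  abort_if(missing(seed), "track_params(): seed is mandatory")
  abort_if(2 * patch_half + 1 < 3, "patch must be at least 3 px")
  abort_if(search_radius < 1, "search_radius must be >= 1")
  structure(list(patch_half = as.integer(patch_half),
                 n_iterations = as.integer(n_iterations),
                 search_radius = as.integer(search_radius),
                 radius_decay = radius_decay,
                 max_disp = as.integer(max_disp),
                 subpixel = isTRUE(subpixel),
                 field_smooth = field_smooth,
                 seed = as.integer(seed)),
            class = "paus_track_params")
}

#' PatchMatch displacement field between two B-mode envelope frames
#'
#' For every pixel `p` of `env_a`, finds the displacement `d` maximizing the
#' normalized cross-correlation between the patch around `p` in `env_a` and
#' the patch around `p + d` in `env_b` (randomized PatchMatch: zero-field
#' initialization, alternating raster propagation, exponentially shrinking
#' random search), then refines to subpixel by a parabolic fit. So `d` is
#' the scene displacement from frame a to frame b, and
#' `env_a(p) ~ env_b(p + d(p))`.
#'
#' @param env_a,env_b non-negative envelope frames of equal size.
#' @param params a [track_params()].
#' @param grid an [image_grid()] giving the pixel pitch; the returned field
#'   is in meters on this grid.
#' @return a `paus_motion_field` (`ux`, `uz` in m) with an extra `ncc`
#'   per-pixel correlation map in `[-1, 1]`.
#' @export
patchmatch_track <- function(env_a, env_b, params, grid) {
  abort_if(!all(dim(env_a) == dim(env_b)), "frame sizes differ")
  abort_if(any(env_a < 0) || any(env_b < 0), "envelopes must be non-negative")
  res <- cpp_patchmatch(env_a, env_b, params$patch_half, params$n_iterations,
                        params$search_radius, params$radius_decay,
                        params$max_disp, params$seed)
  dz <- res$dz
  dx <- res$dx
  if (!params$subpixel) {
    dz <- round(dz)
    dx <- round(dx)
  }
  fs <- params$field_smooth %||% 0
  if (fs > 0) {
    # correlation-weighted smoothing: pixels whose patch match is poor
    # (borders, decorrelated regions) should not pull their neighbors
    w <- pmax(res$ncc, 0)^2 + 1e-9
    hz <- max(1L, round(fs / grid$dz))
    hx <- max(1L, round(fs / grid$dx))
    dz <- box_smooth(dz * w, hz) / box_smooth(w, hz)
    dx <- box_smooth(dx * w, hx) / box_smooth(w, hx)
  }
  f <- motion_field(dx * grid$dx, dz * grid$dz, grid)
  f$ncc <- res$ncc
  f
}

#' Accumulate pairwise displacement fields to the reference frame
#'
#' Given pairwise scene displacements `d_1 .. d_k` (frame i to frame i+1,
#' each on the common grid), composes them into the cumulative field from
#' frame 1 to frame k+1: `c_k(p) = c_{k-1}(p) + d_k(p + c_{k-1}(p))` — the
#' previous cumulative field is *sampled at the displaced position*, not
#' added naively, so smoothly varying fields compose correctly.
#'
#' @param fields list of `paus_motion_field`s (sequential pairs).
#' @return list of cumulative `paus_motion_field`s, entry i mapping frame 1
#'   to frame i+1.
#' @export
accumulate_displacements <- function(fields) {
  abort_if(length(fields) == 0, "empty field list")
  grid <- fields[[1]]$grid
  nz <- grid$nz
  nx <- grid$nx
  rows0 <- matrix(rep(seq_len(nz), nx), nz, nx)
  cols0 <- matrix(rep(seq_len(nx), each = nz), nz, nx)
  out <- vector("list", length(fields))
  cum <- fields[[1]]
  out[[1]] <- cum
  if (length(fields) > 1) {
    for (i in 2:length(fields)) {
      d <- fields[[i]]
      rows <- rows0 + cum$uz / grid$dz
      cols <- cols0 + cum$ux / grid$dx
      dux <- matrix(bilinear_sample(d$ux, rows, cols), nz, nx)
      duz <- matrix(bilinear_sample(d$uz, rows, cols), nz, nx)
      cum <- motion_field(cum$ux + dux, cum$uz + duz, grid)
      out[[i]] <- cum
    }
  }
  out
}

#' Resample a displacement field onto another grid
#'
#' Bilinear interpolation of the field components at the target grid's
#' pixel centers (values clamped to the source footprint at the edges);
#' used to move tracking results from the refined B-mode grid onto the
#' coarser PA grid.
#'
#' @param field a `paus_motion_field`.
#' @param grid target [image_grid()] covering the same physical extent.
#' @return a `paus_motion_field` on `grid`.
#' @export
resample_field <- function(field, grid) {
  src <- field$grid
  if (identical(src$nx, grid$nx) && identical(src$nz, grid$nz) &&
      isTRUE(all.equal(src$x, grid$x)) && isTRUE(all.equal(src$z, grid$z))) {
    return(field)
  }
  px <- grid_pixels(grid)
  rows <- pmin(pmax((px[, 2] - src$z[1]) / src$dz + 1, 1), src$nz)
  cols <- pmin(pmax((px[, 1] - src$x[1]) / src$dx + 1, 1), src$nx)
  motion_field(matrix(bilinear_sample(field$ux, rows, cols), grid$nz, grid$nx),
               matrix(bilinear_sample(field$uz, rows, cols), grid$nz, grid$nx),
               grid)
}

#' Warp an image onto the reference frame with a displacement field
#'
#' Resamples the image at the displaced coordinates by bilinear
#' interpolation: `aligned(p) = image(p + field(p))`. Works for real and
#' complex (pre-envelope) images; samples falling outside the frame are
#' zeroed and flagged in the returned `mask` attribute.
#'
#' @param image `nz x nx` matrix (real or complex).
#' @param field a `paus_motion_field` on the image grid.
#' @param axial_carrier optional axial carrier frequency (cycles per meter)
#'   of a complex beamformed image (`fc / c` for one-way PA delays). The
#'   carrier is demodulated before interpolation and re-applied on the
#'   reference grid afterwards (IQ-style warping) — interpolating the
#'   modulated complex field directly would scramble phase whenever the
#'   carrier is near or beyond the grid's Nyquist limit.
#' @return warped matrix with attribute `mask` (TRUE where valid).
#' @export
warp_image <- function(image, field, axial_carrier = NULL) {
  grid <- field$grid
  abort_if(!all(dim(image) == c(grid$nz, grid$nx)),
           "field is not on the image grid")
  demod <- !is.null(axial_carrier) && is.complex(image)
  if (demod) {
    ph <- exp(-2i * pi * axial_carrier * grid$z)
    image <- image * ph  # recycles down columns (rows are axial)
  }
  rows <- matrix(rep(seq_len(grid$nz), grid$nx), grid$nz, grid$nx) +
    field$uz / grid$dz
  cols <- matrix(rep(seq_len(grid$nx), each = grid$nz), grid$nz, grid$nx) +
    field$ux / grid$dx
  out <- matrix(bilinear_sample(image, rows, cols), grid$nz, grid$nx)
  if (demod) {
    out <- out * exp(2i * pi * axial_carrier * grid$z)
  }
  mask <- matrix(rows >= 1 & rows <= grid$nz & cols >= 1 & cols <= grid$nx,
                 grid$nz, grid$nx)
  attr(out, "mask") <- mask
  out
}
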