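#' Simulate a full fast-sweep spectroscopic acquisition
#'
#' One single-wavelength frame per scheduled wavelength: the ground-truth
#' motion model displaces the scene, one plane-wave B-mode frame is
#' simulated and beamformed, then every fiber in the firing order
#' illuminates the displaced absorption map through its own diffusion
#' fluence and the resulting RF is beamformed into a complex sub-image.
#' Laser-off wavelengths are acquired with zero energy (noise only).
#' All randomness derives from `seed` via named substreams, so the noise
#' stream is independent of the phantom's scatterer stream.
#'
#' @param phantom a [make_phantom()].
#' @param geometry a [probe_geometry()].
#' @param sequence a [scan_sequence()]; `sequence$n_fibers` must equal
#'   `geometry$n_fibers`.
#' @param grid an [image_grid()] (default: the phantom's grid).
#' @param noise list: either explicit RF noise standard deviations
#'   `pa_sigma`, `us_sigma`, or peak-RF SNR targets `pa_snr_db`,
#'   `us_snr_db` calibrated on the first active frame.
#' @param seed top-level integer seed.
#' @param f_number receive f-number gating passed to [das_pa()] for the PA
#'   sub-images (0 = full aperture). Gating trims the long limited-view arc
#'   wings that otherwise pool fluence across an extended absorber and bias
#'   the per-fiber amplitude decay.
#' @param bmode_refine integer factor by which the B-mode grid refines the
#'   PA grid pitch. Speckle tracking needs the envelope sampled finer than
#'   the speckle cell (~ one acoustic wavelength), while PA spectroscopy is
#'   fine on the coarser grid; B-mode is therefore beamformed on its own
#'   refined grid and motion fields are resampled onto the PA grid.
#' @param keep_rf retain the raw RF frames (memory heavy; default FALSE).
#' @return object of class `paus_stack` with per-wavelength sub-image
#'   arrays (`sub`), compounded complex images (`comp`), B-mode envelopes
#'   (`bmode`), ground-truth motion (`motion_true`), per-frame laser
#'   energies and the true background `mu_eff` per wavelength.
#' @export
simulate_acquisition <- function(phantom, geometry, sequence,
                                 grid = phantom$grid,
                                 noise = list(pa_snr_db = 30, us_snr_db = 30),
                                 seed = 1L, bmode_refine = 3L,
                                 f_number = 0, keep_rf = FALSE) {
  abort_if(sequence$n_fibers != geometry$n_fibers,
           "sequence and geometry disagree on the fiber count")
  nw <- sequence$n_wavelengths
  wl <- sequence$wavelengths
  pulse <- gauss_pulse(geometry$center_frequency, geometry$bandwidth_fraction)
  energy <- as.numeric(!(wl %in% sequence$laser_off_wavelengths))
  bgrid <- if (bmode_refine > 1) {
    image_grid(grid$x_range, grid$z_range,
               dx = grid$dx / bmode_refine, dz = grid$dz / bmode_refine)
  } else {
    grid
  }

  # wavelength-dependent background optics drive the true fluence
  musp <- vapply(wl, function(l) mu_s_prime(phantom, l), numeric(1))
  mu_eff_true <- vapply(seq_len(nw), function(i) {
    effective_attenuation(mu_a_background(phantom, wl[i]), musp[i])
  }, numeric(1))

  # PA emitters: material absorption sampled once at the reference
  # positions; fluence follows the (possibly displaced) emitter positions
  em <- phantom$pa_emitters
  em_scale <- diff(grid$x_range) * diff(grid$z_range) / nrow(em)
  mu_em <- lapply(seq_len(nw), function(i) {
    if (energy[i] > 0) mu_a_at(phantom, wl[i], em[, "x"], em[, "z"]) else NULL
  })
  fiber_pos <- geometry$fiber_positions
  emitter_fluence <- function(pos, i) {
    # n_emitters x n_fibers relative fluence at wavelength index i
    d <- matrix(0, nrow(pos), geometry$n_fibers)
    for (f in seq_len(geometry$n_fibers)) {
      d[, f] <- sqrt((pos[, "x"] - fiber_pos[f, 1])^2 + fiber_pos[f, 2]^2 +
                       (pos[, "z"] - fiber_pos[f, 3])^2) * 100
    }
    fluence_point_source(d, mu_eff_true[i], diffusion_coefficient(musp[i]))
  }
  pa_rf_for <- function(pos, mu_q, phi_f, sigma, sd_seed, meta) {
    amp <- phantom$grueneisen * mu_q * phi_f * em_scale
    n_time <- rf_n_time(geometry, grid, pulse, two_way = FALSE)
    rf <- cpp_rf_sim(pos[, "x"], rep(0, nrow(pos)), pos[, "z"], amp,
                     rep(0, nrow(pos)), geometry$element_positions,
                     geometry$sound_speed, geometry$sampling_rate,
                     n_time, 0, pulse$fc, pulse$sigma_t)
    if (sigma > 0) {
      rf <- rf + with_seed(sd_seed, matrix(rnorm(length(rf), sd = sigma),
                                           nrow(rf), ncol(rf)))
    }
    structure(list(samples = rf, sampling_rate = geometry$sampling_rate,
                   t0 = 0, kind = "pa", pulse = pulse, metadata = meta),
              class = "paus_rf")
  }

  # noise calibration on the first active frame (noiseless pre-pass)
  pa_sigma <- noise$pa_sigma
  us_sigma <- noise$us_sigma
  first_act <- which(energy > 0)[1]
  if (is.null(pa_sigma)) {
    stopifnot(!is.null(noise$pa_snr_db), !is.na(first_act))
    u <- sample_motion(phantom$motion_model, first_act, grid)
    pos <- displace_scatterers(em, u)
    phi <- emitter_fluence(pos, first_act)
    peak <- 0
    for (f in seq_len(geometry$n_fibers)) {
      rf <- pa_rf_for(pos, mu_em[[first_act]], phi[, f], 0, 1L, list())
      peak <- max(peak, max(abs(rf$samples)))
    }
    pa_sigma <- peak / 10^(noise$pa_snr_db / 20)
  }
  if (is.null(us_sigma)) {
    stopifnot(!is.null(noise$us_snr_db))
    rf <- simulate_us_rf(phantom$scatterers, geometry, bgrid, pulse)
    us_sigma <- max(abs(rf$samples)) / 10^(noise$us_snr_db / 20)
  }

  sub <- vector("list", nw)
  comp <- vector("list", nw)
  bmode <- vector("list", nw)
  motion_true <- vector("list", nw)
  rf_store <- if (keep_rf) vector("list", nw) else NULL

  for (wdx in seq_len(nw)) {
    u <- sample_motion(phantom$motion_model, wdx, grid)
    motion_true[[wdx]] <- u

    scat <- displace_scatterers(phantom$scatterers, u)
    us_rf <- simulate_us_rf(scat, geometry, bgrid, pulse,
                            noise_sigma = us_sigma,
                            seed = derive_seed(seed, paste0("noise-us-", wdx)),
                            metadata = list(frame = wdx))
    bmode[[wdx]] <- das_us(us_rf, geometry, bgrid)

    pos <- displace_scatterers(em, u)
    phi <- if (energy[wdx] > 0) emitter_fluence(pos, wdx) else NULL
    sub_w <- array(0i, c(grid$nz, grid$nx, geometry$n_fibers))
    rf_w <- if (keep_rf) vector("list", geometry$n_fibers) else NULL
    for (f in sequence$fiber_order) {
      rf <- pa_rf_for(
        pos,
        if (energy[wdx] > 0) mu_em[[wdx]] else rep(0, nrow(pos)),
        if (energy[wdx] > 0) phi[, f] else rep(0, nrow(pos)),
        pa_sigma,
        derive_seed(seed, paste0("noise-pa-", wdx, "-", f)),
        list(wavelength = wl[wdx], fiber = f, laser_energy = energy[wdx]))
      sub_w[, , f] <- das_pa(rf, geometry, grid, f_number = f_number)$data
      if (keep_rf) rf_w[[f]] <- rf
    }
    sub[[wdx]] <- sub_w
    comp[[wdx]] <- matrix(complex(real = rowSums(Re(sub_w), dims = 2),
                                  imaginary = rowSums(Im(sub_w), dims = 2)),
                          grid$nz, grid$nx)
    if (keep_rf) rf_store[[wdx]] <- rf_w
  }

  structure(list(
    grid = grid, bmode_grid = bgrid,
    geometry = geometry, sequence = sequence, pulse = pulse,
    sub = sub, comp = comp, bmode = bmode,
    motion_true = motion_true, laser_energy = energy,
    mu_eff_true = mu_eff_true, mu_s_prime_true = musp,
    noise = list(pa_sigma = pa_sigma, us_sigma = us_sigma),
    rf = rf_store, corrected = FALSE, compensated = FALSE,
    phantom = phantom, seed = as.integer(seed)
  ), class = "paus_stack")
}

#' @export
print.paus_stack <- function(x, ...) {
  cat(sprintf(
    "Spectroscopic stack: %d wavelengths x %d fibers, %d x %d px%s%s\n",
    x$sequence$n_wavelengths, x$geometry$n_fibers, x$grid$nz, x$grid$nx,
    if (isTRUE(x$corrected)) ", motion-corrected" else "",
    if (isTRUE(x$compensated)) ", fluence-compensated" else ""))
  invisible(x)
}

#' Motion-correct a spectroscopic stack via B-mode speckle tracking
#'
#' Estimates pairwise displacements between successive B-mode frames with
#' [patchmatch_track()], accumulates them to the first (reference) frame
#' with [accumulate_displacements()], and warps every sub-image, compounded
#' image and B-mode frame onto the reference.
#'
#' @param stack a `paus_stack`.
#' @param params a [track_params()]; its seed drives the randomized search.
#' @return the corrected stack (`corrected = TRUE`), with `motion_pairwise`
#'   and `motion_cumulative` fields attached.
#' @export
motion_correct <- function(stack, params) {
  nw <- stack$sequence$n_wavelengths
  if (nw < 2) {
    stack$corrected <- TRUE
    return(stack)
  }
  bgrid <- stack$bmode_grid %||% stack$grid
  pairwise <- vector("list", nw - 1)
  for (i in seq_len(nw - 1)) {
    p_i <- params
    p_i$seed <- derive_seed(params$seed, paste0("tracking-", i))
    pairwise[[i]] <- patchmatch_track(stack$bmode[[i]], stack$bmode[[i + 1]],
                                      p_i, bgrid)
  }
  cumulative <- accumulate_displacements(pairwise)

  # one-way PA delays put the axial carrier at fc / c cycles per meter
  carrier <- stack$geometry$center_frequency / stack$geometry$sound_speed
  for (w in 2:nw) {
    fld <- resample_field(cumulative[[w - 1]], stack$grid)
    nf <- dim(stack$sub[[w]])[3]
    for (f in seq_len(nf)) {
      stack$sub[[w]][, , f] <- warp_image(stack$sub[[w]][, , f], fld,
                                          axial_carrier = carrier)
    }
    stack$comp[[w]] <- warp_image(stack$comp[[w]], fld,
                                  axial_carrier = carrier)
    stack$bmode[[w]] <- warp_image(stack$bmode[[w]], cumulative[[w - 1]])
  }
  stack$motion_pairwise <- pairwise
  stack$motion_cumulative <- cumulative
  stack$corrected <- TRUE
  stack
}
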