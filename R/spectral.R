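#' Brute-force search grid for the fluence fit
#'
#' Default: `mu_eff` from 0 to 5 1/cm in steps of 0.05; diffusion
#' coefficients `D = 1/(3 mu_s')` for 15 log-spaced `mu_s'` between 2 and
#' 30 1/cm. Model profiles over this grid can be computed once and cached.
#'
#' @param mu_eff_max,mu_eff_step 1/cm.
#' @param mu_s_prime_range,n_mu_s_prime log-spaced reduced-scattering grid.
#' @return list with `mu_eff`, `mu_s_prime`, `D`.
#' @export
fluence_search_grid <- function(mu_eff_max = 5, mu_eff_step = 0.05,
                                mu_s_prime_range = c(2, 30),
                                n_mu_s_prime = 15) {
  musp <- exp(seq(log(mu_s_prime_range[1]), log(mu_s_prime_range[2]),
                  length.out = n_mu_s_prime))
  list(mu_eff = seq(0, mu_eff_max, by = mu_eff_step),
       mu_s_prime = musp, D = 1 / (3 * musp))
}

#' Per-pixel noise floor from the laser-off frame
#'
#' The 700-nm slot is fired at zero laser energy, so its compounded
#' "image" is pure receive-chain noise; its (optionally box-smoothed)
#' envelope is the per-pixel noise amplitude used for masking and spectral
#' noise subtraction.
#'
#' @param stack a `paus_stack` from [simulate_acquisition()].
#' @param smooth odd box half-width in pixels for local averaging (0 = none).
#' @return `nz x nx` non-negative noise amplitude map.
#' @export
estimate_noise_floor <- function(stack, smooth = 2) {
  off <- which(stack$laser_energy == 0)
  abort_if(length(off) == 0, "stack has no laser-off (zero-energy) frame")
  env <- Mod(stack$comp[[off[1]]])
  if (smooth > 0) env <- box_smooth(env, smooth)
  env
}

box_smooth <- function(m, half) {
  nz <- nrow(m)
  nx <- ncol(m)
  cs <- matrix(0, nz + 1, nx + 1)
  cs[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  z0 <- pmax(seq_len(nz) - half - 1, 0)
  z1 <- pmin(seq_len(nz) + half, nz)
  x0 <- pmax(seq_len(nx) - half - 1, 0)
  x1 <- pmin(seq_len(nx) + half, nx)
  num <- cs[z1 + 1, x1 + 1] - cs[z0 + 1, x1 + 1] - cs[z1 + 1, x0 + 1] +
    cs[z0 + 1, x0 + 1]
  cnt <- outer(z1 - z0, x1 - x0)
  num / cnt
}

active_indices <- function(stack) {
  which(stack$laser_energy > 0)
}

#' Per-pixel amplitude spectra from a spectroscopic stack
#'
#' Envelope of the compounded per-wavelength image at each active
#' wavelength, optionally noise-subtracted (floored at zero) and/or taken
#' from the fluence-compensated images.
#'
#' @param stack a `paus_stack`.
#' @param noise_floor optional map from [estimate_noise_floor()]; when given,
#'   the floor is subtracted and negatives are clipped to zero.
#' @param compensated use the fluence-compensated images (requires
#'   [compensate_fluence()] to have been applied).
#' @return array `nz x nx x n_active`, with attribute `wavelengths`.
#' @export
pixel_spectra <- function(stack, noise_floor = NULL, compensated = FALSE) {
  act <- active_indices(stack)
  src <- if (compensated) {
    abort_if(is.null(stack$comp_comp), "stack is not fluence-compensated")
    stack$comp_comp
  } else {
    stack$comp
  }
  out <- array(0, c(stack$grid$nz, stack$grid$nx, length(act)))
  for (i in seq_along(act)) {
    env <- Mod(src[[act[i]]])
    if (!is.null(noise_floor)) env <- pmax(env - noise_floor, 0)
    out[, , i] <- env
  }
  attr(out, "wavelengths") <- stack$sequence$wavelengths[act]
  out
}

# pooled Beer's-law (log-linear) slope of amplitude*distance vs distance,
# with one intercept per pixel: the initial mu_eff estimate
beer_mu_eff <- function(A, r) {
  y <- log(pmax(A, .Machine$double.xmin) * r)
  yc <- y - rowMeans(y)
  rc <- r - rowMeans(r)
  max(0, -sum(yc * rc) / sum(rc * rc))
}

#' Estimate the effective attenuation coefficient from per-fiber amplitudes
#'
#' The amplitude of the per-fiber partial image at a fixed pixel varies with
#' the fiber-to-pixel distance through the fluence
#' `Phi(r) = exp(-mu_eff r)/(4 pi D r)`. Both measured and modeled per-fiber
#' amplitude vectors are normalized per pixel (divided by their sum over
#' fibers), cancelling the unknown local absorption, and a brute-force grid
#' search minimizes the amplitude-weighted squared error pooled over all
#' masked pixels. A Beer's-law log-linear fit provides the initial bracket.
#'
#' Note: after per-pixel normalization the infinite-medium model is exactly
#' independent of `D` (the `1/(4 pi D)` prefactor cancels), so the residual
#' is flat along the `D` axis; the reported `D_hat` is the tie-break value
#' `1/(3 * 10)` cm. Only `mu_eff` carries information, as expected.
#'
#' @param stack a `paus_stack` (or `NULL` when `amplitudes` and
#'   `distances_cm` are given directly).
#' @param wavelength active wavelength (nm) to fit (stack route).
#' @param geometry probe geometry (defaults to the stack's).
#' @param mask logical `nz x nx` pixel mask; default = compounded amplitude
#'   above `threshold` times the noise floor.
#' @param noise_floor map from [estimate_noise_floor()] (stack route).
#' @param threshold mask threshold factor over the noise floor (default 2).
#' @param search a [fluence_search_grid()].
#' @param max_pixels cap on masked pixels (strongest kept). Beyond bounding
#'   runtime, the brightest speckle maxima carry the cleanest per-fiber
#'   profiles (local absorber dominates the point-spread wings), so a
#'   moderate cap also improves accuracy.
#' @param beer_bracket half-width (1/cm) of the search bracket around the
#'   Beer's-law estimate; default `Inf` (full brute force — the grid is
#'   cheap, and the pooled log-linear Beer estimate is unreliable on
#'   speckle amplitudes). The Beer estimate is always reported in the fit.
#' @param trim_quantile,trim_passes robust trimming: after each pooled fit,
#'   only pixels whose per-pixel profile error is below this quantile are
#'   kept for the next pass (limited-view artifact pixels carry a remote
#'   absorber's fiber signature and would otherwise bias the fit).
#' @param amplitudes optional `n_pixels x n_fibers` matrix of per-fiber
#'   envelope amplitudes (bypasses the stack).
#' @param distances_cm matching `n_pixels x n_fibers` fiber distances (cm).
#' @param noise_power per-fiber sub-image noise power used to debias the
#'   envelope amplitudes (`A <- sqrt(max(A^2 - noise_power, 0))`, the
#'   first-order Rician correction). In the stack route it is estimated
#'   automatically from the laser-off sub-images; pass 0 to disable.
#' @param model_profiles optional cached model matrix from
#'   [fluence_model_profiles()] for these `distances_cm` and `search`.
#' @return object of class `paus_fluence_fit`.
#' @export
estimate_mu_eff <- function(stack = NULL, wavelength = NULL, geometry = NULL,
                            mask = NULL, noise_floor = NULL, threshold = 2,
                            search = fluence_search_grid(),
                            max_pixels = 100, beer_bracket = Inf,
                            trim_quantile = 0.75, trim_passes = 2,
                            amplitudes = NULL, distances_cm = NULL,
                            noise_power = NULL, model_profiles = NULL) {
  if (is.null(amplitudes)) {
    abort_if(is.null(stack) || is.null(wavelength),
             "either a stack + wavelength or amplitudes + distances_cm required")
    w <- match(wavelength, stack$sequence$wavelengths)
    abort_if(is.na(w) || stack$laser_energy[w] == 0,
             "wavelength not an active stack wavelength")
    geometry <- stack$geometry
    env_comp <- Mod(stack$comp[[w]])
    if (is.null(mask)) {
      if (is.null(noise_floor)) noise_floor <- estimate_noise_floor(stack)
      mask <- env_comp > threshold * noise_floor
    }
    abort_if(!any(mask), "no pixels above noise floor")
    idx <- which(mask)
    if (length(idx) > max_pixels) {
      idx <- idx[order(env_comp[idx], decreasing = TRUE)[seq_len(max_pixels)]]
    }
    nf <- dim(stack$sub[[w]])[3]
    amplitudes <- matrix(0, length(idx), nf)
    for (f in seq_len(nf)) {
      sub_env <- Mod(stack$sub[[w]][, , f])
      amplitudes[, f] <- sub_env[idx]
    }
    if (is.null(noise_power)) {
      # per-fiber sub-image noise power from the laser-off frame: envelope
      # magnitudes at low SNR are Rician-inflated, which flattens the
      # amplitude-vs-distance decay and biases mu_eff low
      off <- which(stack$laser_energy == 0)
      noise_power <- if (length(off)) {
        vapply(seq_len(nf), function(f) {
          mean(Mod(stack$sub[[off[1]]][, , f])^2)
        }, numeric(1))
      } else 0
    }
    distances_cm <- fiber_distances_cm(geometry, stack$grid)[idx, , drop = FALSE]
  } else {
    idx <- NULL
    abort_if(is.null(distances_cm) ||
               !all(dim(distances_cm) == dim(amplitudes)),
             "distances_cm must match amplitudes")
  }
  abort_if(nrow(amplitudes) == 0, "no pixels above noise floor")
  if (!is.null(noise_power) && any(noise_power > 0)) {
    amplitudes <- sqrt(pmax(sweep(amplitudes^2, 2, noise_power, "-"), 0))
  }

  rs <- rowSums(amplitudes)
  pos <- rs > 0
  amplitudes <- amplitudes[pos, , drop = FALSE]
  distances_cm <- distances_cm[pos, , drop = FALSE]
  if (!is.null(idx)) idx <- idx[pos]
  rs <- rs[pos]
  abort_if(nrow(amplitudes) == 0, "no pixels above noise floor")
  An <- amplitudes / rs
  # per-PIXEL amplitude weights: brighter pixels carry higher SNR. Weighting
  # each (pixel, fiber) entry by its own measured amplitude instead would
  # correlate the weights with the noise and bias mu_eff high.
  Wt <- matrix(rs / (sum(rs) * ncol(amplitudes)),
               nrow(amplitudes), ncol(amplitudes))

  mu_grid <- search$mu_eff
  mu0 <- beer_mu_eff(amplitudes, distances_cm)
  if (is.finite(beer_bracket)) {
    sel <- abs(mu_grid - mu0) <= beer_bracket
    if (!any(sel)) sel <- rep(TRUE, length(mu_grid))
    mu_grid <- mu_grid[sel]
  }

  if (is.null(model_profiles)) {
    model_profiles <- fluence_model_profiles(distances_cm, mu_grid)
  } else {
    abort_if(!identical(dim(model_profiles)[1:2], dim(amplitudes)) ||
               dim(model_profiles)[3] != length(mu_grid),
             "cached model profiles do not match this mask/search")
  }
  profile_mat <- function(i, rows) {
    matrix(model_profiles[, , i], nrow = nrow(An))[rows, , drop = FALSE]
  }
  pooled_sse <- function(rows) {
    vapply(seq_along(mu_grid), function(i) {
      sum(Wt[rows, , drop = FALSE] *
            (An[rows, , drop = FALSE] - profile_mat(i, rows))^2)
    }, numeric(1))
  }
  keep <- seq_len(nrow(An))
  sse <- pooled_sse(keep)
  best <- which.min(sse)
  # robust trimming: pixels whose normalized per-fiber profile fits the
  # current model worst (limited-view arc artifacts carry the signature of a
  # remote absorber, anti-correlated with their own distance model) are
  # dropped and the pooled fit repeated
  if (trim_passes > 0 && trim_quantile < 1 && length(keep) >= 8) {
    for (pass in seq_len(trim_passes)) {
      perr <- rowSums((An[keep, , drop = FALSE] - profile_mat(best, keep))^2)
      keep <- keep[perr <= quantile(perr, trim_quantile)]
      sse <- pooled_sse(keep)
      best <- which.min(sse)
    }
  }

  structure(list(
    wavelength = wavelength,
    mu_eff_hat = mu_grid[best],
    mu_s_prime_hat = 10,
    D_hat = 1 / 30,
    residual = sse[best],
    residuals = sse,
    mu_grid = mu_grid,
    beer_mu0 = mu0,
    search = search,
    mask = if (is.null(idx)) NULL else idx[keep],
    n_pixels = length(keep)
  ), class = "paus_fluence_fit")
}

#' Precompute normalized fluence model profiles over the mu_eff grid
#'
#' One `exp(-mu r)/r` profile per grid value, normalized per pixel over
#' fibers — the cache the brute-force fit consumes ("all possible fluences
#' calculated once and stored off-line").
#'
#' @param distances_cm `n_pixels x n_fibers` matrix (cm).
#' @param mu_grid vector of `mu_eff` values (1/cm).
#' @return array `n_pixels x n_fibers x length(mu_grid)`.
#' @export
fluence_model_profiles <- function(distances_cm, mu_grid) {
  out <- array(0, c(dim(distances_cm), length(mu_grid)))
  inv_r <- 1 / distances_cm
  for (i in seq_along(mu_grid)) {
    m <- exp(-mu_grid[i] * distances_cm) * inv_r
    out[, , i] <- m / rowSums(m)
  }
  out
}

#' @export
print.paus_fluence_fit <- function(x, ...) {
  cat(sprintf(
    "Fluence fit%s: mu_eff = %.2f 1/cm (Beer init %.2f), %d pixels, SSE %.3g\n",
    if (is.null(x$wavelength)) "" else sprintf(" @ %g nm", x$wavelength),
    x$mu_eff_hat, x$beer_mu0, x$n_pixels, x$residual))
  invisible(x)
}

#' Compensate the spectroscopic stack for wavelength-dependent fluence
#'
#' Divides each active wavelength's compounded image by the fitted total
#' fluence map. `rescale = "neutral"` (default) multiplies all wavelengths by
#' one common constant (mean fitted fluence at the reference depth across
#' wavelengths) so amplitudes stay O(1) without re-introducing any spectral
#' shape; `rescale = "depth"` uses the per-wavelength fluence at the
#' reference depth, making the correction exactly 1 there.
#'
#' @param stack a `paus_stack`.
#' @param fits list of `paus_fluence_fit`, one per active wavelength (in
#'   active-wavelength order).
#' @param rescale `"neutral"` or `"depth"`.
#' @param reference_row grid row index of the reference depth; default the
#'   shallowest masked row of the fits (or row 1).
#' @param floor_frac pixels whose fitted fluence is below `floor_frac` times
#'   the map maximum are flagged and not divided.
#' @param D optional per-active-wavelength diffusion coefficients (cm) used
#'   for the `1/(4 pi D)` prefactor, e.g. `1/(3 mu_s_prime(lambda))` from a
#'   background scattering prior. The per-pixel-normalized amplitude fit
#'   cannot identify `D` (it cancels), but the *true* fluence carries a
#'   `3 mu_s'(lambda)` prefactor; supplying the prior removes that residual
#'   spectral tilt. Default: the fits' tie-break `D_hat` (flat in lambda).
#' @return the stack with `comp_comp` (compensated complex images),
#'   `fits`, `compensated = TRUE`, and `comp_flagged` masks.
#' @export
compensate_fluence <- function(stack, fits, rescale = c("neutral", "depth"),
                               reference_row = NULL, floor_frac = 1e-9,
                               D = NULL) {
  rescale <- match.arg(rescale)
  act <- active_indices(stack)
  abort_if(length(fits) != length(act),
           "need one fluence fit per active wavelength")
  grid <- stack$grid
  if (is.null(reference_row)) {
    rows <- unlist(lapply(fits, function(f) {
      if (is.null(f$mask)) NULL else (f$mask - 1) %% grid$nz + 1
    }))
    reference_row <- if (length(rows)) min(rows) else 1L
  }
  if (is.null(D)) D <- vapply(fits, function(f) f$D_hat, numeric(1))
  abort_if(length(D) != length(act), "need one D per active wavelength")
  phi <- lapply(seq_along(fits), function(i) {
    total_fluence_map(stack$geometry, fits[[i]]$mu_eff_hat, D[i], grid)$total
  })
  ref_vals <- vapply(phi, function(p) mean(p[reference_row, ]), numeric(1))
  scales <- if (rescale == "neutral") rep(mean(ref_vals), length(act)) else ref_vals

  stack$comp_comp <- stack$comp
  stack$comp_flagged <- vector("list", length(stack$comp))
  for (i in seq_along(act)) {
    w <- act[i]
    p <- phi[[i]]
    flag <- p < floor_frac * max(p)
    corr <- scales[i] / p
    corr[flag] <- 1
    stack$comp_comp[[w]] <- stack$comp[[w]] * corr
    stack$comp_flagged[[w]] <- flag
  }
  stack$fits <- fits
  stack$compensated <- TRUE
  stack
}

#' Wavelength-compounded (sigma-lambda) PA image
#'
#' Coherent complex sum of the per-wavelength compounded images over all
#' active wavelengths (the laser-off slot is excluded), then envelope.
#' Warns when the stack has not been motion corrected.
#'
#' @param stack a `paus_stack`.
#' @return object of class `paus_paimage` (`complex`, `envelope`).
#' @export
sigma_lambda_compound <- function(stack) {
  if (!isTRUE(stack$corrected)) {
    warning("stack is not motion-corrected; compounding as-is")
  }
  act <- active_indices(stack)
  acc <- stack$comp[[act[1]]]
  for (w in act[-1]) acc <- acc + stack$comp[[w]]
  structure(list(complex = acc, envelope = Mod(acc), wavelength = NA_real_,
                 n_subimages = length(act)),
            class = "paus_paimage")
}

#' Normalized cross-correlation between two spectra
#'
#' Pearson correlation of the mean-removed spectra (scale-invariant, so it
#' is unchanged by area normalization). Zero-variance inputs return 0.
#'
#' @param x,y numeric vectors on the same wavelength grid.
#' @return value in `[-1, 1]`.
#' @export
spectrum_ncc <- function(x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  den <- sqrt(sum(xc^2) * sum(yc^2))
  if (den <= 0) return(0)
  sum(xc * yc) / den
}

#' Component-weighted PA image from reference-spectrum correlation
#'
#' Per pixel, the NCC between the (fluence-compensated, noise-subtracted,
#' area-normalized) measured spectrum and the area-normalized reference
#' spectrum; the component image is the sigma-lambda envelope times
#' `max(NCC, 0)`. The signed NCC map is retained for diagnostics. Pixels
#' whose sigma-lambda amplitude is below `display_threshold_db` of the image
#' maximum are excluded from spectral statistics via the returned mask.
#'
#' @param stack a fluence-compensated `paus_stack`.
#' @param sigma_lambda result of [sigma_lambda_compound()].
#' @param reference a [paus_spectrum()] covering the active wavelengths.
#' @param noise_floor map from [estimate_noise_floor()] (`NULL` to skip
#'   subtraction, e.g. for noiseless simulations).
#' @param display_threshold_db default -15 dB.
#' @return list of class `paus_component`: `component`, `ncc`, `weight`,
#'   `display_mask`, `reference_values`.
#' @export
component_weighted <- function(stack, sigma_lambda, reference,
                               noise_floor = NULL,
                               display_threshold_db = -15) {
  abort_if(!isTRUE(stack$compensated),
           "stack must be fluence-compensated first")
  act <- active_indices(stack)
  wl <- stack$sequence$wavelengths[act]
  ref <- resample_spectrum(reference, wl)     # errors if not covering
  ref <- normalize_spectrum(ref, wl)
  spec <- pixel_spectra(stack, noise_floor = noise_floor, compensated = TRUE)
  npx <- stack$grid$nz * stack$grid$nx
  X <- matrix(spec, npx, length(act))
  xc <- X - rowMeans(X)
  rc <- ref - mean(ref)
  den <- sqrt(rowSums(xc^2) * sum(rc^2))
  ncc <- as.vector(xc %*% rc)
  ncc <- ifelse(den > 0, ncc / den, 0)
  ncc <- pmin(pmax(ncc, -1), 1)
  ncc_m <- matrix(ncc, stack$grid$nz, stack$grid$nx)
  weight <- pmax(ncc_m, 0)
  comp <- sigma_lambda$envelope * weight
  thr <- max(sigma_lambda$envelope) * 10^(display_threshold_db / 20)
  structure(list(component = comp, ncc = ncc_m, weight = weight,
                 display_mask = sigma_lambda$envelope > thr,
                 reference_values = ref, wavelengths = wl),
            class = "paus_component")
}
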