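#' Default demonstration configuration
#'
#' A three-tube phantom (GNR-like, ink-like, flat broadband absorber) in an
#' Intralipid-like scattering background, imaged with the 10-wavelength
#' fast-sweep schedule. All lengths in the configuration are in mm and are
#' converted to meters internally. The probe block defaults to the
#' hardware-like geometry; the demo overrides use a reduced element count
#' and grid so the full pipeline runs in seconds.
#'
#' @param preset `"demo"` (small, fast) or `"full"` (128 elements,
#'   finer grid).
#' @return nested configuration list.
#' @export
paus_config <- function(preset = c("demo", "full")) {
  preset <- match.arg(preset)
  cfg <- list(
    version = 1L,
    probe = list(
      n_elements = if (preset == "demo") 64L else 128L,
      element_pitch_mm = if (preset == "demo") 0.15 else 0.1,
      center_frequency_mhz = 15, bandwidth_fraction = 0.6,
      sampling_rate_mhz = 62.5, sound_speed = 1540,
      f_number = 2),
    fibers = list(n_per_row = 10L, pitch_mm = 1.5, elevation_mm = 6),
    sequence = list(
      wavelengths = c(700, seq(715, 875, by = 20)),
      laser_off_wavelengths = 700,
      pulse_rate = 1000, fiber_order = "ascending"),
    grid = if (preset == "demo") {
      list(x_mm = c(-4.8, 4.8), z_mm = c(3, 11), dx_mm = 0.15, dz_mm = 0.15)
    } else {
      list(x_mm = c(-6.4, 6.4), z_mm = c(2, 14), dx_mm = 0.1, dz_mm = 0.1)
    },
    phantom = list(
      background = list(mu_a_peak = 0.25, mu_s_prime_800 = 10,
                        mie_slope = 1.3),
      inclusions = list(
        list(kind = "gnr", center_mm = c(-2.8, 7), radius_mm = 0.9,
             concentration = 3),
        list(kind = "water", center_mm = c(0, 8.5), radius_mm = 0.9,
             concentration = 1),
        list(kind = "ink", center_mm = c(2.8, 7), radius_mm = 0.9,
             concentration = 1.5)),
      scatterers_per_cell = 10,
      grueneisen = 1),
    motion = list(type = "none", per_frame_mm = c(0, 0),
                  amplitude_mm = 0.3, period = 12, spatial_wavelength_mm = 8),
    noise = list(pa_snr_db = 30, us_snr_db = 30),
    tracking = list(patch_half = 5L, n_iterations = 5L, search_radius = 16L),
    spectral = list(mask_threshold = 2, max_pixels = 100,
                    display_threshold_db = -15, rescale = "neutral"),
    motion_correction = TRUE,
    references = c("gnr", "ink")
  )
  cfg
}

#' Read a configuration from a JSON file
#' @param path JSON file following the [paus_config()] schema.
#' @return configuration list merged over the demo defaults.
#' @export
read_config_json <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  modifyList(paus_config("demo"), user)
}

config_geometry <- function(cfg) {
  probe_geometry(
    n_elements = cfg$probe$n_elements,
    element_pitch = cfg$probe$element_pitch_mm * 1e-3,
    n_fibers_per_row = cfg$fibers$n_per_row,
    fiber_pitch = cfg$fibers$pitch_mm * 1e-3,
    fiber_elevation = cfg$fibers$elevation_mm * 1e-3,
    center_frequency = cfg$probe$center_frequency_mhz * 1e6,
    bandwidth_fraction = cfg$probe$bandwidth_fraction,
    sampling_rate = cfg$probe$sampling_rate_mhz * 1e6,
    sound_speed = cfg$probe$sound_speed)
}

config_sequence <- function(cfg, geometry) {
  scan_sequence(wavelengths = cfg$sequence$wavelengths,
                n_fibers = geometry$n_fibers,
                pulse_rate = cfg$sequence$pulse_rate,
                laser_off_wavelengths = cfg$sequence$laser_off_wavelengths,
                fiber_order = cfg$sequence$fiber_order)
}

config_grid <- function(cfg) {
  image_grid(x_range = cfg$grid$x_mm * 1e-3, z_range = cfg$grid$z_mm * 1e-3,
             dx = cfg$grid$dx_mm * 1e-3, dz = cfg$grid$dz_mm * 1e-3)
}

config_phantom <- function(cfg, grid, seed) {
  wl_grid <- seq(650, 950, by = 5)
  incs <- lapply(cfg$phantom$inclusions, function(inc) {
    list(center = inc$center_mm * 1e-3, radius = inc$radius_mm * 1e-3,
         spectrum = chromophore_spectrum(inc$kind, wl_grid),
         concentration = inc$concentration,
         kind = inc$kind, shape = "disc")
  })
  mm <- cfg$motion
  model <- motion_model(mm$type,
                        per_frame = (mm$per_frame_mm %||% c(0, 0)) * 1e-3,
                        amplitude = (mm$amplitude_mm %||% 0.3) * 1e-3,
                        period = mm$period %||% 12,
                        spatial_wavelength =
                          (mm$spatial_wavelength_mm %||% 8) * 1e-3)
  make_phantom(
    grid,
    inclusions = incs,
    background = list(
      mu_a_spectrum = chromophore_spectrum(
        "background", wl_grid,
        peak_value = cfg$phantom$background$mu_a_peak),
      mu_s_prime_800 = cfg$phantom$background$mu_s_prime_800,
      mie_slope = cfg$phantom$background$mie_slope),
    scatterers_per_cell = cfg$phantom$scatterers_per_cell,
    fc_hint = cfg$probe$center_frequency_mhz * 1e6,
    sound_speed = cfg$probe$sound_speed,
    grueneisen = cfg$phantom$grueneisen %||% 1,
    motion_model = model,
    seed = derive_seed(seed, "scene"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full fast-sweep pipeline
#'
#' simulate -> beamform (inside the simulator) -> track/motion-correct ->
#' noise floor -> per-wavelength fluence fit -> compensation ->
#' sigma-lambda compounding -> component-weighted images, with per-stage
#' timing logs.
#'
#' @param config configuration list from [paus_config()] /
#'   [read_config_json()].
#' @param seed top-level seed; every stage derives its substream from it.
#' @param out optional directory: the resulting dataset is saved there.
#' @param verbose print stage timings.
#' @return a `paus_dataset` (see [paus_dataset()]).
#' @export
run_pipeline <- function(config = paus_config(), seed = 1L, out = NULL,
                         verbose = FALSE) {
  log_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed (seed %d): %s",
                   name, seed, conditionMessage(e)), call. = FALSE)
    })
    if (verbose) {
      message(sprintf("[pauskit] %-12s %6.2f s", name,
                      proc.time()[["elapsed"]] - t0))
    }
    res
  }

  setup <- log_stage("setup", {
    geometry <- config_geometry(config)
    list(geometry = geometry,
         sequence = config_sequence(config, geometry),
         grid = config_grid(config))
  })
  geometry <- setup$geometry
  sequence <- setup$sequence
  grid <- setup$grid
  phantom <- log_stage("phantom", config_phantom(config, grid, seed))

  stack <- log_stage("simulate", simulate_acquisition(
    phantom, geometry, sequence, grid,
    noise = config$noise, seed = derive_seed(seed, "noise"),
    f_number = config$probe$f_number %||% 0))

  if (isTRUE(config$motion_correction)) {
    tp <- track_params(patch_half = config$tracking$patch_half,
                       n_iterations = config$tracking$n_iterations,
                       search_radius = config$tracking$search_radius,
                       seed = derive_seed(seed, "tracking"))
    stack <- log_stage("track", motion_correct(stack, tp))
  }

  spectral <- log_stage("spectral", {
    floor_map <- estimate_noise_floor(stack)
    act <- stack$sequence$wavelengths[active_indices(stack)]
    fits <- lapply(act, function(l) {
      estimate_mu_eff(stack, wavelength = l, noise_floor = floor_map,
                      threshold = config$spectral$mask_threshold,
                      max_pixels = config$spectral$max_pixels)
    })
    # diffusion prefactor from the configured background scattering prior
    # (the normalized amplitude fit cannot identify D; see vignette)
    D_prior <- 1 / (3 * config$phantom$background$mu_s_prime_800 *
                      (act / 800)^(-config$phantom$background$mie_slope))
    stk <- compensate_fluence(stack, fits,
                              rescale = config$spectral$rescale %||% "neutral",
                              D = D_prior)
    sl <- sigma_lambda_compound(stk)
    comps <- lapply(config$references, function(kind) {
      component_weighted(
        stk, sl, chromophore_spectrum(kind, seq(650, 950, 5)),
        noise_floor = floor_map,
        display_threshold_db = config$spectral$display_threshold_db)
    })
    names(comps) <- config$references
    list(stack = stk, noise_floor = floor_map, fits = fits,
         sigma_lambda = sl, components = comps,
         mu_eff_table = data.frame(
           wavelength_nm = act,
           mu_eff_hat = vapply(fits, function(f) f$mu_eff_hat, numeric(1)),
           mu_eff_true = stack$mu_eff_true[active_indices(stack)]))
  })

  ds <- paus_dataset(
    config = config,
    phantom = phantom,
    images = stack,
    motion = if (isTRUE(config$motion_correction)) {
      list(pairwise = spectral$stack$motion_pairwise,
           cumulative = spectral$stack$motion_cumulative)
    } else NULL,
    spectral = spectral,
    seed = seed)
  if (!is.null(out)) save_dataset(ds, out)
  ds
}

#' Hierarchical result dataset
#'
#' In-memory hierarchical container (groups `config`, `phantom`, `images`,
#' `motion`, `spectral`) with provenance attributes; [save_dataset()] /
#' [load_dataset()] persist it as one file per group in a directory.
#'
#' @param config,phantom,images,motion,spectral group contents.
#' @param seed provenance seed.
#' @return list of class `paus_dataset`.
#' @export
paus_dataset <- function(config = NULL, phantom = NULL, images = NULL,
                         motion = NULL, spectral = NULL, seed = NA_integer_) {
  structure(list(config = config, phantom = phantom, images = images,
                 motion = motion, spectral = spectral,
                 provenance = list(seed = seed,
                                   version = as.character(utils::packageVersion("pauskit")),
                                   created = format(Sys.time(), tz = "UTC"))),
            class = "paus_dataset")
}

#' @param ds a `paus_dataset`.
#' @param dir directory to hold one `.rds` file per group.
#' @rdname paus_dataset
#' @export
save_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in names(ds)) {
    if (!is.null(ds[[g]])) saveRDS(ds[[g]], file.path(dir, paste0(g, ".rds")))
  }
  invisible(dir)
}

#' @rdname paus_dataset
#' @export
load_dataset <- function(dir) {
  abort_if(!dir.exists(dir), sprintf("dataset directory %s not found", dir))
  groups <- c("config", "phantom", "images", "motion", "spectral",
              "provenance")
  ds <- lapply(groups, function(g) {
    f <- file.path(dir, paste0(g, ".rds"))
    if (file.exists(f)) readRDS(f) else NULL
  })
  names(ds) <- groups
  class(ds) <- "paus_dataset"
  ds
}

#' @export
print.paus_dataset <- function(x, ...) {
  cat("PAUS dataset (seed", x$provenance$seed, ") groups:",
      paste(names(x)[!vapply(x, is.null, logical(1))], collapse = ", "), "\n")
  invisible(x)
}
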