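#' Default vibrational band table for ethanol-water mixtures in glass
#'
#' Gaussian band models used by the spectrum simulator. Ethanol bands sit at
#' 435 and 1275 cm-1 and inside the four descriptive intervals 850-910,
#' 1010-1130, 1410-1510 and 2840-3010 cm-1 (CC/CO stretches, CH bends, CH
#' stretches); water contributes the ~500 cm-1 hydrogen-bond band, the
#' 1640 cm-1 OH bend and the broad 3100-3600 cm-1 OH stretch envelope; the
#' borosilicate beaker contributes a broad low-wavenumber background.
#'
#' `amplitude` is the peak height in counts at unit volume fraction of the
#' band's component. Ethanol band heights scale linearly with ethanol volume
#' fraction; water and glass contributions are treated as
#' concentration-independent in the dilute regime covered here (<= 1 Vol%),
#' so the water background cancels exactly under reference subtraction.
#'
#' @return A tibble with columns `component` ("ethanol", "water" or "glass"),
#'   `center` (cm-1), `width` (Gaussian sigma, cm-1) and `amplitude` (counts
#'   per unit volume fraction).
#' @export
raman_bands <- function() {
  tibble::tribble(
    ~component, ~center, ~width, ~amplitude,
    "ethanol",  435,     8,      80000,
    "ethanol",  880,     8,      300000,
    "ethanol",  1050,    8,      200000,
    "ethanol",  1095,    8,      180000,
    "ethanol",  1275,    8,      60000,
    "ethanol",  1454,    10,     120000,
    "ethanol",  2880,    12,     500000,
    "ethanol",  2930,    12,     600000,
    "ethanol",  2975,    12,     400000,
    "water",    500,     80,     300,
    "water",    1640,    30,     150,
    "water",    3350,    150,    1000,
    "glass",    400,     200,    400
  )
}

#' Simulator configuration
#'
#' Collects the grid, band models and noise model of the synthetic Raman
#' spectrometer. The default grid is 300-3215 cm-1 at 1 cm-1 steps (2916
#' points). Noise at each grid point is zero-mean Gaussian with standard
#' deviation `sqrt(noise_floor_sd^2 + shot_noise_scale * clean_intensity)`,
#' a detector floor plus a shot-noise-like variance term. The defaults put
#' the strongest ethanol band of the most concentrated solution (0.962 Vol%)
#' near 5800 counts against a ~6 count noise floor, so the top of the
#' dilution series is cleanly separable while the bottom of the series
#' (around and below 0.01 Vol%, where band heights fall to a few counts)
#' sinks into the noise.
#'
#' @param grid_min,grid_max,grid_step Wavenumber grid in cm-1.
#' @param bands Band table as produced by [raman_bands()].
#' @param noise_floor_sd Detector noise floor, counts (>= 0).
#' @param shot_noise_scale Shot-noise variance per count (>= 0).
#' @param baseline_offset Constant dark/stray-light offset, counts.
#' @param replicates Replicate measurements per solution.
#' @param seed Master seed; each spectrum draws from a substream derived
#'   from `(seed, sample_number, replicate)` so any single spectrum is
#'   reproducible in isolation.
#'
#' @return An object of class `raman_sim_config`.
#' @export
sim_config <- function(grid_min = 300, grid_max = 3215, grid_step = 1,
                       bands = raman_bands(),
                       noise_floor_sd = 5, shot_noise_scale = 0.01,
                       baseline_offset = 100,
                       replicates = 10, seed = 1) {
  stopifnot(is.data.frame(bands),
            all(c("component", "center", "width", "amplitude") %in%
                  names(bands)))
  if (any(bands$width <= 0) || any(bands$amplitude < 0)) {
    abort("Band widths must be > 0 and amplitudes >= 0.",
          class = "ramanboost_invalid_argument")
  }
  if (noise_floor_sd < 0 || shot_noise_scale < 0) {
    abort("Noise parameters must be >= 0.",
          class = "ramanboost_invalid_argument")
  }
  structure(
    list(
      grid = seq(grid_min, grid_max, by = grid_step),
      grid_min = grid_min, grid_max = grid_max, grid_step = grid_step,
      bands = tibble::as_tibble(bands),
      noise_floor_sd = noise_floor_sd,
      shot_noise_scale = shot_noise_scale,
      baseline_offset = baseline_offset,
      replicates = as.integer(replicates),
      seed = as.integer(seed)
    ),
    class = "raman_sim_config"
  )
}

#' @export
print.raman_sim_config <- function(x, ...) {
  cat("<raman_sim_config>\n")
  cat(sprintf("  grid: %g-%g cm-1 at %g cm-1 (%d points)\n",
              x$grid_min, x$grid_max, x$grid_step, length(x$grid)))
  cat(sprintf("  bands: %d (%s)\n", nrow(x$bands),
              paste(unique(x$bands$component), collapse = ", ")))
  cat(sprintf("  noise: floor sd %g counts, shot scale %g\n",
              x$noise_floor_sd, x$shot_noise_scale))
  cat(sprintf("  replicates: %d, seed: %d\n", x$replicates, x$seed))
  invisible(x)
}

# Noise-free intensity on the grid for a given ethanol concentration (Vol%).
clean_intensity <- function(concentration, config) {
  vf <- concentration / 100
  grid <- config$grid
  out <- rep(config$baseline_offset, length(grid))
  for (i in seq_len(nrow(config$bands))) {
    b <- config$bands[i, ]
    mult <- if (b$component == "ethanol") vf else 1
    if (mult == 0) next
    out <- out + b$amplitude * mult * exp(-(grid - b$center)^2 / (2 * b$width^2))
  }
  out
}

#' Simulate one Raman spectrum of an ethanol-water mixture
#'
#' Sums Gaussian bands (ethanol bands scaled by volume fraction), a glass
#' background and a constant offset on the configured grid, then adds
#' Gaussian noise with standard deviation
#' `sqrt(noise_floor_sd^2 + shot_noise_scale * clean)`. The noise stream is
#' seeded from `(config$seed, sample_number, replicate)`, so the same triple
#' always reproduces the identical spectrum.
#'
#' @param concentration Ethanol concentration in Vol%, within [0, 100].
#' @param config A [sim_config()] object.
#' @param sample_number,replicate Provenance indices (also seed the noise).
#' @param noise Set `FALSE` for the noise-free spectrum.
#'
#' @return A tibble with columns `sample_number`, `replicate`,
#'   `concentration`, `wavenumber` and `intensity`, one row per grid point.
#' @export
simulate_spectrum <- function(concentration, config = sim_config(),
                              sample_number = 0L, replicate = 1L,
                              noise = TRUE) {
  if (!is.numeric(concentration) || length(concentration) != 1 ||
      is.na(concentration) || concentration < 0 || concentration > 100) {
    abort("`concentration` must be a single Vol% value in [0, 100].",
          class = "ramanboost_invalid_argument")
  }
  clean <- clean_intensity(concentration, config)
  intensity <- clean
  if (noise) {
    sds <- sqrt(config$noise_floor_sd^2 + config$shot_noise_scale * clean)
    intensity <- withr::with_seed(
      make_seed(config$seed, sample_number, replicate),
      clean + rnorm(length(clean), sd = sds)
    )
  }
  tibble::tibble(
    sample_number = as.integer(sample_number),
    replicate = as.integer(replicate),
    concentration = concentration,
    wavenumber = config$grid,
    intensity = intensity
  )
}

#' Simulate a full dilution-series measurement campaign
#'
#' Generates `config$replicates` spectra for every row of the dilution plan
#' (the pure-water sample 0 doubles as the water reference set) together
#' with a manifest linking each spectrum to its solution, concentration and
#' replicate index.
#'
#' @param plan A dilution plan from [dilution_series()].
#' @param config A [sim_config()].
#' @param noise Set `FALSE` for noise-free spectra.
#'
#' @return An object of class `raman_experiment`: a list with `spectra`
#'   (long tibble: `sample_number`, `replicate`, `concentration`,
#'   `wavenumber`, `intensity`), `manifest` (one row per spectrum), `plan`
#'   and `config`.
#' @export
simulate_experiment <- function(plan = dilution_series(),
                                config = sim_config(), noise = TRUE) {
  if (!is.data.frame(plan) || nrow(plan) < 1) {
    abort("`plan` must be a non-empty dilution plan.",
          class = "ramanboost_invalid_argument")
  }
  combos <- tidyr::expand_grid(
    plan[, c("sample_number", "concentration")],
    replicate = seq_len(config$replicates)
  )
  spectra <- purrr::pmap(combos, function(sample_number, concentration,
                                          replicate) {
    simulate_spectrum(concentration, config, sample_number, replicate,
                      noise = noise)
  }) |>
    purrr::list_rbind()
  manifest <- combos[, c("sample_number", "concentration", "replicate")]
  structure(
    list(spectra = spectra, manifest = manifest, plan = plan,
         config = config),
    class = "raman_experiment"
  )
}

#' @export
print.raman_experiment <- function(x, ...) {
  cat("<raman_experiment>\n")
  cat(sprintf("  %d spectra (%d solutions x %d replicates), %d grid points\n",
              nrow(x$manifest), length(unique(x$manifest$sample_number)),
              max(x$manifest$replicate), length(x$config$grid)))
  cat(sprintf("  concentrations: %s Vol%%\n",
              paste(signif(sort(unique(x$manifest$concentration),
                                decreasing = TRUE), 3), collapse = ", ")))
  invisible(x)
}

#' Water reference spectrum
#'
#' Pointwise mean intensity of the pure-water (sample 0) spectra, optionally
#' restricted to a subset of replicates. Restricting to the training
#' replicates keeps background subtraction free of test-set leakage in
#' cross-validated runs.
#'
#' @param spectra Long spectra tibble (or a `raman_experiment`).
#' @param replicates Optional replicate indices to average over.
#'
#' @return A tibble with columns `wavenumber` and `intensity`.
#' @export
water_reference <- function(spectra, replicates = NULL) {
  if (inherits(spectra, "raman_experiment")) spectra <- spectra$spectra
  w <- dplyr::filter(spectra, .data$sample_number == 0L)
  if (!is.null(replicates)) {
    w <- dplyr::filter(w, .data$replicate %in% !!replicates)
  }
  if (nrow(w) == 0) {
    abort("No sample-0 (pure water) spectra found for the reference.",
          class = "ramanboost_invalid_argument")
  }
  w |>
    dplyr::group_by(.data$wavenumber) |>
    dplyr::summarise(intensity = mean(.data$intensity), .groups = "drop") |>
    dplyr::arrange(.data$wavenumber)
}
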