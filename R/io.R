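#' Write an experiment to spectrum CSV files plus a manifest
#'
#' One CSV per spectrum (header `wavenumber_cm_1,intensity`, one row per
#' grid point) and a `manifest.csv` with columns
#' `sample_number,concentration_volpct,replicate,path`.
#'
#' @param experiment A `raman_experiment`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest tibble including relative paths.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "raman_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- experiment$manifest |>
    dplyr::mutate(path = sprintf("spectrum_s%02d_r%02d.csv",
                                 .data$sample_number, .data$replicate))
  purrr::pwalk(manifest, function(sample_number, concentration, replicate,
                                  path) {
    experiment$spectra |>
      dplyr::filter(.data$sample_number == !!sample_number,
                    .data$replicate == !!replicate) |>
      dplyr::transmute(wavenumber_cm_1 = .data$wavenumber,
                       intensity = .data$intensity) |>
      readr::write_csv(file.path(dir, path))
  })
  out <- manifest |>
    dplyr::transmute(sample_number = .data$sample_number,
                     concentration_volpct = .data$concentration,
                     replicate = .data$replicate, path = .data$path)
  readr::write_csv(out, file.path(dir, "manifest.csv"))
  invisible(out)
}

#' Read an experiment from a manifest of spectrum CSV files
#'
#' @param manifest_path Path to a `manifest.csv` written by
#'   [write_experiment()] (spectrum paths are resolved relative to it).
#' @return A `raman_experiment` (with `plan` and `config` set to `NULL`).
#' @export
read_experiment <- function(manifest_path) {
  man <- readr::read_csv(manifest_path, show_col_types = FALSE)
  stopifnot(all(c("sample_number", "concentration_volpct", "replicate",
                  "path") %in% names(man)))
  base <- dirname(manifest_path)
  spectra <- purrr::pmap(man, function(sample_number, concentration_volpct,
                                       replicate, path) {
    sp <- readr::read_csv(file.path(base, path), show_col_types = FALSE)
    tibble::tibble(sample_number = as.integer(sample_number),
                   replicate = as.integer(replicate),
                   concentration = concentration_volpct,
                   wavenumber = sp$wavenumber_cm_1,
                   intensity = sp$intensity)
  }) |>
    purrr::list_rbind()
  manifest <- tibble::tibble(sample_number = as.integer(man$sample_number),
                             concentration = man$concentration_volpct,
                             replicate = as.integer(man$replicate))
  structure(list(spectra = spectra, manifest = manifest, plan = NULL,
                 config = NULL),
            class = "raman_experiment")
}

#' Write / read a feature table
#'
#' CSV with the feature columns `f0001..f<d>` plus `label` (if present),
#' `sample_number` and `replicate`.
#'
#' @param features Feature tibble from [extract_features()] (optionally
#'   labeled).
#' @param path CSV path.
#' @return `write_features` returns `path` invisibly; `read_features`
#'   returns the tibble.
#' @export
write_features <- function(features, path) {
  cols <- c(feature_cols(features),
            intersect(c("label", "sample_number", "replicate",
                        "concentration"), names(features)))
  readr::write_csv(features[, cols], path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
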