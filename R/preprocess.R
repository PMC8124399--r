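#' Default evaluation intervals for ethanol
#'
#' The four wavenumber windows holding the descriptive ethanol bands:
#' 850-910, 1010-1130, 1410-1510 and 2840-3010 cm-1 (inclusive endpoints).
#'
#' @return A tibble with columns `low` and `high` (cm-1).
#' @export
ethanol_intervals <- function() {
  tibble::tibble(
    low = c(850, 1010, 1410, 2840),
    high = c(910, 1130, 1510, 3010)
  )
}

check_intervals <- function(intervals) {
  stopifnot(is.data.frame(intervals), all(c("low", "high") %in% names(intervals)))
  if (any(intervals$low >= intervals$high)) {
    abort("Each interval needs low < high.",
          class = "ramanboost_invalid_argument")
  }
  o <- order(intervals$low)
  intervals <- intervals[o, ]
  if (nrow(intervals) > 1 &&
      any(intervals$low[-1] <= intervals$high[-nrow(intervals)])) {
    abort("Intervals must be non-overlapping.",
          class = "ramanboost_invalid_argument")
  }
  intervals
}

#' Subtract a water reference spectrum
#'
#' Pointwise subtraction of the water background from every spectrum in a
#' long spectra table. All spectra must share the reference's wavenumber
#' grid exactly.
#'
#' @param spectra Long spectra tibble (or a `raman_experiment`, whose
#'   spectra are then replaced).
#' @param water A reference tibble with `wavenumber` and `intensity`, e.g.
#'   from [water_reference()].
#'
#' @return The input with `intensity` replaced by the background-subtracted
#'   values; all metadata columns are preserved.
#' @export
subtract_water <- function(spectra, water) {
  if (inherits(spectra, "raman_experiment")) {
    spectra$spectra <- subtract_water(spectra$spectra, water)
    return(spectra)
  }
  stopifnot(is.data.frame(water), all(c("wavenumber", "intensity") %in%
                                        names(water)))
  idx <- match(spectra$wavenumber, water$wavenumber)
  if (anyNA(idx)) {
    abort("Spectrum wavenumbers are not all present in the water reference.",
          class = "ramanboost_grid_error")
  }
  n_per <- spectra |>
    dplyr::count(dplyr::pick(dplyr::any_of(c("sample_number", "replicate"))))
  if (any(n_per$n != nrow(water))) {
    abort("Spectra and water reference are on different grids.",
          class = "ramanboost_grid_error")
  }
  spectra$intensity <- spectra$intensity - water$intensity[idx]
  spectra
}

#' Interval derivative/integral features
#'
#' Reduces each spectrum to the features used for classification: within
#' every evaluation interval, either (default, `mode = "derivative"`) the
#' forward finite differences over each adjacent 1 cm-1 grid pair followed
#' by the trapezoidal integral of the interval, or
#' (`mode = "pointwise"`) the raw intensities at every grid point of the
#' interval. Both modes yield 454 features for the default ethanol
#' intervals: widths 60 + 120 + 100 + 170 = 450 differences plus 4
#' integrals, or 61 + 121 + 101 + 171 = 454 grid points.
#'
#' Feature order is fixed and documented: intervals in ascending wavenumber;
#' within an interval, derivatives in ascending wavenumber, then the
#' integral (derivative mode), or intensities in ascending wavenumber
#' (pointwise mode). Columns are named `f0001 ... f<d>`.
#'
#' @param spectra Long spectra tibble (or a `raman_experiment`). Must cover
#'   every interval at 1 cm-1 steps.
#' @param intervals Interval table, see [ethanol_intervals()].
#' @param mode `"derivative"` (differences + integral) or `"pointwise"`.
#'
#' @return A tibble with one row per spectrum: the provenance columns
#'   present in the input (`sample_number`, `replicate`, `concentration`)
#'   followed by the feature columns.
#' @export
extract_features <- function(spectra, intervals = ethanol_intervals(),
                             mode = c("derivative", "pointwise")) {
  mode <- match.arg(mode)
  if (inherits(spectra, "raman_experiment")) spectra <- spectra$spectra
  intervals <- check_intervals(intervals)
  id_cols <- intersect(c("sample_number", "replicate", "concentration"),
                       names(spectra))
  if (length(id_cols) == 0) {
    spectra <- dplyr::mutate(spectra, .spectrum = 1L)
    id_cols <- ".spectrum"
  }
  wide <- spectra |>
    dplyr::arrange(dplyr::pick(dplyr::all_of(c(id_cols, "wavenumber")))) |>
    tidyr::pivot_wider(id_cols = dplyr::all_of(id_cols),
                       names_from = "wavenumber",
                       values_from = "intensity")
  grid <- as.numeric(setdiff(names(wide), id_cols))
  mat <- as.matrix(wide[, setdiff(names(wide), id_cols)])
  feat_blocks <- vector("list", nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    pts <- seq(intervals$low[i], intervals$high[i], by = 1)
    cols <- match(pts, grid)
    if (anyNA(cols)) {
      abort(sprintf(
        "Interval %g-%g cm-1 is not covered by the spectrum grid at 1 cm-1 steps.",
        intervals$low[i], intervals$high[i]),
        class = "ramanboost_coverage_error")
    }
    block <- mat[, cols, drop = FALSE]
    if (mode == "derivative") {
      nd <- length(pts) - 1L
      deriv <- block[, -1L, drop = FALSE] - block[, -ncol(block), drop = FALSE]
      # trapezoid at unit step: sum of interior points + half the endpoints
      integral <- rowSums(block) - 0.5 * (block[, 1L] + block[, ncol(block)])
      feat_blocks[[i]] <- cbind(deriv, integral)
    } else {
      feat_blocks[[i]] <- block
    }
  }
  feats <- do.call(cbind, feat_blocks)
  colnames(feats) <- sprintf("f%04d", seq_len(ncol(feats)))
  if (!all(is.finite(feats))) {
    abort("Non-finite feature values produced.",
          class = "ramanboost_invalid_argument")
  }
  out <- dplyr::bind_cols(wide[, id_cols, drop = FALSE],
                          tibble::as_tibble(feats))
  if (id_cols[1] == ".spectrum") out$.spectrum <- NULL
  out
}

#' Feature column helper
#'
#' @param data A feature tibble.
#' @return Character vector of the `f####` feature column names.
#' @export
feature_cols <- function(data) {
  grep("^f[0-9]+$", names(data), value = TRUE)
}

#' Binary labels from a concentration threshold
#'
#' Adds a `label` column: `+1` where `concentration >= threshold`, else
#' `-1`. By default the threshold must coincide (within `tol`) with one of
#' the positive concentrations present in the data, mirroring thresholds
#' set at the dilution steps of the series; pass `strict = FALSE` to allow
#' arbitrary thresholds.
#'
#' @param data A tibble with a `concentration` column (Vol%).
#' @param threshold Concentration threshold, Vol%.
#' @param strict Require the threshold to match an observed positive
#'   concentration.
#' @param tol Matching tolerance for the strict check.
#'
#' @return `data` with an added numeric `label` column in \{-1, +1\}.
#' @export
make_binary_labels <- function(data, threshold, strict = TRUE, tol = 1e-9) {
  stopifnot(is.data.frame(data), "concentration" %in% names(data))
  if (strict) {
    candidates <- unique(data$concentration[data$concentration > 0])
    if (!any(abs(candidates - threshold) <= tol)) {
      abort(sprintf(
        "Threshold %g Vol%% does not match any positive concentration in the data; use strict = FALSE to override.",
        threshold), class = "ramanboost_invalid_threshold")
    }
  }
  dplyr::mutate(data,
                label = ifelse(.data$concentration >= threshold, 1, -1))
}

#' Partition a dataset into random stacks
#'
#' Randomly permutes the rows and cuts them into `k` contiguous, near-equal
#' stacks: the data batches consumed one at a time by incremental learning.
#'
#' @param data A tibble.
#' @param k Number of stacks (1 <= k <= nrow(data)).
#' @param seed Seed for the permutation.
#'
#' @return `data` in permuted order with an added integer `stack` column in
#'   `1:k`; stack sizes differ by at most one row.
#' @export
partition_stacks <- function(data, k, seed = 1) {
  n <- nrow(data)
  k <- as.integer(k)
  if (is.na(k) || k < 1 || k > n) {
    abort("`k` must satisfy 1 <= k <= nrow(data).",
          class = "ramanboost_invalid_argument")
  }
  perm <- withr::with_seed(make_seed(seed), sample.int(n))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  out <- data[perm, , drop = FALSE]
  out$stack <- rep(seq_len(k), times = sizes)
  out
}
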