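#' Nested cross-validation fold plan
#'
#' Outer loop: leave one complete measurement experiment out (an experiment
#' is one replicate index covering every solution). Inner loop: the
#' remaining points are dealt into `inner_k` folds stratified by solution,
#' so each solution's replicates land in distinct folds; used for
#' hyperparameter selection. Held-out points never receive an inner fold.
#'
#' @param manifest Tibble with `sample_number`, `replicate` and
#'   `concentration`, one row per spectrum; every replicate index must
#'   cover every solution (complete experiments), and at least two
#'   replicates are required.
#' @param inner_k Number of inner folds.
#' @param seed Seed for the inner assignments.
#'
#' @return A tibble with one row per (outer fold, spectrum):
#'   `outer_fold` (the held-out replicate), `sample_number`, `replicate`,
#'   `concentration`, `role` ("test" or "train") and `inner_fold`
#'   (`NA` for test rows).
#' @export
build_folds <- function(manifest, inner_k = 10, seed = 1) {
  stopifnot(all(c("sample_number", "replicate", "concentration") %in%
                  names(manifest)))
  reps <- sort(unique(manifest$replicate))
  samples <- sort(unique(manifest$sample_number))
  complete <- manifest |>
    dplyr::count(.data$replicate) |>
    dplyr::pull(.data$n)
  if (length(reps) < 2 || any(complete != length(samples)) ||
      nrow(manifest) != length(reps) * length(samples)) {
    abort("Manifest must hold >= 2 complete experiments (every replicate covering every solution once).",
          class = "ramanboost_manifest_error")
  }
  purrr::map(reps, function(r) {
    fold <- manifest[, c("sample_number", "replicate", "concentration")]
    fold$outer_fold <- r
    fold$role <- ifelse(fold$replicate == r, "test", "train")
    fold$inner_fold <- NA_integer_
    tr <- which(fold$role == "train")
    # stratify by solution: each solution's replicates spread over folds
    assign <- integer(length(tr))
    withr::with_seed(make_seed(seed, 11L, r), {
      for (s in samples) {
        si <- which(fold$sample_number[tr] == s)
        si <- sample(si)
        offset <- sample.int(inner_k, 1) - 1L
        assign[si] <- ((seq_along(si) - 1L + offset) %% inner_k) + 1L
      }
    })
    fold$inner_fold[tr] <- assign
    fold
  }) |>
    purrr::list_rbind() |>
    dplyr::select("outer_fold", "sample_number", "replicate",
                  "concentration", "role", "inner_fold")
}

#' Confusion-matrix metrics
#'
#' Counts true/false positives and negatives (+1 is the positive class)
#' and derives accuracy (percent), sensitivity (TPR = TP / (TP + FN)) and
#' precision (PPV = TP / (TP + FP)). Ratios with a zero denominator are
#' reported as `NA`, not 0.
#'
#' @param pred,truth Aligned label vectors in \{-1, +1\}.
#' @return A one-row tibble: `tp`, `tn`, `fp`, `fn`, `n`, `accuracy`
#'   (percent), `tpr`, `ppv`.
#' @export
compute_metrics <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) == 0) {
    abort("`pred` and `truth` must be non-empty and aligned.",
          class = "ramanboost_invalid_argument")
  }
  tp <- sum(pred == 1 & truth == 1)
  tn <- sum(pred == -1 & truth == -1)
  fp <- sum(pred == 1 & truth == -1)
  fn <- sum(pred == -1 & truth == 1)
  n <- length(pred)
  tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn, n = n,
    accuracy = 100 * (tp + tn) / n,
    tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_
  )
}

#' Run the full dilution-series benchmark
#'
#' The end-to-end pipeline: simulate (or accept) a dilution-series
#' experiment; for every outer fold, subtract the water reference built
#' from the training experiments only and extract interval features; for
#' every concentration threshold, binarize the labels, tune `C` and
#' `gamma` by Nelder-Mead on inner-CV AUC-ROC over the 90-point training
#' pool, split the pool into `k_stacks` random batches, feed them to the
#' incremental ensemble one at a time, and score the final vote on the
#' held-out experiment. Batches that end up single-class after the random
#' split cannot be trained on and are skipped (logged in the result).
#'
#' @param experiment A `raman_experiment` (from [simulate_experiment()] or
#'   assembled from measured data). `NULL` simulates the default
#'   ten-solution, ten-replicate series with `sim_config(seed = seed)`.
#' @param thresholds Concentration thresholds (Vol%); default: all
#'   positive concentrations of the plan, highest first.
#' @param k_stacks Number of incremental batches per training pool.
#' @param t_k Boosting iterations per batch.
#' @param inner_folds Inner CV folds for tuning.
#' @param vote_mode Final voting mode, see [final_predict()].
#' @param feature_mode Feature extraction mode, see [extract_features()].
#' @param intervals Evaluation intervals.
#' @param seed Master seed for simulation, folds, stack splits and
#'   subset draws.
#' @param verbose Print per-threshold progress.
#'
#' @return An object of class `raman_benchmark`: list with `metrics` (one
#'   row per threshold x outer fold: confusion counts, accuracy, `tpr`,
#'   `ppv`, `train_time_s`, `n_stacks_used`), `summary` (per-threshold
#'   means in descending concentration), and the call configuration.
#' @export
run_experiment <- function(experiment = NULL, thresholds = NULL,
                           k_stacks = 10, t_k = 5, inner_folds = 10,
                           vote_mode = c("eq9_literal", "base_vote"),
                           feature_mode = c("derivative", "pointwise"),
                           intervals = ethanol_intervals(),
                           seed = 1, verbose = FALSE) {
  vote_mode <- match.arg(vote_mode)
  feature_mode <- match.arg(feature_mode)
  if (is.null(experiment)) {
    experiment <- simulate_experiment(dilution_series(),
                                      sim_config(seed = make_seed(seed)))
  }
  stopifnot(inherits(experiment, "raman_experiment"))
  manifest <- experiment$manifest
  if (is.null(thresholds)) {
    thresholds <- sort(unique(manifest$concentration[
      manifest$concentration > 0]), decreasing = TRUE)
  }
  folds <- build_folds(manifest, inner_k = inner_folds, seed = seed)
  outer_ids <- sort(unique(folds$outer_fold))
  rows <- list()
  for (r in outer_ids) {
    fold <- dplyr::filter(folds, .data$outer_fold == r)
    train_reps <- unique(fold$replicate[fold$role == "train"])
    wref <- water_reference(experiment$spectra, replicates = train_reps)
    feats <- experiment$spectra |>
      subtract_water(wref) |>
      extract_features(intervals = intervals, mode = feature_mode)
    feats <- dplyr::inner_join(
      feats, fold[, c("sample_number", "replicate", "role", "inner_fold")],
      by = c("sample_number", "replicate"))
    for (th_i in seq_along(thresholds)) {
      th <- thresholds[th_i]
      t0 <- proc.time()[["elapsed"]]
      labeled <- make_binary_labels(feats, th)
      pool <- dplyr::filter(labeled, .data$role == "train")
      test <- dplyr::filter(labeled, .data$role == "test")
      stopifnot(length(intersect(
        paste(pool$sample_number, pool$replicate),
        paste(test$sample_number, test$replicate))) == 0)
      params <- tune_svm(pool, folds = pool$inner_fold,
                         seed = make_seed(seed, r, th_i))
      stacks <- partition_stacks(pool, k_stacks,
                                 seed = make_seed(seed, 100L + r, th_i))
      ens <- new_ensemble(t_k = t_k)
      used <- 0L
      for (s in seq_len(k_stacks)) {
        batch <- dplyr::filter(stacks, .data$stack == s)
        if (length(unique(batch$label)) < 2) next
        ens_new <- tryCatch(
          learn_increment(ens, batch, params = params,
                          seed = make_seed(seed, r * 100L + th_i, s),
                          on_gate_failure = "truncate"),
          ramanboost_increment_failure = function(e) NULL)
        if (is.null(ens_new)) next   # batch unusable: no hypothesis passed
        ens <- ens_new
        used <- used + 1L
      }
      if (used == 0L) {
        abort(sprintf(
          "Threshold %g, fold %d: every stack was single-class; increase stack sizes.",
          th, r), class = "ramanboost_degenerate_data")
      }
      pred <- final_predict(ens, test, mode = vote_mode)
      m <- compute_metrics(pred, test$label)
      m$threshold <- th
      m$fold <- r
      m$train_time_s <- proc.time()[["elapsed"]] - t0
      m$n_stacks_used <- used
      rows <- c(rows, list(m))
      if (verbose) {
        message(sprintf(
          "fold %d, threshold %.7g Vol%%: accuracy %.1f%% (%d stacks, %.1fs)",
          r, th, m$accuracy, used, m$train_time_s))
      }
    }
  }
  metrics <- purrr::list_rbind(rows) |>
    dplyr::select("threshold", "fold", "tp", "tn", "fp", "fn", "n",
                  "accuracy", "ppv", "tpr", "train_time_s", "n_stacks_used")
  summary <- metrics |>
    dplyr::group_by(.data$threshold) |>
    dplyr::summarise(
      accuracy = mean(.data$accuracy),
      ppv = mean(.data$ppv, na.rm = TRUE),
      tpr = mean(.data$tpr, na.rm = TRUE),
      train_time_s = sum(.data$train_time_s),
      folds = dplyr::n(),
      .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$threshold))
  structure(
    list(metrics = metrics, summary = summary,
         config = list(thresholds = thresholds, k_stacks = k_stacks,
                       t_k = t_k, inner_folds = inner_folds,
                       vote_mode = vote_mode, feature_mode = feature_mode,
                       seed = seed)),
    class = "raman_benchmark"
  )
}

#' @export
print.raman_benchmark <- function(x, ...) {
  cat("<raman_benchmark> per-threshold means over",
      max(x$metrics$fold), "leave-one-experiment-out folds\n")
  s <- x$summary
  cat(sprintf("%12s %9s %6s %6s %9s\n",
              "conc (Vol%)", "acc (%)", "PPV", "TPR", "time (s)"))
  for (i in seq_len(nrow(s))) {
    cat(sprintf("%12.7f %9.1f %6.2f %6.2f %9.1f\n",
                s$threshold[i], s$accuracy[i], s$ppv[i], s$tpr[i],
                s$train_time_s[i]))
  }
  invisible(x)
}

#' @export
tidy.raman_benchmark <- function(x, ...) {
  x$metrics
}

#' @export
glance.raman_benchmark <- function(x, ...) {
  tibble::tibble(n_thresholds = nrow(x$summary),
                 n_folds = length(unique(x$metrics$fold)),
                 mean_accuracy = mean(x$summary$accuracy),
                 min_accuracy = min(x$summary$accuracy))
}

#' Summarize a benchmark and export its accuracy curve
#'
#' Prints the per-threshold summary (accuracy to one decimal, precision
#' and sensitivity to two, as in standard concentration-monitoring
#' reports) and returns the accuracy-versus-concentration series. With
#' `out_dir` set, writes `metrics.csv`, `summary.csv` and
#' `accuracy_curve.csv`.
#'
#' @param benchmark A `raman_benchmark`.
#' @param out_dir Optional output directory.
#' @return Invisibly, a tibble with `concentration` and `accuracy`.
#' @export
report_benchmark <- function(benchmark, out_dir = NULL) {
  stopifnot(inherits(benchmark, "raman_benchmark"))
  print(benchmark)
  curve <- benchmark$summary |>
    dplyr::transmute(concentration = .data$threshold,
                     accuracy = .data$accuracy)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(benchmark$metrics, file.path(out_dir, "metrics.csv"))
    readr::write_csv(benchmark$summary, file.path(out_dir, "summary.csv"))
    readr::write_csv(curve, file.path(out_dir, "accuracy_curve.csv"))
  }
  invisible(curve)
}
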