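#' Initialize uniform sample weights
#'
#' Starting weights for a new data batch: uniform, carrying no prior
#' information about which points are hard.
#'
#' @param n Number of points in the batch (>= 1).
#' @return An object of class `sample_weights`: list with `alpha`
#'   (non-negative raw weights) and `d` (normalized distribution).
#' @export
init_weights <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1) {
    abort("`n` must be an integer >= 1.",
          class = "ramanboost_invalid_argument")
  }
  structure(list(alpha = rep(1, n), d = rep(1 / n, n)),
            class = "sample_weights")
}

#' Renormalize sample weights into a distribution
#'
#' @param weights A `sample_weights` object with at least one positive
#'   `alpha`.
#' @return The object with `d = alpha / sum(alpha)`.
#' @export
normalize_distribution <- function(weights) {
  stopifnot(inherits(weights, "sample_weights"))
  s <- sum(weights$alpha)
  if (!is.finite(s) || s <= 0 || any(weights$alpha < 0)) {
    abort("Weights are degenerate: need non-negative alpha with positive sum.",
          class = "ramanboost_degenerate_weights")
  }
  weights$d <- weights$alpha / s
  weights
}

#' Draw training and test subsets according to a distribution
#'
#' Samples `ceiling(train_frac * n)` row indices without replacement with
#' selection probability proportional to `d` (sequential weighted draws);
#' the remaining rows form the test subset. Draws are retried (fresh seed
#' substream) until the training subset holds both classes, up to
#' `max_retries` attempts.
#'
#' @param data Labeled tibble (both classes present).
#' @param d Normalized sampling distribution over the rows.
#' @param train_frac Fraction of rows assigned to training; the test subset
#'   is never empty.
#' @param seed Seed; identical seeds give identical splits.
#' @param max_retries Redraw budget for the two-class requirement.
#' @return List with `train`, `test` (tibbles), `train_idx` and
#'   `retries`.
#' @export
draw_train_test <- function(data, d, train_frac = 2 / 3, seed = 1,
                            max_retries = 10) {
  n <- nrow(data)
  stopifnot(length(d) == n, n >= 2)
  if (length(unique(data$label)) < 2) {
    abort("Batch holds a single class; cannot draw a two-class subset.",
          class = "ramanboost_degenerate_data")
  }
  n_train <- min(max(ceiling(train_frac * n), 1L), n - 1L)
  for (retry in 0:max_retries) {
    idx <- withr::with_seed(make_seed(seed, 7L, retry),
                            sample.int(n, n_train, prob = d))
    if (length(unique(data$label[idx])) == 2) {
      return(list(train = data[idx, , drop = FALSE],
                  test = data[-idx, , drop = FALSE],
                  train_idx = idx, retries = retry))
    }
  }
  abort(sprintf(
    "Could not draw a two-class training subset in %d attempts.",
    max_retries + 1), class = "ramanboost_sampling_failure")
}

#' Distribution-weighted misclassification of a hypothesis
#'
#' The error mass `sum(d[i] : pred[i] != truth[i])` of a classifier under
#' the current sampling distribution, evaluated over the whole batch.
#'
#' @param pred,truth Label vectors in \{-1, +1\}.
#' @param d Normalized distribution aligned with the labels.
#' @return Error in [0, 1].
#' @export
hypothesis_error <- function(pred, truth, d) {
  stopifnot(length(pred) == length(truth), length(d) == length(truth))
  sum(d[pred != truth])
}

#' Normalized error
#'
#' Maps a weighted error `e < 0.5` to `beta = e / (1 - e)`, the quantity
#' whose negative log is the hypothesis's voting weight. The result is
#' clamped to `[beta_min, 1 - 1e-12]` so a perfect hypothesis still casts a
#' finite (large) vote. An error of 0.5 or more signals that the hypothesis
#' must be discarded and redrawn.
#'
#' @param epsilon Weighted error in [0, 1].
#' @param beta_min Lower clamp.
#' @return `beta` in (0, 1).
#' @export
normalized_error <- function(epsilon, beta_min = 1e-10) {
  if (!is.finite(epsilon) || epsilon < 0) {
    abort("`epsilon` must be a finite non-negative error.",
          class = "ramanboost_invalid_argument")
  }
  if (epsilon >= 0.5) {
    abort(sprintf("Error %.3f >= 0.5: hypothesis must be discarded.", epsilon),
          class = "ramanboost_reject_hypothesis")
  }
  min(max(epsilon / (1 - epsilon), beta_min), 1 - 1e-12)
}

#' Weighted majority vote
#'
#' @param pred A length-m vector or n-by-m matrix of \{-1, +1\} votes (one
#'   column per voter).
#' @param weights Non-negative voting weights, length m.
#' @return Vector of voted labels; ties go to +1.
#' @export
weighted_vote <- function(pred, weights) {
  if (is.null(dim(pred))) pred <- matrix(pred, nrow = 1)
  stopifnot(ncol(pred) == length(weights))
  score <- as.numeric(pred %*% weights)
  ifelse(score >= 0, 1, -1)
}

#' Composite prediction of the hypotheses accepted so far in a batch
#'
#' Weighted majority vote of the base hypotheses, each voting with weight
#' `log(1 / beta)`.
#'
#' @param records List of iteration records, each with elements `model`
#'   (a `csvm`) and `beta`.
#' @param newdata Feature tibble or matrix.
#' @return Vector of voted labels in \{-1, +1\}; ties go to +1.
#' @export
composite_predict <- function(records, newdata) {
  if (length(records) == 0) {
    abort("Need at least one accepted hypothesis.",
          class = "ramanboost_empty_ensemble")
  }
  preds <- vapply(records, function(r) predict(r$model, newdata)$.pred,
                  numeric(nrow(newdata)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  weights <- vapply(records, function(r) log(1 / r$beta), numeric(1))
  weighted_vote(preds, weights)
}

#' Error of the composite hypothesis
#'
#' Distribution-weighted misclassification of the composite vote on the
#' current batch, and its normalized form `B = E / (1 - E)`. A composite
#' error of 0.5 or more raises a discard signal (condition class
#' `ramanboost_reject_composite`): the caller drops the newest hypothesis
#' and redraws.
#'
#' @param records Iteration records of the current batch.
#' @param data Labeled batch tibble.
#' @param d Normalized distribution over the batch.
#' @param beta_min Lower clamp for `B`.
#' @return List with `E`, `B` and the composite predictions `pred`.
#' @export
composite_error <- function(records, data, d, beta_min = 1e-10) {
  pred <- composite_predict(records, data)
  E <- hypothesis_error(pred, data$label, d)
  if (E >= 0.5) {
    abort(sprintf("Composite error %.3f >= 0.5: discard and redraw.", E),
          class = "ramanboost_reject_composite")
  }
  B <- min(max(E / (1 - E), beta_min), 1 - 1e-12)
  list(E = E, B = B, pred = pred)
}

#' Focus the sampling weights on points the composite got wrong
#'
#' Multiplies the weight of every correctly classified point by `B < 1`,
#' leaving misclassified points untouched, then renormalizes: hard points
#' gain relative sampling mass for the next iteration.
#'
#' @param weights A `sample_weights` object.
#' @param correct Logical vector: did the composite classify each point
#'   correctly?
#' @param B Composite normalized error in (0, 1).
#' @return Updated, renormalized `sample_weights`.
#' @export
update_weights <- function(weights, correct, B) {
  stopifnot(inherits(weights, "sample_weights"),
            length(correct) == length(weights$alpha),
            is.finite(B), B > 0, B <= 1)
  weights$alpha <- weights$alpha * ifelse(correct, B, 1)
  normalize_distribution(weights)
}

#' Create an empty incremental ensemble
#'
#' @param t_k Default boosting iterations per incoming batch.
#' @param train_frac Training fraction for within-batch subset draws.
#' @param max_retries Redraw budget at each acceptance gate.
#' @param beta_min Lower clamp for normalized errors.
#' @return An object of class `incremental_ensemble` with no records.
#' @export
new_ensemble <- function(t_k = 5, train_frac = 2 / 3, max_retries = 10,
                         beta_min = 1e-10) {
  structure(
    list(records = list(), n_datasets = 0L, cols = NULL,
         config = list(t_k = t_k, train_frac = train_frac,
                       max_retries = max_retries, beta_min = beta_min),
         version = "1.0"),
    class = "incremental_ensemble"
  )
}

#' Learn one incoming data batch
#'
#' Extends the ensemble with up to `t_k` boosted hypotheses trained on the
#' new batch alone. Per iteration: the weight distribution is normalized;
#' training/test subsets are drawn according to it; a C-SVM is fitted on
#' the training subset; its weighted error over the whole batch must be
#' below 0.5 (else it is discarded and the draw repeated); the composite
#' vote of this batch's accepted hypotheses must also err below 0.5 (else
#' the newest hypothesis is discarded and the draw repeated); finally the
#' weights of correctly composite-classified points are shrunk by the
#' composite normalized error `B`, focusing subsequent draws on hard
#' points.
#'
#' Earlier batches are never touched: the ensemble state holds fitted
#' hypotheses and their errors only, so previously stored records are
#' preserved verbatim and no access to earlier data is needed or possible.
#'
#' @param ensemble An `incremental_ensemble`.
#' @param data Labeled feature tibble for the new batch (both classes).
#' @param t_k Boosting iterations for this batch; defaults to the
#'   ensemble's configured value.
#' @param params SVM hyperparameters as a list with `C` and `gamma` (e.g. a
#'   tuning result). If `NULL`, [tune_svm()] runs once on this batch before
#'   boosting starts.
#' @param seed Seed for this batch's subset draws.
#' @param tune_each_iteration Retune on every boosting iteration's training
#'   subset instead of once per batch (slower; needs each subset to support
#'   stratified inner folds).
#' @param on_gate_failure What to do when no hypothesis passes the error
#'   gates within the retry budget: `"error"` (default) raises an
#'   increment-failure error naming the batch and iteration;
#'   `"truncate"` stops boosting the batch early and keeps the hypotheses
#'   accepted so far (useful on batches near the noise floor, where a
#'   lone hard point can absorb half the weight mass and make the gate
#'   unattainable).
#' @param ... Passed to [tune_svm()] when tuning happens here.
#'
#' @return The extended ensemble; `records` grows by up to `t_k` entries,
#'   each holding the fitted model, `epsilon`, `beta`, `E`, `B`, the batch
#'   index `k`, iteration `t` and `retries` used.
#' @export
learn_increment <- function(ensemble, data, t_k = NULL, params = NULL,
                            seed = 1, tune_each_iteration = FALSE,
                            on_gate_failure = c("error", "truncate"), ...) {
  stopifnot(inherits(ensemble, "incremental_ensemble"))
  on_gate_failure <- match.arg(on_gate_failure)
  t_k <- t_k %||% ensemble$config$t_k
  if (t_k < 1) {
    abort("`t_k` must be >= 1.", class = "ramanboost_invalid_argument")
  }
  if (length(unique(data$label)) < 2) {
    abort("New batch holds a single class; nothing can be learned from it.",
          class = "ramanboost_degenerate_data")
  }
  cols <- ensemble$cols %||% feature_cols(data)
  if (!all(cols %in% names(data))) {
    abort("Batch feature columns do not match the ensemble's.",
          class = "ramanboost_invalid_argument")
  }
  cfg <- ensemble$config
  k <- ensemble$n_datasets + 1L
  if (is.null(params) && !tune_each_iteration) {
    params <- tune_svm(data, seed = make_seed(seed, k, 0L), cols = cols, ...)
  }
  w <- init_weights(nrow(data))
  batch_records <- list()
  batch_preds <- list()   # cached base predictions on this batch
  for (t in seq_len(t_k)) {
    accepted <- FALSE
    for (retry in 0:cfg$max_retries) {
      w <- normalize_distribution(w)
      split <- draw_train_test(data, w$d, train_frac = cfg$train_frac,
                               seed = make_seed(seed, k * 1000L + t, retry),
                               max_retries = cfg$max_retries)
      p <- params
      if (tune_each_iteration) {
        p <- tryCatch(
          tune_svm(split$train,
                   seed = make_seed(seed, k * 1000L + t, 500L + retry),
                   cols = cols, ...),
          error = function(e) params)
        if (is.null(p)) next
      }
      h <- tryCatch(svm_fit(split$train, C = p$C, gamma = p$gamma,
                            cols = cols),
                    error = function(e) NULL)
      if (is.null(h)) next
      pred_h <- predict(h, data)$.pred
      eps <- hypothesis_error(pred_h, data$label, w$d)
      if (eps >= 0.5) next
      beta <- min(max(eps / (1 - eps), cfg$beta_min), 1 - 1e-12)
      cand <- c(batch_records,
                list(list(model = h, beta = beta)))
      cand_preds <- c(batch_preds, list(pred_h))
      votes <- weighted_vote(
        do.call(cbind, cand_preds),
        vapply(cand, function(r) log(1 / r$beta), numeric(1)))
      E <- hypothesis_error(votes, data$label, w$d)
      if (E >= 0.5) next
      B <- min(max(E / (1 - E), cfg$beta_min), 1 - 1e-12)
      w <- update_weights(w, votes == data$label, B)
      rec <- list(model = h, epsilon = eps, beta = beta, E = E, B = B,
                  k = k, t = t, retries = retry,
                  params = list(C = p$C, gamma = p$gamma))
      batch_records <- c(batch_records, list(rec))
      batch_preds <- c(batch_preds, list(pred_h))
      accepted <- TRUE
      break
    }
    if (!accepted) {
      if (on_gate_failure == "truncate" && length(batch_records) > 0) break
      abort(sprintf(
        "Batch %d, iteration %d: no hypothesis passed the error gates in %d draws.",
        k, t, cfg$max_retries + 1),
        class = "ramanboost_increment_failure")
    }
  }
  ensemble$records <- c(ensemble$records, batch_records)
  ensemble$n_datasets <- k
  ensemble$cols <- cols
  ensemble
}

#' Final ensemble prediction
#'
#' Combines everything learned across batches by weighted majority vote.
#' In the default `"eq9_literal"` mode, each accepted iteration's composite
#' hypothesis (the within-batch vote of that batch's hypotheses up to that
#' iteration) casts a vote weighted by `log(1 / B)`. In `"base_vote"` mode
#' the base hypotheses themselves vote with `log(1 / beta)` across all
#' batches, the convention of classic incremental-boosting ensembles. The
#' two modes coincide for a single-hypothesis ensemble; both are exposed
#' because either reading is defensible. Ties go to +1.
#'
#' @param ensemble A trained `incremental_ensemble`.
#' @param newdata Feature tibble or matrix.
#' @param mode `"eq9_literal"` or `"base_vote"`.
#' @return Vector of predicted labels in \{-1, +1\}.
#' @export
final_predict <- function(ensemble, newdata,
                          mode = c("eq9_literal", "base_vote")) {
  mode <- match.arg(mode)
  recs <- ensemble$records
  if (length(recs) == 0) {
    abort("The ensemble has no trained hypotheses.",
          class = "ramanboost_empty_ensemble")
  }
  n <- if (is.matrix(newdata)) nrow(newdata) else nrow(newdata)
  base <- vapply(recs, function(r) predict(r$model, newdata)$.pred,
                 numeric(n))
  if (is.null(dim(base))) base <- matrix(base, nrow = 1)
  if (mode == "base_vote") {
    return(weighted_vote(
      base, vapply(recs, function(r) log(1 / r$beta), numeric(1))))
  }
  ks <- vapply(recs, function(r) r$k, numeric(1))
  betas <- vapply(recs, function(r) log(1 / r$beta), numeric(1))
  composites <- vapply(seq_along(recs), function(i) {
    members <- which(ks == ks[i] &
                       vapply(recs, function(r) r$t, numeric(1)) <=
                         recs[[i]]$t)
    weighted_vote(base[, members, drop = FALSE], betas[members])
  }, numeric(nrow(base)))
  if (is.null(dim(composites))) composites <- matrix(composites, nrow = 1)
  weighted_vote(composites,
                vapply(recs, function(r) log(1 / r$B), numeric(1)))
}

#' @export
predict.incremental_ensemble <- function(object, newdata,
                                         mode = c("eq9_literal",
                                                  "base_vote"), ...) {
  tibble::tibble(.pred = final_predict(object, newdata, mode = mode))
}

#' @export
print.incremental_ensemble <- function(x, ...) {
  cat(sprintf(
    "<incremental_ensemble> %d hypotheses across %d data batches\n",
    length(x$records), x$n_datasets))
  if (length(x$records) > 0) print(tidy(x), n = 5)
  invisible(x)
}

#' Per-iteration summary of an incremental ensemble
#'
#' @param x An `incremental_ensemble`.
#' @param ... Unused.
#' @return A tibble with one row per accepted hypothesis: batch `k`,
#'   iteration `t`, `epsilon`, `beta`, composite error `E`, `B`, draw
#'   `retries` and the hyperparameters used.
#' @export
tidy.incremental_ensemble <- function(x, ...) {
  purrr::map(x$records, function(r) {
    tibble::tibble(k = r$k, t = r$t, epsilon = r$epsilon, beta = r$beta,
                   E = r$E, B = r$B, retries = r$retries,
                   C = r$params$C, gamma = r$params$gamma,
                   train_accuracy = r$model$train_accuracy)
  }) |>
    purrr::list_rbind()
}

#' @export
glance.incremental_ensemble <- function(x, ...) {
  tibble::tibble(n_hypotheses = length(x$records),
                 n_datasets = x$n_datasets,
                 n_features = length(x$cols %||% character()))
}

#' Persist / restore an ensemble
#'
#' The archive is an RDS serialization of the ensemble state (versioned),
#' so a stored ensemble can be reloaded and extended with further batches
#' via [learn_increment()] -- the append-only incremental contract.
#'
#' @param ensemble An `incremental_ensemble`.
#' @param path File path.
#' @return `write_ensemble` returns `path` invisibly; `read_ensemble`
#'   returns the ensemble.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "incremental_ensemble"))
  saveRDS(ensemble, path)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "incremental_ensemble")) {
    abort("File does not hold an incremental ensemble archive.",
          class = "ramanboost_invalid_argument")
  }
  x
}
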