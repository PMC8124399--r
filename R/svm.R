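#' Gaussian radial basis kernel
#'
#' `K(x, y) = exp(-gamma * ||x - y||^2)` with `gamma = 1 / (2 sigma^2)`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param gamma Positive kernel width parameter.
#' @return Kernel value in (0, 1].
#' @export
rbf_kernel <- function(x, y, gamma) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have the same dimension.",
          class = "ramanboost_invalid_argument")
  }
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0) {
    abort("`gamma` must be a single positive number.",
          class = "ramanboost_invalid_argument")
  }
  exp(-gamma * sum((x - y)^2))
}

as_feature_matrix <- function(data, cols) {
  if (is.matrix(data)) return(data[, cols, drop = FALSE])
  as.matrix(data[, cols, drop = FALSE])
}

#' Fit a soft-margin C-SVM base classifier
#'
#' Trains a two-class support vector machine with RBF kernel
#' `exp(-gamma ||xi - xj||^2)` by solving the soft-margin dual (the
#' quadratic program is delegated to libsvm via \pkg{e1071}; features are
#' standardized internally by the backend). The fitted hypothesis exposes
#' both hard \{-1, +1\} predictions and the continuous decision score
#' `f(x)`, oriented so positive scores vote for class `+1`.
#'
#' A hypothesis that classifies less than half of its own training data
#' correctly is rejected with an error: worse-than-chance base learners are
#' useless to the ensemble.
#'
#' By default the margin penalty is class-weighted by inverse class
#' frequency (`C_j = C * n / (2 n_j)`). Boosted subset draws at extreme
#' concentration thresholds are strongly imbalanced (often a single
#' minority point), and an unweighted margin happily sacrifices that point,
#' which stalls the ensemble's weighted-error gate at exactly 0.5; inverse
#' weighting restores the weak-learning property without touching the
#' tuned `C`. Set `class_weights = NULL` for the unweighted primal.
#'
#' @param data Tibble with `f####` feature columns and a `label` column in
#'   \{-1, +1\} (both classes present).
#' @param C Regularization weight, > 0 (penalty on margin violations).
#' @param gamma RBF kernel parameter, > 0.
#' @param cols Feature columns; defaults to all `f####` columns.
#' @param class_weights `"inverse"` (default) or `NULL`, passed to the
#'   backend.
#'
#' @return An object of class `csvm` with elements `model`, `C`, `gamma`,
#'   `cols`, `n` and `train_accuracy`.
#' @export
svm_fit <- function(data, C, gamma, cols = feature_cols(data),
                    class_weights = "inverse") {
  if (!is.numeric(C) || C <= 0 || !is.numeric(gamma) || gamma <= 0) {
    abort("`C` and `gamma` must be positive.",
          class = "ramanboost_invalid_argument")
  }
  y <- data$label
  if (length(unique(y)) < 2) {
    abort("Training data holds a single class; cannot fit a separator.",
          class = "ramanboost_degenerate_data")
  }
  X <- as_feature_matrix(data, cols)
  if (!all(is.finite(X))) {
    abort("Non-finite feature values.", class = "ramanboost_invalid_argument")
  }
  yf <- factor(y, levels = c(-1, 1))
  scale_ok <- apply(X, 2, sd) > 0
  args <- list(x = X, y = yf, type = "C-classification", kernel = "radial",
               cost = C, gamma = gamma, scale = scale_ok)
  if (!is.null(class_weights)) args$class.weights <- class_weights
  model <- do.call(e1071::svm, args)
  fit <- structure(
    list(model = model, C = C, gamma = gamma, cols = cols, n = nrow(X),
         train_accuracy = NA_real_),
    class = "csvm"
  )
  pred <- predict(fit, X)
  fit$train_accuracy <- mean(pred$.pred == y)
  if (fit$train_accuracy < 0.5) {
    abort(sprintf(
      "Hypothesis rejected: training accuracy %.3f is below 0.5.",
      fit$train_accuracy), class = "ramanboost_weak_hypothesis")
  }
  fit
}

#' Predict with a fitted base classifier
#'
#' @param object A `csvm` fit.
#' @param newdata Tibble with the fit's feature columns, or a matrix.
#' @param ... Unused.
#' @return A tibble with `.score` (signed decision value, positive for
#'   class +1) and `.pred` (label in \{-1, +1\}; a zero score maps to +1).
#' @export
predict.csvm <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata, object$cols)
  p <- predict(object$model, X, decision.values = TRUE)
  dv <- attr(p, "decision.values")
  # libsvm labels the score column "<first>/<second>"; positive raw scores
  # vote for <first>. Orient so positive always means class +1.
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  score <- as.numeric(dv[, 1]) * if (first == "1") 1 else -1
  tibble::tibble(.score = score, .pred = ifelse(score >= 0, 1, -1))
}

#' @export
print.csvm <- function(x, ...) {
  cat(sprintf(
    "<csvm> RBF C-SVM: C = %.4g, gamma = %.4g, n = %d, train accuracy = %.3f\n",
    x$C, x$gamma, x$n, x$train_accuracy))
  invisible(x)
}

#' @export
glance.csvm <- function(x, ...) {
  tibble::tibble(C = x$C, gamma = x$gamma, n = x$n,
                 n_support = nrow(x$model$SV),
                 train_accuracy = x$train_accuracy)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the fraction of (positive, negative)
#' pairs in which the positive scores higher, ties counting one half.
#'
#' @param scores Numeric decision scores, higher meaning more positive.
#' @param labels Labels in \{-1, +1\}; both classes must be present.
#' @return AUC in [0, 1].
#' @export
auc_roc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == 1
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    abort("AUC is undefined with a single class.",
          class = "ramanboost_undefined_auc")
  }
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Nelder-Mead simplex minimizer (plug point)
#'
#' Thin wrapper over `stats::optim(method = "Nelder-Mead")` used for
#' hyperparameter search; exposed so the optimizer can be exercised on
#' closed-form test functions independently of any SVM.
#'
#' @param fn Objective `function(par) -> scalar`.
#' @param start Numeric starting point.
#' @param max_evals Maximum objective evaluations.
#' @param reltol Relative convergence tolerance on the objective.
#' @return The `stats::optim` result list (`par`, `value`, `counts`, ...).
#' @export
simplex_minimize <- function(fn, start, max_evals = 60, reltol = 1e-3) {
  optim(start, fn, method = "Nelder-Mead",
        control = list(maxit = max_evals, reltol = reltol))
}

# Stratified k-fold assignment: per class, shuffled members are dealt round
# robin over folds starting at a random offset. Returns integer fold ids.
stratified_folds <- function(labels, k, seed = 1) {
  fold <- integer(length(labels))
  withr::with_seed(make_seed(seed), {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      offset <- sample.int(k, 1) - 1L
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    }
  })
  fold
}

#' Tune C and gamma by Nelder-Mead search on cross-validated AUC-ROC
#'
#' Runs a Nelder-Mead simplex over `(log10 C, log10 gamma)` minimizing the
#' negative mean AUC-ROC across stratified inner folds. Fold assignment is
#' fixed up front from the seed, so every objective evaluation sees the
#' same folds and the search is deterministic. Parameters are clamped to
#' the search box; inner validation folds that end up single-class (only
#' possible when a class has fewer members than folds) are dropped from the
#' mean, and evaluations in which no fold is usable score worst-case.
#'
#' The default start sits at `C = 100`, `gamma = 1e-3`. On cleanly
#' separable thresholds the AUC surface is flat at 1.0 and Nelder-Mead
#' terminates at its starting point, so the start doubles as the
#' flat-regime default; a hard-margin `C` there keeps strongly imbalanced
#' training draws from collapsing onto the majority class (AUC, a ranking
#' criterion, cannot distinguish such solutions).
#'
#' @param data Labeled feature tibble (both classes present).
#' @param inner_folds Number of inner CV folds (default 10). Effective
#'   folds never exceed the minority class count.
#' @param folds Optional explicit per-row fold ids, overriding the
#'   stratified assignment.
#' @param start Starting point `(log10 C, log10 gamma)`.
#' @param box Search box: list with `logC` and `loggamma` ranges.
#' @param max_evals Objective evaluation budget.
#' @param reltol Convergence tolerance on the objective.
#' @param seed Seed for the fold assignment.
#' @param cols Feature columns.
#'
#' @return An object of class `svm_tuning`: list with `C`, `gamma`, `auc`
#'   (inner-CV mean at the optimum), `par`, `evals` and `convergence`.
#' @export
tune_svm <- function(data, inner_folds = 10, folds = NULL,
                     start = c(2, -3),
                     box = list(logC = c(-2, 4), loggamma = c(-6, 1)),
                     max_evals = 60, reltol = 1e-3, seed = 1,
                     cols = feature_cols(data)) {
  y <- data$label
  n_min <- min(table(y))
  if (length(unique(y)) < 2 || n_min < 2) {
    abort("Tuning needs both classes with at least two members each.",
          class = "ramanboost_degenerate_data")
  }
  if (is.null(folds)) {
    k <- min(inner_folds, n_min)
    folds <- stratified_folds(y, k, seed = seed)
  }
  X <- as_feature_matrix(data, cols)
  fold_ids <- sort(unique(folds))
  objective <- function(par) {
    logC <- min(max(par[1], box$logC[1]), box$logC[2])
    logg <- min(max(par[2], box$loggamma[1]), box$loggamma[2])
    aucs <- purrr::map_dbl(fold_ids, function(f) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) {
        return(NA_real_)
      }
      tryCatch({
        d_tr <- tibble::as_tibble(as.data.frame(X[tr, , drop = FALSE]))
        d_tr$label <- y[tr]
        fit <- svm_fit(d_tr, C = 10^logC, gamma = 10^logg,
                       cols = colnames(X))
        sc <- predict(fit, X[!tr, , drop = FALSE])$.score
        auc_roc(sc, y[!tr])
      }, error = function(e) NA_real_)
    })
    if (all(is.na(aucs))) return(1)   # worse than any -AUC
    -mean(aucs, na.rm = TRUE)
  }
  res <- simplex_minimize(objective, start, max_evals = max_evals,
                          reltol = reltol)
  if (res$value >= 1) {
    abort("Hyperparameter tuning failed: no objective evaluation succeeded.",
          class = "ramanboost_tuning_failure")
  }
  par <- c(min(max(res$par[1], box$logC[1]), box$logC[2]),
           min(max(res$par[2], box$loggamma[1]), box$loggamma[2]))
  structure(
    list(C = 10^par[1], gamma = 10^par[2], auc = -res$value, par = par,
         evals = res$counts[["function"]], convergence = res$convergence),
    class = "svm_tuning"
  )
}

#' @export
print.svm_tuning <- function(x, ...) {
  cat(sprintf(
    "<svm_tuning> C = %.4g, gamma = %.4g (inner-CV AUC %.4f, %d evaluations)\n",
    x$C, x$gamma, x$auc, x$evals))
  invisible(x)
}

#' @export
tidy.svm_tuning <- function(x, ...) {
  tibble::tibble(parameter = c("C", "gamma"),
                 estimate = c(x$C, x$gamma),
                 log10 = x$par)
}

#' @export
glance.svm_tuning <- function(x, ...) {
  tibble::tibble(C = x$C, gamma = x$gamma, auc = x$auc, evals = x$evals,
                 convergence = x$convergence)
}
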