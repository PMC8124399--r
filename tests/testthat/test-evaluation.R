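test_that("fold plans hold out whole experiments without leakage", {
  plan <- dilution_series()
  manifest <- tidyr::expand_grid(plan[, c("sample_number", "concentration")],
                                 replicate = 1:10)
  folds <- build_folds(manifest, inner_k = 10, seed = 2)
  expect_equal(sort(unique(folds$outer_fold)), 1:10)
  for (r in c(1, 5, 10)) {
    f <- dplyr::filter(folds, outer_fold == r)
    expect_equal(sum(f$role == "test"), 10)
    expect_equal(sum(f$role == "train"), 90)
    expect_true(all(f$replicate[f$role == "test"] == r))
    expect_true(all(is.na(f$inner_fold[f$role == "test"])))
    expect_true(all(!is.na(f$inner_fold[f$role == "train"])))
    expect_true(all(f$inner_fold[f$role == "train"] %in% 1:10))
  }
  folds2 <- build_folds(manifest, inner_k = 10, seed = 2)
  expect_identical(folds, folds2)
})

test_that("fold plans work at the two-experiment minimum and reject incomplete manifests", {
  plan <- dilution_series(n_samples = 4)
  manifest <- tidyr::expand_grid(plan[, c("sample_number", "concentration")],
                                 replicate = 1:2)
  folds <- build_folds(manifest, seed = 1)
  expect_equal(sort(unique(folds$outer_fold)), 1:2)
  expect_error(build_folds(manifest[-1, ]),
               class = "ramanboost_manifest_error")
  expect_error(build_folds(manifest[manifest$replicate == 1, ]),
               class = "ramanboost_manifest_error")
})

test_that("confusion metrics follow their definitions including undefined ratios", {
  truth <- c(rep(1, 3), rep(-1, 7))
  m <- compute_metrics(truth, truth)
  expect_equal(m$accuracy, 100)
  expect_equal(m$tpr, 1)
  expect_equal(m$ppv, 1)
  # 9 true positives, 1 false negative, nothing else
  m2 <- compute_metrics(c(rep(1, 9), -1), rep(1, 10))
  expect_equal(m2$tp, 9); expect_equal(m2$fn, 1)
  expect_equal(m2$tpr, 0.9)
  expect_equal(m2$ppv, 1)
  # all predicted negative with positives present
  m3 <- compute_metrics(rep(-1, 5), c(1, 1, -1, -1, -1))
  expect_equal(m3$tpr, 0)
  expect_true(is.na(m3$ppv))
  expect_equal(m3$accuracy, 100 * (m3$tp + m3$tn) / m3$n)
  expect_error(compute_metrics(1, c(1, -1)),
               class = "ramanboost_invalid_argument")
})

test_that("a noiseless mini-campaign is classified perfectly end to end", {
  cfg <- tiny_config(replicates = 3)
  exp0 <- simulate_experiment(dilution_series(), cfg, noise = FALSE)
  res <- run_experiment(exp0, thresholds = c(0.962, 0.481),
                        k_stacks = 1, t_k = 3, seed = 4)
  expect_s3_class(res, "raman_benchmark")
  expect_equal(res$summary$accuracy, c(100, 100))
  expect_equal(nrow(res$metrics), 2 * 3)
  # stored metrics are consistent with their own confusion counts
  with(res$metrics, {
    expect_equal(accuracy, 100 * (tp + tn) / n)
    expect_equal(tp + tn + fp + fn, n)
  })
})

test_that("benchmark runs are reproducible for a fixed seed", {
  cfg <- tiny_config(replicates = 3)
  exp0 <- simulate_experiment(dilution_series(), cfg)
  r1 <- run_experiment(exp0, thresholds = 0.962, k_stacks = 2, t_k = 1,
                       seed = 9)
  r2 <- run_experiment(exp0, thresholds = 0.962, k_stacks = 2, t_k = 1,
                       seed = 9)
  expect_identical(dplyr::select(r1$metrics, -train_time_s),
                   dplyr::select(r2$metrics, -train_time_s))
})

test_that("reports expose one summary row and curve point per threshold", {
  cfg <- tiny_config(replicates = 3)
  exp0 <- simulate_experiment(dilution_series(), cfg, noise = FALSE)
  res <- run_experiment(exp0, thresholds = c(0.962, 0.481), k_stacks = 2,
                        t_k = 1, seed = 5)
  out <- withr::local_tempdir()
  curve <- suppressMessages(
    withr::with_output_sink(file.path(out, "log.txt"),
                            report_benchmark(res, out_dir = out)))
  expect_equal(nrow(curve), 2)
  expect_named(curve, c("concentration", "accuracy"))
  expect_equal(curve$concentration, c(0.962, 0.481))
  expect_true(file.exists(file.path(out, "summary.csv")))
  expect_true(file.exists(file.path(out, "accuracy_curve.csv")))
  expect_equal(nrow(readr::read_csv(file.path(out, "accuracy_curve.csv"),
                                    show_col_types = FALSE)), 2)
})

test_that("spectra, manifests and features round-trip through CSV", {
  cfg <- tiny_config(replicates = 2)
  exp0 <- simulate_experiment(dilution_series(n_samples = 3), cfg)
  dir <- withr::local_tempdir()
  write_experiment(exp0, dir)
  back <- read_experiment(file.path(dir, "manifest.csv"))
  expect_equal(back$manifest, exp0$manifest)
  expect_equal(back$spectra$intensity, exp0$spectra$intensity)
  f <- extract_features(exp0) |> make_binary_labels(0.962)
  fp <- file.path(dir, "features.csv")
  write_features(f, fp)
  f2 <- read_features(fp)
  expect_equal(dim(f2), c(nrow(f), 454 + 4))
  expect_equal(f2$label, f$label)
})
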