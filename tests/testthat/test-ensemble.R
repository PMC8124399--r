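test_that("weight initialization is uniform and normalized", {
  w <- init_weights(4)
  expect_equal(w$d, rep(0.25, 4))
  expect_equal(init_weights(1)$d, 1)
  withr::with_seed(1, {
    for (n in sample(1:1000, 10)) {
      expect_equal(sum(init_weights(n)$d), 1)
    }
  })
  expect_error(init_weights(0), class = "ramanboost_invalid_argument")
})

test_that("distribution normalization is exact and scale invariant", {
  w <- init_weights(2); w$alpha <- c(2, 2)
  expect_equal(normalize_distribution(w)$d, c(0.5, 0.5))
  w$alpha <- c(1, 3)
  expect_equal(normalize_distribution(w)$d, c(0.25, 0.75))
  w$alpha <- c(1, 3) * 17.3
  expect_equal(normalize_distribution(w)$d, c(0.25, 0.75))
  w$alpha <- c(0, 0)
  expect_error(normalize_distribution(w),
               class = "ramanboost_degenerate_weights")
})

test_that("hypothesis error is the weighted misclassification mass", {
  d <- rep(0.2, 5)
  truth <- c(1, 1, -1, -1, -1)
  expect_equal(hypothesis_error(truth, truth, d), 0)
  expect_equal(hypothesis_error(c(-1, 1, -1, -1, -1), truth, d), 0.2)
  expect_equal(hypothesis_error(-truth, truth, d), 1)
})

test_that("error normalization follows e/(1-e) with clamping and a reject signal", {
  expect_equal(normalized_error(0.25), 1 / 3)
  expect_equal(normalized_error(0.4), 2 / 3)
  expect_equal(normalized_error(0), 1e-10)
  expect_error(normalized_error(0.5), class = "ramanboost_reject_hypothesis")
  expect_error(normalized_error(0.7), class = "ramanboost_reject_hypothesis")
})

test_that("weighted voting resolves majorities and ties as documented", {
  votes <- matrix(c(1, -1, -1), nrow = 1)
  expect_equal(weighted_vote(votes, c(1.0, 0.5, 0.4)), 1)
  expect_equal(weighted_vote(matrix(c(1, -1), 1), c(1, 1)), 1)  # tie -> +1
  expect_equal(weighted_vote(matrix(c(1, -1, -1), 1), c(0.4, 0.5, 1.0)), -1)
  expect_equal(weighted_vote(matrix(1, 1, 1), 2.5), 1)          # lone voter
})

test_that("weighted voting matches a brute-force argmax oracle", {
  withr::with_seed(31, {
    for (i in 1:500) {
      m <- sample(1:7, 1); n <- sample(1:6, 1)
      votes <- matrix(sample(c(-1, 1), n * m, replace = TRUE), n, m)
      weights <- runif(m)
      expect_equal(weighted_vote(votes, weights),
                   vote_bruteforce(votes, weights))
    }
  })
})

test_that("the weight update focuses mass on misclassified points", {
  w <- init_weights(10)
  correct <- rep(TRUE, 10)
  w1 <- update_weights(w, correct, 0.5)
  expect_equal(w1$d, rep(0.1, 10))         # uniform stays uniform
  correct[3] <- FALSE
  w2 <- update_weights(init_weights(10), correct, 0.5)
  expect_equal(w2$d[3], 0.1 / 0.55)        # 0.1818...
  expect_equal(sum(w2$d), 1)
  w3 <- update_weights(init_weights(10), correct, 1)
  expect_equal(w3$d, rep(0.1, 10))         # B = 1 leaves weights unchanged
})

test_that("relative mass of misclassified points never decreases", {
  withr::with_seed(7, {
    for (i in 1:50) {
      n <- sample(3:30, 1)
      w <- init_weights(n)
      w$alpha <- runif(n) + 0.01
      w <- normalize_distribution(w)
      correct <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (all(correct)) correct[1] <- FALSE
      B <- runif(1, 0.01, 0.99)
      w2 <- update_weights(w, correct, B)
      expect_true(all(w2$d[!correct] >= w$d[!correct] - 1e-12))
      expect_equal(sum(w2$d), 1, tolerance = 1e-9)
    }
  })
})

test_that("distribution-weighted draws split, include hot points, and reproduce", {
  d <- make_clusters(n_per = 5, seed = 4)   # 10 rows
  sp <- draw_train_test(d, rep(0.1, 10), train_frac = 0.5, seed = 2)
  expect_equal(nrow(sp$train), 5)
  expect_equal(nrow(sp$test), 5)
  expect_equal(sort(c(sp$train_idx, setdiff(1:10, sp$train_idx))), 1:10)
  sp2 <- draw_train_test(d, rep(0.1, 10), train_frac = 0.5, seed = 2)
  expect_identical(sp$train_idx, sp2$train_idx)
  # concentrated mass: the hot point is drawn nearly always
  dd <- c(0.97, rep(0.03 / 9, 9))
  hits <- sum(vapply(1:1000, function(s) {
    1 %in% draw_train_test(d, dd, train_frac = 0.5, seed = s)$train_idx
  }, logical(1)))
  expect_gte(hits / 1000, 0.9)
})

test_that("a single separable batch yields one hypothesis that is the ensemble", {
  d <- make_clusters(n_per = 6, sep = 15, seed = 6)
  ens <- learn_increment(new_ensemble(), d, t_k = 1,
                         params = list(C = 10, gamma = 0.05), seed = 1)
  expect_length(ens$records, 1)
  base <- predict(ens$records[[1]]$model, d)$.pred
  expect_equal(final_predict(ens, d, "eq9_literal"), base)
  expect_equal(final_predict(ens, d, "base_vote"), base)
  td <- tidy(ens)
  expect_equal(td$epsilon, 0)
  expect_equal(td$k, 1L)
})

test_that("learning new batches preserves earlier records byte-identically", {
  d1 <- make_clusters(n_per = 6, sep = 12, seed = 8)
  d2 <- make_clusters(n_per = 6, sep = 12, seed = 9)
  ens1 <- learn_increment(new_ensemble(), d1, t_k = 2,
                          params = list(C = 10, gamma = 0.05), seed = 1)
  frozen <- serialize(ens1$records, NULL)
  rm(d1)   # the first batch is gone; the update must not need it
  ens2 <- learn_increment(ens1, d2, t_k = 2,
                          params = list(C = 10, gamma = 0.05), seed = 2)
  expect_length(ens2$records, 4)
  expect_identical(serialize(ens2$records[seq_len(2)], NULL), frozen)
  expect_equal(ens2$n_datasets, 2L)
  expect_equal(vapply(ens2$records, function(r) r$k, numeric(1)),
               c(1, 1, 2, 2))
})

test_that("every stored record respects the acceptance gates", {
  d1 <- make_clusters(n_per = 8, sep = 4, seed = 12)  # moderately separated
  d2 <- make_clusters(n_per = 8, sep = 4, seed = 13)
  ens <- learn_increment(new_ensemble(), d1, t_k = 3,
                         params = list(C = 10, gamma = 0.1), seed = 3)
  ens <- learn_increment(ens, d2, t_k = 3,
                         params = list(C = 10, gamma = 0.1), seed = 4)
  td <- tidy(ens)
  expect_true(all(td$epsilon < 0.5))
  expect_true(all(td$E < 0.5))
  expect_true(all(td$beta > 0 & td$beta < 1))
  expect_true(all(td$B > 0 & td$B < 1))
})

test_that("duplicating every record leaves final predictions unchanged", {
  d <- make_clusters(n_per = 6, sep = 3, seed = 14)
  ens <- learn_increment(new_ensemble(), d, t_k = 3,
                         params = list(C = 1, gamma = 0.1), seed = 5)
  doubled <- ens
  doubled$records <- c(ens$records, ens$records)
  for (mode in c("eq9_literal", "base_vote")) {
    expect_equal(final_predict(doubled, d, mode), final_predict(ens, d, mode))
  }
})

test_that("an unlearnable batch fails with an increment-failure error", {
  cd <- tibble::tibble(f0001 = rep(0, 6), f0002 = rep(0, 6),
                       label = rep(c(-1, 1), 3))
  ens <- new_ensemble(max_retries = 2)
  expect_error(learn_increment(ens, cd, t_k = 1,
                               params = list(C = 1, gamma = 1)),
               class = "ramanboost_increment_failure")
  # truncate mode still errors when not even one hypothesis was accepted
  expect_error(learn_increment(ens, cd, t_k = 1,
                               params = list(C = 1, gamma = 1),
                               on_gate_failure = "truncate"),
               class = "ramanboost_increment_failure")
})

test_that("ensembles round-trip through their archive", {
  d <- make_clusters(n_per = 6, sep = 12, seed = 15)
  ens <- learn_increment(new_ensemble(), d, t_k = 1,
                         params = list(C = 10, gamma = 0.05), seed = 1)
  path <- withr::local_tempfile(fileext = ".rds")
  write_ensemble(ens, path)
  back <- read_ensemble(path)
  expect_identical(serialize(back$records, NULL), serialize(ens$records, NULL))
  expect_equal(final_predict(back, d), final_predict(ens, d))
})
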