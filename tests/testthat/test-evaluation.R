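test_that("information indices reproduce published precision/recall arithmetic", {
  # cells from a published 5-fold benchmark: F1 and G recomputed from the
  # printed 4-decimal precision/recall pairs agree at that precision
  idx <- indices_from_pr(0.5000, 0.7143)
  expect_equal(idx$f1, 0.5882, tolerance = 1e-4)
  expect_equal(idx$g, 0.5976, tolerance = 1e-4)
  expect_equal(indices_from_pr(1.0000, 0.2857)$g, 0.5345, tolerance = 1e-4)

  perfect <- information_indices(7, 0, 0, 7)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$g, 1)

  expect_warning(zero <- information_indices(0, 0, 3, 4), "precision")
  expect_equal(zero$precision, 0)
  expect_equal(zero$f1, 0)
  expect_error(information_indices(-1, 0, 0, 0), class = "rankcbr_invalid_input")
})

test_that("F1 and G are the harmonic and geometric means, ordered F1 <= G", {
  withr::with_seed(3, {
    for (rep in 1:50) {
      cc <- as.list(stats::rmultinom(1, 20, rep(0.25, 4))[, 1])
      idx <- suppressWarnings(information_indices(cc[[1]], cc[[2]], cc[[3]], cc[[4]]))
      lo <- min(idx$precision, idx$recall)
      hi <- max(idx$precision, idx$recall)
      expect_true(idx$f1 >= lo - 1e-12 && idx$f1 <= hi + 1e-12)
      expect_true(idx$g >= lo - 1e-12 && idx$g <= hi + 1e-12)
      expect_gte(idx$g + 1e-12, idx$f1)  # AM-GM chain on the two means
      if (idx$precision == idx$recall) {
        expect_equal(idx$f1, idx$precision)
        expect_equal(idx$g, idx$precision)
      }
    }
  })
})

test_that("fold summaries use order statistics, the mean, and the n-1 standard deviation", {
  reports <- tibble::tibble(
    fold = 1:5, model = "RWCBR",
    precision = c(1.0000, 1.0000, 0.7778, 1.0000, 0.7778),
    recall = c(0.7143, 0.8571, 1.0000, 1.0000, 1.0000),
    f1 = c(0.8333, 0.9231, 0.8750, 1.0000, 0.8750),
    g = c(0.8452, 0.9258, 0.8819, 1.0000, 0.8819)
  )
  s <- summarize_folds(reports)
  expect_lt(abs(s$AVG[s$index == "precision"] - 0.9111), 1.01e-4)
  expect_lt(abs(s$STD[s$index == "f1"] - 0.0637), 1.01e-4)
  expect_equal(s$MIN[s$index == "recall"], 0.7143)
  expect_equal(s$MAX[s$index == "g"], 1)

  const <- tibble::tibble(fold = 1:3, model = "X", precision = 0.8,
                          recall = 0.8, f1 = 0.8, g = 0.8)
  sc <- summarize_folds(const)
  expect_true(all(sc$STD == 0))
  expect_true(all(sc$MIN == sc$AVG & sc$AVG == sc$MAX))
  expect_error(summarize_folds(const[0, ]), class = "rankcbr_invalid_input")
})

test_that("stratified folds are balanced, exhaustive, disjoint and seeded", {
  labels <- rep(c("cancer", "control"), each = 35)
  folds <- stratified_kfold(labels, 5, seed = 9)
  for (k in 1:5) {
    expect_equal(sum(folds == k), 14)
    expect_equal(sum(folds == k & labels == "cancer"), 7)
    expect_equal(sum(folds != k), 56)
  }
  expect_identical(stratified_kfold(labels, 5, seed = 9), folds)
  expect_false(identical(stratified_kfold(labels, 5, seed = 10), folds))
  expect_error(stratified_kfold(c("cancer", rep("control", 9)), 5),
               class = "rankcbr_stratification_error")
})

test_that("the k-NN baseline is exact on memorised cases and separable cohorts", {
  tbl <- make_feature_table(n = 12, seed = 6)
  hit <- knn_baseline(tbl, tbl[4, ], k = 1)
  expect_equal(hit$label, tbl$label[4])

  cohort <- generate_cohort(separable_spec(n_subjects = 20, grid_length = 101))
  f <- extract_features(cohort)
  folds <- stratified_kfold(f$label, 2, seed = 1)
  train <- f[folds == 1, ]
  test <- f[folds == 2, ]
  attr(train, "temps") <- attr(f, "temps")
  pred <- knn_baseline(train, test, k = 5, temps = attr(f, "temps"))
  expect_equal(pred$label, test$label)
  expect_error(knn_baseline(tbl, tbl[1, ], k = 99),
               class = "rankcbr_retrieval_error")
})

test_that("the SCUCC composite separates reference-like from anti-correlated curves", {
  withr::with_seed(8, {
    base <- 3 * exp(-0.5 * ((seq(45, 90, length.out = 60) - 63) / 5)^2)
    reference <- t(replicate(10, base + stats::rnorm(60, 0, 0.1)))
  })
  like_mean <- scucc_coefficient(reference, colMeans(reference))
  flipped <- scucc_coefficient(reference, max(base) - base)
  expect_gt(like_mean, 0.5)
  expect_lt(flipped, 0)

  train <- make_feature_table(n = 16, seed = 10, signal = "IND", effect = 4)
  pred <- scucc_classify(train, train)
  expect_true(all(pred$label %in% c("cancer", "control")))
  expect_error(scucc_coefficient(reference[1, , drop = FALSE], base),
               class = "rankcbr_invalid_input")
})

test_that("the experiment harness validates models and is seed-deterministic", {
  cohort <- generate_cohort(cohort_spec(n_subjects = 16, grid_length = 101,
                                        seed = 3))
  expect_error(run_experiment(cohort, models = "XGB"),
               class = "rankcbr_config_error")
  fit1 <- run_experiment(cohort, models = c("CLCBR", "KNN"), k_folds = 2,
                         seed = 5, knn_k = 3)
  fit2 <- run_experiment(cohort, models = c("CLCBR", "KNN"), k_folds = 2,
                         seed = 5, knn_k = 3)
  expect_identical(fit1$fold_reports, fit2$fold_reports)
  expect_identical(fit1$summary, fit2$summary)
  expect_equal(nrow(fit1$fold_reports), 4)
})

test_that("experiment accessors expose tidy folds, weights, summary and a glance row", {
  cohort <- generate_cohort(cohort_spec(n_subjects = 12, grid_length = 101,
                                        seed = 6))
  fit <- run_experiment(cohort, models = c("CLCBR", "RWCBR"), k_folds = 2,
                        seed = 2)
  folds <- tidy(fit)
  expect_s3_class(folds, "tbl_df")
  expect_true(all(c("fold", "model", "precision", "recall", "f1", "g")
                  %in% names(folds)))
  w <- tidy(fit, "weights")
  expect_equal(unique(as.character(w$model)), "RWCBR")
  expect_equal(sum(w$weight[w$fold == 1]), 1, tolerance = 1e-9)
  g <- glance(fit)
  expect_equal(nrow(g), 1)
  expect_true(g$best_model %in% c("CLCBR", "RWCBR"))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_output(print(fit), "Average information indices")
})

test_that("weight estimation never sees the test fold", {
  # moving a test-fold case far away must not change the training weights
  cohort <- generate_cohort(cohort_spec(n_subjects = 12, grid_length = 101,
                                        seed = 8))
  f <- extract_features(cohort)
  folds <- stratified_kfold(f$label, 2, seed = 1)
  train <- f[folds != 1, ]
  attr(train, "temps") <- attr(f, "temps")
  w_before <- rank_weights(train)
  f2 <- f
  f2$T2[folds == 1] <- 90
  train2 <- f2[folds != 1, ]
  attr(train2, "temps") <- attr(f, "temps")
  expect_identical(rank_weights(train2), w_before)
})
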