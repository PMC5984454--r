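test_that("the rank-sum test reproduces small exact cases and degenerate ties", {
  res <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1 / 3)  # 2/6 of the U distribution at the tail
  expect_equal(res$method, "exact")

  # identical multisets carry no separation evidence
  res <- wilcoxon_rank_sum(c(1, 2, 2), c(2, 1, 2))
  expect_equal(res$p_value, 1)

  expect_error(wilcoxon_rank_sum(numeric(0), 1), class = "rankcbr_invalid_input")
})

test_that("the rank-sum test agrees with wilcox.test on both code paths", {
  withr::with_seed(5, {
    for (rep in 1:20) {
      x <- stats::rnorm(sample(3:6, 1))
      y <- stats::rnorm(sample(3:6, 1))
      mine <- wilcoxon_rank_sum(x, y)
      ref <- stats::wilcox.test(x, y, exact = TRUE)
      expect_equal(mine$statistic, unname(ref$statistic))
      expect_equal(mine$p_value, ref$p.value)
    }
    for (rep in 1:20) {
      x <- sample(1:8, 15, replace = TRUE)   # heavy ties -> normal path
      y <- sample(1:8, 12, replace = TRUE)
      mine <- wilcoxon_rank_sum(x, y)
      ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
      expect_equal(mine$method, "normal")
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    }
  })
})

test_that("the rank-sum p-value is invariant to strictly increasing score transforms", {
  x <- c(0.2, 1.5, 3.1, 0.9)
  y <- c(2.2, 4.0, 0.4)
  f <- function(v) exp(v) + 2
  expect_equal(wilcoxon_rank_sum(x, y)$p_value,
               wilcoxon_rank_sum(f(x), f(y))$p_value)
})

test_that("every weighting scheme satisfies the simplex constraints on random training sets", {
  withr::with_seed(99, {
    for (rep in 1:40) {
      tbl <- make_feature_table(n = sample(8:16, 1), seed = sample.int(1e6, 1),
                                ind_len = 12)
      for (w in list(rank_weights(tbl), entropy_weights(tbl),
                     suppressWarnings(wald_weights(tbl)), equal_weights(tbl))) {
        expect_equal(sum(w$weight), 1, tolerance = 1e-9)
        expect_true(all(w$weight >= -1e-12 & w$weight <= 1 + 1e-12))
        expect_equal(w$feature, c("IR", "T1", "T2", "PEAK1", "PEAK2", "IND"))
      }
    }
  })
})

test_that("rank weights reward the separating feature and need both classes", {
  tbl <- make_feature_table(n = 40, seed = 21, signal = "T2", effect = 6)
  w <- rank_weights(tbl)
  expect_equal(w$feature[which.max(w$weight)], "T2")

  one_class <- tbl[tbl$label == "cancer", ]
  attr(one_class, "temps") <- attr(tbl, "temps")
  expect_error(rank_weights(one_class), class = "rankcbr_estimation_error")
})

test_that("rank weights support the mean-distance reference variant", {
  # note: with balanced classes a pure location shift leaves the mean
  # distance to all cases symmetric between classes, so this variant is not
  # expected to single out the shifted feature -- only to honour the
  # weight contract (which is why the control-median reference is default)
  tbl <- make_feature_table(n = 16, seed = 8, signal = "T2", effect = 6)
  w <- rank_weights(tbl, reference = "average")
  expect_equal(sum(w$weight), 1, tolerance = 1e-9)
  expect_true(all(w$weight >= 0 & w$weight <= 1))
})

test_that("lower p-values never receive smaller rank weights", {
  tbl <- make_feature_table(n = 30, seed = 13, signal = "PEAK1", effect = 8)
  temps <- attr(tbl, "temps")
  scores <- rankcbr:::feature_scores(tbl, "median", temps)
  is_cancer <- tbl$label == "cancer"
  p <- vapply(scores, function(s) {
    wilcoxon_rank_sum(s[is_cancer], s[!is_cancer])$p_value
  }, numeric(1))
  w <- rank_weights(tbl)
  expect_equal(order(p), order(-w$weight))
})

test_that("entropy weights follow the stated per-feature entropy model", {
  tbl <- make_feature_table(n = 30, seed = 2, ind_len = 40)
  tbl$IR <- rep(c(0, 1), 15)        # empirical rate 0.5 -> 1 bit
  tbl$T1 <- rep(50, 30)             # constant -> zero entropy -> zero weight
  w <- entropy_weights(tbl)
  expect_equal(w$weight[w$feature == "T1"], 0)
  # the 40-point curve dominates every scalar feature
  expect_gte(w$weight[w$feature == "IND"],
             max(w$weight[w$feature != "IND"]))
  # recompute the IR share from the closed-form entropies
  gauss_h <- function(v) max(0, 0.5 * log2(2 * pi * exp(1) * v))
  curves <- do.call(rbind, tbl$IND)
  total <- 1 + gauss_h(var(tbl$T2)) + gauss_h(var(tbl$PEAK1)) +
    gauss_h(var(tbl$PEAK2)) +
    sum(apply(curves, 2, function(col) gauss_h(var(col))))
  expect_equal(w$weight[w$feature == "IR"], 1 / total)
})

test_that("Wald weights recover an informative predictor and degrade gracefully", {
  tbl <- make_feature_table(n = 200, seed = 31, signal = "T2", effect = 4)
  w <- wald_weights(tbl)
  expect_equal(w$feature[which.max(w$weight)], "T2")

  flat <- make_feature_table(n = 12, seed = 4)
  flat$IR <- 0
  flat$T1 <- 50
  flat$T2 <- 60
  flat$PEAK1 <- 3
  flat$PEAK2 <- 5
  flat$IND <- rep(list(rep(2, 15)), 12)
  expect_warning(w0 <- wald_weights(flat), "equal")
  expect_equal(w0$weight, rep(1 / 6, 6))
})

test_that("equal weights split the simplex uniformly", {
  expect_equal(equal_weights()$weight, rep(1 / 6, 6))
  one <- equal_weights("IND")
  expect_equal(one$weight, 1)
  expect_error(equal_weights(character(0)), class = "rankcbr_invalid_input")
})
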