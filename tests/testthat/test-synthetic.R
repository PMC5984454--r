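test_that("cohort generation honours its cohort_spec: size, grid, label balance, determinism", {
  spec <- cohort_spec(n_subjects = 70, cancer_fraction = 0.5,
                      grid_length = 451, seed = 1)
  cohort <- generate_cohort(spec)
  expect_equal(nrow(cohort), 70)
  expect_equal(length(cohort_temps(cohort)), 451)
  expect_equal(cohort_temps(cohort)[1], 45)
  expect_equal(cohort_temps(cohort)[451], 90)
  expect_equal(sum(cohort$label == "cancer"), 35)
  expect_true(all(cohort_matrix(cohort) >= 0))
  expect_identical(generate_cohort(spec), cohort)

  # exact rounding of the label count, odd sizes included
  c9 <- generate_cohort(cohort_spec(n_subjects = 9, cancer_fraction = 0.4,
                                    grid_length = 11, seed = 2))
  expect_equal(sum(c9$label == "cancer"), round(9 * 0.4))
})

test_that("a subject's curve is invariant to the cohort size", {
  small <- generate_cohort(cohort_spec(n_subjects = 10, grid_length = 51, seed = 3))
  large <- generate_cohort(cohort_spec(n_subjects = 14, grid_length = 51, seed = 3))
  expect_identical(as.numeric(cohort_matrix(small)[2, ]),
                   as.numeric(cohort_matrix(large)[2, ]))
})

test_that("with all variance parameters zero, same-class curves are identical and classes differ", {
  cohort <- generate_cohort(separable_spec(n_subjects = 10, grid_length = 101))
  m <- cohort_matrix(cohort)
  cancer <- m[cohort$label == "cancer", ]
  control <- m[cohort$label == "control", ]
  expect_true(all(apply(cancer, 2, function(x) diff(range(x)) == 0)))
  expect_true(all(apply(control, 2, function(x) diff(range(x)) == 0)))
  temps <- cohort_temps(cohort)
  expect_gt(discrete_frechet(cbind(temps, cancer[1, ]),
                             cbind(temps, control[1, ])), 0)
})

test_that("class-separated second peaks produce separable extracted T2", {
  spec <- cohort_spec(
    n_subjects = 12, grid_length = 451, seed = 5,
    control = peak_params(mu1 = 50, mu2 = 62, amp1 = 3, amp2 = 5,
                          p_single_peak = 0, jitter_sd = 0, p_neg_start = 0),
    cancer = peak_params(mu1 = 50, mu2 = 75, amp1 = 3, amp2 = 5,
                         p_single_peak = 0, jitter_sd = 0, p_neg_start = 0),
    noise_sd = 0.01, subject_sd = 0
  )
  f <- extract_features(generate_cohort(spec))
  expect_true(max(f$T2[f$label == "control"]) < min(f$T2[f$label == "cancer"]))
})

test_that("invalid cohort specifications are rejected", {
  expect_error(cohort_spec(n_subjects = 0), class = "rankcbr_invalid_spec")
  expect_error(cohort_spec(grid_length = 1), class = "rankcbr_invalid_spec")
  expect_error(cohort_spec(cancer_fraction = 1.2), class = "rankcbr_invalid_spec")
  expect_error(cohort_spec(grid_start = 90, grid_end = 45),
               class = "rankcbr_invalid_spec")
  expect_error(peak_params(mu1 = 60), class = "rankcbr_invalid_spec")
  expect_error(peak_params(sd1 = -1), class = "rankcbr_invalid_spec")
})

test_that("cohort CSV round-trips at full precision and rejects malformed files", {
  cohort <- generate_cohort(cohort_spec(n_subjects = 6, grid_length = 21, seed = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(cohort))

  bad_label <- cohort
  bad_label$label[3] <- "tumour"
  write_cohort(bad_label, path)
  expect_error(read_cohort(path), "tumour", class = "rankcbr_parse_error")

  write_cohort(cohort, path)
  expect_error(read_cohort(path, grid_length = 451),
               class = "rankcbr_shape_error")

  writeLines(c("id,label,T45", "S001,control,1.0"), path)
  expect_error(read_cohort(path), class = "rankcbr_parse_error")

  writeLines(c("subject_id,label,T45,T46", "S001,control,1.0,abc"), path)
  expect_error(read_cohort(path), class = "rankcbr_parse_error")
})

test_that("a YAML config maps one-to-one onto a cohort spec", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_subjects: 8", "cancer_fraction: 0.5", "grid_length: 31", "seed: 4",
    "noise_sd: 0", "subject_sd: 0",
    "control:", "  mu1: 49", "  mu2: 60", "  p_single_peak: 0", "  jitter_sd: 0",
    "cancer:", "  mu1: 51", "  mu2: 70", "  p_single_peak: 0", "  jitter_sd: 0"
  ), path)
  spec <- read_cohort_config(path)
  expect_s3_class(spec, "cohort_spec")
  expect_equal(spec$n_subjects, 8L)
  expect_equal(spec$control$mu2, 60)
  cohort <- generate_cohort(spec)
  expect_equal(nrow(cohort), 8)
  expect_s3_class(plot_cohort(cohort), "ggplot")
})
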