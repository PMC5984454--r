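# Independent oracles and fixture builders used across the suite.

# Exhaustive discrete Frechet distance: minimum over every monotone coupling
# of the maximal pointwise gap. Branch-and-bound over the coupling tree; the
# pruning never removes the optimum, so the result is exact. Usable only for
# short curves.
frechet_bruteforce <- function(A, B) {
  n <- nrow(A)
  m <- nrow(B)
  d <- function(i, j) sqrt(sum((A[i, ] - B[j, ])^2))
  best <- Inf
  rec <- function(i, j, cur) {
    cur <- max(cur, d(i, j))
    if (cur > best) return(invisible())
    if (i == n && j == m) {
      best <<- min(best, cur)
      return(invisible())
    }
    if (i < n) rec(i + 1, j, cur)
    if (j < m) rec(i, j + 1, cur)
    if (i < n && j < m) rec(i + 1, j + 1, cur)
  }
  rec(1, 1, 0)
  best
}

# Exact two-sided Wilcoxon rank-sum p-value by exhaustive enumeration of all
# choose(n1 + n0, n1) assignments of the pooled ranks to group 1. Tie-free
# samples only.
wilcoxon_exact_enum <- function(x, y) {
  n1 <- length(x)
  n0 <- length(y)
  n <- n1 + n0
  stopifnot(!anyDuplicated(c(x, y)))
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- utils::combn(n, n1, function(idx) sum(idx) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Random feature table respecting the feature invariants (IR binary, T1 in
# [45,55], T2 in [56,90], peaks nonnegative, IND a nonnegative curve on a
# short grid). `signal` names one feature shifted by `effect` in the cancer
# class; all others are class-independent noise.
make_feature_table <- function(n = 20, seed = 1, ind_len = 15,
                               signal = NULL, effect = 3) {
  withr::with_seed(seed, {
    labels <- rep(c("cancer", "control"), length.out = n)
    temps <- seq(45, 90, length.out = ind_len)
    shift <- function(f, base) base + (labels == "cancer") * effect *
      (identical(signal, f))
    tbl <- tibble::tibble(
      subject_id = sprintf("C%03d", seq_len(n)),
      label = labels,
      IR = stats::rbinom(n, 1, if (identical(signal, "IR")) {
        ifelse(labels == "cancer", 0.9, 0.1)
      } else 0.5),
      T1 = pmin(55, pmax(45, shift("T1", stats::rnorm(n, 49, 1)))),
      T2 = pmin(90, pmax(56, shift("T2", stats::rnorm(n, 62, 1)))),
      PEAK1 = pmax(0, shift("PEAK1", stats::rnorm(n, 3, 0.5))),
      PEAK2 = pmax(0, shift("PEAK2", stats::rnorm(n, 5, 0.5)))
    )
    tbl$IND <- lapply(seq_len(n), function(i) {
      base <- 3 * exp(-0.5 * ((temps - 63) / 5)^2)
      bump <- if (identical(signal, "IND") && labels[i] == "cancer") {
        effect * exp(-0.5 * ((temps - 75) / 3)^2)
      } else 0
      pmax(0, base + bump + stats::rnorm(ind_len, 0, 0.3))
    })
    attr(tbl, "temps") <- temps
    tbl
  })
}

# Random short curve in the (temperature, heat-capacity) plane.
random_curve <- function(len) {
  cbind(sort(stats::runif(len, 0, 10)), stats::runif(len, 0, 5))
}

# Zero-variance, class-separable cohort spec: every same-class curve is
# identical and the two classes differ in second-peak location and balance.
separable_spec <- function(n_subjects = 70, grid_length = 451, seed = 1) {
  cohort_spec(
    n_subjects = n_subjects, grid_length = grid_length, seed = seed,
    control = peak_params(mu1 = 49, mu2 = 62, sd1 = 2, sd2 = 3.5,
                          amp1 = 3, amp2 = 5.5,
                          p_single_peak = 0, jitter_sd = 0, p_neg_start = 0),
    cancer = peak_params(mu1 = 51, mu2 = 68, sd1 = 2.5, sd2 = 4.5,
                         amp1 = 4, amp2 = 3.5,
                         p_single_peak = 0, jitter_sd = 0, p_neg_start = 0),
    noise_sd = 0, subject_sd = 0
  )
}
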