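#' Wilcoxon rank-sum (Mann--Whitney) test
#'
#' Two-sample rank test used to score how well each feature separates the
#' two clinical classes. Pooled ranks use average ranks for ties. The
#' statistic reported is the Mann--Whitney form: the rank sum of group 1
#' minus `n1 * (n1 + 1) / 2`, which lies in `[0, n1 * n0]`. The two-sided
#' p-value comes from the exact null distribution when the pooled sample is
#' small (`n1 + n0 <= 12`) and tie-free, otherwise from the normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param x Numeric scores of group 1 (the positive / cancer class).
#' @param y Numeric scores of group 0 (the control class).
#' @param method `"auto"` (default), `"exact"`, or `"normal"`.
#' @return A one-row tibble with `statistic` (Mann--Whitney form), `rank_sum`
#'   (rank sum of group 1), `p_value`, `n1`, `n0` and `method` used.
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4)) # statistic 0, exact p = 1/3
#' @export
wilcoxon_rank_sum <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (length(x) == 0 || length(y) == 0) {
    abort("both groups must be nonempty", class = "rankcbr_invalid_input")
  }
  n1 <- length(x)
  n0 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  rank_sum <- sum(r[seq_len(n1)])
  u <- rank_sum - n1 * (n1 + 1) / 2
  ties <- table(pooled)
  has_ties <- any(ties > 1)
  if (method == "auto") {
    method <- if (!has_ties && n1 + n0 <= 12) "exact" else "normal"
  }
  if (method == "exact") {
    if (has_ties) {
      abort("exact p-values are undefined with ties; use method = \"normal\"",
            class = "rankcbr_invalid_input")
    }
    p <- min(1, 2 * min(pwilcox(u, n1, n0), 1 - pwilcox(u - 1, n1, n0)))
  } else {
    mu <- n1 * n0 / 2
    n <- n1 + n0
    tie_term <- if (n > 1) sum(ties^3 - ties) / (n * (n - 1)) else 0
    sigma2 <- n1 * n0 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - 0.5 * sign(u - mu)) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
  }
  tibble::tibble(statistic = u, rank_sum = rank_sum, p_value = p,
                 n1 = n1, n0 = n0, method = method)
}

weight_tbl <- function(w, scheme) {
  out <- tibble::tibble(feature = cbr_features(), weight = unname(w[cbr_features()]))
  attr(out, "scheme") <- scheme
  out
}

check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2) {
    abort("weight estimation needs both classes in the training set",
          class = "rankcbr_estimation_error")
  }
}

# Per-feature scalar scores used by the rank-based weights: each training
# case's local distance to a fixed class-0 (control) pseudo-target, built as
# the feature-wise median of the control cases (point-wise median curve for
# IND). With reference = "average" the score is instead the mean local
# distance to every training case.
feature_scores <- function(features, reference, temps) {
  scalars <- c("IR", "T1", "T2", "PEAK1", "PEAK2")
  curves <- do.call(rbind, features$IND)
  if (reference == "median") {
    ctrl <- features$label == "control"
    ref <- lapply(scalars, function(f) median(features[[f]][ctrl]))
    names(ref) <- scalars
    ref_curve <- cbind(temps, apply(curves[ctrl, , drop = FALSE], 2, median))
    scores <- lapply(scalars, function(f) (features[[f]] - ref[[f]])^2)
    names(scores) <- scalars
    scores$IND <- vapply(features$IND, function(y) {
      frechet_dp(cbind(temps, y), ref_curve)
    }, numeric(1))
  } else {
    n <- nrow(features)
    scores <- lapply(scalars, function(f) {
      vapply(features[[f]], function(v) mean((features[[f]] - v)^2), numeric(1))
    })
    names(scores) <- scalars
    dmat <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        dmat[i, j] <- dmat[j, i] <-
          frechet_dp(cbind(temps, curves[i, ]), cbind(temps, curves[j, ]))
      }
    }
    scores$IND <- rowMeans(dmat)
  }
  tibble::as_tibble(scores)
}

#' Wilcoxon-rank feature weights (RWCBR)
#'
#' The rank-based weighting scheme at the core of the package. For each
#' feature, every training case is reduced to a scalar score -- its local
#' distance to a control-class reference case (feature-wise median of the
#' control training cases; point-wise median curve for IND) -- and a Wilcoxon
#' rank-sum test compares the scores of the cancer cases against those of the
#' control cases. A feature whose distances-to-control separate the classes
#' well yields a small p-value, and weights are allocated proportional to
#' `1 - p`:
#' \deqn{\omega_f = \frac{1 - p_f}{\sum_g (1 - p_g)}.}
#' Being rank-based, the weights are invariant to any strictly increasing
#' transform of a feature's score scale and require no normality assumption.
#'
#' @param features Training feature tibble from [extract_features()]; both
#'   classes must be present.
#' @param reference `"median"` (default: fixed control-median pseudo-target)
#'   or `"average"` (mean distance to every training case).
#' @param temps Temperature grid (defaults to the `"temps"` attribute).
#' @return A tibble with columns `feature` and `weight`; weights are in
#'   \[0, 1\] and sum to 1.
#' @export
rank_weights <- function(features, reference = c("median", "average"),
                         temps = attr(features, "temps")) {
  reference <- match.arg(reference)
  check_two_classes(features$label)
  scores <- feature_scores(features, reference, temps)
  is_cancer <- features$label == "cancer"
  p <- vapply(scores, function(s) {
    wilcoxon_rank_sum(s[is_cancer], s[!is_cancer])$p_value
  }, numeric(1))
  w <- 1 - p
  if (sum(w) < 1e-12) {
    warn("no feature shows any class separation; falling back to equal weights")
    return(equal_weights(features))
  }
  weight_tbl(w / sum(w), "RWCBR")
}

#' Entropy feature weights (ETCBR)
#'
#' Allocates weight proportional to each feature's information content in
#' the training set, with no use of the class labels. IR is treated as
#' Bernoulli (Shannon entropy of the empirical rate, in bits); the scalar
#' features as normal (differential entropy `0.5 * log2(2 * pi * e * var)`,
#' floored at 0); and the IND curve as the sum over grid points of the
#' per-point floored normal differential entropies -- which is why the
#' 451-point curve typically dominates the weight vector under this scheme.
#'
#' @inheritParams rank_weights
#' @return A tibble with columns `feature` and `weight` summing to 1.
#' @export
entropy_weights <- function(features, temps = attr(features, "temps")) {
  if (nrow(features) < 2) {
    abort("entropy weights need at least 2 training cases",
          class = "rankcbr_estimation_error")
  }
  bern <- function(p) {
    if (p <= 0 || p >= 1) 0 else -p * log2(p) - (1 - p) * log2(1 - p)
  }
  gauss_h <- function(v) max(0, 0.5 * log2(2 * pi * exp(1) * v))
  curves <- do.call(rbind, features$IND)
  h <- c(
    IR = bern(mean(features$IR)),
    T1 = gauss_h(stats::var(features$T1)),
    T2 = gauss_h(stats::var(features$T2)),
    PEAK1 = gauss_h(stats::var(features$PEAK1)),
    PEAK2 = gauss_h(stats::var(features$PEAK2)),
    IND = sum(vapply(seq_len(ncol(curves)),
                     function(j) gauss_h(stats::var(curves[, j])), numeric(1)))
  )
  if (sum(h) < 1e-12) {
    warn("all features have zero entropy; falling back to equal weights")
    return(equal_weights(features))
  }
  weight_tbl(h / sum(h), "ETCBR")
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Logistic-regression Wald feature weights (LWCBR)
#'
#' Fits a binary logistic regression of the class label on the six features
#' and allocates weight proportional to the squared Wald statistic
#' `(beta / se)^2` of each coefficient (intercept excluded). The 451-point
#' IND curve cannot enter a logistic model fitted on a few dozen cases as
#' 451 separate predictors, so it is reduced to one scalar: the trapezoidal
#' area under the curve. Predictors are standardised before fitting and the
#' iteratively reweighted least squares solver carries a small ridge penalty
#' (1e-4) so that separable training sets still yield a finite fit.
#'
#' @inheritParams rank_weights
#' @param max_iter Maximum IRLS iterations (default 100). Non-convergence
#'   raises a condition of class `rankcbr_convergence_error` carrying the
#'   last iterate in its `beta` field.
#' @param ridge Ridge penalty on the standardised coefficients.
#' @return A tibble with columns `feature` and `weight` summing to 1. If
#'   every Wald statistic is (numerically) zero the scheme falls back to
#'   equal weights.
#' @export
wald_weights <- function(features, temps = attr(features, "temps"),
                         max_iter = 100, ridge = 1e-4) {
  check_two_classes(features$label)
  y <- as.numeric(features$label == "cancer")
  ind_auc <- vapply(features$IND, function(v) trapz(temps, v), numeric(1))
  X <- cbind(IR = features$IR, T1 = features$T1, T2 = features$T2,
             PEAK1 = features$PEAK1, PEAK2 = features$PEAK2, IND = ind_auc)
  X <- apply(X, 2, function(col) {
    s <- sd(col)
    if (s < 1e-12) rep(0, length(col)) else (col - mean(col)) / s
  })
  Xd <- cbind(1, X)
  p_dim <- ncol(Xd)
  pen <- diag(c(0, rep(ridge, p_dim - 1)))
  # penalised log-likelihood; the ridge makes it strictly concave with a
  # finite maximiser even under complete separation
  pll <- function(beta) {
    eta <- drop(Xd %*% beta)
    sum(y * eta - log1p(exp(eta))) - 0.5 * ridge * sum(beta[-1]^2)
  }
  beta <- rep(0, p_dim)
  ll <- pll(beta)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    xtw <- t(Xd * w)
    direction <- drop(solve(xtw %*% Xd + pen, xtw %*% z)) - beta
    # damped Newton: halve the step until the objective improves
    step <- 1
    repeat {
      beta_new <- beta + step * direction
      ll_new <- pll(beta_new)
      if (ll_new >= ll - 1e-12 || step < 1e-8) break
      step <- step / 2
    }
    moved <- max(abs(beta_new - beta))
    beta <- beta_new
    if (abs(ll_new - ll) < 1e-10 * (1 + abs(ll_new)) ||
        moved < 1e-8 * (1 + max(abs(beta)))) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  if (!converged) {
    abort("logistic fit did not converge within `max_iter` iterations",
          class = "rankcbr_convergence_error", beta = beta)
  }
  mu <- stats::plogis(drop(Xd %*% beta))
  w <- pmax(mu * (1 - mu), 1e-10)
  cov <- solve(t(Xd * w) %*% Xd + pen)
  se <- sqrt(diag(cov))[-1]
  wald <- (beta[-1] / se)^2
  names(wald) <- colnames(X)
  if (any(!is.finite(wald)) || sum(wald) < 1e-12) {
    warn("degenerate Wald statistics; falling back to equal weights")
    return(equal_weights(features))
  }
  weight_tbl(wald / sum(wald), "LWCBR")
}

#' Equal feature weights (CLCBR)
#'
#' The classical case-based-reasoning baseline: every feature gets weight
#' `1 / m`.
#'
#' @param features A feature tibble, or a character vector of feature names.
#' @return A tibble with columns `feature` and `weight`.
#' @export
equal_weights <- function(features = cbr_features()) {
  nms <- if (is.character(features)) features else cbr_features()
  if (length(nms) == 0) {
    abort("need at least one feature", class = "rankcbr_invalid_input")
  }
  out <- tibble::tibble(feature = nms, weight = rep(1 / length(nms), length(nms)))
  attr(out, "scheme") <- "CLCBR"
  out
}
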