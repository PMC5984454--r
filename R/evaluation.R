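#' Precision, recall, F-1 score and G-measure from confusion counts
#'
#' The four information indices used to score every classifier, with cancer
#' as the positive class:
#' precision = tp / (tp + fp), recall = tp / (tp + fn),
#' F-1 = 2 * precision * recall / (precision + recall) (harmonic mean),
#' G = sqrt(precision * recall) (geometric mean). A zero denominator yields
#' 0 with a warning, so fold summaries stay total.
#'
#' @param tp,fp,fn,tn Nonnegative integer confusion counts (true/false
#'   positives/negatives).
#' @return A one-row tibble with `precision`, `recall`, `f1`, `g`.
#' @examples
#' information_indices(tp = 5, fp = 5, fn = 2, tn = 2)
#' @export
information_indices <- function(tp, fp, fn, tn) {
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("confusion counts must be nonnegative integers",
          class = "rankcbr_invalid_input")
  }
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warn(paste0(what, " denominator is zero; reporting 0"))
      0
    } else num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  indices_from_pr(precision, recall)
}

#' F-1 and G-measure from a precision/recall pair
#'
#' @param precision,recall Values in \[0, 1\].
#' @return A one-row tibble with `precision`, `recall`, `f1`, `g`.
#' @export
indices_from_pr <- function(precision, recall) {
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  tibble::tibble(precision = precision, recall = recall,
                 f1 = f1, g = sqrt(precision * recall))
}

# Confusion counts of predictions against truth (positive class = cancer).
confusion_counts <- function(truth, predicted) {
  list(tp = sum(truth == "cancer" & predicted == "cancer"),
       fp = sum(truth == "control" & predicted == "cancer"),
       fn = sum(truth == "cancer" & predicted == "control"),
       tn = sum(truth == "control" & predicted == "control"))
}

#' Summarise per-fold information indices
#'
#' MIN/AVG/STD/MAX per model and index over the cross-validation folds. STD
#' is the sample standard deviation (n - 1 denominator).
#'
#' @param fold_reports A tibble with columns `fold`, `model`, `precision`,
#'   `recall`, `f1`, `g` (one row per fold x model).
#' @return A tibble with columns `model`, `index`, `MIN`, `AVG`, `STD`,
#'   `MAX`.
#' @export
summarize_folds <- function(fold_reports) {
  if (!is.data.frame(fold_reports) || nrow(fold_reports) == 0) {
    abort("`fold_reports` must be a nonempty data frame",
          class = "rankcbr_invalid_input")
  }
  long <- tidyr::pivot_longer(
    fold_reports,
    dplyr::all_of(c("precision", "recall", "f1", "g")),
    names_to = "index", values_to = "value"
  )
  dplyr::summarise(
    dplyr::group_by(long, .data$model, .data$index),
    MIN = min(.data$value),
    AVG = mean(.data$value),
    STD = sd(.data$value),
    MAX = max(.data$value),
    .groups = "drop"
  )
}

#' Stratified k-fold assignment
#'
#' Shuffles each class independently (under the given seed) and deals its
#' members round-robin into the folds, so class proportions are equal across
#' folds up to rounding -- a balanced 70-subject cohort split 5 ways gives
#' every fold exactly 7 cancer and 7 control test cases (14 test, 56 train).
#'
#' @param labels Character vector of class labels.
#' @param k_folds Number of folds (>= 2, and at most the size of the
#'   smallest class).
#' @param seed Integer seed for the shuffle.
#' @return Integer vector of fold ids in `1..k_folds`, parallel to `labels`.
#' @export
stratified_kfold <- function(labels, k_folds = 5, seed = 1) {
  if (k_folds < 2) {
    abort("`k_folds` must be >= 2", class = "rankcbr_stratification_error")
  }
  if (k_folds > min(table(labels))) {
    abort("`k_folds` exceeds the size of the smallest class",
          class = "rankcbr_stratification_error")
  }
  assignment <- integer(length(labels))
  withr::with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- sample(idx)
      assignment[idx] <- rep_len(seq_len(k_folds), length(idx))
    }
  })
  assignment
}

#' k-nearest-neighbour baseline classifier
#'
#' Majority vote of the k nearest training cases under an unweighted global
#' distance: the sum over features of the local distances, each feature's
#' distances min--max scaled to \[0, 1\] across the training cases (raw sums
#' would be dominated by whichever feature happens to have the largest
#' units). A feature whose distances are constant contributes nothing. Vote
#' ties predict `"control"`.
#'
#' @param train,test Feature tibbles.
#' @param k Number of neighbours (default 5).
#' @param temps Temperature grid.
#' @return A tibble with one row per test case: `subject_id`, `label`
#'   (predicted) and `probability` (`p(cancer)` among the k neighbours).
#' @export
knn_baseline <- function(train, test, k = 5, temps = attr(train, "temps")) {
  if (k < 1 || k > nrow(train)) {
    abort(sprintf("`k` must lie in [1, %d]", nrow(train)),
          class = "rankcbr_retrieval_error")
  }
  purrr::map_dfr(seq_len(nrow(test)), function(i) {
    dists <- local_distance_table(train, test[i, ], temps = temps)
    scaled <- purrr::map(dists, function(d) {
      rng <- range(d)
      if (diff(rng) == 0) rep(0, length(d)) else (d - rng[1]) / diff(rng)
    })
    total <- Reduce(`+`, scaled)
    nbrs <- order(total, seq_along(total))[seq_len(k)]
    p_cancer <- mean(train$label[nbrs] == "cancer")
    tibble::tibble(subject_id = test$subject_id[i],
                   label = if (p_cancer > 0.5) "cancer" else "control",
                   probability = p_cancer)
  })
}

#' Composite coefficient of the SCUCC baseline
#'
#' Statistical classification using a composite coefficient: the target
#' curve is scored against the reference (control) curves by the weighted
#' product `c = rho_bar^P * p_bar`, where `rho_bar` is the mean Pearson
#' correlation between the target and each reference curve, and `p_bar` is
#' the mean over grid points of the two-sided normal tail probability of the
#' target value under the point-wise reference mean and standard deviation.
#' Grid points where the reference standard deviation is (numerically) zero
#' are skipped with a warning; if every point is degenerate, the tail
#' probability degrades to an exact-match indicator (its zero-variance
#' limit).
#'
#' @param reference Matrix of reference (control-class) curves, one row per
#'   case.
#' @param target Numeric target curve on the same grid.
#' @param P Weight factor of the composite coefficient (default 1).
#' @return The composite coefficient (a scalar; large means control-like).
#' @export
scucc_coefficient <- function(reference, target, P = 1) {
  reference <- as.matrix(reference)
  if (nrow(reference) < 2) {
    abort("SCUCC needs at least 2 reference curves",
          class = "rankcbr_invalid_input")
  }
  if (ncol(reference) != length(target)) {
    abort("target curve and reference grid lengths differ",
          class = "rankcbr_shape_error")
  }
  rho_bar <- mean(apply(reference, 1, function(r) {
    if (sd(r) == 0 || sd(target) == 0) return(0)
    cor(target, r)
  }))
  mu <- colMeans(reference)
  sdev <- apply(reference, 2, sd)
  ok <- sdev > 1e-12
  if (!all(ok)) {
    warn(sprintf("%d grid point(s) with degenerate reference sd skipped",
                 sum(!ok)))
  }
  if (any(ok)) {
    p_bar <- mean(2 * pnorm(-abs(target[ok] - mu[ok]) / sdev[ok]))
  } else {
    p_bar <- mean(abs(target - mu) < 1e-12)
  }
  rho_bar^P * p_bar
}

# Calibrate the SCUCC decision threshold on training composites: predict
# cancer when c < threshold; pick the threshold maximising training F1
# (candidates are midpoints of the sorted training composites plus the two
# outer extremes; ties resolve to the smallest candidate).
scucc_threshold <- function(composites, labels) {
  s <- sort(unique(composites))
  cand <- c(min(s) - 1, if (length(s) > 1) (utils::head(s, -1) + utils::tail(s, -1)) / 2,
            max(s) + 1)
  f1 <- vapply(cand, function(thr) {
    pred <- ifelse(composites < thr, "cancer", "control")
    cc <- confusion_counts(labels, pred)
    if (cc$tp == 0) 0 else 2 * cc$tp / (2 * cc$tp + cc$fp + cc$fn)
  }, numeric(1))
  cand[which.max(f1)]
}

#' Classify test curves with the SCUCC baseline
#'
#' Builds the reference set from the control-class training curves,
#' calibrates the decision threshold on the training composites (maximising
#' training F1), then labels each test curve `"control"` when its composite
#' coefficient is at or above the threshold and `"cancer"` otherwise.
#'
#' @param train,test Feature tibbles (the IND curves are used).
#' @param P Weight factor of the composite coefficient (default 1).
#' @return A tibble with one row per test case: `subject_id`, `label`
#'   (predicted) and `composite`.
#' @export
scucc_classify <- function(train, test, P = 1) {
  reference <- do.call(rbind, train$IND[train$label == "control"])
  comp_train <- vapply(train$IND, function(v) {
    suppressWarnings(scucc_coefficient(reference, v, P))
  }, numeric(1))
  thr <- scucc_threshold(comp_train, train$label)
  comp_test <- vapply(test$IND, function(v) {
    suppressWarnings(scucc_coefficient(reference, v, P))
  }, numeric(1))
  tibble::tibble(subject_id = test$subject_id,
                 label = ifelse(comp_test < thr, "cancer", "control"),
                 composite = comp_test)
}
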